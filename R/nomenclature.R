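## The f/d chromosome-name grammar.
##
##   name  := token ("f" token)*
##   token := INT ("d" INT)?
##
## "1f2"  - fusion of whole elements 1 and 2
## "3d1"  - first ancestral part of a fissioned element 3
## "5d1f6d1f6d3" - fusion of parts, in chromosome order
##
## d-indices number the retained parts of an element along the ancestral
## chromosome (part 1 = ancestral-first), so they stay dense even when
## internal ancestral material was lost. Chromosome orientation in an
## assembly is arbitrary; names are canonicalized to the numerically
## smaller of the two reading directions.

WHOLE <- NA_integer_

#' Construct a chromosome name
#'
#' @param element Integer vector of element ids, one per name part, in
#'   chromosome order.
#' @param part Integer vector of part indices (`NA` = whole element).
#' @return Object of class `chrom_name`.
#' @export
chrom_name <- function(element, part = rep(WHOLE, length(element))) {
  stopifnot(length(element) == length(part), length(element) >= 1L,
            all(element >= 1L), all(is.na(part) | part >= 1L))
  structure(list(element = as.integer(element), part = as.integer(part)),
            class = "chrom_name")
}

#' Print form of a chromosome name
#' @param name A [chrom_name()].
#' @return Single string.
#' @export
format_name <- function(name) {
  tok <- ifelse(is.na(name$part), name$element,
                paste0(name$element, "d", name$part))
  paste(tok, collapse = "f")
}

#' @export
format.chrom_name <- function(x, ...) format_name(x)

#' @export
print.chrom_name <- function(x, ...) {
  cat(format_name(x), "\n")
  invisible(x)
}

#' @export
`==.chrom_name` <- function(e1, e2) {
  identical(e1$element, e2$element) &&
    identical(is.na(e1$part), is.na(e2$part)) &&
    identical(e1$part[!is.na(e1$part)], e2$part[!is.na(e2$part)])
}

#' Parse a chromosome name
#'
#' Accepts the grammar `token ("f" token)*` with `token := INT ("d" INT)?`.
#' Leading zeros, `d0`, empty tokens and dangling separators are rejected
#' with the column position of the offence.
#'
#' @param text Name string.
#' @return A [chrom_name()].
#' @export
parse_name <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  if (n == 0L) stop_data("name syntax error at column 1: empty name")
  chars <- strsplit(text, "")[[1]]
  pos <- 1L
  els <- integer(0); prt <- integer(0)
  read_int <- function() {
    start <- pos
    while (pos <= n && chars[pos] %in% as.character(0:9)) pos <<- pos + 1L
    if (pos == start)
      stop_data("name syntax error at column ", start, ": expected integer")
    s <- paste(chars[start:(pos - 1L)], collapse = "")
    if (nchar(s) > 1L && substr(s, 1, 1) == "0")
      stop_data("name syntax error at column ", start, ": leading zero")
    as.integer(s)
  }
  repeat {
    e <- read_int()
    if (e < 1L)
      stop_data("name syntax error: element id must be >= 1")
    p <- WHOLE
    if (pos <= n && chars[pos] == "d") {
      dcol <- pos
      pos <- pos + 1L
      p <- read_int()
      if (p < 1L)
        stop_data("name syntax error at column ", dcol + 1L, ": d0 part index")
    }
    els <- c(els, e); prt <- c(prt, p)
    if (pos > n) break
    if (chars[pos] != "f")
      stop_data("name syntax error at column ", pos, ": expected 'f'")
    pos <- pos + 1L
    if (pos > n)
      stop_data("name syntax error at column ", pos, ": dangling 'f'")
  }
  chrom_name(els, prt)
}

## numeric-lexicographic comparison of part sequences; WHOLE sorts before
## any numbered part of the same element
name_key <- function(name) {
  rbind(name$element, ifelse(is.na(name$part), 0L, name$part))
}

key_less <- function(a, b) {
  la <- ncol(a); lb <- ncol(b)
  for (i in seq_len(min(la, lb))) {
    if (a[1, i] != b[1, i]) return(a[1, i] < b[1, i])
    if (a[2, i] != b[2, i]) return(a[2, i] < b[2, i])
  }
  la < lb
}

#' Reverse a chromosome name (opposite reading direction)
#' @param name A [chrom_name()].
#' @return A [chrom_name()].
#' @export
reverse_name <- function(name) {
  chrom_name(rev(name$element), rev(name$part))
}

#' Canonicalize a chromosome name
#'
#' Returns the numerically smaller of the name and its reversal (element
#' id, then part index, compared position by position). Idempotent and
#' invariant to the assembly's arbitrary strand choice.
#'
#' @param name A [chrom_name()] or a name string.
#' @return A [chrom_name()].
#' @export
canonicalize_name <- function(name) {
  if (is.character(name)) name <- parse_name(name)
  r <- reverse_name(name)
  if (key_less(name_key(r), name_key(name))) r else name
}

#' Derive chromosome names for one species
#'
#' Requires the genome-wide decomposition: an element split over several
#' segments receives d-indices by ranking its segments on the median
#' intra-element ancestral order of their genes (part 1 = ancestral-first).
#' When no intra-element order is available the fallback ranks parts by
#' descending gene count, with a warning. A chromosome's name is its
#' segments' tokens joined by `f` in chromosome order, canonicalized.
#' W chromosomes are never renamed and keep their input name; chromosomes
#' with no segments are left unnamed (`NA`).
#'
#' @param comp A `species_composition` from [decompose()].
#' @param elements An [ancestral_elements()] object.
#' @param genome Optional [genome_table()]; if supplied, W-labelled
#'   chromosomes keep their input name and all chromosomes (even empty
#'   ones) are listed.
#' @return data.frame with columns `species`, `chrom`, `name`,
#'   `n_segments`, `renamed`; attribute `"parts"` holds the per-segment
#'   part assignment (segments table with a `part` column and `token`).
#' @export
name_chromosomes <- function(comp, elements, genome = NULL) {
  s <- comp$segments
  s$part <- NA_integer_
  ## genome-wide d-indices per element
  for (e in unique(s$element)) {
    rows <- which(s$element == e)
    if (length(rows) < 2L) next
    med <- s$med_order[rows]
    if (any(is.na(med))) {
      warning("element ", e, " split but no intra-element order; ",
              "parts ranked by descending gene count", call. = FALSE)
      o <- order(-s$n_genes[rows], s$chrom[rows], s$seg_index[rows])
    } else {
      o <- order(med, s$chrom[rows], s$seg_index[rows])
    }
    s$part[rows[o]] <- seq_along(rows)
  }
  s$token <- ifelse(is.na(s$part), as.character(s$element),
                    paste0(s$element, "d", s$part))

  chroms <- if (!is.null(genome)) genome$chroms$chrom else unique(s$chrom)
  wlab <- if (!is.null(genome))
    genome$chroms$chrom[genome$chroms$sex_label == "W"] else character(0)
  out <- data.frame(species = comp$species, chrom = chroms,
                    name = NA_character_, n_segments = 0L, renamed = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    ch <- out$chrom[i]
    if (ch %in% wlab) { out$name[i] <- ch; next }
    rows <- which(s$chrom == ch)
    if (!length(rows)) next
    rows <- rows[order(s$seg_index[rows])]
    nm <- canonicalize_name(chrom_name(s$element[rows], s$part[rows]))
    out$name[i] <- format_name(nm)
    out$n_segments[i] <- length(rows)
    out$renamed[i] <- TRUE
  }
  attr(out, "parts") <- s
  out
}

#' Fusion and fission event labels for one species
#'
#' One fusion label per adjacent segment pair on every chromosome (printed
#' as the two tokens joined by `f`, in the canonical name orientation) and
#' one fission label per element split into k >= 2 parts, printed
#' `<element>d-<k>`.
#'
#' @param naming Result of [name_chromosomes()].
#' @return data.frame with columns `species`, `kind`, `label`, `chrom`
#'   (`NA` for fission labels), `element`.
#' @export
event_labels <- function(naming) {
  s <- attr(naming, "parts")
  out <- list()
  for (i in seq_len(nrow(naming))) {
    ch <- naming$chrom[i]
    rows <- which(s$chrom == ch)
    if (length(rows) < 2L) next
    rows <- rows[order(s$seg_index[rows])]
    tok <- s$token[rows]
    ## use canonical orientation so labels match the printed name
    nm <- chrom_name(s$element[rows], s$part[rows])
    if (key_less(name_key(reverse_name(nm)), name_key(nm))) tok <- rev(tok)
    for (j in seq_len(length(tok) - 1L))
      out[[length(out) + 1L]] <- data.frame(
        species = naming$species[i], kind = "fusion",
        label = paste0(tok[j], "f", tok[j + 1L]), chrom = ch,
        element = NA_integer_, stringsAsFactors = FALSE)
  }
  ks <- table(s$element[!is.na(s$part)])
  for (e in names(ks)) {
    k <- max(s$part[s$element == as.integer(e)], na.rm = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      species = unique(naming$species), kind = "fission",
      label = paste0(e, "d-", k), chrom = NA_character_,
      element = as.integer(e), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(species = character(), kind = character(),
                      label = character(), chrom = character(),
                      element = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a random valid chromosome name (testing utility)
#' @param max_element Largest element id to draw from.
#' @param max_parts Largest d-index.
#' @param max_tokens Maximum number of fused tokens.
#' @return A [chrom_name()].
#' @export
random_name <- function(max_element = 31L, max_parts = 4L, max_tokens = 5L) {
  k <- sample.int(max_tokens, 1L)
  el <- sample.int(max_element, k, replace = TRUE)
  pr <- ifelse(stats::runif(k) < 0.5, WHOLE,
               sample.int(max_parts, k, replace = TRUE))
  chrom_name(el, as.integer(pr))
}
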