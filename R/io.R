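## Core domain containers and readers/writers.
##
## Internal coordinate convention: 0-based, half-open [start, end) in base
## pairs, everywhere. Readers convert on the way in (GFF3 is 1-based
## inclusive), writers convert back. BED is already half-open and is used
## as-is.

TE_CLASSES <- c("DNA", "LINE", "LTR", "RC", "SINE", "Unknown")

#' Transposable-element class vocabulary
#'
#' The six repeat classes used throughout: DNA transposons, LINEs, LTR
#' retrotransposons, rolling-circle (Helitron) elements, SINEs, and
#' unclassified repeats.
#'
#' @return Character vector of class labels.
#' @export
te_classes <- function() TE_CLASSES

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(paste0(...), call. = FALSE)

#' Construct a genome table
#'
#' Bundles one species' gene coordinates with its chromosome metadata and
#' builds the per-chromosome gene-order rank index. Ranks are 1-based along
#' each chromosome, ordered by start coordinate with deterministic
#' tie-breaking by end coordinate and then gene id.
#'
#' @param species Species name (single string).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand` (`+`, `-` or `*` for unknown). Coordinates are
#'   0-based half-open.
#' @param chroms Optional data.frame with columns `chrom`, `sex_label`
#'   (`A`, `Z` or `W`), `length_bp` and optionally `gc`. Chromosomes absent
#'   from `chroms` but present in `genes` are an error when `chroms` is
#'   given; when `chroms` is `NULL` metadata is derived (label `A`,
#'   `length_bp` = max gene end).
#' @param neo_sex Set `TRUE` to allow more than one Z- or W-labelled
#'   chromosome (neo-sex-chromosome systems).
#' @return An object of class `genome_table`: a list with elements
#'   `species`, `genes` (sorted by chromosome and rank, with a `rank`
#'   column) and `chroms`.
#' @export
genome_table <- function(species, genes, chroms = NULL, neo_sex = FALSE) {
  stopifnot(is.character(species), length(species) == 1L)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop_data("gene table for '", species, "' lacks column(s): ",
              paste(miss, collapse = ", "))
  if (is.null(genes$strand)) genes$strand <- "*"
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  bad <- which(!(genes$start >= 0 & genes$start < genes$end))
  if (length(bad))
    stop_data("invalid coordinates (need 0 <= start < end) for gene(s) ",
              paste(utils::head(genes$gene_id[bad], 5), collapse = ", "),
              " of species '", species, "'")
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    stop_data("duplicate gene id(s) in species '", species, "': ",
              paste(unique(utils::head(dup, 5)), collapse = ", "))

  if (is.null(chroms)) {
    len <- tapply(genes$end, genes$chrom, max)
    chroms <- data.frame(chrom = names(len), sex_label = "A",
                         length_bp = as.numeric(len), gc = NA_real_,
                         stringsAsFactors = FALSE)
  } else {
    chroms <- as.data.frame(chroms, stringsAsFactors = FALSE)
    if (!all(c("chrom", "sex_label", "length_bp") %in% names(chroms)))
      stop_data("chromosome metadata needs columns chrom, sex_label, length_bp")
    if (is.null(chroms$gc)) chroms$gc <- NA_real_
    chroms$chrom <- as.character(chroms$chrom)
    undecl <- setdiff(unique(genes$chrom), chroms$chrom)
    if (length(undecl))
      stop_data("species '", species, "': gene(s) on undeclared chromosome(s): ",
                paste(undecl, collapse = ", "))
    if (!all(chroms$sex_label %in% c("A", "Z", "W")))
      stop_data("sex_label must be one of A, Z, W")
    for (lab in c("Z", "W")) {
      if (!neo_sex && sum(chroms$sex_label == lab) > 1L)
        stop_data("species '", species, "': more than one ", lab,
                  "-labelled chromosome (set neo_sex = TRUE to allow)")
    }
    mx <- tapply(genes$end, genes$chrom, max)
    short <- names(mx)[mx > chroms$length_bp[match(names(mx), chroms$chrom)]]
    if (length(short))
      stop_data("species '", species, "': chromosome length_bp smaller than ",
                "max gene end on: ", paste(short, collapse = ", "))
  }
  ## rank index: start, then end, then gene_id (stable, deterministic)
  o <- order(genes$chrom, genes$start, genes$end, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                           FUN = seq_along)
  rownames(genes) <- NULL
  structure(list(species = species, genes = genes, chroms = chroms),
            class = "genome_table")
}

#' @export
print.genome_table <- function(x, ...) {
  cat("genome_table: ", x$species, " - ", nrow(x$genes), " genes on ",
      nrow(x$chroms), " chromosomes\n", sep = "")
  invisible(x)
}

#' Read a gene map into a genome table
#'
#' @param path File path.
#' @param dialect One of `"tsv"` (project dialect: header
#'   `species gene_id chrom start end strand`, 0-based half-open), `"gff3"`
#'   (gene features; 1-based inclusive, converted internally) or `"bed"`
#'   (`chrom start end name [score strand]`, used as-is).
#' @param species Species name; required for gff3/bed, optional check for tsv.
#' @param chrom_meta Optional chromosome metadata data.frame or path to a
#'   metadata TSV (`species chrom sex_label length_bp [gc]`).
#' @param ... Passed to [genome_table()].
#' @return A [genome_table()].
#' @export
read_gene_map <- function(path, dialect = c("tsv", "gff3", "bed"),
                          species = NULL, chrom_meta = NULL, ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_data("file not found: ", path)
  if (is.character(chrom_meta)) chrom_meta <- read_chrom_meta(chrom_meta)
  genes <- switch(dialect,
    tsv = {
      d <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
      need <- c("species", "gene_id", "chrom", "start", "end")
      if (!all(need %in% names(d)))
        stop_data("gene map TSV needs header columns ",
                  paste(need, collapse = ", "))
      sp <- unique(d$species)
      if (length(sp) != 1L)
        stop_data("gene map TSV must contain exactly one species, found: ",
                  paste(sp, collapse = ", "))
      if (!is.null(species) && species != sp)
        stop_data("gene map species '", sp, "' does not match '", species, "'")
      species <- sp
      data.frame(gene_id = d$gene_id, chrom = d$chrom,
                 start = as.numeric(d$start), end = as.numeric(d$end),
                 strand = d$strand %||% "*", stringsAsFactors = FALSE)
    },
    gff3 = {
      if (is.null(species)) stop_data("species is required for GFF3 input")
      ln <- readLines(path)
      keep <- !grepl("^#", ln) & nzchar(ln)
      idx <- which(keep)
      fld <- strsplit(ln[keep], "\t", fixed = TRUE)
      nf <- lengths(fld)
      if (any(nf < 9))
        stop_data("malformed GFF3 line ", idx[which(nf < 9)[1]], " in ", path)
      m <- do.call(rbind, fld)
      gene <- m[, 3] == "gene"
      if (!any(gene)) gene <- rep(TRUE, nrow(m))  # plain gene lists
      m <- m[gene, , drop = FALSE]
      ids <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
      noid <- !grepl("ID=", m[, 9])
      if (any(noid)) ids[noid] <- paste0("feat", which(noid))
      data.frame(gene_id = ids, chrom = m[, 1],
                 start = as.numeric(m[, 4]) - 1, end = as.numeric(m[, 5]),
                 strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "*"),
                 stringsAsFactors = FALSE)
    },
    bed = {
      if (is.null(species)) stop_data("species is required for BED input")
      d <- utils::read.table(path, stringsAsFactors = FALSE)
      if (ncol(d) < 4) stop_data("gene BED needs >= 4 columns (name in col 4)")
      data.frame(gene_id = as.character(d[[4]]), chrom = as.character(d[[1]]),
                 start = as.numeric(d[[2]]), end = as.numeric(d[[3]]),
                 strand = if (ncol(d) >= 6) d[[6]] else "*",
                 stringsAsFactors = FALSE)
    })
  cm <- NULL
  if (!is.null(chrom_meta)) {
    cm <- chrom_meta[chrom_meta$species == species,
                     c("chrom", "sex_label", "length_bp",
                       intersect("gc", names(chrom_meta)))]
  }
  genome_table(species, genes, chroms = cm, ...)
}

#' Read chromosome metadata TSV
#'
#' Columns `species chrom sex_label length_bp [gc]`.
#' @param path File path.
#' @return data.frame.
#' @export
read_chrom_meta <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "chrom", "sex_label", "length_bp")
  if (!all(need %in% names(d)))
    stop_data("chromosome metadata needs columns ", paste(need, collapse = ", "))
  d$chrom <- as.character(d$chrom)
  if (is.null(d$gc)) d$gc <- NA_real_
  d
}

#' Write a genome table as a project-dialect gene map TSV
#' @param genome A [genome_table()].
#' @param path Output path.
#' @export
write_gene_map <- function(genome, path) {
  g <- genome$genes
  out <- data.frame(species = genome$species, gene_id = g$gene_id,
                    chrom = g$chrom, start = g$start, end = g$end,
                    strand = g$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- orthology ----

#' Construct an orthology table
#'
#' Long-format orthogroup membership: one row per gene. A gene may belong to
#' at most one orthogroup.
#'
#' @param df data.frame with columns `orthogroup`, `species`, `gene_id`.
#' @return Object of class `orthology_table` (a data.frame).
#' @export
orthology_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("orthogroup", "species", "gene_id") %in% names(df)))
  df$orthogroup <- as.character(df$orthogroup)
  df$species <- as.character(df$species)
  df$gene_id <- as.character(df$gene_id)
  key <- paste(df$species, df$gene_id, sep = "\r")
  dup <- df[duplicated(key) | duplicated(key, fromLast = TRUE), , drop = FALSE]
  if (nrow(dup)) {
    multi <- unique(dup$gene_id[stats::ave(as.integer(factor(dup$orthogroup)),
      paste(dup$species, dup$gene_id, sep = "\r"),
      FUN = function(z) length(unique(z))) > 1])
    if (length(multi))
      stop_data("gene(s) listed under more than one orthogroup: ",
                paste(utils::head(multi, 5), collapse = ", "))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("orthology_table", "data.frame")
  df
}

#' Read a wide orthogroup TSV
#'
#' First column is the orthogroup id; one column per species holding
#' comma-separated gene ids (the common orthogroup-table layout). Empty
#' cells mean no member in that species.
#'
#' @param path File path.
#' @return An [orthology_table()].
#' @export
read_orthogroups <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (ncol(d) < 2) stop_data("orthogroup table needs >= 2 columns")
  og <- d[[1]]
  sp <- names(d)[-1]
  rows <- list()
  for (j in seq_along(sp)) {
    cells <- d[[j + 1]]
    genes <- strsplit(cells, "\\s*,\\s*")
    n <- lengths(genes)
    has <- n > 0
    v <- unlist(genes, use.names = FALSE)
    v <- v[nzchar(v)]
    reps <- vapply(genes, function(g) sum(nzchar(g)), 1L)
    rows[[j]] <- data.frame(orthogroup = rep(og, reps), species = sp[j],
                            gene_id = v, stringsAsFactors = FALSE)
  }
  orthology_table(do.call(rbind, rows))
}

#' Write an orthology table in the wide orthogroup TSV dialect
#' @param orth An [orthology_table()].
#' @param path Output path.
#' @export
write_orthogroups <- function(orth, path) {
  sp <- sort(unique(orth$species))
  ogs <- unique(orth$orthogroup)
  wide <- matrix("", nrow = length(ogs), ncol = length(sp),
                 dimnames = list(ogs, sp))
  agg <- stats::aggregate(gene_id ~ orthogroup + species, data = orth,
                          FUN = function(g) paste(g, collapse = ","))
  wide[cbind(match(agg$orthogroup, ogs), match(agg$species, sp))] <- agg$gene_id
  out <- data.frame(orthogroup_id = ogs, wide, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("orthogroup_id", sp)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep low-copy orthogroups
#'
#' Retains orthogroups in which no species has more than `max_copies`
#' members, the filter used before ancestral-genome work (excess copies
#' confound both element inference and the duplication tally).
#'
#' @param orth An [orthology_table()].
#' @param max_copies Maximum per-species copy number (default 2).
#' @return Filtered [orthology_table()].
#' @export
filter_low_copy <- function(orth, max_copies = 2L) {
  stopifnot(max_copies >= 1L)
  cnt <- table(orth$orthogroup, orth$species)
  keep <- rownames(cnt)[apply(cnt, 1, max) <= max_copies]
  out <- orth[orth$orthogroup %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("orthology_table", "data.frame")
  out
}

#' Map gene ids of one species to their orthogroup
#' @param orth An [orthology_table()].
#' @param species Species name.
#' @return Named character vector gene_id -> orthogroup.
#' @export
gene_orthogroup_map <- function(orth, species) {
  s <- orth[orth$species == species, , drop = FALSE]
  stats::setNames(s$orthogroup, s$gene_id)
}

## ---- trees ----

#' Read a rooted species tree (Newick)
#'
#' @param path File path.
#' @param species Optional species names that must all be tree leaves;
#'   mismatches are an error listing the missing names.
#' @return An `ape` `phylo` object.
#' @export
read_species_tree <- function(path, species = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop_data("could not parse Newick tree: ", path)
  if (!is.null(species)) {
    miss <- setdiff(species, tr$tip.label)
    if (length(miss))
      stop_data("species missing from tree: ", paste(miss, collapse = ", "))
  }
  tr
}

#' Write a species tree (Newick)
#' @param tree `phylo` object.
#' @param path Output path.
#' @export
write_species_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

## ---- interval tracks ----

#' Construct an interval track
#'
#' @param species Species name.
#' @param intervals data.frame with columns `chrom`, `start`, `end`,
#'   `class` (half-open coordinates).
#' @param classes Allowed class vocabulary; defaults to [te_classes()].
#'   Use `NULL` to skip the vocabulary check.
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   check `end <= length`.
#' @return Object of class `interval_track` (a data.frame with a `species`
#'   attribute).
#' @export
interval_track <- function(species, intervals, classes = te_classes(),
                           chrom_lengths = NULL) {
  d <- as.data.frame(intervals, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "class") %in% names(d)))
  d$chrom <- as.character(d$chrom)
  d$start <- as.numeric(d$start)
  d$end <- as.numeric(d$end)
  d$class <- as.character(d$class)
  if (any(!(d$start >= 0 & d$start < d$end)))
    stop_data("interval track '", species, "': need 0 <= start < end")
  if (!is.null(classes)) {
    bad <- setdiff(unique(d$class), classes)
    if (length(bad))
      stop_data("interval class(es) outside vocabulary: ",
                paste(bad, collapse = ", "))
  }
  if (!is.null(chrom_lengths)) {
    L <- chrom_lengths[d$chrom]
    if (any(is.na(L)) || any(d$end > L))
      stop_data("interval beyond declared chromosome length in '", species, "'")
  }
  rownames(d) <- NULL
  attr(d, "species") <- species
  class(d) <- c("interval_track", "data.frame")
  d
}

#' Read an interval track (BED or RepeatMasker out)
#'
#' BED: columns `chrom start end class`. RepeatMasker `.out`: the
#' repeat class/family field is collapsed onto the six TE classes
#' (`DNA* -> DNA`, `LINE* -> LINE`, `SINE* -> SINE`, `LTR* -> LTR`,
#' `RC*`/Helitron `-> RC`, anything else `-> Unknown`); coordinates are
#' converted from 1-based inclusive to half-open.
#'
#' @param path File path.
#' @param species Species name.
#' @param dialect `"bed"` or `"rm"`.
#' @param ... Passed to [interval_track()].
#' @return An [interval_track()].
#' @export
read_intervals <- function(path, species, dialect = c("bed", "rm"), ...) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    d <- utils::read.table(path, stringsAsFactors = FALSE)
    if (ncol(d) < 4) stop_data("interval BED needs 4 columns (class in col 4)")
    iv <- data.frame(chrom = d[[1]], start = d[[2]], end = d[[3]],
                     class = d[[4]], stringsAsFactors = FALSE)
  } else {
    ln <- readLines(path)
    ln <- ln[-seq_len(min(3L, length(ln)))]   # header block
    ln <- trimws(ln[nzchar(trimws(ln))])
    fld <- strsplit(ln, "\\s+")
    m <- do.call(rbind, lapply(fld, function(x) x[c(5, 6, 7, 11)]))
    cls <- m[, 4]
    class6 <- ifelse(grepl("^DNA", cls), "DNA",
              ifelse(grepl("^LINE", cls), "LINE",
              ifelse(grepl("^SINE", cls), "SINE",
              ifelse(grepl("^LTR", cls), "LTR",
              ifelse(grepl("^RC|Helitron", cls), "RC", "Unknown")))))
    iv <- data.frame(chrom = m[, 1], start = as.numeric(m[, 2]) - 1,
                     end = as.numeric(m[, 3]), class = class6,
                     stringsAsFactors = FALSE)
  }
  interval_track(species, iv, ...)
}

#' Write an interval track as BED
#' @param track An [interval_track()].
#' @param path Output path.
#' @export
write_intervals <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "class")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Per-chromosome GC fraction from a FASTA file
#'
#' GC is (G+C)/(A+C+G+T), case-insensitive, ambiguity codes ignored.
#' Requires the Biostrings package.
#'
#' @param path FASTA path.
#' @return Named numeric vector of GC fractions.
#' @export
gc_from_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop_data("gc_from_fasta() needs the Biostrings package")
  s <- Biostrings::readDNAStringSet(path)
  f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  gc <- (f[, "G"] + f[, "C"]) / pmax(1, rowSums(f))
  stats::setNames(as.numeric(gc), sub("\\s.*", "", names(s)))
}
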