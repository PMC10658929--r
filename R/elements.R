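## Ancestral elements: the numbered ancestral chromosomes that act as the
## conserved building blocks of extant karyotypes (the moth-and-butterfly
## analogue of Muller/Nigon elements). This module infers the element
## partition of orthogroups from rearrangement-free backbone species,
## assigns extant chromosomes to elements by shared orthologous gene
## content, and decomposes chromosomes into ordered element segments.

#' Construct an ancestral element set
#'
#' @param membership data.frame with columns `element` (positive integer,
#'   1..K dense), `orthogroup`, and optionally `order_rank` (intra-element
#'   ancestral gene order, 1-based).
#' @param z_element Element id carrying the Z chromosome, or `NA`.
#' @param unassigned Character vector of orthogroups that could not be
#'   placed in any element (reported, never silently assigned).
#' @return Object of class `ancestral_elements`.
#' @export
ancestral_elements <- function(membership, z_element = NA_integer_,
                               unassigned = character()) {
  m <- as.data.frame(membership, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "orthogroup") %in% names(m)))
  m$element <- as.integer(m$element)
  m$orthogroup <- as.character(m$orthogroup)
  if (is.null(m$order_rank)) m$order_rank <- NA_real_
  ids <- sort(unique(m$element))
  if (length(ids) && !identical(ids, seq_len(max(ids))))
    stop_data("element ids must be 1..K with no gaps")
  if (anyDuplicated(m$orthogroup))
    stop_data("orthogroup assigned to more than one element")
  m <- m[order(m$element, m$order_rank, m$orthogroup), , drop = FALSE]
  rownames(m) <- NULL
  structure(list(membership = m, z_element = as.integer(z_element),
                 unassigned = unassigned),
            class = "ancestral_elements")
}

#' @export
print.ancestral_elements <- function(x, ...) {
  k <- length(unique(x$membership$element))
  cat("ancestral_elements: ", k, " elements, ", nrow(x$membership),
      " orthogroups", if (!is.na(x$z_element))
        paste0(" (Z = element ", x$z_element, ")"), "\n", sep = "")
  invisible(x)
}

#' Number of elements
#' @param elements An [ancestral_elements()] object.
#' @return Integer count.
#' @export
n_elements <- function(elements) length(unique(elements$membership$element))

#' Orthogroup -> element lookup
#' @param elements An [ancestral_elements()] object.
#' @return Named integer vector.
#' @export
element_map <- function(elements) {
  stats::setNames(elements$membership$element, elements$membership$orthogroup)
}

order_map <- function(elements) {
  stats::setNames(elements$membership$order_rank,
                  elements$membership$orthogroup)
}

#' Infer ancestral elements from backbone species
#'
#' Backbone species are extant species judged to retain the ancestral
#' karyotype (no inter-chromosomal rearrangement on their lineages). Their
#' chromosomes are clustered into orthologous groups: a graph is built with
#' one node per backbone chromosome and an edge whenever two chromosomes of
#' different species share at least `threshold` orthogroups; each connected
#' component becomes one element. An orthogroup joins the element holding
#' the majority of its backbone placements (ties are left unassigned and
#' reported). Elements are numbered by descending orthogroup count (ties by
#' smallest contained orthogroup id); the element holding the most
#' Z-labelled backbone chromosomes is flagged as the Z element. Intra-element
#' order is taken from the first-listed backbone species' gene order (genes
#' absent there are appended following the later backbone species).
#'
#' @param genomes List of [genome_table()] objects (named or not).
#' @param orth Low-copy-filtered [orthology_table()].
#' @param backbone Character vector of backbone species names, first one
#'   donating the intra-element order.
#' @param threshold Minimum shared orthogroups for a chromosome-pair edge
#'   (default 8).
#' @return An [ancestral_elements()] object. Warnings flag components mixing
#'   Z- and A-labelled chromosomes and a component count differing from the
#'   backbone karyotype.
#' @export
infer_elements <- function(genomes, orth, backbone, threshold = 8L) {
  gmap <- stats::setNames(genomes, vapply(genomes, `[[`, "", "species"))
  miss <- setdiff(backbone, names(gmap))
  if (length(miss))
    stop_data("backbone species without genomes: ", paste(miss, collapse = ", "))
  kary <- vapply(backbone, function(s) nrow(gmap[[s]]$chroms), 1L)
  if (length(unique(kary)) != 1L)
    stop_data("backbone species differ in chromosome count: ",
              paste(paste0(backbone, "=", kary), collapse = ", "))

  ## orthogroup -> chromosome per backbone species (majority chromosome of
  ## its copies; deterministic tie-break by chromosome name)
  og_chrom <- list()
  for (s in backbone) {
    g <- gmap[[s]]$genes
    om <- gene_orthogroup_map(orth, s)
    og <- om[g$gene_id]
    keep <- !is.na(og)
    t2 <- table(og[keep], g$chrom[keep])
    og_chrom[[s]] <- stats::setNames(colnames(t2)[apply(t2, 1, which.max)],
                                     rownames(t2))
  }

  ## chromosome-pair graph across species
  nodes <- unlist(lapply(backbone, function(s)
    paste(s, gmap[[s]]$chroms$chrom, sep = "\r")), use.names = FALSE)
  edges <- character(0)
  for (i in seq_along(backbone)) for (j in seq_along(backbone)) {
    if (j <= i) next
    a <- og_chrom[[backbone[i]]]; b <- og_chrom[[backbone[j]]]
    shared <- intersect(names(a), names(b))
    if (!length(shared)) next
    cnt <- table(a[shared], b[shared])
    hit <- which(cnt >= threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      edges <- c(edges,
                 rbind(paste(backbone[i], rownames(cnt)[hit[, 1]], sep = "\r"),
                       paste(backbone[j], colnames(cnt)[hit[, 2]], sep = "\r")))
    }
  }
  gr <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(nodes)
  if (length(edges)) gr <- gr + igraph::edges(edges)
  comp <- igraph::components(gr)$membership

  singleton <- names(comp)[comp %in% which(tabulate(comp) == 1)]
  if (length(backbone) > 1L && length(singleton))
    warning(length(singleton), " backbone chromosome(s) share < ", threshold,
            " orthogroups with every other backbone chromosome",
            call. = FALSE)
  if (max(comp) != kary[1])
    warning("component count (", max(comp), ") differs from backbone ",
            "karyotype (", kary[1], ")", call. = FALSE)

  ## Z/A mixing check
  sexlab <- unlist(lapply(backbone, function(s) {
    cm <- gmap[[s]]$chroms
    stats::setNames(cm$sex_label, paste(s, cm$chrom, sep = "\r"))
  }))
  for (k in seq_len(max(comp))) {
    labs <- sexlab[names(comp)[comp == k]]
    if (length(unique(labs[labs != "W"])) > 1L)
      warning("component ", k, " mixes sex labels: ",
              paste(names(table(labs)), table(labs), collapse = ", ",
                    sep = "="), call. = FALSE)
  }

  ## orthogroup -> component by majority vote over backbone placements
  all_ogs <- sort(unique(unlist(lapply(og_chrom, names), use.names = FALSE)))
  votes <- lapply(all_ogs, function(o) {
    v <- integer(0)
    for (s in backbone) {
      ch <- og_chrom[[s]][o]
      if (!is.na(ch)) v <- c(v, comp[[paste(s, ch, sep = "\r")]])
    }
    v
  })
  maj <- vapply(votes, function(v) {
    tb <- sort(table(v), decreasing = TRUE)
    if (length(tb) > 1L && tb[1] == tb[2]) NA_integer_
    else as.integer(names(tb)[1])
  }, 1L)
  unassigned <- all_ogs[is.na(maj)]
  ogdf <- data.frame(orthogroup = all_ogs[!is.na(maj)],
                     comp = maj[!is.na(maj)], stringsAsFactors = FALSE)
  if (!nrow(ogdf)) {
    warning("no orthogroup could be assigned to an element ",
            "(all placements tied)", call. = FALSE)
    return(ancestral_elements(
      data.frame(element = integer(), orthogroup = character(),
                 order_rank = numeric()), unassigned = unassigned))
  }

  ## renumber components by descending orthogroup count, tie by smallest og
  sizes <- table(ogdf$comp)
  minog <- tapply(ogdf$orthogroup, ogdf$comp, min)
  ord <- order(-as.integer(sizes[as.character(seq_len(max(comp)))]),
               minog[as.character(seq_len(max(comp)))])
  renum <- integer(max(comp)); renum[ord] <- seq_len(max(comp))
  ogdf$element <- renum[ogdf$comp]

  ## Z element: component with most Z-labelled backbone chromosomes
  zl <- names(sexlab)[sexlab == "Z"]
  z_el <- NA_integer_
  if (length(zl)) {
    zc <- table(renum[comp[zl]])
    z_el <- as.integer(names(zc)[which.max(zc)])
  }

  ## intra-element order from the backbone species in listed order
  rank_of <- list()
  for (s in backbone) {
    g <- gmap[[s]]$genes
    om <- gene_orthogroup_map(orth, s)
    og <- om[g$gene_id]
    keep <- !is.na(og) & !duplicated(og)
    pos <- order(match(g$chrom[keep], gmap[[s]]$chroms$chrom), g$rank[keep])
    rank_of[[s]] <- stats::setNames(seq_along(pos), og[keep][pos])
  }
  ogdf$order_rank <- NA_real_
  for (el in unique(ogdf$element)) {
    rows <- which(ogdf$element == el)
    placed <- logical(length(rows))
    nxt <- 1L
    for (s in backbone) {
      r <- rank_of[[s]][ogdf$orthogroup[rows]]
      new <- !placed & !is.na(r)
      if (!any(new)) next
      o <- order(r[new])
      ogdf$order_rank[rows[new][o]] <- seq.int(nxt, nxt + sum(new) - 1L)
      placed[new] <- TRUE
      nxt <- nxt + sum(new)
    }
  }
  ancestral_elements(ogdf[, c("element", "orthogroup", "order_rank")],
                     z_element = z_el, unassigned = unassigned)
}

#' Read / write element definition TSV
#'
#' Columns `element_id orthogroup_id order_rank is_Z` (order_rank may be
#' empty; is_Z is 0/1).
#' @param path File path.
#' @return An [ancestral_elements()] object.
#' @export
read_elements <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("element_id", "orthogroup_id")
  if (!all(need %in% names(d)))
    stop_data("element TSV needs columns ", paste(need, collapse = ", "))
  z <- NA_integer_
  if (!is.null(d$is_Z) && any(d$is_Z == 1))
    z <- unique(d$element_id[d$is_Z == 1])
  if (length(z) > 1) stop_data("more than one element flagged Z")
  ancestral_elements(data.frame(element = d$element_id,
                                orthogroup = d$orthogroup_id,
                                order_rank = d$order_rank %||% NA_real_),
                     z_element = z)
}

#' @rdname read_elements
#' @param elements An [ancestral_elements()] object.
#' @export
write_elements <- function(elements, path) {
  m <- elements$membership
  out <- data.frame(element_id = m$element, orthogroup_id = m$orthogroup,
                    order_rank = m$order_rank,
                    is_Z = as.integer(!is.na(elements$z_element) &
                                        m$element == elements$z_element))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign extant chromosomes to ancestral elements
#'
#' A chromosome is assigned every element with which it shares at least
#' `threshold` orthologous genes (counted over the chromosome's gene copies
#' whose orthogroup belongs to the element). Chromosomes with an empty
#' element set are unassigned - the typical situation for W chromosomes,
#' which carry no ancestral orthologs.
#'
#' @param genome A [genome_table()].
#' @param orth An [orthology_table()].
#' @param elements An [ancestral_elements()] object.
#' @param threshold Minimum shared gene count (default 8).
#' @return Object of class `assignment_table`: data.frame with columns
#'   `species`, `chrom`, `element`, `n_shared`, `assigned` retaining all
#'   nonzero counts; assigned rows meet the threshold.
#' @export
assign_chromosomes <- function(genome, orth, elements, threshold = 8L) {
  om <- gene_orthogroup_map(orth, genome$species)
  em <- element_map(elements)
  g <- genome$genes
  el <- em[om[g$gene_id]]
  keep <- !is.na(el)
  if (!any(keep)) {
    out <- data.frame(species = character(), chrom = character(),
                      element = integer(), n_shared = integer(),
                      assigned = logical())
  } else {
    cnt <- as.data.frame(table(chrom = g$chrom[keep], element = el[keep]),
                         stringsAsFactors = FALSE)
    cnt <- cnt[cnt$Freq > 0, , drop = FALSE]
    out <- data.frame(species = genome$species, chrom = cnt$chrom,
                      element = as.integer(cnt$element),
                      n_shared = cnt$Freq,
                      assigned = cnt$Freq >= threshold,
                      stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$element), , drop = FALSE]
  }
  ## carry unassigned chromosomes (zero conserved genes) for reporting
  attr(out, "unassigned_chroms") <-
    setdiff(genome$chroms$chrom, out$chrom[out$assigned])
  rownames(out) <- NULL
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Decompose chromosomes into ancestral element segments
#'
#' Each conserved gene (one whose orthogroup belongs to an element) is
#' labelled with its element; maximal runs of one element along the
#' chromosome become candidate segments. Orphan genes (no element) never
#' break runs, and foreign interruptions shorter than `min_segment_genes`
#' are bridged: their genes are set aside as movement candidates rather
#' than treated as rearranged segments, keeping the segment rule and the
#' gene-movement rule mutually exclusive. A contiguous run of one element is
#' additionally split where at least `min_segment_genes` orthogroups of that
#' element lie strictly between two neighbouring genes in ancestral order
#' yet are retained elsewhere in the species - the signature of two
#' different ancestral parts fused side by side. Runs with at least
#' `min_segment_genes` genes are reported as segments; all other conserved
#' genes go to `unplaced`.
#'
#' @param genome A [genome_table()].
#' @param orth An [orthology_table()].
#' @param elements An [ancestral_elements()] object.
#' @param min_segment_genes Minimum genes per segment (default 8, the same
#'   constant as chromosome assignment).
#' @return Object of class `species_composition`: list with `species`,
#'   `segments` (chrom, seg_index, element, n_genes, first_gene, last_gene,
#'   med_order, genes list-column), `unplaced` (gene_id, chrom, orthogroup,
#'   element, host_has_element) and `orphan` (gene_id, chrom).
#' @export
decompose <- function(genome, orth, elements, min_segment_genes = 8L) {
  om <- gene_orthogroup_map(orth, genome$species)
  em <- element_map(elements)
  orank <- order_map(elements)
  g <- genome$genes
  og <- unname(om[g$gene_id])
  el <- unname(em[og])

  orphan <- data.frame(gene_id = g$gene_id[is.na(el)],
                       chrom = g$chrom[is.na(el)], stringsAsFactors = FALSE)
  segs <- list(); unpl <- list()

  ## species-wide retained orthogroups per element (for run splitting)
  cons <- data.frame(gene_id = g$gene_id, chrom = g$chrom, rank = g$rank,
                     og = og, el = el, stringsAsFactors = FALSE)
  cons <- cons[!is.na(cons$el), , drop = FALSE]

  for (ch in genome$chroms$chrom) {
    cc <- cons[cons$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$rank), , drop = FALSE]
    if (!nrow(cc)) next
    lab <- cc$el
    alive <- rep(TRUE, nrow(cc))      # FALSE -> sent to unplaced (bridged)

    ## bridge short foreign interruptions flanked by one element
    repeat {
      idx <- which(alive)
      if (!length(idx)) break
      r <- rle(lab[idx])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      done <- TRUE
      if (length(r$values) >= 3L) {
        for (i in 2:(length(r$values) - 1L)) {
          if (r$lengths[i] < min_segment_genes &&
              r$values[i - 1L] == r$values[i + 1L] &&
              r$values[i] != r$values[i - 1L]) {
            alive[idx[starts[i]:ends[i]]] <- FALSE
            done <- FALSE
            break
          }
        }
      }
      if (done) break
    }

    ## final runs over surviving genes
    idx <- which(alive)
    r <- rle(lab[idx])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- lapply(seq_along(r$values), function(i)
      idx[starts[i]:ends[i]])

    ## split runs holding two ancestral parts side by side
    split_runs <- list()
    for (run in runs) {
      e <- lab[run[1]]
      rk <- unname(orank[cc$og[run]])
      if (length(run) < 2L || all(is.na(rk))) {
        split_runs <- c(split_runs, list(run))
        next
      }
      memb <- elements$membership[elements$membership$element == e, ,
                                  drop = FALSE]
      cut <- integer(0)
      run_ogs <- cc$og[run]
      for (i in seq_len(length(run) - 1L)) {
        a <- rk[i]; b <- rk[i + 1L]
        if (is.na(a) || is.na(b)) next
        lo <- min(a, b); hi <- max(a, b)
        if (hi - lo <= 1) next
        between <- memb$orthogroup[!is.na(memb$order_rank) &
                                     memb$order_rank > lo &
                                     memb$order_rank < hi]
        if (!length(between)) next
        ## retained in this species but outside this run?
        present <- between[between %in% cons$og]
        outside <- setdiff(present, run_ogs)
        if (length(outside) >= min_segment_genes)
          cut <- c(cut, i)
      }
      if (!length(cut)) {
        split_runs <- c(split_runs, list(run))
      } else {
        bnd <- c(0L, cut, length(run))
        for (k in seq_len(length(bnd) - 1L))
          split_runs <- c(split_runs,
                          list(run[(bnd[k] + 1L):bnd[k + 1L]]))
      }
    }

    ## segments vs unplaced
    seg_i <- 0L
    for (run in split_runs) {
      if (length(run) >= min_segment_genes) {
        seg_i <- seg_i + 1L
        rk <- unname(orank[cc$og[run]])
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = ch, seg_index = seg_i, element = lab[run[1]],
          n_genes = length(run), first_gene = cc$gene_id[run[1]],
          last_gene = cc$gene_id[run[length(run)]],
          med_order = if (all(is.na(rk))) NA_real_
                      else stats::median(rk, na.rm = TRUE),
          genes = I(list(cc$gene_id[run])), stringsAsFactors = FALSE)
      } else {
        unpl[[length(unpl) + 1L]] <- data.frame(
          gene_id = cc$gene_id[run], chrom = ch, orthogroup = cc$og[run],
          element = lab[run], stringsAsFactors = FALSE)
      }
    }
    dead <- which(!alive)
    if (length(dead))
      unpl[[length(unpl) + 1L]] <- data.frame(
        gene_id = cc$gene_id[dead], chrom = ch, orthogroup = cc$og[dead],
        element = lab[dead], stringsAsFactors = FALSE)
  }

  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), seg_index = integer(),
               element = integer(), n_genes = integer(),
               first_gene = character(), last_gene = character(),
               med_order = numeric(), genes = I(list()))
  unplaced <- if (length(unpl)) do.call(rbind, unpl) else
    data.frame(gene_id = character(), chrom = character(),
               orthogroup = character(), element = integer())
  if (nrow(unplaced)) {
    host_el <- split(segments$element, segments$chrom)
    unplaced$host_has_element <- mapply(function(e, ch)
      e %in% (host_el[[ch]] %||% integer(0)),
      unplaced$element, unplaced$chrom)
    unplaced <- unplaced[order(unplaced$chrom, unplaced$gene_id), ,
                         drop = FALSE]
  } else unplaced$host_has_element <- logical(0)
  rownames(segments) <- rownames(unplaced) <- NULL
  structure(list(species = genome$species, segments = segments,
                 unplaced = unplaced, orphan = orphan),
            class = "species_composition")
}

#' @export
print.species_composition <- function(x, ...) {
  cat("species_composition: ", x$species, " - ", nrow(x$segments),
      " segments, ", nrow(x$unplaced), " unplaced, ", nrow(x$orphan),
      " orphan genes\n", sep = "")
  invisible(x)
}

#' Write compositions TSV
#'
#' Columns `species chrom segment_index element_id n_genes first_gene
#' last_gene`.
#' @param comp A `species_composition`.
#' @param path Output path.
#' @export
write_compositions <- function(comp, path) {
  s <- comp$segments
  out <- data.frame(species = comp$species, chrom = s$chrom,
                    segment_index = s$seg_index, element_id = s$element,
                    n_genes = s$n_genes, first_gene = s$first_gene,
                    last_gene = s$last_gene)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
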