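## Anchor-based collinear block detection between chromosome pairs,
## breakpoint-region extraction, and the W-chromosome all-vs-all
## collinearity network.
##
## A block is a maximal chain of orthologous gene anchors: rank_a strictly
## increasing, rank_b strictly monotone (increasing for "+", decreasing for
## "-"), and consecutive anchors at most max_gap apart in both rank spaces
## (ranks are gene-order ranks on the chromosome, so the gap counts
## intervening genes). Chains are grown greedily left to right - start at
## the first unused anchor, always append the next feasible anchor - which
## yields the lexicographically smallest maximal chain from that start;
## committed chains consume their anchors and the scan repeats. This
## deterministic definition replaces external DP-scored collinearity tools
## and is exactly checkable against exhaustive chain enumeration.

#' Build orthologous gene anchors between two chromosomes
#'
#' One anchor per gene pair of a shared orthogroup. Tandem duplicates (two
#' genes of one orthogroup at consecutive ranks on one chromosome) are
#' collapsed to the first by rank before anchoring.
#'
#' @param genome_a,genome_b [genome_table()] objects.
#' @param orth An [orthology_table()] (low-copy recommended).
#' @param chrom_a,chrom_b Chromosome names.
#' @return data.frame `gene_a`, `gene_b`, `orthogroup`, `rank_a`, `rank_b`,
#'   sorted by `rank_a` then `rank_b`.
#' @export
build_anchors <- function(genome_a, genome_b, orth, chrom_a, chrom_b) {
  side <- function(gt, ch) {
    g <- gt$genes[gt$genes$chrom == ch, , drop = FALSE]
    om <- gene_orthogroup_map(orth, gt$species)
    g$og <- unname(om[g$gene_id])
    g <- g[!is.na(g$og), , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    ## collapse tandem duplicates: same orthogroup in consecutive
    ## conserved-gene positions
    if (nrow(g) > 1L) {
      drop <- c(FALSE, g$og[-1] == g$og[-nrow(g)])
      g <- g[!drop, , drop = FALSE]
    }
    g
  }
  a <- side(genome_a, chrom_a)
  b <- side(genome_b, chrom_b)
  shared <- intersect(a$og, b$og)
  if (!length(shared))
    return(data.frame(gene_a = character(), gene_b = character(),
                      orthogroup = character(), rank_a = integer(),
                      rank_b = integer()))
  a <- a[a$og %in% shared, , drop = FALSE]
  b <- b[b$og %in% shared, , drop = FALSE]
  m <- merge(
    data.frame(orthogroup = a$og, gene_a = a$gene_id, rank_a = a$rank,
               start_a = a$start, end_a = a$end, stringsAsFactors = FALSE),
    data.frame(orthogroup = b$og, gene_b = b$gene_id, rank_b = b$rank,
               start_b = b$start, end_b = b$end, stringsAsFactors = FALSE),
    by = "orthogroup")
  m <- m[order(m$rank_a, m$rank_b), , drop = FALSE]
  rownames(m) <- NULL
  m
}

## greedy chain from anchor `from` (index into anchors ordered by rank_a):
## repeatedly append the next unused feasible anchor; dir = +1 / -1
greedy_chain <- function(anchors, used, from, dir, max_gap) {
  chain <- from
  last <- from
  n <- nrow(anchors)
  i <- from
  while (i < n) {
    i <- i + 1L
    if (used[i]) next
    da <- anchors$rank_a[i] - anchors$rank_a[last]
    db <- dir * (anchors$rank_b[i] - anchors$rank_b[last])
    if (da <= 0) next
    if (da > max_gap) break   # rank_a sorted: no later anchor can be closer
    if (db <= 0 || db > max_gap) next
    chain <- c(chain, i)
    last <- i
  }
  chain
}

#' Find collinear blocks between two chromosomes
#'
#' @param genome_a,genome_b [genome_table()] objects.
#' @param orth An [orthology_table()].
#' @param chrom_a,chrom_b Chromosome names; defaults scan every chromosome
#'   pair with shared orthogroups.
#' @param min_block_genes Minimum anchors per reported block (default 5;
#'   use 7 for W-network edges, 10 for genome-wide scans).
#' @param max_gap Maximum rank gap between consecutive anchors on either
#'   chromosome (default 25).
#' @return data.frame of class `synteny_blocks`: `block_id`, `chrom_a`,
#'   `chrom_b`, `orientation`, `n_anchors`, `a_start`, `a_end`, `b_start`,
#'   `b_end` (bp extents from first anchor gene start to last anchor gene
#'   end), with the per-block anchor tables in the `"anchors"` attribute.
#' @export
find_blocks <- function(genome_a, genome_b, orth, chrom_a = NULL,
                        chrom_b = NULL, min_block_genes = 5L,
                        max_gap = 25L) {
  ca <- chrom_a %||% genome_a$chroms$chrom
  cb <- chrom_b %||% genome_b$chroms$chrom
  blocks <- list(); anchor_sets <- list()
  for (A in ca) for (B in cb) {
    ## chaining runs in a canonical frame for the unordered chromosome
    ## pair (lexicographically smaller (species, chrom) side first), so
    ## the block set is symmetric under swapping the two genomes
    canonical <- paste(genome_a$species, A, sep = "\r") <=
      paste(genome_b$species, B, sep = "\r")
    anc <- if (canonical) build_anchors(genome_a, genome_b, orth, A, B)
           else build_anchors(genome_b, genome_a, orth, B, A)
    if (nrow(anc) < min_block_genes) next
    chains <- chain_anchors(anc, max_gap)
    for (chain in chains) {
      if (length(chain$idx) < min_block_genes) next
      sub <- anc[chain$idx, , drop = FALSE]
      if (!canonical) {
        sub <- data.frame(orthogroup = sub$orthogroup,
                          gene_a = sub$gene_b, rank_a = sub$rank_b,
                          start_a = sub$start_b, end_a = sub$end_b,
                          gene_b = sub$gene_a, rank_b = sub$rank_a,
                          start_b = sub$start_a, end_b = sub$end_a,
                          stringsAsFactors = FALSE)
        sub <- sub[order(sub$rank_a), , drop = FALSE]
      }
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom_a = A, chrom_b = B, orientation = chain$dir,
        n_anchors = nrow(sub),
        a_start = min(sub$start_a), a_end = max(sub$end_a),
        b_start = min(sub$start_b), b_end = max(sub$end_b),
        stringsAsFactors = FALSE)
      anchor_sets[[length(anchor_sets) + 1L]] <- sub
    }
  }
  res <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom_a = character(), chrom_b = character(),
               orientation = character(), n_anchors = integer(),
               a_start = numeric(), a_end = numeric(), b_start = numeric(),
               b_end = numeric())
  if (nrow(res)) {
    o <- order(res$chrom_a, res$a_start, res$chrom_b, res$b_start)
    res <- res[o, , drop = FALSE]
    anchor_sets <- anchor_sets[o]
    res$block_id <- seq_len(nrow(res))
    res <- res[, c("block_id", "chrom_a", "chrom_b", "orientation",
                   "n_anchors", "a_start", "a_end", "b_start", "b_end")]
  } else res$block_id <- integer(0)
  rownames(res) <- NULL
  attr(res, "anchors") <- anchor_sets
  class(res) <- c("synteny_blocks", "data.frame")
  res
}

## Deterministic chain selection on one anchor table: while anchors remain,
## grow the + and - greedy chains from the first unused anchor, commit the
## longer one (ties -> "+"), mark its anchors used. Every anchor ends in
## exactly one chain; chains below the reporting threshold are dropped by
## the caller.
chain_anchors <- function(anchors, max_gap) {
  n <- nrow(anchors)
  used <- rep(FALSE, n)
  chains <- list()
  repeat {
    from <- which(!used)[1]
    if (is.na(from)) break
    cp <- greedy_chain(anchors, used, from, +1L, max_gap)
    cm <- greedy_chain(anchors, used, from, -1L, max_gap)
    if (length(cp) >= length(cm)) {
      chains[[length(chains) + 1L]] <- list(idx = cp, dir = "+")
      used[cp] <- TRUE
    } else {
      chains[[length(chains) + 1L]] <- list(idx = cm, dir = "-")
      used[cm] <- TRUE
    }
  }
  chains
}

#' Breakpoint regions between collinear blocks on a focal chromosome
#'
#' The bp gaps between adjacent block extents on each focal-side
#' chromosome, after merging overlapping extents. Chromosome ends are
#' excluded (a chromosome needs at least two blocks to yield a region);
#' zero-length gaps from abutting or overlapping blocks are skipped and
#' logged in the `"skipped"` attribute.
#'
#' @param blocks A `synteny_blocks` data.frame.
#' @param species Species name stamped on the output.
#' @return data.frame `species`, `chrom`, `start`, `end`, `left_block`,
#'   `right_block`.
#' @export
find_breakpoints <- function(blocks, species = NA_character_) {
  out <- list(); skipped <- 0L
  for (ch in unique(blocks$chrom_a)) {
    b <- blocks[blocks$chrom_a == ch, , drop = FALSE]
    if (nrow(b) < 2L) next
    b <- b[order(b$a_start, b$a_end), , drop = FALSE]
    ## merge overlapping extents, remembering the last block of each merged
    ## stretch
    ms <- b$a_start[1]; me <- b$a_end[1]; mid <- b$block_id[1]
    merged <- list()
    for (i in seq_len(nrow(b))[-1]) {
      if (b$a_start[i] < me) {        # overlap: extend
        if (b$a_end[i] > me) { me <- b$a_end[i]; mid <- b$block_id[i] }
        skipped <- skipped + 1L
      } else {
        merged[[length(merged) + 1L]] <- c(ms, me, mid)
        ms <- b$a_start[i]; me <- b$a_end[i]; mid <- b$block_id[i]
      }
    }
    merged[[length(merged) + 1L]] <- c(ms, me, mid)
    if (length(merged) < 2L) next
    first_ids <- vapply(merged, `[`, 0, 3)
    for (i in seq_len(length(merged) - 1L)) {
      gs <- merged[[i]][2]; ge <- merged[[i + 1L]][1]
      if (ge <= gs) { skipped <- skipped + 1L; next }
      out[[length(out) + 1L]] <- data.frame(
        species = species, chrom = ch, start = gs, end = ge,
        left_block = merged[[i]][3], right_block = first_ids[i + 1L],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(species = character(), chrom = character(), start = numeric(),
               end = numeric(), left_block = numeric(),
               right_block = numeric())
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' All-vs-all W-chromosome collinearity network
#'
#' Builds pairwise collinear blocks between the W chromosomes of the given
#' species and connects two W chromosomes whenever some block holds at
#' least `min_genes_edge` anchors. Transitive connectivity (connected
#' components) carries the common-origin argument: W chromosomes need not
#' all share one segment to descend from one ancestral W.
#'
#' @param w_genomes Named list of [genome_table()] objects, each containing
#'   a W-labelled chromosome.
#' @param orth An [orthology_table()].
#' @param min_genes_edge Minimum collinear genes per qualifying block
#'   (default 7).
#' @param max_gap Passed to [find_blocks()].
#' @return List with symmetric matrices `block_counts` and `gene_counts`
#'   (zero diagonal), logical `edge` matrix, and `components` (named
#'   membership vector).
#' @export
w_network <- function(w_genomes, orth, min_genes_edge = 7L, max_gap = 25L) {
  if (is.null(names(w_genomes)))
    names(w_genomes) <- vapply(w_genomes, `[[`, "", "species")
  sp <- names(w_genomes)
  wch <- vapply(sp, function(s) {
    cm <- w_genomes[[s]]$chroms
    w <- cm$chrom[cm$sex_label == "W"]
    if (!length(w)) stop_data("species '", s, "' has no W-labelled chromosome")
    w[1]
  }, "")
  n <- length(sp)
  bc <- matrix(0L, n, n, dimnames = list(sp, sp))
  gc <- matrix(0L, n, n, dimnames = list(sp, sp))
  ed <- matrix(FALSE, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    bl <- find_blocks(w_genomes[[i]], w_genomes[[j]], orth,
                      chrom_a = wch[i], chrom_b = wch[j],
                      min_block_genes = min_genes_edge, max_gap = max_gap)
    bc[i, j] <- bc[j, i] <- nrow(bl)
    gc[i, j] <- gc[j, i] <- sum(bl$n_anchors)
    ed[i, j] <- ed[j, i] <- any(bl$n_anchors >= min_genes_edge)
  }
  g <- igraph::graph_from_adjacency_matrix(ed, mode = "undirected")
  comp <- igraph::components(g)$membership
  list(block_counts = bc, gene_counts = gc, edge = ed,
       components = comp)
}

#' Write blocks TSV / breakpoints BED
#' @param blocks A `synteny_blocks` data.frame.
#' @param path Output path.
#' @export
write_blocks <- function(blocks, path) {
  utils::write.table(as.data.frame(blocks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_blocks
#' @param regions Breakpoint regions from [find_breakpoints()].
#' @export
write_breakpoints_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
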