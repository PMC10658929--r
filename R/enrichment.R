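## Permutation test for TE-class enrichment in breakpoint regions versus
## random region sets with the same size distribution.

## overlap of one TE set with a set of (possibly overlapping) regions on
## one chromosome; half-open intervals, >= 1 bp overlap. Returns a logical
## vector over TEs. Regions sorted by start; a TE (s,e) overlaps some
## region iff among regions with start < e the running maximum end
## exceeds s.
.overlaps_any <- function(te_start, te_end, reg_start, reg_end) {
  if (!length(reg_start)) return(rep(FALSE, length(te_start)))
  o <- order(reg_start)
  rs <- reg_start[o]
  re_cummax <- cummax(reg_end[o])
  j <- findInterval(te_end - 0.5, rs)    # regions with start < te_end
  hit <- j >= 1L
  hit[hit] <- re_cummax[j[hit]] > te_start[hit]
  hit
}

#' Count TEs overlapping a region set, by class
#'
#' Each TE interval is counted once per class when it overlaps at least
#' one region by at least 1 bp (half-open coordinates); a TE spanning two
#' regions still counts once.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param tes An [interval_track()] (or data.frame with `chrom`, `start`,
#'   `end`, `class`).
#' @param classes Class vocabulary for zero-filled output (default
#'   [te_classes()]).
#' @return Named integer vector of counts per class.
#' @export
count_te_overlaps <- function(regions, tes, classes = te_classes()) {
  hits <- rep(FALSE, nrow(tes))
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    ti <- which(tes$chrom == ch)
    if (!length(ti)) next
    hits[ti] <- .overlaps_any(tes$start[ti], tes$end[ti], r$start, r$end)
  }
  cnt <- table(factor(tes$class[hits], levels = classes))
  stats::setNames(as.integer(cnt), classes)
}

#' Permutation test for TE enrichment in breakpoint regions
#'
#' Each simulation places one random region per observed region, keeping
#' its length: a chromosome is chosen with probability proportional to the
#' number of valid start positions (length - region length + 1) and the
#' start is uniform in the valid range; placed regions may overlap each
#' other and the observed regions (the null constrains only the size
#' distribution). The one-sided p-value per TE class is the fraction of
#' simulations whose count is greater than or equal to the observed count;
#' the optional pseudocount mode reports (k+1)/(n+1). Depletion is visible
#' descriptively through the null quantiles.
#'
#' @param regions Observed regions (`chrom`, `start`, `end`).
#' @param tes An [interval_track()].
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param n_sims Number of simulations (default 10000).
#' @param seed Mandatory RNG seed.
#' @param pseudocount Use the (k+1)/(n+1) estimator (default `FALSE`).
#' @param per_chromosome Keep each random region on its observed
#'   chromosome instead of pooling (default `FALSE`).
#' @param no_overlap Reject placements overlapping an already-placed
#'   random region in the same simulation (default `FALSE`).
#' @param classes Class vocabulary (default [te_classes()]).
#' @return data.frame of class `enrichment_result`: one row per class with
#'   `te_class`, `observed`, `null_mean`, `null_sd`, `null_q50`,
#'   `null_q95`, `null_q99`, `p_value`, `n_sims`, `seed`, `p_mode`; the
#'   full null count matrix is in the `"null_counts"` attribute.
#' @export
te_permutation_test <- function(regions, tes, chrom_lengths,
                                n_sims = 10000L, seed,
                                pseudocount = FALSE, per_chromosome = FALSE,
                                no_overlap = FALSE,
                                classes = te_classes()) {
  if (missing(seed)) stop_data("seed is required for te_permutation_test()")
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  len <- as.numeric(regions$end - regions$start)
  too_long <- len > max(chrom_lengths)
  if (any(too_long))
    stop_data("region(s) longer than every chromosome: ",
              paste(utils::head(which(too_long), 5), collapse = ", "))
  if (per_chromosome) {
    bad <- len > chrom_lengths[regions$chrom]
    if (any(bad))
      stop_data("region(s) longer than their own chromosome: ",
                paste(utils::head(which(bad), 5), collapse = ", "))
  }
  observed <- count_te_overlaps(regions, tes, classes)

  ## pre-split TEs by chromosome for fast per-simulation counting
  chs <- names(chrom_lengths)
  te_by_ch <- lapply(chs, function(ch) {
    i <- which(tes$chrom == ch)
    list(start = tes$start[i], end = tes$end[i],
         class = factor(tes$class[i], levels = classes))
  })
  names(te_by_ch) <- chs
  nr <- length(len)
  wts <- lapply(seq_len(nr), function(i) pmax(0, chrom_lengths - len[i] + 1))
  set.seed(seed)
  null_counts <- matrix(0L, nrow = n_sims, ncol = length(classes),
                        dimnames = list(NULL, classes))
  for (s in seq_len(n_sims)) {
    if (per_chromosome) {
      ch_pick <- regions$chrom
    } else {
      ## valid-start-weighted chromosome choice per region length
      ch_pick <- character(nr)
      for (i in seq_len(nr))
        ch_pick[i] <- chs[sample.int(length(chs), 1L, prob = wts[[i]])]
    }
    starts <- numeric(nr)
    for (i in seq_len(nr)) {
      L <- chrom_lengths[[ch_pick[i]]]
      tries <- 0L
      repeat {
        st <- floor(stats::runif(1, 0, L - len[i] + 1))
        if (!no_overlap) break
        prev <- which(ch_pick[seq_len(i - 1L)] == ch_pick[i])
        if (!length(prev) ||
            all(st + len[i] <= starts[prev] |
                st >= starts[prev] + len[prev])) break
        tries <- tries + 1L
        if (tries %% 100L == 0L && !per_chromosome) {
          ## a crowded draw can be unplaceable on this chromosome:
          ## re-draw the chromosome as well
          ch_pick[i] <- chs[sample.int(length(chs), 1L, prob = wts[[i]])]
          L <- chrom_lengths[[ch_pick[i]]]
        }
        if (tries >= 10000L)
          stop_data("could not place non-overlapping random regions ",
                    "(region set too crowded for the genome)")
      }
      starts[i] <- st
    }
    acc <- integer(length(classes))
    for (ch in unique(ch_pick)) {
      t <- te_by_ch[[ch]]
      if (!length(t$start)) next
      ri <- which(ch_pick == ch)
      hit <- .overlaps_any(t$start, t$end, starts[ri], starts[ri] + len[ri])
      if (any(hit)) acc <- acc + tabulate(t$class[hit],
                                          nbins = length(classes))
    }
    null_counts[s, ] <- acc
  }
  k <- colSums(null_counts >= rep(observed, each = n_sims))
  p <- if (pseudocount) (k + 1) / (n_sims + 1) else k / n_sims
  res <- data.frame(
    te_class = classes, observed = as.integer(observed),
    null_mean = colMeans(null_counts),
    null_sd = apply(null_counts, 2, stats::sd),
    null_q50 = apply(null_counts, 2, stats::median),
    null_q95 = apply(null_counts, 2, stats::quantile, probs = 0.95),
    null_q99 = apply(null_counts, 2, stats::quantile, probs = 0.99),
    p_value = as.numeric(p), n_sims = n_sims, seed = seed,
    p_mode = if (pseudocount) "pseudocount" else "k/n",
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "null_counts") <- null_counts
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Draw a uniform random TE track (null model / testing utility)
#'
#' Places `round(density * length)` TEs of each class per chromosome at
#' uniform positions (Poisson-distributed counts), each of fixed length.
#'
#' @param chrom_lengths Named numeric vector.
#' @param density Expected TEs per bp, recycled over classes (may be a
#'   named vector over classes).
#' @param te_length TE interval length in bp (default 500).
#' @param classes Classes to draw (default [te_classes()]).
#' @param species Species stamp.
#' @return An [interval_track()].
#' @export
random_te_track <- function(chrom_lengths, density, te_length = 500,
                            classes = te_classes(), species = "sim") {
  dens <- rep_len(density, length(classes))
  names(dens) <- classes
  if (!is.null(names(density))) dens[names(density)] <- density
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    for (cl in classes) {
      n <- stats::rpois(1, dens[[cl]] * L)
      if (!n) next
      st <- floor(stats::runif(n, 0, max(1, L - te_length)))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = st, end = pmin(st + te_length, L), class = cl,
        stringsAsFactors = FALSE)
    }
  }
  iv <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               class = character())
  interval_track(species, iv, classes = classes)
}
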