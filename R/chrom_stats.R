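## Descriptive per-chromosome features and the comparative statistics used
## for Z-vs-autosome contrasts: Pearson product-moment correlation and the
## one-sided Wilcoxon rank-sum test with an exact small-sample branch.

#' Per-chromosome feature table
#'
#' One row per chromosome of every genome: sex class, bp length, GC, gene
#' count, lineage-specific gene count and proportion, assigned element set
#' and (optionally) the derived name.
#'
#' @param genomes Named list of [genome_table()] objects.
#' @param orth An [orthology_table()].
#' @param elements An [ancestral_elements()] object.
#' @param names Optional list/data.frame of [name_chromosomes()] results
#'   (rbound) supplying `new_name`.
#' @param threshold Assignment threshold passed to [assign_chromosomes()].
#' @return data.frame with columns `species`, `chrom`, `new_name`,
#'   `sex_label`, `length_bp`, `gc`, `n_genes`, `n_lineage_specific`,
#'   `proportion_lineage_specific`, `elements`.
#' @export
chrom_feature_table <- function(genomes, orth, elements, names = NULL,
                                threshold = 8L) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, "", "species")
  ls <- lineage_specific_counts(genomes, orth)
  out <- list()
  for (sp in base::names(genomes)) {
    gt <- genomes[[sp]]
    asg <- assign_chromosomes(gt, orth, elements, threshold = threshold)
    elset <- tapply(asg$element[asg$assigned], asg$chrom[asg$assigned],
                    function(e) paste(sort(e), collapse = ","))
    l <- ls[ls$species == sp, , drop = FALSE]
    d <- data.frame(species = sp, chrom = gt$chroms$chrom,
                    new_name = NA_character_,
                    sex_label = gt$chroms$sex_label,
                    length_bp = gt$chroms$length_bp, gc = gt$chroms$gc,
                    n_genes = l$n_total_genes[match(gt$chroms$chrom, l$chrom)],
                    n_lineage_specific =
                      l$n_lineage_specific[match(gt$chroms$chrom, l$chrom)],
                    proportion_lineage_specific =
                      l$proportion[match(gt$chroms$chrom, l$chrom)],
                    elements = NA_character_, stringsAsFactors = FALSE)
    hit <- match(d$chrom, base::names(elset))
    d$elements[!is.na(hit)] <- unlist(elset)[hit[!is.na(hit)]]
    out[[sp]] <- d
  }
  res <- do.call(rbind, out)
  if (!is.null(names)) {
    nm <- if (is.data.frame(names)) names else do.call(rbind, names)
    i <- match(paste(res$species, res$chrom), paste(nm$species, nm$chrom))
    res$new_name <- nm$name[i]
  }
  rownames(res) <- NULL
  res
}

#' Pearson product-moment correlation test
#'
#' r with the two-sided p-value from the t transform on n-2 degrees of
#' freedom. Incomplete pairs (NA in either variable) are dropped pairwise;
#' the number dropped is reported.
#'
#' @param x,y Numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List of class `kv_test`: `statistic` (r), `t`, `df`, `p_value`,
#'   `alternative`, `n`, `n_dropped`, `method`.
#' @export
pearson_cor_test <- function(x, y,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_data("pearson_cor_test needs >= 3 complete pairs")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2
  tt <- r * sqrt(df / max(1e-300, 1 - r^2))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tt), df),
              greater = stats::pt(tt, df, lower.tail = FALSE),
              less = stats::pt(tt, df))
  structure(list(statistic = r, t = tt, df = df, p_value = min(1, p),
                 alternative = alternative, n = n, n_dropped = n_dropped,
                 method = "pearson"), class = "kv_test")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic is U, the number of (x, y) pairs with x > y (ties count
#' one half). When both groups have at most `exact_max` observations and
#' there are no ties, the p-value is exact (the full permutation
#' distribution of U); otherwise midranks with the tie-corrected normal
#' approximation are used, without continuity correction, and the `method`
#' tag says which branch ran.
#'
#' @param x,y Numeric vectors (group 1 and group 2).
#' @param alternative `"greater"` (x tends larger), `"less"` or
#'   `"two.sided"`.
#' @param exact_max Largest per-group size for the exact branch (default 8).
#' @return List of class `kv_test`: `statistic` (U), `p_value`,
#'   `alternative`, `n` (c(n1, n2)), `method` (`"exact"` or
#'   `"normal-approx"`).
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("greater", "less",
                                              "two.sided"),
                              exact_max = 8L) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop_data("both groups must be nonempty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    ## exact tail of the Mann-Whitney U distribution
    p_le <- stats::pwilcox(u, n1, n2)
    p_ge <- 1 - if (u >= 1) stats::pwilcox(u - 1, n1, n2) else 0
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) /
                              (N * (N - 1)))
    z <- if (sig2 > 0) (u - mu) / sqrt(sig2) else 0
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = min(1, 2 * stats::pnorm(-abs(z))))
    method <- "normal-approx"
  }
  structure(list(statistic = u, p_value = p, alternative = alternative,
                 n = c(n1, n2), method = method), class = "kv_test")
}

#' @export
print.kv_test <- function(x, ...) {
  cat(x$method, " test: statistic = ", format(x$statistic, digits = 6),
      ", p = ", format(x$p_value, digits = 4), " (", x$alternative, ")\n",
      sep = "")
  invisible(x)
}

#' Z-versus-autosome comparisons on a feature table
#'
#' Runs the standard one-sided Wilcoxon rank-sum contrasts (Z greater than
#' autosomes) on chromosome length, GC, gene count, and the number and
#' proportion of lineage-specific genes, pooling chromosomes across
#' species. W chromosomes are excluded.
#'
#' @param features Output of [chrom_feature_table()].
#' @param alternative Direction for each contrast, recycled (default
#'   `"greater"`).
#' @return data.frame: one row per contrast with `feature`, `statistic`,
#'   `p_value`, `alternative`, `n_z`, `n_a`, `method`.
#' @export
z_autosome_tests <- function(features, alternative = "greater") {
  feats <- c("length_bp", "gc", "n_genes", "n_lineage_specific",
             "proportion_lineage_specific")
  alt <- rep_len(alternative, length(feats))
  f <- features[features$sex_label != "W", , drop = FALSE]
  out <- lapply(seq_along(feats), function(i) {
    v <- f[[feats[i]]]
    z <- v[f$sex_label == "Z"]; a <- v[f$sex_label == "A"]
    z <- z[!is.na(z)]; a <- a[!is.na(a)]
    if (!length(z) || !length(a))
      return(data.frame(feature = feats[i], statistic = NA_real_,
                        p_value = NA_real_, alternative = alt[i],
                        n_z = length(z), n_a = length(a),
                        method = NA_character_))
    w <- wilcoxon_rank_sum(z, a, alternative = alt[i])
    data.frame(feature = feats[i], statistic = w$statistic,
               p_value = w$p_value, alternative = alt[i],
               n_z = length(z), n_a = length(a), method = w$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
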