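# In-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Elements with `sizes[e]` orthogroups each, ids E<e>G<i>, ordered.
toy_elements <- function(sizes, z_element = NA_integer_) {
  memb <- do.call(rbind, lapply(seq_along(sizes), function(e) {
    data.frame(element = e,
               orthogroup = sprintf("E%dG%02d", e, seq_len(sizes[e])),
               order_rank = seq_len(sizes[e]))
  }))
  ancestral_elements(memb, z_element = z_element)
}

# Build a genome + matching 1:1 orthology for one species from a list of
# chromosomes, each a character vector of orthogroup ids in order (NA
# entries become orphan genes). Gene ids are "<sp>_<og>" / "<sp>_ls<i>".
toy_genome <- function(sp, chrom_ogs, sex = NULL) {
  genes <- list(); orth <- list(); ls_i <- 0
  for (ch in names(chrom_ogs)) {
    ogs <- chrom_ogs[[ch]]
    ids <- character(length(ogs))
    for (i in seq_along(ogs)) {
      if (is.na(ogs[i])) {
        ls_i <- ls_i + 1
        ids[i] <- sprintf("%s_ls%03d", sp, ls_i)
      } else {
        ids[i] <- paste0(sp, "_", ogs[i])
        orth[[length(orth) + 1]] <- data.frame(
          orthogroup = ogs[i], species = sp, gene_id = ids[i])
      }
    }
    if (length(ogs))
      genes[[ch]] <- data.frame(
        gene_id = ids, chrom = ch, start = (seq_along(ogs) - 1) * 2000,
        end = (seq_along(ogs) - 1) * 2000 + 1000, strand = "+")
  }
  gdf <- do.call(rbind, genes)
  chroms <- data.frame(chrom = names(chrom_ogs),
                       sex_label = if (is.null(sex)) "A"
                                   else sex[names(chrom_ogs)],
                       length_bp = vapply(chrom_ogs, function(o)
                         max(2000 * length(o), 10000), 0),
                       gc = NA_real_)
  list(genome = genome_table(sp, gdf, chroms),
       orth = do.call(rbind, orth))
}

og_range <- function(e, i) sprintf("E%dG%02d", e, i)

# The four caption scenarios as one toy species (plus helpers B uses two
# chromosomes). Elements: 1,2,4,7 = 20 genes; 3 = 20 (parts 10+10);
# 5 = 20 (10+10); 6 = 27 (9+9+9).
fig1_toy <- function() {
  el <- toy_elements(c(20, 20, 20, 20, 20, 27, 20))
  chrom_ogs <- list(
    chrA = c(og_range(1, 1:20), og_range(2, 1:20)),          # 1f2
    chrB1 = og_range(3, 1:10),                               # 3d1
    chrB2 = og_range(3, 11:20),                              # 3d2
    chrC = og_range(4, 1:20),                                # 4
    chrD1 = c(og_range(5, 1:10), og_range(6, 1:9),
              og_range(6, 19:27)),                           # 5d1f6d1f6d3
    chrD2 = c(og_range(5, 11:20), og_range(6, 10:18),
              og_range(7, 1:20)),                            # 5d2f6d2f7
    chrW = rep(NA_character_, 5))
  sex <- c(chrA = "A", chrB1 = "A", chrB2 = "A", chrC = "A", chrD1 = "A",
           chrD2 = "A", chrW = "W")
  tg <- toy_genome("toy", chrom_ogs, sex = sex)
  list(elements = el, genome = tg$genome,
       orth = orthology_table(tg$orth))
}

# Brute-force Wilcoxon rank-sum oracle: full enumeration of group-1
# assignments of the pooled sample.
brute_wilcoxon <- function(x, y, alternative) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  p_ge <- mean(us >= u_obs)
  p_le <- mean(us <= u_obs)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Exhaustive-chain oracle for the synteny module: enumerate all maximal
# valid chains from the first unused anchor by depth-first search, select
# the lexicographically smallest per orientation, commit the longer of the
# two (ties -> "+"), repeat. Mirrors the stated chain definition, computed
# by enumeration instead of a single greedy pass.
oracle_chains <- function(anchors, max_gap) {
  n <- nrow(anchors)
  used <- rep(FALSE, n)
  feas <- function(last, j, dir) {
    da <- anchors$rank_a[j] - anchors$rank_a[last]
    db <- dir * (anchors$rank_b[j] - anchors$rank_b[last])
    da > 0 && da <= max_gap && db > 0 && db <= max_gap
  }
  all_maximal <- function(from, dir) {
    out <- list()
    dfs <- function(chain) {
      last <- chain[length(chain)]
      nxt <- which(!used & seq_len(n) > last)
      nxt <- nxt[vapply(nxt, function(j) feas(last, j, dir), TRUE)]
      if (!length(nxt)) {
        out[[length(out) + 1]] <<- chain
      } else {
        for (j in nxt) dfs(c(chain, j))
      }
    }
    dfs(from)
    out
  }
  lex_min <- function(chains) {
    best <- chains[[1]]
    for (c2 in chains[-1]) {
      k <- min(length(best), length(c2))
      cmp <- which(best[seq_len(k)] != c2[seq_len(k)])
      smaller <- if (length(cmp)) c2[cmp[1]] < best[cmp[1]]
                 else length(c2) < length(best)
      if (smaller) best <- c2
    }
    best
  }
  chains <- list()
  repeat {
    from <- which(!used)[1]
    if (is.na(from)) break
    cp <- lex_min(all_maximal(from, +1L))
    cm <- lex_min(all_maximal(from, -1L))
    if (length(cp) >= length(cm)) {
      chains[[length(chains) + 1]] <- list(idx = cp, dir = "+")
      used[cp] <- TRUE
    } else {
      chains[[length(chains) + 1]] <- list(idx = cm, dir = "-")
      used[cm] <- TRUE
    }
  }
  chains
}

# Random two-species chromosome pair sharing a permuted gene order.
random_chrom_pair <- function(n_genes, seed) {
  set.seed(seed)
  ogs <- sprintf("OG%03d", seq_len(n_genes))
  a <- toy_genome("spA", list(chr1 = ogs))
  b <- toy_genome("spB", list(chr1 = sample(ogs)))
  list(genome_a = a$genome, genome_b = b$genome,
       orth = orthology_table(rbind(a$orth, b$orth)))
}

run_pipeline <- function(sim) {
  lorth <- filter_low_copy(sim$orth)
  comps <- lapply(sim$genomes, decompose, orth = lorth,
                  elements = sim$elements)
  feats <- extract_features(comps, lorth, sim$elements)
  placed <- place_events(feats, sim$tree)
  list(lorth = lorth, comps = comps, feats = feats, placed = placed)
}
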