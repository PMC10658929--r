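# Simulator invariants: determinism, zero-rate identity, replay,
# conservation bookkeeping, TE bias calibration.

zero_rates <- list(fusion = 0, fission = 0, movement = 0, loss = 0,
                   duplication = 0, birth = 0)

test_that("zero rates reproduce the ancestral genome at every tip", {
  cfg <- sim_config(n_taxa = 5, n_elements = 6,
                    element_genes = c(40, 35, 30, 25, 20, 14),
                    rates = zero_rates, with_w = FALSE)
  sim <- simulate_karyotypes(cfg, seed = 2)
  expect_length(sim$truth$events, 0)
  em <- element_map(sim$elements)
  for (sp in names(sim$genomes)) {
    g <- sim$genomes[[sp]]
    expect_equal(nrow(g$genes), 164)  # sum of element sizes
    expect_equal(nrow(g$chroms), 6)
    # per-chromosome gene content equals one element, in ancestral order
    om <- gene_orthogroup_map(sim$orth, sp)
    for (ch in g$chroms$chrom) {
      on_ch <- g$genes[g$genes$chrom == ch, ]
      ogs <- om[on_ch$gene_id[order(on_ch$rank)]]
      els <- unique(em[ogs])
      expect_length(els, 1)
      memb <- sim$elements$membership
      want <- memb$orthogroup[memb$element == els]
      expect_equal(unname(ogs), want[order(
        memb$order_rank[memb$element == els])])
    }
  }
})

test_that("a fixed seed reproduces the simulation exactly", {
  cfg <- sim_config(n_taxa = 6, n_elements = 8,
                    element_genes = c(60, 50, 40, 35, 30, 25, 20, 14))
  a <- simulate_karyotypes(cfg, seed = 12)
  b <- simulate_karyotypes(cfg, seed = 12)
  expect_identical(lapply(a$genomes, `[[`, "genes"),
                   lapply(b$genomes, `[[`, "genes"))
  expect_identical(a$orth, b$orth)
  expect_identical(lapply(a$te_tracks, as.data.frame),
                   lapply(b$te_tracks, as.data.frame))
  c2 <- simulate_karyotypes(cfg, seed = 13)
  expect_false(identical(lapply(a$genomes, `[[`, "genes"),
                         lapply(c2$genomes, `[[`, "genes")))
})

test_that("fusion junction counts in the tips match the truth log", {
  cfg <- sim_config(n_taxa = 4, n_elements = 6,
                    element_genes = c(60, 50, 40, 35, 30, 25),
                    rates = list(fusion = 1, fission = 0, movement = 0,
                                 loss = 0, duplication = 0, birth = 0))
  sim <- simulate_karyotypes(cfg, seed = 8)
  n_fusion_events <- sum(vapply(sim$truth$events, function(e)
    e$kind == "fusion", TRUE))
  expect_gt(n_fusion_events, 0)
  # junctions present in tips = created minus those on pruned paths;
  # with fission off, every junction on a root-to-tip path survives
  for (sp in names(sim$truth$tips)) {
    st <- sim$truth$tips[[sp]]
    n_j <- sum(vapply(st, function(it) sum(it$type == "junction"), 0L))
    # every fusion on the path reduces the gene-bearing chromosome count
    # by one and leaves one junction (fission is off, W carries no genes)
    n_chr <- sum(vapply(st, function(it) any(it$type == "gene"), TRUE))
    expect_equal(n_j, cfg$n_elements - n_chr)
  }
})

test_that("replay of the truth log reproduces every tip genome", {
  for (seed in 1:5) {
    cfg <- sim_config(n_taxa = 8, n_elements = 10,
                      element_genes = c(80, 70, 60, 55, 50, 45, 40, 30,
                                        20, 14),
                      rates = list(fusion = 0.5, fission = 0.25,
                                   movement = 1, loss = 1.5,
                                   duplication = 0.8, birth = 1.5))
    sim <- simulate_karyotypes(cfg, seed = seed)
    re <- replay_truth(sim$truth)
    for (sp in names(sim$genomes)) {
      expect_identical(re[[sp]]$genes, sim$genomes[[sp]]$genes)
      expect_identical(re[[sp]]$chroms[, c("chrom", "sex_label", "length_bp")],
                       sim$genomes[[sp]]$chroms[, c("chrom", "sex_label",
                                                    "length_bp")])
    }
  }
})

test_that("ancestral genes are conserved: retained + lost partitions hold", {
  sim <- simulate_karyotypes(sim_config(n_taxa = 6), seed = 19)
  m <- sim$elements$membership
  cnt <- table(factor(sim$orth$orthogroup, levels = m$orthogroup),
               factor(sim$orth$species, levels = names(sim$genomes)))
  for (sp in names(sim$genomes)) {
    n_lost <- sum(cnt[, sp] == 0)
    n_retained <- sum(cnt[, sp] > 0)
    expect_equal(n_lost + n_retained, nrow(m))
    # copy numbers never exceed the low-copy bound
    expect_lte(max(cnt[, sp]), 2)
  }
  # truth loss totals agree with the zero-copy census
  ld <- sim$truth$loss_dup
  expect_equal(sum(ld$total_losses), sum(cnt == 0))
  expect_equal(sum(ld$total_duplications), sum(cnt == 2))
})

test_that("breakpoint-biased TE insertion hits the configured multiplier", {
  bias <- 4
  cfg <- sim_config(n_taxa = 6, rates = list(fusion = 1.2, fission = 0,
                                             movement = 0, loss = 0,
                                             duplication = 0, birth = 0),
                    te = list(background = 3e-4, bias = bias,
                              window = 8000))
  tot_obs <- 0; tot_bg <- 0; wbp <- 0
  for (seed in 31:34) {
    sim <- simulate_karyotypes(cfg, seed = seed)
    for (sp in names(sim$te_tracks)) {
      bp <- sim$truth$breakpoints[sim$truth$breakpoints$species == sp, ]
      if (!nrow(bp)) next
      te <- sim$te_tracks[[sp]]
      lens <- stats::setNames(sim$genomes[[sp]]$chroms$length_bp,
                              sim$genomes[[sp]]$chroms$chrom)
      for (i in seq_len(nrow(bp))) {
        w0 <- max(0, bp$pos[i] - 8000)
        w1 <- min(lens[[bp$chrom[i]]], bp$pos[i] + 8000)
        inwin <- te$chrom == bp$chrom[i] & te$class == "LTR" &
          te$start < w1 & te$end > w0
        tot_obs <- tot_obs + sum(inwin)
        wbp <- wbp + (w1 - w0)
      }
    }
  }
  # expected ~ bias x background density x summed window width (edge
  # effects from 500 bp TE length make this approximate)
  expected <- bias * 3e-4 * wbp
  expect_gt(tot_obs, expected - 3 * sqrt(expected))
  expect_lt(tot_obs, expected + 3 * sqrt(expected) + 0.1 * expected)
})

test_that("destructive rate combinations are refused", {
  cfg <- sim_config(n_taxa = 4, n_elements = 2, element_genes = c(20, 14),
                    rates = list(loss = 30))
  expect_error(simulate_karyotypes(cfg, seed = 1), "turnover")
  expect_error(simulate_karyotypes(sim_config()), "seed")
})
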