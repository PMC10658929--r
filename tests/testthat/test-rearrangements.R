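# Feature extraction, parsimony placement, per-element counting.

toy_tree <- function(txt) ape::read.tree(text = txt)

# one fusion junction (elements 1 and 2) in the given species, ancestral
# karyotype in the rest
fusion_world <- function(carriers, all_species, el_sizes = c(20, 15, 12)) {
  el <- toy_elements(el_sizes)
  genomes <- list(); orth <- list()
  for (sp in all_species) {
    if (sp %in% carriers) {
      chrom_ogs <- list(chr1 = c(og_range(1, 1:20), og_range(2, 1:15)),
                        chr2 = og_range(3, 1:12))
    } else {
      chrom_ogs <- list(chr1 = og_range(1, 1:20),
                        chr2 = og_range(2, 1:15),
                        chr3 = og_range(3, 1:12))
    }
    tg <- toy_genome(sp, chrom_ogs)
    genomes[[sp]] <- tg$genome
    orth[[sp]] <- tg$orth
  }
  orth <- orthology_table(do.call(rbind, orth))
  comps <- lapply(genomes, decompose, orth = orth, elements = el)
  list(elements = el, orth = orth, comps = comps, genomes = genomes)
}

test_that("ancestral-karyotype species yield zero features", {
  w <- fusion_world(character(0), c("A", "B", "C"))
  feats <- extract_features(w$comps, w$orth, w$elements)
  expect_length(feats, 0)
})

test_that("a junction shared by two species is one feature with two carriers", {
  w <- fusion_world(c("A", "B"), c("A", "B", "C"))
  feats <- extract_features(w$comps, w$orth, w$elements)
  expect_length(feats, 1)
  expect_equal(feats[[1]]$kind, "fusion")
  expect_setequal(feats[[1]]$carriers, c("A", "B"))
  expect_setequal(feats[[1]]$elements, c(1, 2))
})

test_that("a fission observed in one species is one feature with one carrier", {
  el <- toy_elements(c(20, 15))
  split_sp <- toy_genome("A", list(chr1 = og_range(1, 1:10),
                                   chr2 = og_range(1, 11:20),
                                   chr3 = og_range(2, 1:15)))
  whole_sp <- toy_genome("B", list(chr1 = og_range(1, 1:20),
                                   chr2 = og_range(2, 1:15)))
  orth <- orthology_table(rbind(split_sp$orth, whole_sp$orth))
  comps <- list(A = decompose(split_sp$genome, orth, el),
                B = decompose(whole_sp$genome, orth, el))
  feats <- extract_features(comps, orth, el)
  expect_length(feats, 1)
  expect_equal(feats[[1]]$kind, "fission")
  expect_equal(feats[[1]]$carriers, "A")
  expect_equal(feats[[1]]$label, "1d-2")
})

test_that("clade carriers place one event at their MRCA", {
  w <- fusion_world(c("A", "B"), c("A", "B", "C"))
  feats <- extract_features(w$comps, w$orth, w$elements)
  tree <- toy_tree("((A,B),C);")
  placed <- place_events(feats, tree)
  expect_equal(nrow(placed), 1)
  expect_equal(placed$node, ape::getMRCA(tree, c("A", "B")))
  expect_equal(placed$node_type, "ancestral")
  expect_equal(placed$n_gains, 1L)
})

test_that("scattered carriers resolve to independent species-level gains", {
  # hand-checked small parsimony with the root constrained absent:
  # carriers {A, C} on ((A,B),C) need two gains, at A and at C
  w <- fusion_world(c("A", "C"), c("A", "B", "C"))
  feats <- extract_features(w$comps, w$orth, w$elements)
  tree <- toy_tree("((A,B),C);")
  placed <- place_events(feats, tree)
  expect_equal(nrow(placed), 2)
  expect_setequal(placed$node_label, c("A", "C"))
  expect_true(all(placed$node_type == "species"))
  expect_true(all(placed$n_gains == 2L))
})

test_that("a universally carried feature maps to the root", {
  w <- fusion_world(c("A", "B", "C"), c("A", "B", "C"))
  feats <- extract_features(w$comps, w$orth, w$elements)
  tree <- toy_tree("((A,B),C);")
  placed <- place_events(feats, tree)
  expect_equal(nrow(placed), 1)
  expect_equal(placed$node, length(tree$tip.label) + 1L)
})

test_that("excluded species drop out of carrier sets; orphan features are logged", {
  w <- fusion_world(c("A"), c("A", "B", "C"))
  feats <- extract_features(w$comps, w$orth, w$elements)
  tree <- toy_tree("((A,B),C);")
  placed <- place_events(feats, tree, excluded = "A")
  expect_equal(nrow(placed), 0)
  expect_length(attr(placed, "dropped"), 1)
})

test_that("per-element counts follow the pairwise junction convention", {
  el <- toy_elements(c(10, 10, 10))
  placed <- data.frame(
    feature_id = 1:3,
    kind = c("fusion", "fusion", "fission"),
    label = c("1f2", "3f3", "2d-2"),
    elements = c("1,2", "3", "2"),
    node = 1:3, node_label = "x", node_type = "species", n_gains = 1L)
  cnt <- count_by_element(placed, el)
  expect_equal(cnt$n_fusions, c(1L, 1L, 2L))   # same-element junction: +2
  expect_equal(cnt$n_fissions, c(0L, 1L, 0L))
  # every fusion gain contributes exactly two element increments
  expect_equal(sum(cnt$n_fusions), 2 * sum(placed$kind == "fusion"))
  expect_equal(sum(cnt$n_fissions), sum(placed$kind == "fission"))
  # empty event table -> all zeros
  cnt0 <- count_by_element(placed[0, ], el)
  expect_true(all(cnt0$n_fusions == 0 & cnt0$n_fissions == 0))
})

test_that("event extraction is invariant to species input order", {
  sim <- simulate_karyotypes(sim_config(n_taxa = 8), seed = 9)
  pl <- run_pipeline(sim)
  feats_rev <- extract_features(rev(pl$comps), pl$lorth, sim$elements)
  lab <- function(f) sort(vapply(f, function(x)
    paste(x$kind, x$label, paste(sort(x$carriers), collapse = "+")), ""))
  expect_identical(lab(feats_rev), lab(pl$feats))
})

test_that("unresolvable species are flagged on either bound", {
  # 7 segments on one chromosome (bound 5)
  el <- toy_elements(rep(10, 7))
  ogs <- unlist(lapply(1:7, function(e) og_range(e, 1:10)))
  tg <- toy_genome("messy", list(chr1 = ogs))
  comp <- decompose(tg$genome, orthology_table(tg$orth), el)
  expect_equal(nrow(comp$segments), 7)
  fl <- flag_unresolvable(list(messy = comp))
  expect_false(fl$resolvable)
  expect_match(fl$reasons, "segments per chromosome")
  # ancestral karyotype is never flagged
  tg2 <- toy_genome("tidy", stats::setNames(
    lapply(1:7, function(e) og_range(e, 1:10)), paste0("chr", 1:7)))
  comp2 <- decompose(tg2$genome, orthology_table(tg2$orth), el)
  fl2 <- flag_unresolvable(list(tidy = comp2))
  expect_true(fl2$resolvable)
  # infinite bounds flag nobody
  fl3 <- flag_unresolvable(list(messy = comp),
                           max_segments_per_chrom = Inf,
                           max_total_segments = Inf)
  expect_true(fl3$resolvable)
})
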