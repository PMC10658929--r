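# Element inference, chromosome assignment and decomposition.

make_backbone <- function(n_species = 3, sizes = c(20, 15, 12, 10)) {
  el <- toy_elements(sizes)
  genomes <- list(); orth <- list()
  for (s in seq_len(n_species)) {
    sp <- paste0("bb", s)
    chrom_ogs <- lapply(seq_along(sizes), function(e)
      og_range(e, seq_len(sizes[e])))
    names(chrom_ogs) <- paste0("chr", seq_along(sizes))
    tg <- toy_genome(sp, chrom_ogs)
    genomes[[sp]] <- tg$genome
    orth[[sp]] <- tg$orth
  }
  list(elements = el, genomes = genomes,
       orth = orthology_table(do.call(rbind, orth)))
}

test_that("infer_elements recovers the element partition from identical backbones", {
  bb <- make_backbone(3)
  inf <- infer_elements(bb$genomes, bb$orth, backbone = names(bb$genomes))
  expect_equal(n_elements(inf), 4)
  # numbering by descending gene count reproduces the truth partition
  truth <- element_map(bb$elements)
  got <- element_map(inf)
  expect_identical(got[names(truth)], truth)
  # intra-element order from the first backbone species
  m <- inf$membership[inf$membership$element == 1, ]
  expect_equal(m$orthogroup[order(m$order_rank)], og_range(1, 1:20))
})

test_that("a single backbone species yields its own karyotype as elements", {
  bb <- make_backbone(1)
  inf <- infer_elements(bb$genomes, bb$orth, backbone = names(bb$genomes))
  expect_equal(n_elements(inf), 4)
  expect_equal(unname(table(inf$membership$element)),
               as.integer(c(20, 15, 12, 10)), ignore_attr = TRUE)
})

test_that("chromosome pairs sharing fewer orthogroups than the threshold stay apart", {
  # two single-chromosome species sharing exactly 7 orthogroups
  # (brute-force shared count below), plus 3 private orthogroups each
  el <- toy_elements(c(13))
  a <- toy_genome("A", list(chr1 = og_range(1, 1:10)))
  b <- toy_genome("B", list(chr1 = og_range(1, 4:13)))
  shared <- length(intersect(og_range(1, 1:10), og_range(1, 4:13)))
  expect_equal(shared, 7)
  orth <- orthology_table(rbind(a$orth, b$orth))
  warns <- testthat::capture_warnings(
    inf <- infer_elements(list(a$genome, b$genome), orth,
                          backbone = c("A", "B"), threshold = 8))
  expect_true(any(grepl("share < 8", warns)))
  # no edge: two singleton components; the 7 shared orthogroups have tied
  # placements and are reported unassigned, the private ones are placed
  expect_equal(n_elements(inf), 2)
  expect_setequal(inf$unassigned, og_range(1, 4:10))
  # with 8 shared genes the same pair merges into a single element
  a8 <- toy_genome("A", list(chr1 = og_range(1, 1:10)))
  b8 <- toy_genome("B", list(chr1 = og_range(1, 3:12)))
  orth8 <- orthology_table(rbind(a8$orth, b8$orth))
  inf8 <- infer_elements(list(a8$genome, b8$genome), orth8,
                         backbone = c("A", "B"), threshold = 8)
  expect_equal(n_elements(inf8), 1)
  expect_equal(nrow(inf8$membership), 12)
})

test_that("element definitions round-trip through the TSV dialect", {
  el <- toy_elements(c(10, 9), z_element = 2L)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_elements(el, p)
  el2 <- read_elements(p)
  expect_equal(el2$membership$element, el$membership$element)
  expect_equal(el2$membership$orthogroup, el$membership$orthogroup)
  expect_equal(el2$z_element, 2L)
})

test_that("assignment uses the shared-ortholog threshold in both directions", {
  el <- toy_elements(c(30, 20))
  # chr1: 50 genes of element 1; chrX8: exactly 8 genes of element 2;
  # chrX7: exactly 7 genes of element 2
  tg <- toy_genome("sp", list(
    chr1 = og_range(1, 1:30),
    chrX8 = og_range(2, 1:8),
    chrX7 = og_range(2, 13:19)))
  orth <- orthology_table(tg$orth)
  asg <- assign_chromosomes(tg$genome, orth, el, threshold = 8)
  expect_equal(asg$element[asg$chrom == "chr1" & asg$assigned], 1L)
  expect_equal(asg$element[asg$chrom == "chrX8" & asg$assigned], 2L)
  expect_length(asg$element[asg$chrom == "chrX7" & asg$assigned], 0)
  expect_true("chrX7" %in% attr(asg, "unassigned_chroms"))
})

test_that("raising the assignment threshold never adds elements", {
  sim <- simulate_karyotypes(sim_config(n_taxa = 4, n_elements = 6,
    element_genes = c(40, 35, 30, 25, 20, 14)), seed = 11)
  lorth <- filter_low_copy(sim$orth)
  for (sp in names(sim$genomes)) {
    sets <- lapply(c(5, 8, 12, 20), function(th) {
      a <- assign_chromosomes(sim$genomes[[sp]], lorth, sim$elements,
                              threshold = th)
      split(a$element[a$assigned], a$chrom[a$assigned])
    })
    for (i in seq_len(length(sets) - 1)) {
      for (ch in names(sets[[i + 1]]))
        expect_true(all(sets[[i + 1]][[ch]] %in%
                          (sets[[i]][[ch]] %||% integer(0))))
    }
  }
})

test_that("W-like chromosomes with no ancestral orthologs stay unassigned", {
  el <- toy_elements(c(20))
  tg <- toy_genome("sp", list(chr1 = og_range(1, 1:20),
                              chrW = rep(NA_character_, 10)),
                   sex = c(chr1 = "A", chrW = "W"))
  asg <- assign_chromosomes(tg$genome, orthology_table(tg$orth), el)
  expect_false("chrW" %in% asg$chrom)
  expect_true("chrW" %in% attr(asg, "unassigned_chroms"))
})

test_that("decompose forms segments, bridges short interruptions, splits parts", {
  fx <- fig1_toy()
  comp <- decompose(fx$genome, fx$orth, fx$elements)
  segs <- comp$segments
  # chrA: two segments 1 then 2
  expect_equal(segs$element[segs$chrom == "chrA"], c(1L, 2L))
  # chrD1: 5, 6, 6 (the run of element 6 splits into two ancestral parts)
  expect_equal(segs$element[segs$chrom == "chrD1"], c(5L, 6L, 6L))
  # chrC single whole element
  expect_equal(segs$element[segs$chrom == "chrC"], 4L)

  # short foreign interruption: 3 genes of element 9 inside 50 of element 4
  el <- toy_elements(c(50, rep(10, 7), 20))
  ogs <- c(og_range(1, 1:25), og_range(9, 1:3), og_range(1, 26:50))
  tg <- toy_genome("sp", list(chr1 = ogs))
  comp2 <- decompose(tg$genome, orthology_table(tg$orth), el)
  expect_equal(comp2$segments$element[comp2$segments$chrom == "chr1"], 1L)
  expect_equal(comp2$segments$n_genes[comp2$segments$chrom == "chr1"], 50L)
  expect_setequal(comp2$unplaced$orthogroup, og_range(9, 1:3))
})

test_that("segments and unplaced genes partition the conserved genes exactly", {
  sim <- simulate_karyotypes(sim_config(n_taxa = 6), seed = 3)
  lorth <- filter_low_copy(sim$orth)
  em <- element_map(sim$elements)
  for (sp in names(sim$genomes)) {
    comp <- decompose(sim$genomes[[sp]], lorth, sim$elements)
    om <- gene_orthogroup_map(lorth, sp)
    g <- sim$genomes[[sp]]$genes
    conserved <- g$gene_id[!is.na(em[om[g$gene_id]])]
    seg_genes <- unlist(comp$segments$genes)
    expect_length(intersect(seg_genes, comp$unplaced$gene_id), 0)
    expect_setequal(c(seg_genes, comp$unplaced$gene_id), conserved)
  }
})

test_that("decompose recovers true segments exactly without gene movement", {
  cfg <- sim_config(n_taxa = 8, rates = list(movement = 0, loss = 0.3,
                                             duplication = 0.3, birth = 0.5,
                                             fusion = 0.4, fission = 0.15))
  sim <- simulate_karyotypes(cfg, seed = 5)
  lorth <- filter_low_copy(sim$orth)
  tn <- truth_names(sim$truth)
  for (sp in names(sim$genomes)) {
    comp <- decompose(sim$genomes[[sp]], lorth, sim$elements)
    nm <- name_chromosomes(comp, sim$elements, sim$genomes[[sp]])
    t <- tn[tn$species == sp, ]
    hit <- match(t$chrom, nm$chrom)
    expect_false(anyNA(hit))
    expect_equal(nm$name[hit], t$name)
    expect_equal(nrow(comp$unplaced), 0)
  }
})
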