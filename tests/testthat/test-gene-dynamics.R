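# Movement detection, copy/cut calls, loss/duplication and
# lineage-specific tallies.

# Two-chromosome species: element 10-like source (here element 1) and a
# Z-labelled destination (element 2). `with_parental` keeps a second copy
# of the moved orthogroup on the source chromosome.
movement_toy <- function(with_parental) {
  el <- toy_elements(c(20, 15), z_element = 2L)
  src_ogs <- og_range(1, 1:20)
  z_ogs <- c(og_range(2, 1:15), "E1G20")  # E1G20 copy sits on the Z
  genes <- list(); orth <- list()
  mk <- function(sp_gene, ch, i, og) {
    orth[[length(orth) + 1]] <<- data.frame(orthogroup = og, species = "sp",
                                            gene_id = sp_gene)
    data.frame(gene_id = sp_gene, chrom = ch, start = (i - 1) * 2000,
               end = (i - 1) * 2000 + 1000, strand = "+")
  }
  rows <- list()
  src <- if (with_parental) src_ogs else setdiff(src_ogs, "E1G20")
  for (i in seq_along(src))
    rows[[length(rows) + 1]] <- mk(paste0("a", i), "chrA", i, src[i])
  for (i in seq_along(z_ogs))
    rows[[length(rows) + 1]] <- mk(paste0("z", i), "chrZ", i, z_ogs[i])
  gdf <- do.call(rbind, rows)
  chroms <- data.frame(chrom = c("chrA", "chrZ"), sex_label = c("A", "Z"),
                       length_bp = 1e5, gc = NA_real_)
  g <- genome_table("sp", gdf, chroms)
  o <- orthology_table(do.call(rbind, orth))
  comp <- decompose(g, o, el)
  list(el = el, genome = g, orth = o, comp = comp)
}

test_that("an off-element gene with no paralog at the source is a cut movement", {
  t <- movement_toy(with_parental = FALSE)
  mv <- detect_movements(list(sp = t$comp), t$orth, t$el,
                         list(sp = t$genome))
  expect_equal(nrow(mv), 1)
  expect_equal(mv$orthogroup, "E1G20")
  expect_equal(mv$source_class, "A")
  expect_equal(mv$dest_class, "Z")
  expect_equal(mv$mechanism, "cut")
  expect_true(is.na(mv$parental_gene))
})

test_that("a retained source copy makes the movement copy-type with a parental gene", {
  t <- movement_toy(with_parental = TRUE)
  mv <- detect_movements(list(sp = t$comp), t$orth, t$el,
                         list(sp = t$genome))
  expect_equal(nrow(mv), 1)
  expect_equal(mv$mechanism, "copy")
  expect_equal(mv$parental_gene, "a20")   # the chrA copy of E1G20
})

test_that("genes sitting on a chromosome housing their own element are not movements", {
  el <- toy_elements(c(20, 15))
  tg <- toy_genome("sp", list(chr1 = og_range(1, 1:20),
                              chr2 = og_range(2, 1:15)))
  orth <- orthology_table(tg$orth)
  comp <- decompose(tg$genome, orth, el)
  mv <- detect_movements(list(sp = comp), orth, el, list(sp = tg$genome))
  expect_equal(nrow(mv), 0)
})

test_that("movement categories are exhaustive, disjoint and zero-filled", {
  empty <- detect_movements(list(), orthology_table(
    data.frame(orthogroup = character(), species = character(),
               gene_id = character())), toy_elements(c(10)), list())
  cl <- classify_movements(empty)
  expect_equal(cl$category, c("A->A", "A->Z", "Z->A", "A->W", "Z->W"))
  expect_true(all(cl$n_genes == 0))

  ev <- data.frame(species = "sp", gene_id = c("g1", "g2"),
                   orthogroup = c("OG1", "OG2"), source_element = c(1L, 1L),
                   source_class = "A", dest_chrom = c("chrZ", "chrW"),
                   dest_class = c("Z", "W"), mechanism = "cut",
                   parental_gene = NA_character_, low_confidence = FALSE)
  cl2 <- classify_movements(ev)
  expect_equal(cl2$n_genes[cl2$category == "A->Z"], 1L)
  expect_equal(cl2$n_genes[cl2$category == "A->W"], 1L)
  expect_equal(sum(cl2$n_genes), 2L)
})

test_that("movement categories on simulated data match the truth log", {
  sim <- simulate_karyotypes(sim_config(n_taxa = 10), seed = 21)
  pl <- run_pipeline(sim)
  mv <- detect_movements(pl$comps, pl$lorth, sim$elements, sim$genomes)
  td <- sim$truth$movements[sim$truth$movements$detectable, ]
  t_cat <- table(factor(paste0(td$source_class, "->", td$dest_class),
                        levels = c("A->A", "A->Z", "Z->A", "A->W", "Z->W")))
  i_cat <- classify_movements(mv)
  expect_equal(i_cat$n_genes, as.integer(t_cat))
})

test_that("loss and duplication tallies follow the copy-number definitions", {
  # 3 species, element of 2 genes; spB misses one gene -> 1 loss on 2
  # ancestral genes = 0.5 losses/gene; spC carries 2 copies of the other
  el <- toy_elements(c(2))
  ga <- toy_genome("spA", list(chr1 = c("E1G01", "E1G02")))
  gb <- toy_genome("spB", list(chr1 = c("E1G01")))
  gc_ <- toy_genome("spC", list(chr1 = c("E1G01", "E1G02")))
  extra <- data.frame(orthogroup = "E1G02", species = "spC",
                      gene_id = "spC_E1G02_b")
  gcg <- gc_$genome
  gcg$genes <- rbind(gcg$genes,
                     data.frame(gene_id = "spC_E1G02_b", chrom = "chr1",
                                start = 4000, end = 5000, strand = "+",
                                rank = 3L))
  gcg <- genome_table("spC", gcg$genes[, 1:5],
                      data.frame(chrom = "chr1", sex_label = "A",
                                 length_bp = 10000, gc = NA_real_))
  orth <- orthology_table(rbind(ga$orth, gb$orth, gc_$orth, extra))
  st <- loss_dup_stats(list(spA = ga$genome, spB = gb$genome, spC = gcg),
                       orth, el)
  expect_equal(st$total_losses, 1L)
  expect_equal(st$losses_per_gene, 0.5)
  expect_equal(st$total_duplications, 1L)
  expect_equal(st$duplications_per_gene, 0.5)

  # all species single-copy everywhere -> all zeros
  st0 <- loss_dup_stats(list(spA = ga$genome, spC = gc_$genome),
                        orthology_table(rbind(ga$orth, gc_$orth)), el)
  expect_equal(st0$total_losses, 0L)
  expect_equal(st0$total_duplications, 0L)
})

test_that("loss/dup totals do not depend on species processing order", {
  sim <- simulate_karyotypes(sim_config(n_taxa = 6), seed = 13)
  lorth <- filter_low_copy(sim$orth)
  a <- loss_dup_stats(sim$genomes, lorth, sim$elements)
  b <- loss_dup_stats(rev(sim$genomes), lorth, sim$elements)
  expect_identical(a, b)
})

test_that("lineage-specific genes are those with no homolog in other species", {
  # chr1: 6 conserved + 4 lineage-specific of 10 genes -> proportion 0.4
  el <- toy_elements(c(6))
  tg <- toy_genome("spA", list(chr1 = c(og_range(1, 1:6),
                                        rep(NA_character_, 4))))
  other <- toy_genome("spB", list(chr1 = og_range(1, 1:6)))
  # one orthogroup private to spA: counts as lineage-specific too
  priv <- data.frame(orthogroup = "PRIV1", species = "spA",
                     gene_id = "spA_p1")
  g2 <- tg$genome
  g2$genes <- rbind(g2$genes[, 1:5],
                    data.frame(gene_id = "spA_p1", chrom = "chr1",
                               start = 30000, end = 31000, strand = "+"))
  g2 <- genome_table("spA", g2$genes,
                     data.frame(chrom = "chr1", sex_label = "A",
                                length_bp = 40000, gc = NA_real_))
  orth <- orthology_table(rbind(tg$orth, other$orth, priv))
  ls <- lineage_specific_counts(list(spA = g2, spB = other$genome), orth)
  a <- ls[ls$species == "spA", ]
  expect_equal(a$n_lineage_specific, 5L)   # 4 orphans + 1 private
  expect_equal(a$n_total_genes, 11L)
  expect_equal(a$proportion, 5 / 11)
  b <- ls[ls$species == "spB", ]
  expect_equal(b$n_lineage_specific, 0L)
})
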