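# Collinear block chaining, breakpoint extraction, W network.

test_that("identical gene order yields one forward block", {
  pr <- random_chrom_pair(20, seed = 1)
  # overwrite B with identical order
  ogs <- sprintf("OG%03d", 1:20)
  b <- toy_genome("spB", list(chr1 = ogs))
  orth <- orthology_table(rbind(
    pr$orth[pr$orth$species == "spA", ], b$orth))
  bl <- find_blocks(pr$genome_a, b$genome, orth)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$orientation, "+")
  expect_equal(bl$n_anchors, 20L)
})

test_that("reversed gene order yields one reverse block", {
  ogs <- sprintf("OG%03d", 1:20)
  a <- toy_genome("spA", list(chr1 = ogs))
  b <- toy_genome("spB", list(chr1 = rev(ogs)))
  orth <- orthology_table(rbind(a$orth, b$orth))
  bl <- find_blocks(a$genome, b$genome, orth)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$orientation, "-")
  expect_equal(bl$n_anchors, 20L)
})

test_that("tandem duplicate anchors collapse to the first copy", {
  ogs <- sprintf("OG%03d", 1:10)
  a_ogs <- c(ogs[1:5], "OG005", ogs[6:10])   # tandem copy of OG005
  ga <- genome_table("spA", data.frame(
    gene_id = sprintf("a%02d", seq_along(a_ogs)), chrom = "chr1",
    start = (seq_along(a_ogs) - 1) * 2000,
    end = (seq_along(a_ogs) - 1) * 2000 + 1000))
  b <- toy_genome("spB", list(chr1 = ogs))
  orth <- orthology_table(rbind(
    data.frame(orthogroup = a_ogs, species = "spA",
               gene_id = sprintf("a%02d", seq_along(a_ogs))),
    b$orth))
  anc <- build_anchors(ga, b$genome, orth, "chr1", "chr1")
  expect_equal(nrow(anc), 10)   # not 11: the tandem copy is collapsed
  expect_false("a06" %in% anc$gene_a)
})

test_that("greedy chaining equals exhaustive enumeration on random permutations", {
  # cross-checked against the DFS oracle over all maximal valid chains
  for (seed in 1:40) {
    n <- sample(8:30, 1)
    pr <- random_chrom_pair(n, seed = seed)
    gap <- sample(c(3, 5, 10, 25), 1)
    anc <- build_anchors(pr$genome_a, pr$genome_b, pr$orth, "chr1", "chr1")
    got <- karyevo:::chain_anchors(anc, max_gap = gap)
    want <- oracle_chains(anc, max_gap = gap)
    expect_equal(length(got), length(want))
    for (k in seq_along(got)) {
      expect_identical(got[[k]]$idx, want[[k]]$idx)
      expect_identical(got[[k]]$dir, want[[k]]$dir)
    }
  }
})

test_that("block finding is symmetric up to orientation and rank swap", {
  for (seed in 41:50) {
    pr <- random_chrom_pair(25, seed = seed)
    ab <- find_blocks(pr$genome_a, pr$genome_b, pr$orth,
                      min_block_genes = 3)
    ba <- find_blocks(pr$genome_b, pr$genome_a, pr$orth,
                      min_block_genes = 3)
    expect_equal(nrow(ab), nrow(ba))
    key <- function(bl, swap) {
      anc <- attr(bl, "anchors")
      sort(vapply(anc, function(a) {
        og <- a$orthogroup[order(if (swap) a$rank_b else a$rank_a)]
        paste(og, collapse = ",")
      }, ""))
    }
    expect_identical(key(ab, FALSE), key(ba, TRUE))
  }
})

test_that("breakpoints are the gaps between block extents, ends excluded", {
  bl <- data.frame(block_id = 1:2, chrom_a = "chr1", chrom_b = "x",
                   orientation = "+", n_anchors = 5L,
                   a_start = c(0, 150), a_end = c(100, 300),
                   b_start = 0, b_end = 1)
  br <- find_breakpoints(bl, species = "sp")
  expect_equal(nrow(br), 1)
  expect_equal(c(br$start, br$end), c(100, 150))
  # single block: only ends, no regions
  br1 <- find_breakpoints(bl[1, ], species = "sp")
  expect_equal(nrow(br1), 0)
  # three blocks -> two regions
  bl3 <- rbind(bl, data.frame(block_id = 3L, chrom_a = "chr1",
                              chrom_b = "x", orientation = "+",
                              n_anchors = 5L, a_start = 400, a_end = 500,
                              b_start = 0, b_end = 1))
  br3 <- find_breakpoints(bl3, species = "sp")
  expect_equal(nrow(br3), 2)
  expect_equal(br3$start, c(100, 300))
  expect_equal(br3$end, c(150, 400))
  # abutting blocks produce no zero-length region
  bl0 <- bl; bl0$a_start[2] <- 100
  br0 <- find_breakpoints(bl0, species = "sp")
  expect_equal(nrow(br0), 0)
  expect_gt(attr(br0, "skipped"), 0)
})

test_that("blocks, breakpoints and end gaps tile the focal chromosome", {
  sim <- simulate_karyotypes(sim_config(n_taxa = 6), seed = 17)
  lorth <- filter_low_copy(sim$orth)
  sps <- names(sim$genomes)
  bl <- find_blocks(sim$genomes[[sps[1]]], sim$genomes[[sps[2]]], lorth,
                    min_block_genes = 5)
  br <- find_breakpoints(bl, species = sps[1])
  lens <- stats::setNames(sim$genomes[[sps[1]]]$chroms$length_bp,
                          sim$genomes[[sps[1]]]$chroms$chrom)
  for (ch in unique(bl$chrom_a)) {
    b <- bl[bl$chrom_a == ch, ]
    b <- b[order(b$a_start), ]
    # merge overlapping extents
    pieces <- list()
    s <- b$a_start[1]; e <- b$a_end[1]
    for (i in seq_len(nrow(b))[-1]) {
      if (b$a_start[i] < e) e <- max(e, b$a_end[i])
      else { pieces[[length(pieces) + 1]] <- c(s, e)
             s <- b$a_start[i]; e <- b$a_end[i] }
    }
    pieces[[length(pieces) + 1]] <- c(s, e)
    gaps <- br[br$chrom == ch, c("start", "end")]
    segs <- rbind(do.call(rbind, pieces),
                  as.matrix(gaps),
                  c(0, pieces[[1]][1]),
                  c(e, lens[[ch]]))
    dimnames(segs) <- NULL
    segs <- segs[segs[, 1] < segs[, 2], , drop = FALSE]
    segs <- segs[order(segs[, 1]), , drop = FALSE]
    # contiguous, non-overlapping cover of [0, L]
    expect_equal(segs[1, 1], 0)
    expect_equal(segs[nrow(segs), 2], unname(lens[[ch]]))
    if (nrow(segs) > 1)
      expect_equal(segs[-1, 1], segs[-nrow(segs), 2], ignore_attr = TRUE)
  }
})

test_that("the W network connects chains transitively into one component", {
  # A-B and B-C share blocks, A-C do not: still one component
  og_ab <- sprintf("AB%02d", 1:8)
  og_bc <- sprintf("BC%02d", 1:8)
  wa <- toy_genome("A", list(W = og_ab), sex = c(W = "W"))
  wb <- toy_genome("B", list(W = c(og_ab, og_bc)), sex = c(W = "W"))
  wc <- toy_genome("C", list(W = og_bc), sex = c(W = "W"))
  wd <- toy_genome("D", list(W = sprintf("DD%02d", 1:8)), sex = c(W = "W"))
  orth <- orthology_table(rbind(wa$orth, wb$orth, wc$orth, wd$orth))
  net <- w_network(list(A = wa$genome, B = wb$genome, C = wc$genome,
                        D = wd$genome), orth, min_genes_edge = 7)
  expect_true(net$edge["A", "B"])
  expect_true(net$edge["B", "C"])
  expect_false(net$edge["A", "C"])
  expect_equal(net$components[["A"]], net$components[["C"]])
  # the isolated W is its own component
  expect_false(net$components[["D"]] == net$components[["A"]])
  # matrices symmetric with zero diagonal
  expect_identical(net$block_counts, t(net$block_counts))
  expect_true(all(diag(net$block_counts) == 0))
  expect_equal(net$gene_counts["A", "B"], 8L)
})
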