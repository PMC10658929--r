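## Karyotype-evolution simulator with complete truth logs.
##
## An ancestral genome of K elements (one per chromosome, genes in a fixed
## ancestral order) evolves along a rooted species tree. Per branch, event
## counts are Poisson-distributed for each event kind:
##   fusion       - two chromosomes joined end-to-end, each in a random
##                  orientation (a junction marker records the joint)
##   fission      - one chromosome cut at a uniform inter-gene point (cuts
##                  are constrained so every element split leaves at least
##                  min_part_genes genes on each side, keeping parts
##                  detectable)
##   movement     - one conserved gene relocated to a uniform position on
##                  another chromosome; with probability copy_fraction the
##                  source copy is retained (copy/RNA-type), otherwise cut
##   loss         - one single-copy conserved gene deleted
##   duplication  - one single-copy conserved gene duplicated in place
##   birth        - one new lineage-specific gene (no orthogroup) inserted;
##                  the Z-carrying chromosome can draw births at an
##                  elevated rate via z_ls_multiplier
## Copy numbers never exceed two per orthogroup per species, matching the
## low-copy orthology filter downstream. A W chromosome (no ancestral
## orthologs, the female-limited chromosome) is carried from the root when
## with_w is set; it receives movements and births but never fuses or
## fissions - a deliberate simplification.
##
## The truth log records every event with all random choices resolved, so
## replaying it from the ancestral genome reproduces the extant genomes
## exactly, and derives per-species ground truth for every pipeline stage.

#' Simulator configuration
#'
#' Defaults emulate the study conditions of a deep lepidopteran-style
#' radiation: 31 ancestral elements with 14-259 genes each, Z at size rank
#' 20, modest per-branch rearrangement rates.
#'
#' @param n_taxa Number of tip species (used when `tree` is `NULL`).
#' @param tree Optional rooted `phylo`; default a random coalescent tree.
#' @param n_elements Number of ancestral elements (default 31).
#' @param element_genes Optional integer vector of element gene counts
#'   (descending); default sampled uniformly on 14..259 and sorted.
#' @param z_rank Size rank of the Z element (default 20, i.e. element 20).
#' @param rates Named per-branch Poisson means: `fusion`, `fission`,
#'   `movement`, `loss`, `duplication`, `birth`.
#' @param copy_fraction Probability a movement retains the source copy.
#' @param z_ls_multiplier Relative birth weight of the Z-carrying
#'   chromosome (default 1 = no excess).
#' @param with_w Carry a W chromosome (default `TRUE`).
#' @param min_part_genes Minimum genes per fission part (default 8).
#' @param te Transposable-element track parameters: `background` (expected
#'   TEs per bp per class), `bias` (density multiplier near breakpoints),
#'   `bias_class`, `window` (half-width bp), `te_length`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 16L, tree = NULL, n_elements = 31L,
                       element_genes = NULL, z_rank = 20L,
                       rates = list(fusion = 0.3, fission = 0.1,
                                    movement = 0.5, loss = 1,
                                    duplication = 0.5, birth = 1),
                       copy_fraction = 0.5, z_ls_multiplier = 1,
                       with_w = TRUE, min_part_genes = 8L,
                       te = list(background = 2e-4, bias = 1,
                                 bias_class = "LTR", window = 10000,
                                 te_length = 500)) {
  base_rates <- list(fusion = 0.3, fission = 0.1, movement = 0.5, loss = 1,
                     duplication = 0.5, birth = 1)
  base_rates[names(rates)] <- rates
  base_te <- list(background = 2e-4, bias = 1, bias_class = "LTR",
                  window = 10000, te_length = 500)
  base_te[names(te)] <- te
  if (any(unlist(base_rates) < 0)) stop_data("rates must be >= 0")
  if (copy_fraction < 0 || copy_fraction > 1)
    stop_data("copy_fraction must lie in [0, 1]")
  structure(list(n_taxa = n_taxa, tree = tree, n_elements = n_elements,
                 element_genes = element_genes,
                 z_rank = min(z_rank, n_elements), rates = base_rates,
                 copy_fraction = copy_fraction,
                 z_ls_multiplier = z_ls_multiplier, with_w = with_w,
                 min_part_genes = min_part_genes, te = base_te),
            class = "sim_config")
}

GENE_SPAN <- 1000
GENE_STEP <- 2000

empty_items <- function() {
  data.frame(type = character(), uid = character(), og = character(),
             element = integer(), moved = logical(),
             stringsAsFactors = FALSE)
}

gene_items <- function(uid, og, element) {
  data.frame(type = "gene", uid = uid, og = og, element = element,
             moved = FALSE, stringsAsFactors = FALSE)
}

junction_item <- function(jid) {
  data.frame(type = "junction", uid = jid, og = NA_character_,
             element = NA_integer_, moved = FALSE, stringsAsFactors = FALSE)
}

## ---- event application (shared by simulation and replay) ----

apply_event <- function(genome, ev) {
  switch(ev$kind,
    fusion = {
      a <- genome[[ev$chrom_a]]; b <- genome[[ev$chrom_b]]
      if (ev$rev_a) a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
      if (ev$rev_b) b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
      genome[[ev$chrom_a]] <- NULL
      genome[[ev$chrom_b]] <- NULL
      genome[[ev$new_id]] <- rbind(a, junction_item(ev$jid), b)
    },
    fission = {
      it <- genome[[ev$chrom]]
      left <- it[seq_len(ev$left_upto), , drop = FALSE]
      right <- it[seq.int(ev$right_from, nrow(it)), , drop = FALSE]
      genome[[ev$chrom]] <- NULL
      genome[[ev$new_left]] <- left
      genome[[ev$new_right]] <- right
    },
    move = {
      src <- genome[[ev$from_chrom]]
      i <- which(src$uid == ev$uid)
      gene <- src[i, , drop = FALSE]
      if (ev$mechanism == "cut") {
        genome[[ev$from_chrom]] <- src[-i, , drop = FALSE]
      } else {
        gene$uid <- ev$new_uid
      }
      gene$moved <- TRUE
      dst <- genome[[ev$to_chrom]]
      genome[[ev$to_chrom]] <- insert_rows(dst, gene, ev$after)
    },
    loss = {
      it <- genome[[ev$chrom]]
      genome[[ev$chrom]] <- it[it$uid != ev$uid, , drop = FALSE]
    },
    dup = {
      it <- genome[[ev$chrom]]
      i <- which(it$uid == ev$uid)
      gene <- it[i, , drop = FALSE]
      gene$uid <- ev$new_uid
      genome[[ev$chrom]] <- insert_rows(it, gene, i)
    },
    birth = {
      it <- genome[[ev$chrom]]
      gene <- gene_items(ev$uid, NA_character_, NA_integer_)
      genome[[ev$chrom]] <- insert_rows(it, gene, ev$after)
    },
    stop_data("unknown event kind: ", ev$kind))
  genome
}

insert_rows <- function(df, rows, after) {
  n <- nrow(df)
  if (after >= n) return(rbind(df, rows))
  if (after <= 0) return(rbind(rows, df))
  rbind(df[seq_len(after), , drop = FALSE], rows,
        df[seq.int(after + 1L, n), , drop = FALSE])
}

## rows (item indices) of conserved genes
gene_rows <- function(it) which(it$type == "gene" & !is.na(it$og))

## copy count per orthogroup in the whole genome
og_copies <- function(genome) {
  ogs <- unlist(lapply(genome, function(it) it$og[it$type == "gene"]),
                use.names = FALSE)
  table(ogs[!is.na(ogs)])
}

z_chrom_of <- function(genome, z_el) {
  zc <- vapply(genome, function(it)
    sum(it$type == "gene" & !is.na(it$element) & it$element == z_el), 0L)
  if (all(zc == 0)) return(NA_character_)
  names(genome)[which.max(zc)]
}

## ---- simulation ----

#' Simulate karyotype evolution with a truth log
#'
#' @param config A [sim_config()].
#' @param seed Mandatory RNG seed.
#' @return List of class `karyo_sim`: `genomes` (named list of
#'   [genome_table()]), `orth` ([orthology_table()]), `elements`
#'   ([ancestral_elements()]), `tree` (`phylo`), `te_tracks` (named list of
#'   [interval_track()]), `truth` (the `karyo_truth` log).
#' @export
simulate_karyotypes <- function(config = sim_config(), seed) {
  if (missing(seed)) stop_data("seed is required for simulate_karyotypes()")
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)

  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rcoal(config$n_taxa,
                       tip.label = sprintf("sp%02d", seq_len(config$n_taxa)))
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  ## ancestral genome
  K <- config$n_elements
  sizes <- config$element_genes
  if (is.null(sizes)) sizes <- sample(14:259, K, replace = TRUE)
  sizes <- sort(as.integer(sizes), decreasing = TRUE)
  total_genes <- sum(sizes)
  turnover <- with(config$rates, loss + duplication + movement + birth)
  if (turnover > 0.5 * total_genes)
    stop_data("rates imply > 50% expected gene turnover per branch; ",
              "truth would be unrecoverable")
  z_el <- config$z_rank
  og_id <- 0L
  ancestor <- list()
  memb <- list()
  for (e in seq_len(K)) {
    ogs <- sprintf("OG%05d", og_id + seq_len(sizes[e]))
    og_id <- og_id + sizes[e]
    ancestor[[paste0("c", e)]] <- gene_items(ogs, ogs, e)
    memb[[e]] <- data.frame(element = e, orthogroup = ogs,
                            order_rank = seq_along(ogs))
  }
  elements <- ancestral_elements(do.call(rbind, memb), z_element = z_el)
  if (config$with_w) ancestor[["cW"]] <- empty_items()

  counters <- new.env()
  counters$chrom <- K
  counters$jid <- 0L
  counters$fid <- 0L
  counters$copy <- 0L
  counters$ls <- 0L

  events <- list()        # flat, in application order, each with $branch
  junction_log <- list()  # jid -> sides at creation
  fission_log <- list()   # fid -> element splits at cut

  draw_branch_events <- function(genome, node) {
    r <- config$rates
    kinds <- c(rep("fusion", stats::rpois(1, r$fusion)),
               rep("fission", stats::rpois(1, r$fission)),
               rep("move", stats::rpois(1, r$movement)),
               rep("loss", stats::rpois(1, r$loss)),
               rep("dup", stats::rpois(1, r$duplication)),
               rep("birth", stats::rpois(1, r$birth)))
    if (length(kinds) > 1L) kinds <- sample(kinds)
    for (kind in kinds) {
      ev <- propose_event(genome, kind, node)
      if (is.null(ev)) next
      genome <- apply_event(genome, ev)
      events[[length(events) + 1L]] <<- ev
    }
    genome
  }

  propose_event <- function(genome, kind, node) {
    ids <- sort(names(genome))
    auto_ids <- setdiff(ids, "cW")
    switch(kind,
      fusion = {
        elig <- auto_ids[vapply(genome[auto_ids],
                                function(it) any(it$type == "gene"), TRUE)]
        if (length(elig) < 2L) return(NULL)
        pick <- sample(elig, 2L)
        counters$chrom <- counters$chrom + 1L
        counters$jid <- counters$jid + 1L
        jid <- sprintf("J%04d", counters$jid)
        ev <- list(kind = "fusion", branch = node, chrom_a = pick[1],
                   chrom_b = pick[2],
                   rev_a = stats::runif(1) < 0.5,
                   rev_b = stats::runif(1) < 0.5,
                   new_id = paste0("c", counters$chrom), jid = jid)
        ## truth: the terminal same-element runs meeting at the joint
        a <- genome[[pick[1]]]; b <- genome[[pick[2]]]
        if (ev$rev_a) a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
        if (ev$rev_b) b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
        junction_log[[jid]] <<- list(
          jid = jid, branch = node,
          side_a = terminal_run(a, tail = TRUE),
          side_b = terminal_run(b, tail = FALSE))
        ev
      },
      fission = {
        elig <- auto_ids[vapply(genome[auto_ids], function(it)
          sum(it$type == "gene") >= 2L, TRUE)]
        if (!length(elig)) return(NULL)
        for (ch in sample(elig)) {
          it <- genome[[ch]]
          gaps <- valid_cuts(it, config$min_part_genes)
          if (!length(gaps)) next
          g <- if (length(gaps) == 1L) gaps else sample(gaps, 1L)
          gp <- gene_positions(it)
          left_upto <- gp[g]
          right_from <- gp[g + 1L]
          counters$chrom <- counters$chrom + 2L
          counters$fid <- counters$fid + 1L
          fid <- sprintf("F%04d", counters$fid)
          ## junction markers inside the cut gap dissolve
          mid <- if (right_from - left_upto > 1L)
            it$uid[seq.int(left_upto + 1L, right_from - 1L)] else character(0)
          ev <- list(kind = "fission", branch = node, chrom = ch,
                     left_upto = left_upto, right_from = right_from,
                     new_left = paste0("c", counters$chrom - 1L),
                     new_right = paste0("c", counters$chrom),
                     fid = fid, dissolved = mid)
          splits <- element_splits(it, left_upto, right_from)
          fission_log[[fid]] <<- list(fid = fid, branch = node,
                                      element = splits$element,
                                      parts = splits$parts)
          return(ev)
        }
        NULL
      },
      move = {
        pool <- list()
        for (ch in ids) {
          rows <- gene_rows(genome[[ch]])
          if (length(rows))
            pool[[ch]] <- data.frame(ch = ch, row = rows,
                                     stringsAsFactors = FALSE)
        }
        pool <- do.call(rbind, pool)
        if (is.null(pool) || !nrow(pool)) return(NULL)
        k <- sample.int(nrow(pool), 1L)
        src <- pool$ch[k]; row <- pool$row[k]
        gene <- genome[[src]][row, ]
        dests <- setdiff(ids, src)
        if (!length(dests)) return(NULL)
        dst <- if (length(dests) == 1L) dests else sample(dests, 1L)
        copies <- sum(vapply(genome, function(it)
          sum(it$type == "gene" & !is.na(it$og) & it$og == gene$og), 0L))
        mech <- if (copies < 2L && stats::runif(1) < config$copy_fraction)
          "copy" else "cut"
        new_uid <- NA_character_
        if (mech == "copy") {
          counters$copy <- counters$copy + 1L
          new_uid <- paste0(gene$og, ".m", counters$copy)
        }
        list(kind = "move", branch = node, uid = gene$uid, og = gene$og,
             element = gene$element, from_chrom = src, to_chrom = dst,
             after = sample.int(nrow(genome[[dst]]) + 1L, 1L) - 1L,
             mechanism = mech, new_uid = new_uid)
      },
      loss = {
        cp <- og_copies(genome)
        single <- names(cp)[cp == 1]
        if (!length(single)) return(NULL)
        og <- if (length(single) == 1L) single else sample(single, 1L)
        for (ch in ids) {
          it <- genome[[ch]]
          i <- which(it$type == "gene" & !is.na(it$og) & it$og == og)
          if (length(i))
            return(list(kind = "loss", branch = node, chrom = ch,
                        uid = it$uid[i[1]], og = og,
                        element = it$element[i[1]]))
        }
        NULL
      },
      dup = {
        cp <- og_copies(genome)
        single <- names(cp)[cp == 1]
        if (!length(single)) return(NULL)
        og <- if (length(single) == 1L) single else sample(single, 1L)
        for (ch in ids) {
          it <- genome[[ch]]
          i <- which(it$type == "gene" & !is.na(it$og) & it$og == og)
          if (length(i)) {
            counters$copy <- counters$copy + 1L
            return(list(kind = "dup", branch = node, chrom = ch,
                        uid = it$uid[i[1]], og = og,
                        element = it$element[i[1]],
                        new_uid = paste0(og, ".d", counters$copy)))
          }
        }
        NULL
      },
      birth = {
        w <- rep(1, length(ids))
        zc <- z_chrom_of(genome, z_el)
        if (!is.na(zc)) w[ids == zc] <- config$z_ls_multiplier
        ch <- ids[sample.int(length(ids), 1L, prob = w)]
        counters$ls <- counters$ls + 1L
        list(kind = "birth", branch = node, chrom = ch,
             uid = sprintf("LS%05d", counters$ls),
             after = sample.int(nrow(genome[[ch]]) + 1L, 1L) - 1L)
      })
  }

  ## preorder traversal
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- ancestor
  edge_order <- preorder_edges(tree)
  for (k in edge_order) {
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    states[[child]] <- draw_branch_events(states[[parent]], child)
  }

  ## tip emission
  tips <- stats::setNames(vector("list", ntip), tree$tip.label)
  genomes <- list(); orth_rows <- list(); te_tracks <- list()
  bp_rows <- list()
  for (ti in seq_len(ntip)) {
    sp <- tree$tip.label[ti]
    emitted <- emit_tip(states[[ti]], sp, z_el, config)
    tips[[sp]] <- emitted$state
    genomes[[sp]] <- emitted$genome
    orth_rows[[sp]] <- emitted$orth
    te_tracks[[sp]] <- emitted$te
    bp_rows[[sp]] <- emitted$breakpoints
  }
  orth_df <- do.call(rbind, orth_rows)
  orth <- orthology_table(orth_df[!is.na(orth_df$orthogroup), , drop = FALSE])

  truth <- structure(list(
    config = config, seed = seed, tree = tree,
    ancestor = ancestor, elements = elements, events = events,
    junctions = junction_log, fissions = fission_log, tips = tips,
    breakpoints = do.call(rbind, bp_rows)), class = "karyo_truth")
  truth <- derive_truth(truth, genomes, orth)

  structure(list(genomes = genomes, orth = orth, elements = elements,
                 tree = tree, te_tracks = te_tracks, truth = truth),
            class = "karyo_sim")
}

preorder_edges <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids_edges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    ke <- kids_edges[[as.character(nd)]]
    if (is.null(ke)) next
    ke <- ke[order(tree$edge[ke, 2])]
    out <- c(out, ke)
    stack <- c(stack, tree$edge[ke, 2])
  }
  out
}

gene_positions <- function(it) which(it$type == "gene")

## gaps between consecutive genes where every element split by the cut
## keeps >= min_part genes on both sides
valid_cuts <- function(it, min_part) {
  gp <- gene_positions(it)
  m <- length(gp)
  if (m < 2L) return(integer(0))
  e <- it$element[gp]
  conserved <- !is.na(e) & !it$moved[gp]
  ok <- rep(TRUE, m - 1L)
  for (el in unique(e[conserved])) {
    isel <- conserved & e == el
    left <- cumsum(isel)[-m]
    tot <- sum(isel)
    right <- tot - left
    bad <- left > 0 & right > 0 & (left < min_part | right < min_part)
    ok <- ok & !bad
  }
  which(ok)
}

element_splits <- function(it, left_upto, right_from) {
  n <- nrow(it)
  lg <- it[seq_len(left_upto), , drop = FALSE]
  rg <- it[seq.int(right_from, n), , drop = FALSE]
  lg <- lg[lg$type == "gene" & !is.na(lg$element) & !lg$moved, , drop = FALSE]
  rg <- rg[rg$type == "gene" & !is.na(rg$element) & !rg$moved, , drop = FALSE]
  both <- intersect(unique(lg$element), unique(rg$element))
  list(element = both,
       parts = lapply(both, function(el)
         list(left = lg$og[lg$element == el], right = rg$og[rg$element == el])))
}

## terminal same-element run of conserved genes (tail or head of items)
terminal_run <- function(it, tail = TRUE) {
  g <- it[it$type == "gene" & !is.na(it$element) & !it$moved, , drop = FALSE]
  if (!nrow(g)) return(list(element = NA_integer_, ogs = character(0)))
  if (tail) g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
  el <- g$element[1]
  run <- g$og[cumsum(g$element != el) == 0]
  list(element = el, ogs = run)
}

emit_tip <- function(state, sp, z_el, config) {
  ids <- names(state)
  ng <- vapply(state, function(it) sum(it$type == "gene"), 0L)
  auto <- setdiff(ids, "cW")
  ord <- auto[order(-ng[auto], auto)]
  names_map <- stats::setNames(paste0("chr", seq_along(ord)), ord)
  if ("cW" %in% ids) names_map["cW"] <- "chrW"
  zc <- z_chrom_of(state[auto], z_el)

  genes <- list(); chroms <- list(); orth <- list(); bps <- list()
  for (cid in c(ord, intersect("cW", ids))) {
    it <- state[[cid]]
    ch <- names_map[[cid]]
    gp <- gene_positions(it)
    n <- length(gp)
    L <- max(GENE_STEP * n, 10000)
    if (n) {
      st <- (seq_len(n) - 1) * GENE_STEP
      genes[[cid]] <- data.frame(
        gene_id = it$uid[gp], chrom = ch, start = st,
        end = st + GENE_SPAN, strand = "+", stringsAsFactors = FALSE)
      orth[[cid]] <- data.frame(orthogroup = it$og[gp], species = sp,
                                gene_id = it$uid[gp],
                                stringsAsFactors = FALSE)
    }
    ## junction-marker bp positions: midpoint of the flanking gene gap
    jp <- which(it$type == "junction")
    if (length(jp) && n) {
      pos_of <- function(j) {
        nl <- sum(gp < j)    # genes to the left
        if (nl == 0) return(0)
        if (nl == n) return(L)
        (nl - 1) * GENE_STEP + GENE_SPAN + (GENE_STEP - GENE_SPAN) / 2
      }
      bps[[cid]] <- data.frame(species = sp, chrom = ch,
                               pos = vapply(jp, pos_of, 0),
                               jid = it$uid[jp], stringsAsFactors = FALSE)
    }
    chroms[[cid]] <- data.frame(
      chrom = ch,
      sex_label = if (cid == "cW") "W"
                  else if (!is.na(zc) && cid == zc) "Z" else "A",
      length_bp = L, gc = round(stats::runif(1, 0.34, 0.40), 4),
      stringsAsFactors = FALSE)
  }
  gdf <- do.call(rbind, genes) %||% data.frame(
    gene_id = character(), chrom = character(), start = numeric(),
    end = numeric(), strand = character())
  cdf <- do.call(rbind, chroms)
  gt <- genome_table(sp, gdf, cdf)

  bp <- do.call(rbind, bps) %||%
    data.frame(species = character(), chrom = character(), pos = numeric(),
               jid = character())

  ## TE track: uniform background plus optional excess near breakpoints
  te <- config$te
  chrom_lengths <- stats::setNames(cdf$length_bp, cdf$chrom)
  track <- random_te_track(chrom_lengths, te$background,
                           te_length = te$te_length, species = sp)
  if (te$bias > 1 && nrow(bp)) {
    extra <- list()
    for (i in seq_len(nrow(bp))) {
      L <- chrom_lengths[[bp$chrom[i]]]
      w0 <- max(0, bp$pos[i] - te$window)
      w1 <- min(L, bp$pos[i] + te$window)
      n_x <- stats::rpois(1, te$background * (te$bias - 1) * (w1 - w0))
      if (!n_x) next
      st <- floor(stats::runif(n_x, w0, max(w0 + 1, w1 - te$te_length)))
      extra[[length(extra) + 1L]] <- data.frame(
        chrom = bp$chrom[i], start = st,
        end = pmin(st + te$te_length, L), class = te$bias_class,
        stringsAsFactors = FALSE)
    }
    if (length(extra)) {
      iv <- rbind(as.data.frame(track), do.call(rbind, extra))
      track <- interval_track(sp, iv[order(iv$chrom, iv$start), ])
    }
  }
  list(state = state, genome = gt,
       orth = do.call(rbind, orth) %||%
         data.frame(orthogroup = character(), species = character(),
                    gene_id = character()),
       te = track, breakpoints = bp)
}

## derive per-species ground truth from the final states and event log
derive_truth <- function(truth, genomes, orth) {
  tree <- truth$tree
  ntip <- length(tree$tip.label)
  z_el <- truth$elements$z_element
  min_seg <- truth$config$min_part_genes

  ## per-tip resident elements (>= min_seg unmoved conserved genes)
  resident <- list()
  tip_chrom_name <- list()
  for (sp in names(truth$tips)) {
    st <- truth$tips[[sp]]
    gt <- genomes[[sp]]
    ## map state chrom ids to emitted names via gene membership
    nm <- stats::setNames(rep(NA_character_, length(st)), names(st))
    gene_chrom <- stats::setNames(gt$genes$chrom, gt$genes$gene_id)
    for (cid in names(st)) {
      gp <- gene_positions(st[[cid]])
      if (length(gp)) nm[cid] <- unname(gene_chrom[st[[cid]]$uid[gp[1]]])
      else if (cid == "cW") nm[cid] <- "chrW"
    }
    tip_chrom_name[[sp]] <- nm
    resident[[sp]] <- lapply(st, function(it) {
      g <- it[it$type == "gene" & !is.na(it$element) & !it$moved, ,
              drop = FALSE]
      cnt <- table(g$element)
      as.integer(names(cnt)[cnt >= min_seg])
    })
  }

  ## movements at the tips: moved flags on surviving genes
  mv <- list()
  sex_of <- lapply(genomes, function(g)
    stats::setNames(g$chroms$sex_label, g$chroms$chrom))
  for (sp in names(truth$tips)) {
    st <- truth$tips[[sp]]
    for (cid in names(st)) {
      it <- st[[cid]]
      i <- which(it$type == "gene" & it$moved & !is.na(it$og))
      if (!length(i)) next
      res_el <- resident[[sp]][[cid]]
      ch <- tip_chrom_name[[sp]][[cid]]
      for (k in i) {
        e <- it$element[k]
        detectable <- !(e %in% res_el)
        ## tip-visible mechanism: does a sibling copy sit on a chromosome
        ## still housing the source element?
        sib <- NULL
        for (cid2 in names(st)) {
          it2 <- st[[cid2]]
          j <- which(it2$type == "gene" & !is.na(it2$og) &
                       it2$og == it$og[k] & it2$uid != it$uid[k])
          if (length(j) && e %in% resident[[sp]][[cid2]]) sib <- it2$uid[j[1]]
        }
        mv[[length(mv) + 1L]] <- data.frame(
          species = sp, gene_id = it$uid[k], orthogroup = it$og[k],
          source_element = e,
          source_class = if (!is.na(z_el) && e == z_el) "Z" else "A",
          dest_chrom = ch, dest_class = unname(sex_of[[sp]][ch]),
          mechanism = if (is.null(sib)) "cut" else "copy",
          detectable = detectable, stringsAsFactors = FALSE)
      }
    }
  }
  truth$movements <- do.call(rbind, mv) %||% data.frame(
    species = character(), gene_id = character(), orthogroup = character(),
    source_element = integer(), source_class = character(),
    dest_chrom = character(), dest_class = character(),
    mechanism = character(), detectable = logical())

  ## losses / duplications per species at the tips (duplication = two
  ## surviving copies, whether born by in-place duplication or by a
  ## copy-type movement, matching the two-copy counting convention)
  m <- truth$elements$membership
  cnt <- table(factor(orth$orthogroup, levels = m$orthogroup),
               factor(orth$species, levels = names(truth$tips)))
  loss_og <- rowSums(cnt == 0)
  dup_og <- rowSums(cnt == 2)
  truth$loss_dup <- data.frame(
    element = sort(unique(m$element)),
    total_losses = as.integer(tapply(loss_og[m$orthogroup], m$element, sum)),
    total_duplications = as.integer(tapply(dup_og[m$orthogroup], m$element,
                                           sum)))

  ## lineage-specific genes (no orthogroup)
  ls <- list()
  for (sp in names(truth$tips)) {
    st <- truth$tips[[sp]]
    for (cid in names(st)) {
      it <- st[[cid]]
      i <- which(it$type == "gene" & is.na(it$og))
      if (length(i))
        ls[[length(ls) + 1L]] <- data.frame(
          species = sp, gene_id = it$uid[i],
          chrom = tip_chrom_name[[sp]][[cid]], stringsAsFactors = FALSE)
    }
  }
  truth$ls_genes <- do.call(rbind, ls) %||% data.frame(
    species = character(), gene_id = character(), chrom = character())

  ## junction carriers at the tips
  for (jid in names(truth$junctions)) {
    carriers <- character(0)
    for (sp in names(truth$tips)) {
      st <- truth$tips[[sp]]
      if (any(vapply(st, function(it)
        any(it$type == "junction" & it$uid == jid), TRUE)))
        carriers <- c(carriers, sp)
    }
    truth$junctions[[jid]]$carriers <- carriers
  }
  ## fission carriers: tips below the branch
  below <- tips_below(tree)
  for (fid in names(truth$fissions))
    truth$fissions[[fid]]$carriers <- below[[truth$fissions[[fid]]$branch]]
  truth
}

tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  ## accumulate post-order
  for (k in rev(preorder_edges(tree))) {
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    out[[parent]] <- c(out[[parent]], out[[child]])
  }
  out
}

#' Replay a truth log from the ancestral genome
#'
#' Applies the recorded events branch by branch starting from the logged
#' ancestral genome and re-emits every tip genome. Used to verify that the
#' log captures the complete history: the result must equal the simulated
#' genomes exactly.
#'
#' @param truth A `karyo_truth` log.
#' @return Named list of [genome_table()] objects.
#' @export
replay_truth <- function(truth) {
  tree <- truth$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  by_branch <- split(truth$events,
                     vapply(truth$events, `[[`, 1L, "branch"))
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- truth$ancestor
  for (k in preorder_edges(tree)) {
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    g <- states[[parent]]
    for (ev in by_branch[[as.character(child)]] %||% list())
      g <- apply_event(g, ev)
    states[[child]] <- g
  }
  out <- list()
  for (ti in seq_len(ntip)) {
    sp <- tree$tip.label[ti]
    ## re-emit deterministically without touching the RNG state
    out[[sp]] <- emit_layout(states[[ti]], sp, truth$elements$z_element)
  }
  out
}

## coordinate/naming layout only (no TE or GC draws) - shared tip geometry
emit_layout <- function(state, sp, z_el) {
  ids <- names(state)
  ng <- vapply(state, function(it) sum(it$type == "gene"), 0L)
  auto <- setdiff(ids, "cW")
  ord <- auto[order(-ng[auto], auto)]
  names_map <- stats::setNames(paste0("chr", seq_along(ord)), ord)
  if ("cW" %in% ids) names_map["cW"] <- "chrW"
  zc <- z_chrom_of(state[auto], z_el)
  genes <- list(); chroms <- list()
  for (cid in c(ord, intersect("cW", ids))) {
    it <- state[[cid]]
    gp <- gene_positions(it)
    n <- length(gp)
    if (n) {
      st <- (seq_len(n) - 1) * GENE_STEP
      genes[[cid]] <- data.frame(gene_id = it$uid[gp],
                                 chrom = names_map[[cid]], start = st,
                                 end = st + GENE_SPAN, strand = "+",
                                 stringsAsFactors = FALSE)
    }
    chroms[[cid]] <- data.frame(
      chrom = names_map[[cid]],
      sex_label = if (cid == "cW") "W"
                  else if (!is.na(zc) && cid == zc) "Z" else "A",
      length_bp = max(GENE_STEP * n, 10000), gc = NA_real_,
      stringsAsFactors = FALSE)
  }
  genome_table(sp, do.call(rbind, genes), do.call(rbind, chroms))
}

#' Truth-derived chromosome compositions and names
#'
#' Reconstructs each tip chromosome's true element-segment sequence from
#' the final state (junction markers separate ancestral pieces; moved and
#' lineage-specific genes are ignored; stretches with fewer than
#' `min_segment_genes` retained genes are dropped, mirroring the
#' detectability threshold) and derives the true f/d names.
#'
#' @param truth A `karyo_truth` log.
#' @param min_segment_genes Detectability threshold (default from config).
#' @return data.frame `species`, `chrom`, `name`.
#' @export
truth_names <- function(truth, min_segment_genes = NULL) {
  min_seg <- min_segment_genes %||% truth$config$min_part_genes
  om <- order_map(truth$elements)
  out <- list()
  for (sp in names(truth$tips)) {
    st <- truth$tips[[sp]]
    segs <- list()
    for (cid in names(st)) {
      it <- st[[cid]]
      if (cid == "cW") next
      brk <- cumsum(it$type == "junction")
      for (piece in split(seq_len(nrow(it)), brk)) {
        g <- it[piece, , drop = FALSE]
        g <- g[g$type == "gene" & !is.na(g$element) & !g$moved, ,
               drop = FALSE]
        if (nrow(g) < min_seg) next
        segs[[length(segs) + 1L]] <- data.frame(
          cid = cid, element = g$element[1],
          med = stats::median(om[g$og], na.rm = TRUE),
          pos = piece[1], stringsAsFactors = FALSE)
      }
    }
    if (!length(segs)) next
    s <- do.call(rbind, segs)
    s$part <- NA_integer_
    for (e in unique(s$element)) {
      rows <- which(s$element == e)
      if (length(rows) < 2L) next
      s$part[rows[order(s$med[rows])]] <- seq_along(rows)
    }
    ## chromosome order
    gt_names <- tip_names_of(st, sp, truth$elements$z_element)
    for (cid in unique(s$cid)) {
      rows <- which(s$cid == cid)
      rows <- rows[order(s$pos[rows])]
      nm <- canonicalize_name(chrom_name(s$element[rows], s$part[rows]))
      out[[length(out) + 1L]] <- data.frame(
        species = sp, chrom = gt_names[[cid]], name = format_name(nm),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out) %||%
    data.frame(species = character(), chrom = character(),
               name = character())
}

tip_names_of <- function(state, sp, z_el) {
  ids <- names(state)
  ng <- vapply(state, function(it) sum(it$type == "gene"), 0L)
  auto <- setdiff(ids, "cW")
  ord <- auto[order(-ng[auto], auto)]
  nm <- stats::setNames(paste0("chr", seq_along(ord)), ord)
  if ("cW" %in% ids) nm["cW"] <- "chrW"
  nm
}

#' Score pipeline recovery against a truth log
#'
#' @param truth A `karyo_truth` log.
#' @param features `rearr_features` from [extract_features()].
#' @param placed `placed_events` from [place_events()].
#' @param movements data.frame from [detect_movements()] (optional).
#' @param loss_dup data.frame from [loss_dup_stats()] (optional).
#' @param names_df data.frame from rbound [name_chromosomes()] results
#'   (optional).
#' @return List of class `recovery_report` with per-stage precision /
#'   recall / accuracy entries and the matched-event bookkeeping.
#' @export
score_recovery <- function(truth, features, placed, movements = NULL,
                           loss_dup = NULL, names_df = NULL) {
  tree <- truth$tree
  ## observable truth events
  tj <- Filter(function(j) length(j$carriers) > 0, truth$junctions)
  tf <- Filter(function(f) length(f$carriers) > 0, truth$fissions)

  is_fus <- vapply(features, function(f) f$kind == "fusion", TRUE)
  inf_fus <- features[is_fus]
  inf_fis <- features[!is_fus]

  match_fus <- function(j, f) {
    je <- sort(c(j$side_a$element, j$side_b$element))
    if (!identical(je, sort(f$elements))) return(FALSE)
    s1 <- length(intersect(j$side_a$ogs, f$sides[[1]])) > 0 &&
      length(intersect(j$side_b$ogs, f$sides[[2]])) > 0
    s2 <- length(intersect(j$side_a$ogs, f$sides[[2]])) > 0 &&
      length(intersect(j$side_b$ogs, f$sides[[1]])) > 0
    s1 || s2
  }
  match_fis <- function(t, f) {
    if (!f$elements %in% t$element) return(FALSE)
    i <- which(t$element == f$elements)[1]
    lr <- t$parts[[i]]
    hit_l <- which(vapply(f$sides, function(s)
      length(intersect(s, lr$left)) > 0, TRUE))
    hit_r <- which(vapply(f$sides, function(s)
      length(intersect(s, lr$right)) > 0, TRUE))
    length(hit_l) > 0 && length(hit_r) > 0 &&
      !length(intersect(hit_l, hit_r))
  }

  ## feature ids within the original features list
  feat_ids_fus <- which(is_fus); feat_ids_fis <- which(!is_fus)

  score_kind <- function(tr_events, inf_feats, feat_ids, matcher, kind) {
    t_matched <- logical(length(tr_events))
    i_matched <- logical(length(inf_feats))
    node_hit <- logical(length(tr_events))
    for (a in seq_along(tr_events)) for (b in seq_along(inf_feats)) {
      if (matcher(tr_events[[a]], inf_feats[[b]])) {
        t_matched[a] <- TRUE
        i_matched[b] <- TRUE
        gains <- placed$node[placed$kind == kind &
                               placed$feature_id == feat_ids[b]]
        if (tr_events[[a]]$branch %in% gains) node_hit[a] <- TRUE
      }
    }
    list(n_truth = length(tr_events), n_inferred = length(inf_feats),
         n_matched_truth = sum(t_matched),
         n_matched_inferred = sum(i_matched),
         n_node_exact = sum(node_hit),
         recall = if (length(t_matched)) mean(t_matched) else NA_real_,
         precision = if (length(i_matched)) mean(i_matched) else NA_real_)
  }

  fus <- score_kind(tj, inf_fus, feat_ids_fus, match_fus, "fusion")
  fis <- score_kind(tf, inf_fis, feat_ids_fis, match_fis, "fission")

  out <- list(fusion = fus, fission = fis)
  nt <- fus$n_truth + fis$n_truth
  ni <- fus$n_inferred + fis$n_inferred
  nm <- fus$n_matched_truth + fis$n_matched_truth
  nmi <- fus$n_matched_inferred + fis$n_matched_inferred
  nnode <- fus$n_node_exact + fis$n_node_exact
  out$event_recall <- if (nt) nm / nt else NA_real_
  out$event_precision <- if (ni) nmi / ni else NA_real_
  out$placement_accuracy <- if (nm) nnode / nm else NA_real_
  out$counts <- c(n_truth = nt, n_inferred = ni, n_matched_truth = nm,
                  n_matched_inferred = nmi, n_node_exact = nnode)

  if (!is.null(movements)) {
    td <- truth$movements[truth$movements$detectable, , drop = FALSE]
    tkey <- paste(td$species, td$gene_id)
    ikey <- paste(movements$species, movements$gene_id)
    out$movement <- list(
      recall = if (length(tkey)) mean(tkey %in% ikey) else NA_real_,
      precision = if (length(ikey)) mean(ikey %in% tkey) else NA_real_,
      n_truth = length(tkey), n_inferred = length(ikey))
    shared <- intersect(tkey, ikey)
    if (length(shared)) {
      tm <- td$mechanism[match(shared, tkey)]
      im <- movements$mechanism[match(shared, ikey)]
      out$movement$mechanism_accuracy <- mean(tm == im)
      tc <- paste0(td$source_class, "->", td$dest_class)[match(shared, tkey)]
      ic <- paste0(movements$source_class, "->",
                   movements$dest_class)[match(shared, ikey)]
      out$movement$category_accuracy <- mean(tc == ic)
    }
  }
  if (!is.null(loss_dup)) {
    t <- truth$loss_dup
    i <- loss_dup[match(t$element, loss_dup$element), , drop = FALSE]
    out$loss_dup <- list(
      losses_exact = all(t$total_losses == i$total_losses),
      dups_exact = all(t$total_duplications == i$total_duplications),
      loss_rmse = sqrt(mean((t$total_losses - i$total_losses)^2)),
      dup_rmse = sqrt(mean((t$total_duplications -
                              i$total_duplications)^2)))
  }
  if (!is.null(names_df)) {
    tn <- truth_names(truth)
    key <- paste(tn$species, tn$chrom)
    ikey <- paste(names_df$species, names_df$chrom)
    hit <- match(key, ikey)
    ok <- !is.na(hit) & tn$name == names_df$name[hit]
    out$name_accuracy <- if (length(ok)) mean(ok) else NA_real_
  }
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report\n")
  cat("  events: recall ", format(x$event_recall, digits = 3),
      ", precision ", format(x$event_precision, digits = 3),
      ", placement ", format(x$placement_accuracy, digits = 3), "\n",
      sep = "")
  if (!is.null(x$movement))
    cat("  movements: recall ", format(x$movement$recall, digits = 3),
        ", precision ", format(x$movement$precision, digits = 3), "\n",
        sep = "")
  invisible(x)
}
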