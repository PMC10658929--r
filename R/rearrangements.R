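## Fusion/fission features across species and their parsimony placement on
## the species tree.
##
## A fusion feature is a junction: the unordered pair of element segments
## meeting side by side on a chromosome. Junction observations from
## different species are identified when the element pair matches and the
## orthogroup content of both flanking segments overlaps, which is robust
## to per-species gene loss. A fission feature is an element observed split
## into parts; observations are identified when their part partitions agree
## on the orthogroups the two species share. Multi-way fusions count as
## pairwise junctions, so a 3-element chromosome carries 2 fusion features.

#' Extract rearrangement features from per-species compositions
#'
#' @param comps Named list of `species_composition` objects (one per
#'   species, names = species).
#' @param orth An [orthology_table()].
#' @param elements An [ancestral_elements()] object.
#' @return Object of class `rearr_features`: a list of features, each a
#'   list with `kind` (`"fusion"`/`"fission"`), `elements` (the one or two
#'   element ids involved), `carriers` (species), `label` (representative
#'   printed form), and `sides` (list of orthogroup sets: the two junction
#'   flanks, or the fission parts, unions over carriers).
#' @export
extract_features <- function(comps, orth, elements) {
  if (is.null(names(comps)))
    names(comps) <- vapply(comps, `[[`, "", "species")

  fus_obs <- list(); fis_obs <- list()
  for (sp in names(comps)) {
    cmp <- comps[[sp]]
    s <- cmp$segments
    if (!nrow(s)) next
    om <- gene_orthogroup_map(orth, sp)
    seg_ogs <- lapply(s$genes, function(g) unique(unname(om[g])))
    ## junction observations: adjacent segments on a chromosome
    for (ch in unique(s$chrom)) {
      rows <- which(s$chrom == ch)
      rows <- rows[order(s$seg_index[rows])]
      if (length(rows) < 2L) next
      for (j in seq_len(length(rows) - 1L)) {
        a <- rows[j]; b <- rows[j + 1L]
        fus_obs[[length(fus_obs) + 1L]] <- list(
          species = sp, el = sort(c(s$element[a], s$element[b])),
          side_a = list(el = s$element[a], ogs = seg_ogs[[a]]),
          side_b = list(el = s$element[b], ogs = seg_ogs[[b]]))
      }
    }
    ## fission observations: element split over >= 2 segments
    for (e in unique(s$element)) {
      rows <- which(s$element == e)
      if (length(rows) < 2L) next
      o <- order(s$med_order[rows], s$chrom[rows], s$seg_index[rows])
      fis_obs[[length(fis_obs) + 1L]] <- list(
        species = sp, el = e, parts = seg_ogs[rows[o]])
    }
  }

  feats <- list()

  ## --- cluster fusion observations ---
  if (length(fus_obs)) {
    pair_key <- vapply(fus_obs, function(o) paste(o$el, collapse = "|"), "")
    for (pk in unique(pair_key)) {
      obs <- fus_obs[pair_key == pk]
      n <- length(obs)
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j <= i) next
        if (junction_match(obs[[i]], obs[[j]])) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
      roots <- vapply(seq_len(n), find, 1L)
      for (r in unique(roots)) {
        grp <- obs[roots == r]
        sides <- junction_sides(grp)
        feats[[length(feats) + 1L]] <- list(
          kind = "fusion", elements = grp[[1]]$el,
          carriers = sort(unique(vapply(grp, `[[`, "", "species"))),
          label = paste0(grp[[1]]$side_a$el, "f", grp[[1]]$side_b$el),
          sides = sides)
      }
    }
  }

  ## --- cluster fission observations ---
  if (length(fis_obs)) {
    el_key <- vapply(fis_obs, `[[`, 1, "el")
    for (e in unique(el_key)) {
      obs <- fis_obs[el_key == e]
      n <- length(obs)
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j <= i) next
        if (partition_compatible(obs[[i]]$parts, obs[[j]]$parts)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
      roots <- vapply(seq_len(n), find, 1L)
      for (r in unique(roots)) {
        grp <- obs[roots == r]
        k <- max(vapply(grp, function(o) length(o$parts), 1L))
        sides <- merge_partitions(grp)
        feats[[length(feats) + 1L]] <- list(
          kind = "fission", elements = e,
          carriers = sort(unique(vapply(grp, `[[`, "", "species"))),
          label = paste0(e, "d-", k), sides = sides)
      }
    }
  }
  structure(feats, class = "rearr_features")
}

#' @export
print.rearr_features <- function(x, ...) {
  cat("rearr_features: ", sum(vapply(x, function(f) f$kind == "fusion", TRUE)),
      " fusion + ", sum(vapply(x, function(f) f$kind == "fission", TRUE)),
      " fission feature(s)\n", sep = "")
  invisible(x)
}

## two junction observations match when their element pairs are equal and a
## side pairing exists with nonempty orthogroup overlap on both sides
junction_match <- function(a, b) {
  straight <- a$side_a$el == b$side_a$el && a$side_b$el == b$side_b$el &&
    length(intersect(a$side_a$ogs, b$side_a$ogs)) > 0 &&
    length(intersect(a$side_b$ogs, b$side_b$ogs)) > 0
  crossed <- a$side_a$el == b$side_b$el && a$side_b$el == b$side_a$el &&
    length(intersect(a$side_a$ogs, b$side_b$ogs)) > 0 &&
    length(intersect(a$side_b$ogs, b$side_a$ogs)) > 0
  straight || crossed
}

junction_sides <- function(grp) {
  ref <- grp[[1]]
  sa <- ref$side_a$ogs; sb <- ref$side_b$ogs
  for (o in grp[-1]) {
    if (length(intersect(o$side_a$ogs, sa)) >= length(intersect(o$side_a$ogs, sb))) {
      sa <- union(sa, o$side_a$ogs); sb <- union(sb, o$side_b$ogs)
    } else {
      sa <- union(sa, o$side_b$ogs); sb <- union(sb, o$side_a$ogs)
    }
  }
  list(sa, sb)
}

## two part-partitions of one element are compatible when no orthogroup
## pair shared by both is split differently
partition_compatible <- function(p, q) {
  mp <- part_index(p); mq <- part_index(q)
  shared <- intersect(names(mp), names(mq))
  if (!length(shared)) return(FALSE)
  tab <- table(mp[shared], mq[shared])
  all(rowSums(tab > 0) <= 1) && all(colSums(tab > 0) <= 1)
}

part_index <- function(parts) {
  stats::setNames(rep(seq_along(parts), lengths(parts)),
                  unlist(parts, use.names = FALSE))
}

merge_partitions <- function(grp) {
  base <- grp[[1]]$parts
  for (o in grp[-1]) {
    mb <- part_index(base)
    for (i in seq_along(o$parts)) {
      hit <- mb[intersect(o$parts[[i]], names(mb))]
      if (length(hit)) {
        j <- as.integer(names(sort(table(hit), decreasing = TRUE))[1])
        base[[j]] <- union(base[[j]], o$parts[[i]])
      } else {
        base[[length(base) + 1L]] <- o$parts[[i]]
      }
    }
  }
  base
}

#' Place rearrangement features on the species tree by parsimony
#'
#' Presence/absence small parsimony with equal gain and loss weights
#' (fissions can genuinely dissolve earlier fusions, so irreversibility
#' would be wrong). Every feature is absent from the ancestral karyotype;
#' a feature carried by all tips arises by a single stem gain reported at
#' the root. Among minimum-change solutions, ties are broken toward gains
#' over losses (scattered carriers count as independent gains) and then
#' toward deeper (older) gains. A feature whose carriers form a clade maps
#' to that clade's root; a single carrier maps to the leaf.
#'
#' @param features A `rearr_features` object.
#' @param tree Rooted `phylo` species tree containing all carriers.
#' @param excluded Species to drop from carrier sets (unresolvable
#'   species); features left without carriers are dropped and logged in the
#'   `"dropped"` attribute.
#' @return data.frame of class `placed_events` with one row per gain:
#'   `feature_id`, `kind`, `label`, `elements` (comma string), `node` (ape
#'   node number), `node_label` (leaf name or internal id), `node_type`
#'   (`"species"`/`"ancestral"`), `n_gains` (independent gains of the
#'   feature on the tree).
#' @export
place_events <- function(features, tree, excluded = character()) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- list(); dropped <- character()

  for (fi in seq_along(features)) {
    f <- features[[fi]]
    carriers <- setdiff(f$carriers, excluded)
    if (!length(carriers)) {
      dropped <- c(dropped, f$label)
      next
    }
    state <- tree$tip.label %in% carriers
    gains <- sankoff_gains(tree, state, kids, root)
    for (nd in gains) {
      out[[length(out) + 1L]] <- data.frame(
        feature_id = fi, kind = f$kind, label = f$label,
        elements = paste(f$elements, collapse = ","),
        node = nd,
        node_label = if (nd <= ntip) tree$tip.label[nd]
                     else paste0("node", nd),
        node_type = if (nd <= ntip) "species" else "ancestral",
        n_gains = length(gains), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(feature_id = integer(), kind = character(),
               label = character(), elements = character(), node = integer(),
               node_label = character(), node_type = character(),
               n_gains = integer())
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  class(res) <- c("placed_events", "data.frame")
  res
}

## Sankoff DP over states {absent=1, present=2}. Gains and losses both
## cost one change; a feature may arise on the stem above the root (that
## stem gain also costs one change and is emitted as an event at the
## root), but the root carries no feature for free - rearrangement
## features are absent from the ancestral karyotype. Losses carry a tiny
## extra weight so that among minimum-change solutions the one with fewer
## losses (more, shallower gains - independent events) wins; remaining
## exact ties switch the feature on as deep (old) as possible.
sankoff_gains <- function(tree, tip_state, kids, root) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  eps <- 1e-3
  cost <- matrix(Inf, nrow = nnode, ncol = 2)
  cost[seq_len(ntip), 1] <- ifelse(tip_state, Inf, 0)
  cost[seq_len(ntip), 2] <- ifelse(tip_state, 0, Inf)
  ## process internal nodes in reverse breadth-first order from the root
  pend <- root
  bfs <- integer(0)
  while (length(pend)) {
    nd <- pend[1]; pend <- pend[-1]
    bfs <- c(bfs, nd)
    ch <- kids[[as.character(nd)]]
    if (!is.null(ch)) pend <- c(pend, ch[ch > ntip])
  }
  for (nd in rev(bfs)) {
    ch <- kids[[as.character(nd)]]
    c0 <- 0; c1 <- 0
    for (cc in ch) {
      c0 <- c0 + min(cost[cc, 1], cost[cc, 2] + 1)         # gain below
      c1 <- c1 + min(cost[cc, 1] + 1 + eps, cost[cc, 2])   # loss below
    }
    cost[nd, 1] <- c0
    cost[nd, 2] <- c1
  }
  ## root: absent for free, present via a stem gain (one change)
  assign <- integer(nnode)
  gains <- integer(0)
  if (cost[root, 2] + 1 <= cost[root, 1]) {
    assign[root] <- 2L
    gains <- root
  } else {
    assign[root] <- 1L
  }
  stack <- root
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    ch <- kids[[as.character(nd)]]
    for (cc in ch) {
      if (assign[nd] == 1L) {
        keep <- cost[cc, 1]
        flip <- cost[cc, 2] + 1
        assign[cc] <- if (flip <= keep) 2L else 1L  # tie: deeper gain
        if (assign[cc] == 2L) gains <- c(gains, cc)
      } else {
        on <- cost[cc, 2]
        off <- cost[cc, 1] + 1 + eps
        assign[cc] <- if (on <= off) 2L else 1L
      }
      if (cc > length(tree$tip.label)) stack <- c(stack, cc)
    }
  }
  sort(gains)
}

#' Count placed events per ancestral element
#'
#' Each fusion gain increments both elements at its junction (the same
#' element twice for a same-element junction); each fission gain increments
#' its element once.
#'
#' @param placed A `placed_events` data.frame.
#' @param elements An [ancestral_elements()] object (defines the element
#'   universe so untouched elements report zeros).
#' @return data.frame `element`, `n_fusions`, `n_fissions`.
#' @export
count_by_element <- function(placed, elements) {
  els <- sort(unique(elements$membership$element))
  fus <- integer(length(els)); fis <- integer(length(els))
  names(fus) <- names(fis) <- els
  if (nrow(placed)) {
    for (i in seq_len(nrow(placed))) {
      ev <- as.integer(strsplit(placed$elements[i], ",")[[1]])
      if (placed$kind[i] == "fusion") {
        if (length(ev) == 1L) ev <- c(ev, ev)
        for (e in ev) fus[as.character(e)] <- fus[as.character(e)] + 1L
      } else {
        fis[as.character(ev[1])] <- fis[as.character(ev[1])] + 1L
      }
    }
  }
  data.frame(element = els, n_fusions = unname(fus),
             n_fissions = unname(fis))
}

#' Flag species whose rearrangements are too complex to resolve
#'
#' Species exceeding either bound are excluded from event counting (their
#' history cannot be disentangled), though their determinate chromosome
#' names remain usable.
#'
#' @param comps Named list of `species_composition` objects.
#' @param max_segments_per_chrom Bound on segments on any one chromosome
#'   (default 5).
#' @param max_total_segments Bound on total segments in the species
#'   (default 60).
#' @return data.frame `species`, `resolvable`, `reasons`.
#' @export
flag_unresolvable <- function(comps, max_segments_per_chrom = 5L,
                              max_total_segments = 60L) {
  if (is.null(names(comps)))
    names(comps) <- vapply(comps, `[[`, "", "species")
  out <- lapply(names(comps), function(sp) {
    s <- comps[[sp]]$segments
    reasons <- character(0)
    if (nrow(s)) {
      per <- table(s$chrom)
      if (any(per > max_segments_per_chrom))
        reasons <- c(reasons, paste0("max segments per chromosome exceeded (",
                                     max(per), " > ", max_segments_per_chrom,
                                     ")"))
      if (nrow(s) > max_total_segments)
        reasons <- c(reasons, paste0("total segment count exceeded (",
                                     nrow(s), " > ", max_total_segments, ")"))
    }
    data.frame(species = sp, resolvable = !length(reasons),
               reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write placed events / element counts TSVs
#' @param placed A `placed_events` data.frame.
#' @param path Output path.
#' @export
write_events <- function(placed, path) {
  utils::write.table(placed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
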