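## Gene-level evolutionary accounting: inter-chromosomal movements with
## copy/cut mechanism calls, ancestral gene loss and duplication tallies,
## and lineage-specific gene counts.

#' Detect inter-chromosomal gene movements
#'
#' A conserved gene has moved when the ancestral element of its orthogroup
#' is not among the elements of the chromosome it sits on; operationally
#' these are exactly the unplaced genes of [decompose()] whose element is
#' absent from the host chromosome's segments (keeping the movement rule
#' the complement of the segment rule). A movement is `copy`-type
#' (RNA-mediated, retrotransposed candidate) when another same-species
#' member of the orthogroup - the parental gene - resides on a chromosome
#' whose composition contains the source element, and `cut`-type
#' (DNA-mediated) otherwise.
#'
#' @param comps Named list of `species_composition` objects.
#' @param orth An [orthology_table()] (low-copy filtered).
#' @param elements An [ancestral_elements()] object.
#' @param genomes Named list of [genome_table()] objects (for destination
#'   chromosome sex classes).
#' @return data.frame with one row per moved gene copy: `species`,
#'   `gene_id`, `orthogroup`, `source_element`, `source_class` (`A`/`Z`),
#'   `dest_chrom`, `dest_class` (`A`/`Z`/`W`), `mechanism`
#'   (`copy`/`cut`), `parental_gene` (`NA` for cut), `low_confidence`
#'   (destination has an empty composition yet is not W-labelled).
#' @export
detect_movements <- function(comps, orth, elements, genomes) {
  if (is.null(names(comps)))
    names(comps) <- vapply(comps, `[[`, "", "species")
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, "", "species")
  z_el <- elements$z_element
  out <- list()
  for (sp in names(comps)) {
    cmp <- comps[[sp]]
    u <- cmp$unplaced
    if (!nrow(u)) next
    u <- u[!u$host_has_element, , drop = FALSE]
    if (!nrow(u)) next
    gt <- genomes[[sp]]
    sex <- stats::setNames(gt$chroms$sex_label, gt$chroms$chrom)
    seg_el <- split(cmp$segments$element, cmp$segments$chrom)
    gene_chrom <- stats::setNames(gt$genes$chrom, gt$genes$gene_id)
    gene_rank <- stats::setNames(gt$genes$rank, gt$genes$gene_id)
    sp_orth <- orth[orth$species == sp, , drop = FALSE]
    og_genes <- split(sp_orth$gene_id, sp_orth$orthogroup)
    for (i in seq_len(nrow(u))) {
      e <- u$element[i]
      sibs <- setdiff(og_genes[[u$orthogroup[i]]], u$gene_id[i])
      parental <- NA_character_
      if (length(sibs)) {
        sib_ch <- gene_chrom[sibs]
        on_src <- vapply(sib_ch, function(ch)
          e %in% (seg_el[[ch]] %||% integer(0)), TRUE)
        cand <- sibs[on_src]
        if (length(cand))
          parental <- cand[order(gene_rank[cand], cand)][1]
      }
      host_empty <- is.null(seg_el[[u$chrom[i]]]) ||
        !length(seg_el[[u$chrom[i]]])
      out[[length(out) + 1L]] <- data.frame(
        species = sp, gene_id = u$gene_id[i], orthogroup = u$orthogroup[i],
        source_element = e,
        source_class = if (!is.na(z_el) && e == z_el) "Z" else "A",
        dest_chrom = u$chrom[i],
        dest_class = unname(sex[u$chrom[i]]),
        mechanism = if (is.na(parental)) "cut" else "copy",
        parental_gene = parental,
        low_confidence = host_empty && sex[u$chrom[i]] != "W",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(species = character(), gene_id = character(),
               orthogroup = character(), source_element = integer(),
               source_class = character(), dest_chrom = character(),
               dest_class = character(), mechanism = character(),
               parental_gene = character(), low_confidence = logical())
  rownames(res) <- NULL
  res
}

MOVEMENT_CATEGORIES <- c("A->A", "A->Z", "Z->A", "A->W", "Z->W")

#' Classify gene movements by source and destination class
#'
#' The five categories autosome-to-autosome, autosome-to-Z, Z-to-autosome,
#' autosome-to-W and Z-to-W (Z-to-Z cannot arise with a single Z element).
#' Counts are reported twice: per gene copy and per orthogroup (two copies
#' of one orthogroup moved off-element count once in the latter).
#'
#' @param events data.frame from [detect_movements()].
#' @return data.frame `category`, `n_genes`, `n_orthogroups`, all
#'   categories present (zeros included).
#' @export
classify_movements <- function(events) {
  cat_of <- paste0(events$source_class, "->", events$dest_class)
  n_genes <- table(factor(cat_of, levels = MOVEMENT_CATEGORIES))
  key <- !duplicated(paste(events$species, events$orthogroup, cat_of))
  n_og <- table(factor(cat_of[key], levels = MOVEMENT_CATEGORIES))
  data.frame(category = MOVEMENT_CATEGORIES,
             n_genes = as.integer(n_genes),
             n_orthogroups = as.integer(n_og))
}

#' Per-element gene loss and duplication statistics
#'
#' For every element and every species: an orthogroup with zero copies in
#' the species counts one loss, and one with two copies counts one
#' duplication (requires the low-copy filter, max 2 copies). Losses are
#' counted per extant species with no tree correction, so a loss shared by
#' a clade is counted once per descendant - a deliberate, documented upward
#' bias matching the per-species definition.
#'
#' @param genomes Named list of [genome_table()] objects.
#' @param orth Low-copy [orthology_table()].
#' @param elements An [ancestral_elements()] object.
#' @return data.frame `element`, `n_ancestral_genes`, `total_losses`,
#'   `total_duplications`, `losses_per_gene`, `duplications_per_gene`.
#' @export
loss_dup_stats <- function(genomes, orth, elements) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, "", "species")
  species <- sort(names(genomes))
  m <- elements$membership
  ogs <- m$orthogroup
  ## copies per (orthogroup, species), zero-filled over the element ogs
  sub <- orth[orth$species %in% species & orth$orthogroup %in% ogs, ,
              drop = FALSE]
  cnt <- table(factor(sub$orthogroup, levels = ogs),
               factor(sub$species, levels = species))
  if (any(cnt > 2))
    warning("orthogroup with > 2 copies in a species; ",
            "apply filter_low_copy() first", call. = FALSE)
  loss_per_og <- rowSums(cnt == 0)
  dup_per_og <- rowSums(cnt == 2)
  el <- m$element
  tl <- tapply(loss_per_og[ogs], el, sum)
  td <- tapply(dup_per_og[ogs], el, sum)
  ng <- table(el)
  ids <- sort(unique(el))
  data.frame(element = ids,
             n_ancestral_genes = as.integer(ng[as.character(ids)]),
             total_losses = as.integer(tl[as.character(ids)]),
             total_duplications = as.integer(td[as.character(ids)]),
             losses_per_gene = as.numeric(tl[as.character(ids)] /
                                            ng[as.character(ids)]),
             duplications_per_gene = as.numeric(td[as.character(ids)] /
                                                  ng[as.character(ids)]))
}

#' Lineage-specific gene counts per chromosome
#'
#' A gene is lineage-specific when it belongs to no orthogroup, or only to
#' orthogroups whose members all come from its own species (no homolog in
#' any other analyzed species).
#'
#' @param genomes Named list of [genome_table()] objects.
#' @param orth An [orthology_table()] (unfiltered: the full orthogroup
#'   universe defines "homolog elsewhere").
#' @return data.frame `species`, `chrom`, `n_lineage_specific`,
#'   `n_total_genes`, `proportion` (`NA` for empty chromosomes).
#' @export
lineage_specific_counts <- function(genomes, orth) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, "", "species")
  nsp_per_og <- tapply(orth$species, orth$orthogroup,
                       function(s) length(unique(s)))
  out <- list()
  for (sp in names(genomes)) {
    gt <- genomes[[sp]]
    om <- gene_orthogroup_map(orth, sp)
    og <- om[gt$genes$gene_id]
    ls <- is.na(og) | nsp_per_og[og] <= 1
    ls[is.na(ls)] <- TRUE
    n_ls <- tapply(ls, gt$genes$chrom, sum)
    n_all <- table(gt$genes$chrom)
    chroms <- gt$chroms$chrom
    nl <- as.integer(n_ls[chroms]); nl[is.na(nl)] <- 0L
    na <- as.integer(n_all[chroms]); na[is.na(na)] <- 0L
    out[[sp]] <- data.frame(species = sp, chrom = chroms,
                            n_lineage_specific = nl, n_total_genes = na,
                            proportion = ifelse(na > 0, nl / na, NA_real_),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
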