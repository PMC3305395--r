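other_lineages <- function(lineage) setdiff(LINEAGES, lineage)
other_sex <- function(sex) if (sex == "XY") "XX" else "XY"

#' Recipe for a lineage-enriched signature
#'
#' `sex_specific`: higher in the focal (lineage, sex) group than the
#' opposite-sex same-lineage group, and higher than every other lineage of
#' the same sex, all at one stage. `sex_independent`: higher than every other
#' lineage within XY and within XX, and identically expressed between XX and
#' XY focal cells (the sexually undifferentiated progenitor signature).
#'
#' @param lineage Focal lineage.
#' @param sex Focal sex (ignored for `sex_independent`).
#' @param stage Stage.
#' @param mode "sex_specific" or "sex_independent".
#' @return A [recipe()].
#' @export
enriched_recipe <- function(lineage, sex, stage,
                            mode = c("sex_specific", "sex_independent")) {
  mode <- match.arg(mode)
  directional_recipe(lineage, sex, stage, mode, wanted = "higher",
                     label = "enriched")
}

#' Recipe for a lineage-depleted signature
#'
#' As [enriched_recipe()] with every call direction reversed: the focal
#' group is lower than the opposite-sex group (sex-specific) and lower than
#' every other lineage; the sex-independent variant additionally requires
#' XX/XY identity in the focal lineage.
#'
#' @inheritParams enriched_recipe
#' @return A [recipe()].
#' @export
depleted_recipe <- function(lineage, sex, stage,
                            mode = c("sex_specific", "sex_independent")) {
  mode <- match.arg(mode)
  directional_recipe(lineage, sex, stage, mode, wanted = "lower",
                     label = "depleted")
}

directional_recipe <- function(lineage, sex, stage, mode, wanted, label) {
  steps <- list()
  if (mode == "sex_specific") {
    steps <- c(steps, list(step_compare(grp(lineage, sex, stage),
                                        grp(lineage, other_sex(sex), stage),
                                        wanted)))
    for (ol in other_lineages(lineage))
      steps <- c(steps, list(step_compare(grp(lineage, sex, stage),
                                          grp(ol, sex, stage), wanted)))
    name <- sprintf("%s %s %s %s (sex-specific)", sex, lineage, stage, label)
  } else {
    for (s in SEXES)
      for (ol in other_lineages(lineage))
        steps <- c(steps, list(step_compare(grp(lineage, s, stage),
                                            grp(ol, s, stage), wanted)))
    steps <- c(steps, list(step_compare(grp(lineage, "XX", stage),
                                        grp(lineage, "XY", stage),
                                        "identical")))
    name <- sprintf("%s %s %s (sex-independent)", lineage, stage, label)
  }
  recipe(name, steps)
}

#' Sex-specific or sex-independent lineage-enriched gene list
#'
#' @param study A filtered [expression_study()].
#' @param lineage,sex,stage Focal group coordinates.
#' @param cfg A [threshold_config()].
#' @param mode "sex_specific" or "sex_independent".
#' @return A [gene_list()].
#' @export
lineage_enriched <- function(study, lineage, sex = "XY", stage,
                             cfg = threshold_config(),
                             mode = c("sex_specific", "sex_independent")) {
  evaluate_recipe(study, enriched_recipe(lineage, sex, stage, match.arg(mode)),
                  cfg)
}

#' Sex-specific or sex-independent lineage-depleted gene list
#'
#' @inheritParams lineage_enriched
#' @return A [gene_list()].
#' @export
lineage_depleted <- function(study, lineage, sex = "XY", stage,
                             cfg = threshold_config(),
                             mode = c("sex_specific", "sex_independent")) {
  evaluate_recipe(study, depleted_recipe(lineage, sex, stage, match.arg(mode)),
                  cfg)
}

#' Recipe for Leydig-cell genes
#'
#' Both the sorted interstitium and the sorted "endothelial" fraction contain
#' Leydig cells, so Leydig genes surface as the intersection of four
#' conditions: higher in the XY interstitium than XY supporting and germ
#' cells; higher in XY endothelial cells than XY supporting and germ cells;
#' higher in the XY interstitium than the XX stroma; and higher in XY
#' endothelial than XX endothelial cells — all at one late stage. The
#' depleted variant reverses every direction.
#'
#' @param stage Stage (the later stages, where fetal Leydig cells exist).
#' @param direction "enriched" or "depleted".
#' @return A [recipe()].
#' @export
leydig_recipe <- function(stage, direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  w <- if (direction == "enriched") "higher" else "lower"
  recipe(sprintf("Leydig %s %s", direction, stage),
         step_compare(grp("interstitial_stromal", "XY", stage),
                      grp("supporting", "XY", stage), w),
         step_compare(grp("interstitial_stromal", "XY", stage),
                      grp("germ", "XY", stage), w),
         step_compare(grp("endothelial", "XY", stage),
                      grp("supporting", "XY", stage), w),
         step_compare(grp("endothelial", "XY", stage),
                      grp("germ", "XY", stage), w),
         step_compare(grp("interstitial_stromal", "XY", stage),
                      grp("interstitial_stromal", "XX", stage), w),
         step_compare(grp("endothelial", "XY", stage),
                      grp("endothelial", "XX", stage), w))
}

#' Leydig-cell gene list
#'
#' @param study A filtered [expression_study()].
#' @param stage Stage at which to deduce Leydig genes (E13.5 gives the
#'   maximal removal list and is the default used against endothelial lists).
#' @param cfg A [threshold_config()].
#' @param direction "enriched" or "depleted".
#' @return A [gene_list()].
#' @export
leydig_genes <- function(study, stage = "E13.5", cfg = threshold_config(),
                         direction = c("enriched", "depleted")) {
  evaluate_recipe(study, leydig_recipe(stage, match.arg(direction)), cfg)
}

#' Single-comparison sexual dimorphism and cross-lineage overlap
#'
#' For each lineage a single XX-vs-XY pairwise comparison at one stage yields
#' the XY-higher and XX-higher dimorphic lists. Genes are then cross-tabulated
#' by the set of lineages in which they are dimorphic; when transcript
#' clusters of one gene disagree, the gene is counted once, in the
#' highest-overlap category (the largest lineage set carried by any of its
#' clusters; ties broken by sorted order).
#'
#' @param study A filtered [expression_study()].
#' @param stage Stage.
#' @param cfg A [threshold_config()].
#' @param lineages Lineages to compare (endothelial excluded by default, as
#'   in the published overlap analysis).
#' @return A list with `lists` (per lineage and direction, [gene_list()]s),
#'   `overlap` (data.frame: direction, category, n_genes) and `gene_category`
#'   (data.frame: direction, gene_symbol, category).
#' @export
dimorphic_overlaps <- function(study, stage, cfg = threshold_config(),
                               lineages = c("supporting",
                                            "interstitial_stromal", "germ")) {
  lists <- list()
  membership <- list(XY = list(), XX = list())
  for (L in lineages) {
    calls <- compare_groups(study, grp(L, "XY", stage), grp(L, "XX", stage),
                            cfg)
    lists[[paste0(L, ".XY_higher")]] <- call_set(calls, "higher")
    lists[[paste0(L, ".XX_higher")]] <- call_set(calls, "lower")
    membership$XY[[L]] <- calls$cluster_id[calls$call == "higher"]
    membership$XX[[L]] <- calls$cluster_id[calls$call == "lower"]
  }
  cat_rows <- list()
  for (dir in c("XY", "XX")) {
    # per cluster: set of lineages in which it is dimorphic in this direction
    all_ids <- unique(unlist(membership[[dir]]))
    if (!length(all_ids)) next
    sets <- lapply(all_ids, function(id)
      lineages[vapply(lineages, function(L) id %in% membership[[dir]][[L]],
                      TRUE)])
    names(sets) <- all_ids
    syms <- cluster_symbols(study, all_ids)
    for (g in unique(syms[nzchar(syms)])) {
      gsets <- sets[all_ids[syms == g]]
      sizes <- lengths(gsets)
      best <- gsets[sizes == max(sizes)]
      labs <- sort(vapply(best, function(s) paste(sort(s), collapse = "+"),
                          ""))
      cat_rows[[length(cat_rows) + 1L]] <-
        data.frame(direction = dir, gene_symbol = g, category = labs[1],
                   n_lineages = max(sizes), stringsAsFactors = FALSE)
    }
  }
  gene_category <- if (length(cat_rows)) do.call(rbind, cat_rows)
    else data.frame(direction = character(), gene_symbol = character(),
                    category = character(), n_lineages = integer())
  overlap <- if (nrow(gene_category))
    stats::aggregate(gene_symbol ~ direction + category, gene_category,
                     length)
  else data.frame(direction = character(), category = character(),
                  gene_symbol = integer())
  names(overlap)[names(overlap) == "gene_symbol"] <- "n_genes"
  list(lists = lists, overlap = overlap, gene_category = gene_category)
}

#' Genes shared by exactly two lineages at equal levels
#'
#' The convergent-expression follow-up to the overlap analysis: genes
#' sexually dimorphic in two lineages, expressed identically in those two
#' lineages (within the over-expressing sex), and enriched in both relative
#' to the remaining lineages.
#'
#' @param study A filtered [expression_study()].
#' @param stage Stage.
#' @param sex The over-expressing sex.
#' @param lineage_pair Character vector of the two focal lineages.
#' @param cfg A [threshold_config()].
#' @param background_lineages Lineages the pair must exceed; defaults to all
#'   remaining lineages.
#' @return A [gene_list()].
#' @export
shared_pair_signature <- function(study, stage, sex, lineage_pair,
                                  cfg = threshold_config(),
                                  background_lineages = NULL) {
  stopifnot(length(lineage_pair) == 2)
  if (is.null(background_lineages))
    background_lineages <- setdiff(LINEAGES, lineage_pair)
  steps <- list(step_compare(grp(lineage_pair[1], sex, stage),
                             grp(lineage_pair[2], sex, stage), "identical"))
  for (L in lineage_pair) {
    steps <- c(steps, list(step_compare(grp(L, sex, stage),
                                        grp(L, other_sex(sex), stage),
                                        "higher")))
    for (bg in background_lineages)
      steps <- c(steps, list(step_compare(grp(L, sex, stage),
                                          grp(bg, sex, stage), "higher")))
  }
  evaluate_recipe(study,
                  recipe(sprintf("%s shared %s %s", sex,
                                 paste(lineage_pair, collapse = "+"), stage),
                         steps),
                  cfg)
}
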