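#' Score recovery of one planted pattern
#'
#' Confusion counts at the gene level: sensitivity is the fraction of
#' planted genes of the pattern found in the detected list; the
#' false-positive rate is the fraction of unplanted ("null") genes in the
#' detected list. Genes planted with *other* patterns are excluded from both
#' — several templates genuinely belong to more than one list (a maintained
#' male-primed germ gene really is sex-specifically enriched in XY germ
#' cells at the end stage), so they are neither hits nor false alarms here.
#'
#' @param truth Ground-truth table from [simulate_study()].
#' @param pattern Pattern name in the truth table.
#' @param detected A [gene_list()] or character vector of gene symbols.
#' @param universe Optional character vector of gene symbols actually
#'   retained after filtering (the FPR denominator); defaults to all truth
#'   genes.
#' @return One-row data.frame: pattern, n_planted, n_recovered, sensitivity,
#'   n_null, n_false_positive, fpr.
#' @export
score_recovery <- function(truth, pattern, detected, universe = NULL) {
  det <- unique(if (inherits(detected, "gene_list")) detected$gene_symbols
                else as.character(detected))
  planted <- truth$gene_symbol[truth$pattern == pattern]
  nulls <- truth$gene_symbol[truth$pattern == "null"]
  if (!is.null(universe)) {
    planted <- intersect(planted, universe)
    nulls <- intersect(nulls, universe)
  }
  tp <- sum(planted %in% det)
  fp <- sum(nulls %in% det)
  data.frame(pattern = pattern,
             n_planted = length(planted), n_recovered = tp,
             sensitivity = if (length(planted)) tp / length(planted) else NA,
             n_null = length(nulls), n_false_positive = fp,
             fpr = if (length(nulls)) fp / length(nulls) else NA,
             stringsAsFactors = FALSE)
}

#' Run every list recipe against a simulated study and score recovery
#'
#' Evaluates each signature recipe the default simulation plants genes for —
#' sex-specific and sex-independent enrichment/depletion, the progenitor
#' signature, the Leydig deduction, all three priming methods for both
#' sexes, and the multi-lineage dimorphism overlap — and scores each against
#' the ground truth. Level-tag rows report classification accuracy among the
#' recovered primed genes (tagged similar vs intermediate).
#'
#' @param study The *filtered* simulated study.
#' @param truth Ground-truth table.
#' @param cfg A [threshold_config()].
#' @param spec The [simulation_spec()] used (supplies stages and the priming
#'   lineage).
#' @return A data.frame with one detection row per recipe and one level-tag
#'   row per primed pattern (`measure` column distinguishes them).
#' @export
recovery_suite <- function(study, truth, cfg = threshold_config(),
                           spec = simulation_spec()) {
  st <- spec$stages
  start <- st[1]; mid <- st[2]; end <- st[length(st)]
  pl <- spec$priming_lineage
  universe <- unique(study$clusters$gene_symbol)
  rows <- list()
  add <- function(pattern, detected, measure = "detection",
                  recipe_name = NULL) {
    r <- score_recovery(truth, pattern, detected, universe)
    r$measure <- measure
    r$recipe <- recipe_name %||%
      (if (inherits(detected, "gene_list")) detected$name else pattern)
    rows[[length(rows) + 1L]] <<- r
  }

  add("sex_specific",
      lineage_enriched(study, "supporting", "XY", mid, cfg, "sex_specific"))
  add("lineage_enriched",
      lineage_enriched(study, "supporting", stage = mid, cfg = cfg,
                       mode = "sex_independent"))
  add("lineage_depleted",
      lineage_depleted(study, pl, stage = mid, cfg = cfg,
                       mode = "sex_independent"))
  add("sex_independent_progenitor",
      lineage_enriched(study, "supporting", stage = start, cfg = cfg,
                       mode = "sex_independent"))
  add("leydig_contaminant", leydig_genes(study, end, cfg))

  for (sex_for in c("male", "female")) {
    primed <- find_primed(study, pl, start, end, sex_for, cfg, "all_primed")
    retain <- if (sex_for == "male") "XY" else "XX"
    levels <- classify_level(study, primed, pl, retain, start, end, cfg,
                             "enriched")
    for (kind in c("similar", "intermediate")) {
      patt <- sprintf("%s_primed_%s", sex_for, kind)
      add(patt, primed, recipe_name = primed$name)
      hit <- levels$gene_tags$gene_symbol[levels$gene_tags$tag == kind]
      planted <- truth$gene_symbol[truth$pattern == patt]
      recovered <- intersect(planted, unique(primed$gene_symbols))
      acc <- if (length(recovered)) mean(recovered %in% hit) else NA
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = patt, n_planted = length(recovered),
        n_recovered = sum(recovered %in% hit), sensitivity = acc,
        n_null = NA, n_false_positive = NA, fpr = NA,
        measure = "level_tag", recipe = primed$name,
        stringsAsFactors = FALSE)
    }
    # enriched_primed is a strict subset check on the same plants
    enr <- find_primed(study, pl, start, end, sex_for, cfg,
                       "enriched_primed")
    add(sprintf("%s_primed_similar", sex_for), enr,
        recipe_name = enr$name)
  }
  dep <- find_primed(study, pl, start, end, "male", cfg, "depleted_primed")
  add("depleted_primed", dep)

  ov <- dimorphic_overlaps(study, end, cfg)
  two <- ov$gene_category
  det <- two$gene_symbol[two$direction == "XY" &
                         two$category == "interstitial_stromal+supporting"]
  add("dimorphic_multilineage", det, recipe_name =
        sprintf("XY dimorphic overlap %s", end))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("pattern", "recipe", "measure", "n_planted", "n_recovered",
          "sensitivity", "n_null", "n_false_positive", "fpr")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
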