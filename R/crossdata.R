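#' Canonical gene-symbol normalization
#'
#' Cross-platform comparisons are symbol-keyed only, so casing drift between
#' annotation vintages is normalised to the canonical mouse form (initial
#' capital, rest lower case). Empty symbols give `NA`.
#'
#' @param symbols Character vector.
#' @return Normalised character vector.
#' @export
normalize_symbol <- function(symbols) {
  out <- ifelse(nzchar(symbols),
                paste0(toupper(substr(symbols, 1, 1)),
                       tolower(substr(symbols, 2, nchar(symbols)))),
                NA_character_)
  out
}

list_symbols <- function(x) {
  s <- if (inherits(x, "gene_list")) x$gene_symbols else as.character(x)
  s <- normalize_symbol(s)
  unique(s[!is.na(s)])
}

#' Symbol-keyed map between two studies
#'
#' @param study_a,study_b [expression_study()] objects from different
#'   platforms.
#' @return A data.frame: gene_symbol, clusters_a, clusters_b
#'   (comma-separated cluster ids per platform; symbols present in at least
#'   one study).
#' @export
symbol_map <- function(study_a, study_b) {
  sa <- normalize_symbol(study_a$clusters$gene_symbol)
  sb <- normalize_symbol(study_b$clusters$gene_symbol)
  syms <- sort(unique(stats::na.omit(c(sa, sb))))
  data.frame(
    gene_symbol = syms,
    clusters_a = vapply(syms, function(g)
      paste(study_a$clusters$cluster_id[!is.na(sa) & sa == g],
            collapse = ","), ""),
    clusters_b = vapply(syms, function(g)
      paste(study_b$clusters$cluster_id[!is.na(sb) & sb == g],
            collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Restrict a primed list to symbols carried by an enrichment list
#'
#' Keeps the members of a (second-platform) primed list whose gene symbol
#' also appears in a lineage-specific enrichment list from the reference
#' study. Membership is decided on normalised symbols; cluster ids are never
#' compared across platforms.
#'
#' @param primed_b A [gene_list()] from study B.
#' @param enriched_a A [gene_list()] (or character symbol vector, or list of
#'   either) from study A.
#' @return The restricted [gene_list()].
#' @export
restrict_by_enrichment <- function(primed_b, enriched_a) {
  if (is.list(enriched_a) && !inherits(enriched_a, "gene_list"))
    keep_syms <- unique(unlist(lapply(enriched_a, list_symbols)))
  else keep_syms <- list_symbols(enriched_a)
  sym_b <- normalize_symbol(primed_b$gene_symbols)
  keep <- !is.na(sym_b) & sym_b %in% keep_syms
  gene_list(name = paste0(primed_b$name, " [restricted to enriched]"),
            cluster_ids = primed_b$cluster_ids[keep],
            gene_symbols = primed_b$gene_symbols[keep],
            recipe = list(steps = c(primed_b$recipe$steps,
                                    list(list(type = "restrict_symbols",
                                              n_symbols = length(keep_syms))))))
}

#' Interstitial/stromal-associated removal set
#'
#' The three-step deduction of genes to subtract from a supporting-cell
#' priming analysis (one focal sex at a time): (1) genes higher in the focal
#' sex's interstitial cells than its supporting cells; (2) genes sexually
#' dimorphic in both the supporting and the interstitial/stromal cells, minus
#' step 1; (3) all genes sexually dimorphic in the interstitial/stromal
#' cells, minus step 2. The result contains genes sexually dimorphic in the
#' interstitial cells and not the supporting cells, plus genes dimorphic in
#' both when expression is higher in the interstitial/stromal cells.
#'
#' @param study A filtered [expression_study()].
#' @param stage Stage (E12.5 in the study design).
#' @param cfg A [threshold_config()].
#' @param sex Focal (over-expressing) sex, "XY" or "XX".
#' @return A [gene_list()].
#' @export
interstromal_removal_set <- function(study, stage, cfg = threshold_config(),
                                     sex = "XY") {
  O <- other_sex(sex)
  int_vs_supp <- compare_groups(study, grp("interstitial_stromal", sex, stage),
                                grp("supporting", sex, stage), cfg)
  supp_dim <- compare_groups(study, grp("supporting", sex, stage),
                             grp("supporting", O, stage), cfg)
  int_dim <- compare_groups(study, grp("interstitial_stromal", sex, stage),
                            grp("interstitial_stromal", O, stage), cfg)
  s1 <- int_vs_supp$cluster_id[int_vs_supp$call == "higher"]
  A <- int_dim$cluster_id[int_dim$call == "higher"]
  B <- supp_dim$cluster_id[supp_dim$call == "higher"]
  s2 <- setdiff(intersect(A, B), s1)
  ids <- setdiff(A, s2)
  gene_list(name = sprintf("%s interstitial/stromal removal set %s", sex,
                           stage),
            cluster_ids = ids, gene_symbols = cluster_symbols(study, ids),
            recipe = list(steps = list(
              step_compare(grp("interstitial_stromal", sex, stage),
                           grp("interstitial_stromal", O, stage), "higher"),
              step_subtract(s2, "dimorphic in both, higher in supporting"))))
}

#' Relaxed "prior priming" recipe
#'
#' The priming pattern with the progenitor-identity requirement relaxed:
#' rather than being identical between the sexes at the start stage, the sex
#' for which the gene is primed already has higher expression there. Used to
#' ask whether genes already dimorphic at the reference study's start stage
#' show an earlier trace of priming.
#'
#' @inheritParams priming_recipe
#' @return A [recipe()].
#' @export
prior_priming_recipe <- function(lineage, start_stage, end_stage,
                                 sex_for = c("male", "female")) {
  sex_for <- match.arg(sex_for)
  R <- if (sex_for == "male") "XY" else "XX"
  O <- other_sex(R)
  L <- lineage
  recipe(sprintf("%s %s prior-priming (%s..%s)", L, sex_for, start_stage,
                 end_stage),
         step_compare(grp(L, R, start_stage), grp(L, O, start_stage),
                      "higher"),
         step_compare(grp(L, R, end_stage), grp(L, O, end_stage), "higher"),
         step_compare(grp(L, O, start_stage), grp(L, O, end_stage), "higher"),
         step_exclude(grp(L, R, start_stage), grp(L, R, end_stage), "higher"))
}

#' Cross-dataset primed-gene overlap report
#'
#' Partitions the primed symbols of a second study (B) by their behaviour in
#' the reference study (A): primed in both; sexually dimorphic at A's start
#' stage with a prior-priming signature; dimorphic at A's start stage
#' without one; neither primed nor dimorphic in A (including symbols absent
#' from A's platform). The four categories partition the B primed symbols.
#'
#' @param primed_b [gene_list()] (or symbol vector) of primed genes in B.
#' @param primed_a [gene_list()] (or symbol vector) of primed genes in A.
#' @param dimorphic_a Genes sexually dimorphic at A's start stage.
#' @param prior_priming_a Genes with the relaxed prior-priming signature in A
#'   (see [prior_priming_recipe()]).
#' @return A list: `counts` (named integer vector over the four categories),
#'   `membership` (data.frame gene_symbol, category).
#' @export
primed_overlap_report <- function(primed_b, primed_a, dimorphic_a,
                                  prior_priming_a) {
  b <- list_symbols(primed_b)
  a_primed <- list_symbols(primed_a)
  a_dim <- list_symbols(dimorphic_a)
  a_prior <- list_symbols(prior_priming_a)
  category <- ifelse(b %in% a_primed, "primed_in_both",
              ifelse(b %in% a_dim & b %in% a_prior,
                     "dimorphic_with_prior_priming",
              ifelse(b %in% a_dim, "dimorphic_without_prior_priming",
                     "not_primed_or_dimorphic_in_a")))
  counts <- vapply(c("primed_in_both", "dimorphic_with_prior_priming",
                     "dimorphic_without_prior_priming",
                     "not_primed_or_dimorphic_in_a"),
                   function(k) sum(category == k), 0L)
  list(counts = counts,
       membership = data.frame(gene_symbol = b, category = category,
                               stringsAsFactors = FALSE))
}

#' Start-point stability diagnostic
#'
#' Compares two candidate start stages for a priming analysis: how many
#' genes primed from the earlier stage are already sexually dimorphic by the
#' later one, and how often genes identical between the sexes at both stages
#' are nonetheless shifting expression concordantly in both sexes between
#' them (a pattern that confounds a repression/maintenance reading).
#'
#' @param study A filtered [expression_study()].
#' @param lineage Focal lineage.
#' @param stage_early,stage_late The two candidate start stages.
#' @param end_stage Differentiated stage of the priming analysis.
#' @param cfg A [threshold_config()].
#' @return A list: `n_primed_early`, `n_dimorphic_by_late`,
#'   `frac_dimorphic_by_late`, `n_identical_both`, `frac_identical_both`,
#'   `n_concordant_shift`, `frac_concordant_shift`.
#' @export
startpoint_stability <- function(study, lineage, stage_early, stage_late,
                                 end_stage, cfg = threshold_config()) {
  primed <- union(
    find_primed(study, lineage, stage_early, end_stage, "male", cfg,
                "all_primed")$cluster_ids,
    find_primed(study, lineage, stage_early, end_stage, "female", cfg,
                "all_primed")$cluster_ids)
  dim_late <- compare_groups(study, grp(lineage, "XY", stage_late),
                             grp(lineage, "XX", stage_late), cfg)
  dim_early <- compare_groups(study, grp(lineage, "XY", stage_early),
                              grp(lineage, "XX", stage_early), cfg)
  is_dim <- dim_late$cluster_id[dim_late$call %in% c("higher", "lower")]
  ident_early <- dim_early$cluster_id[dim_early$call == "identical"]
  ident_late <- dim_late$cluster_id[dim_late$call == "identical"]
  ident_both <- intersect(primed, intersect(ident_early, ident_late))
  shift_xy <- compare_groups(study, grp(lineage, "XY", stage_late),
                             grp(lineage, "XY", stage_early), cfg)
  shift_xx <- compare_groups(study, grp(lineage, "XX", stage_late),
                             grp(lineage, "XX", stage_early), cfg)
  up_both <- intersect(shift_xy$cluster_id[shift_xy$call == "higher"],
                       shift_xx$cluster_id[shift_xx$call == "higher"])
  down_both <- intersect(shift_xy$cluster_id[shift_xy$call == "lower"],
                         shift_xx$cluster_id[shift_xx$call == "lower"])
  concordant <- intersect(ident_both, union(up_both, down_both))
  n_primed <- length(primed)
  list(n_primed_early = n_primed,
       n_dimorphic_by_late = length(intersect(primed, is_dim)),
       frac_dimorphic_by_late =
         if (n_primed) length(intersect(primed, is_dim)) / n_primed else NA,
       n_identical_both = length(ident_both),
       frac_identical_both =
         if (n_primed) length(ident_both) / n_primed else NA,
       n_concordant_shift = length(concordant),
       frac_concordant_shift =
         if (length(ident_both)) length(concordant) / length(ident_both)
         else NA)
}
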