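#' Recipe identifying primed genes
#'
#' A gene is primed when it is expressed in the sexually undifferentiated
#' progenitor (identical between XX and XY at the start stage), then
#' repressed by one sex and maintained or activated by the other at the end
#' stage. Three methods:
#' \describe{
#'   \item{all_primed}{(male example) identical XX/XY at start; higher in XY
#'     than XX at end; higher in XX at start than at end (repression in XX);
#'     genes also higher in XY at start than at end are removed (differential
#'     repression).}
#'   \item{enriched_primed}{all_primed plus lineage-specific enrichment of the
#'     focal lineage at the start stage in both sexes and at the end stage in
#'     the retaining sex.}
#'   \item{depleted_primed}{(male example) identical XX/XY at start;
#'     lineage-specific repression at start in both sexes (every other
#'     lineage higher); higher in XX than XY at end (remains repressed in
#'     XY); lineage-specific repression in XY at end; higher in XX at end
#'     than start (activation in XX); genes also higher in XY at end than at
#'     start are removed (differential activation).}
#' }
#' "Male-primed" always means the male program retains the progenitor state
#' (maintained expression for the first two methods, maintained depletion for
#' the third); "female-primed" is the mirror image.
#'
#' @param lineage Focal lineage (germ or supporting in the study design).
#' @param start_stage,end_stage Progenitor and differentiated stages.
#' @param sex_for "male" or "female".
#' @param method One of "all_primed", "enriched_primed", "depleted_primed".
#' @return A [recipe()].
#' @export
priming_recipe <- function(lineage, start_stage, end_stage,
                           sex_for = c("male", "female"),
                           method = c("all_primed", "enriched_primed",
                                      "depleted_primed")) {
  sex_for <- match.arg(sex_for)
  method <- match.arg(method)
  R <- if (sex_for == "male") "XY" else "XX"   # retaining sex
  O <- other_sex(R)
  L <- lineage
  name <- sprintf("%s %s-primed %s (%s..%s)", L, sex_for, method,
                  start_stage, end_stage)
  if (method %in% c("all_primed", "enriched_primed")) {
    steps <- list(
      step_compare(grp(L, "XX", start_stage), grp(L, "XY", start_stage),
                   "identical"),
      step_compare(grp(L, R, end_stage), grp(L, O, end_stage), "higher"),
      step_compare(grp(L, O, start_stage), grp(L, O, end_stage), "higher"),
      step_exclude(grp(L, R, start_stage), grp(L, R, end_stage), "higher"))
    if (method == "enriched_primed") {
      for (ol in other_lineages(L)) steps <- c(steps, list(
        step_compare(grp(L, R, start_stage), grp(ol, R, start_stage),
                     "higher"),
        step_compare(grp(L, O, start_stage), grp(ol, O, start_stage),
                     "higher"),
        step_compare(grp(L, R, end_stage), grp(ol, R, end_stage), "higher")))
    }
  } else {
    steps <- list(
      step_compare(grp(L, "XX", start_stage), grp(L, "XY", start_stage),
                   "identical"),
      step_compare(grp(L, O, end_stage), grp(L, R, end_stage), "higher"),
      step_compare(grp(L, O, end_stage), grp(L, O, start_stage), "higher"),
      step_exclude(grp(L, R, end_stage), grp(L, R, start_stage), "higher"))
    for (ol in other_lineages(L)) steps <- c(steps, list(
      step_compare(grp(ol, R, start_stage), grp(L, R, start_stage), "higher"),
      step_compare(grp(ol, O, start_stage), grp(L, O, start_stage), "higher"),
      step_compare(grp(ol, R, end_stage), grp(L, R, end_stage), "higher")))
  }
  recipe(name, steps)
}

#' Find primed genes by one method
#'
#' @param study A filtered [expression_study()].
#' @param lineage Focal lineage.
#' @param start_stage,end_stage Progenitor and differentiated stages (the
#'   study defaults are E11.5 and E13.5 for germ cells, E11.5 and E12.5 for
#'   supporting cells).
#' @param sex_for "male" or "female".
#' @param cfg A [threshold_config()].
#' @param method Priming method, see [priming_recipe()].
#' @return A [gene_list()].
#' @export
find_primed <- function(study, lineage, start_stage, end_stage,
                        sex_for = c("male", "female"),
                        cfg = threshold_config(),
                        method = c("all_primed", "enriched_primed",
                                   "depleted_primed")) {
  evaluate_recipe(study,
                  priming_recipe(lineage, start_stage, end_stage,
                                 match.arg(sex_for), match.arg(method)),
                  cfg)
}

#' Recipe for the marker-list denominator of a priming method
#'
#' The denominator ("all male/female genes") against which the percentage of
#' primed genes is computed: for all_primed, the end-stage sexually dimorphic
#' genes of the lineage (step 2 alone); for enriched_primed, additionally
#' lineage-enriched at the end stage in the retaining sex (steps 2 and 7);
#' for depleted_primed, higher in the opposite sex at the end stage and
#' lineage-depleted in the retaining sex at the end stage (steps 4 and 5).
#'
#' @inheritParams priming_recipe
#' @return A [recipe()].
#' @export
marker_recipe <- function(lineage, end_stage, sex_for = c("male", "female"),
                          method = c("all_primed", "enriched_primed",
                                     "depleted_primed")) {
  sex_for <- match.arg(sex_for)
  method <- match.arg(method)
  R <- if (sex_for == "male") "XY" else "XX"
  O <- other_sex(R)
  L <- lineage
  name <- sprintf("%s %s markers (%s) %s", L, sex_for, method, end_stage)
  if (method == "all_primed") {
    steps <- list(step_compare(grp(L, R, end_stage), grp(L, O, end_stage),
                               "higher"))
  } else if (method == "enriched_primed") {
    steps <- list(step_compare(grp(L, R, end_stage), grp(L, O, end_stage),
                               "higher"))
    for (ol in other_lineages(L))
      steps <- c(steps, list(step_compare(grp(L, R, end_stage),
                                          grp(ol, R, end_stage), "higher")))
  } else {
    steps <- list(step_compare(grp(L, O, end_stage), grp(L, R, end_stage),
                               "higher"))
    for (ol in other_lineages(L))
      steps <- c(steps, list(step_compare(grp(ol, R, end_stage),
                                          grp(L, R, end_stage), "higher")))
  }
  recipe(name, steps)
}

#' Marker-list denominator for a priming method
#'
#' @inheritParams find_primed
#' @return A [gene_list()].
#' @export
marker_denominator <- function(study, lineage, end_stage,
                               sex_for = c("male", "female"),
                               cfg = threshold_config(),
                               method = c("all_primed", "enriched_primed",
                                          "depleted_primed")) {
  evaluate_recipe(study,
                  marker_recipe(lineage, end_stage, match.arg(sex_for),
                                match.arg(method)),
                  cfg)
}

#' Classify primed genes as similar, intermediate, or other
#'
#' Relative to the differentiated level in the retaining sex: a primed gene
#' expressed in the progenitor at the retained level (identical call between
#' start and end stage in the retaining sex) is "similar"; one expressed
#' between the two sexes' final levels (higher at the end stage for
#' maintained genes, higher at the start stage for depleted-primed genes) is
#' "intermediate"; anything else is "other". Gene-level resolution of
#' duplicate transcript clusters: a symbol whose clusters fall into both the
#' similar and intermediate categories is counted as "other"; a symbol with
#' one categorised cluster and one uncategorised cluster keeps the defined
#' category.
#'
#' @param study A filtered [expression_study()].
#' @param primed A primed [gene_list()].
#' @param lineage Focal lineage.
#' @param retaining_sex "XY" or "XX" (the sex keeping the progenitor state).
#' @param start_stage,end_stage Stages of the priming analysis.
#' @param cfg A [threshold_config()].
#' @param direction "enriched" for maintained/activated genes (the all and
#'   enriched methods), "depleted" for the depleted method.
#' @return A list with `cluster_tags` (named character vector over primed
#'   clusters) and `gene_tags` (data.frame gene_symbol, tag).
#' @export
classify_level <- function(study, primed, lineage, retaining_sex,
                           start_stage, end_stage, cfg = threshold_config(),
                           direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  calls <- compare_groups(study, grp(lineage, retaining_sex, end_stage),
                          grp(lineage, retaining_sex, start_stage), cfg)
  rows <- match(primed$cluster_ids, calls$cluster_id)
  cl <- calls$call[rows]
  inter_call <- if (direction == "enriched") "higher" else "lower"
  tag <- ifelse(cl == "identical", "similar",
                ifelse(cl == inter_call, "intermediate", "other"))
  names(tag) <- primed$cluster_ids
  syms <- primed$gene_symbols
  gene_tags <- do.call(rbind, lapply(unique(syms[nzchar(syms)]), function(g) {
    tg <- unique(tag[syms == g])
    out <- if (all(c("similar", "intermediate") %in% tg)) "other"
           else if ("similar" %in% tg) "similar"
           else if ("intermediate" %in% tg) "intermediate"
           else "other"
    data.frame(gene_symbol = g, tag = out, stringsAsFactors = FALSE)
  }))
  if (is.null(gene_tags))
    gene_tags <- data.frame(gene_symbol = character(), tag = character())
  list(cluster_tags = tag, gene_tags = gene_tags)
}

#' Full priming analysis for one lineage and method
#'
#' Runs [find_primed()] for both sexes, tags expression levels with
#' [classify_level()], computes the marker denominators, and returns
#' everything needed by the bias-model tests.
#'
#' @inheritParams find_primed
#' @return A list of class `priming_result`: `method`, `male_primed`,
#'   `female_primed` ([gene_list()]s), `male_levels`, `female_levels`
#'   (from [classify_level()]), `male_markers`, `female_markers`
#'   ([gene_list()]s), and gene-level counts `n_male`, `n_female`,
#'   `n_male_markers`, `n_female_markers`.
#' @export
priming_analysis <- function(study, lineage, start_stage, end_stage,
                             cfg = threshold_config(),
                             method = c("all_primed", "enriched_primed",
                                        "depleted_primed")) {
  method <- match.arg(method)
  dir <- if (method == "depleted_primed") "depleted" else "enriched"
  male <- find_primed(study, lineage, start_stage, end_stage, "male", cfg,
                      method)
  female <- find_primed(study, lineage, start_stage, end_stage, "female",
                        cfg, method)
  res <- list(
    method = method, lineage = lineage,
    start_stage = start_stage, end_stage = end_stage,
    male_primed = male, female_primed = female,
    male_levels = classify_level(study, male, lineage, "XY", start_stage,
                                 end_stage, cfg, dir),
    female_levels = classify_level(study, female, lineage, "XX", start_stage,
                                   end_stage, cfg, dir),
    male_markers = marker_denominator(study, lineage, end_stage, "male", cfg,
                                      method),
    female_markers = marker_denominator(study, lineage, end_stage, "female",
                                        cfg, method))
  res$n_male <- gene_level_count(male)
  res$n_female <- gene_level_count(female)
  res$n_male_markers <- gene_level_count(res$male_markers)
  res$n_female_markers <- gene_level_count(res$female_markers)
  class(res) <- "priming_result"
  res
}

#' @export
print.priming_result <- function(x, ...) {
  cat(sprintf("priming_result [%s, %s, %s..%s]\n", x$lineage, x$method,
              x$start_stage, x$end_stage))
  cat(sprintf("  male-primed:   %d genes (%d clusters) of %d male markers\n",
              x$n_male, length(x$male_primed), x$n_male_markers))
  cat(sprintf("  female-primed: %d genes (%d clusters) of %d female markers\n",
              x$n_female, length(x$female_primed), x$n_female_markers))
  invisible(x)
}
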