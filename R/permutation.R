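# Deterministic small hash of a recipe name, so every named recipe draws an
# independent stream from the same base seed and adding recipes does not
# reshuffle existing results. Kept below 2^31 - 1.
recipe_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 1014743
  as.integer((seed %% 2111489) * 1014 + h %% 1014)
}

#' Permutation-based false discovery rate for a composed gene list
#'
#' The sample-to-group assignment of exactly the arrays participating in the
#' recipe's comparisons is randomly permuted (group sizes preserved), the
#' comparison and exclusion steps are re-evaluated, and the resulting list
#' size recorded — `n_permutations` times (draws with replacement from the
#' permutation space). Subtraction steps (e.g. Leydig-gene removal) are
#' ignored during permutations. The FDR is the mean permuted gene count
#' divided by the observed gene count; cluster-level counts and the median
#' are reported alongside.
#'
#' @param study A filtered [expression_study()].
#' @param rec A [recipe()].
#' @param cfg A [threshold_config()] (supplies `n_permutations` and
#'   `fdr_acceptable`).
#' @param seed Base seed; the recipe name derives an independent stream.
#' @return A list of class `fdr_result`: observed cluster/gene counts,
#'   permuted count vectors, means, medians, `fdr` (gene level),
#'   `fdr_clusters`, `acceptable`, and the seed used. When the observed
#'   count is zero the FDR is `NA` and `acceptable` is `NA`.
#' @export
permutation_fdr <- function(study, rec, cfg = threshold_config(), seed = 1L) {
  observed <- evaluate_recipe(study, rec, cfg)
  obs_cl <- length(observed$cluster_ids)
  obs_gn <- gene_level_count(observed)
  part <- participating_samples(rec, study$samples)
  derived <- recipe_seed(seed, rec$name)
  perm_cl <- integer(cfg$n_permutations)
  perm_gn <- integer(cfg$n_permutations)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(derived)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  design_cols <- c("lineage", "sex", "stage")
  for (i in seq_len(cfg$n_permutations)) {
    perm_samples <- study$samples
    perm_samples[part, design_cols] <-
      study$samples[sample(part), design_cols]
    gl <- evaluate_recipe(study, rec, cfg, samples = perm_samples,
                          skip_subtract = TRUE)
    perm_cl[i] <- length(gl$cluster_ids)
    perm_gn[i] <- gene_level_count(gl)
  }
  fdr <- if (obs_gn > 0) mean(perm_gn) / obs_gn else NA_real_
  structure(list(list_name = rec$name,
                 observed_clusters = obs_cl, observed_genes = obs_gn,
                 permuted_clusters = perm_cl, permuted_genes = perm_gn,
                 mean_permuted_clusters = mean(perm_cl),
                 median_permuted_clusters = stats::median(perm_cl),
                 mean_permuted_genes = mean(perm_gn),
                 median_permuted_genes = stats::median(perm_gn),
                 fdr = fdr,
                 fdr_clusters = if (obs_cl > 0) mean(perm_cl) / obs_cl
                                else NA_real_,
                 acceptable = if (is.na(fdr)) NA else fdr <= cfg$fdr_acceptable,
                 seed = derived),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("fdr_result '%s'\n", x$list_name))
  cat(sprintf("  observed: %d clusters / %d genes\n", x$observed_clusters,
              x$observed_genes))
  cat(sprintf("  permuted: mean %.2f / median %.1f genes over %d permutations\n",
              x$mean_permuted_genes, x$median_permuted_genes,
              length(x$permuted_genes)))
  if (is.na(x$fdr)) cat("  FDR: not applicable (observed count 0)\n")
  else cat(sprintf("  FDR = %.1f%% (%sacceptable)\n", 100 * x$fdr,
                   if (isTRUE(x$acceptable)) "" else "not "))
  invisible(x)
}

#' Summarise several FDR results as one table
#'
#' Mirrors the published permutation-summary layout: list name, observed
#' clusters and genes, mean and median permuted counts at both levels,
#' FDR percentage, acceptability flag.
#'
#' @param results A list of `fdr_result` objects.
#' @return A data.frame.
#' @export
fdr_table <- function(results) {
  do.call(rbind, lapply(results, function(x)
    data.frame(list_name = x$list_name,
               observed_clusters = x$observed_clusters,
               observed_genes = x$observed_genes,
               mean_permuted_clusters = x$mean_permuted_clusters,
               median_permuted_clusters = x$median_permuted_clusters,
               mean_permuted_genes = x$mean_permuted_genes,
               median_permuted_genes = x$median_permuted_genes,
               fdr_pct = 100 * x$fdr, acceptable = x$acceptable,
               stringsAsFactors = FALSE)))
}
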