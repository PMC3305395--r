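# Exact binomial tail probabilities by direct pmf summation. The two-sided
# p-value is the standard exact definition: the sum over all outcomes whose
# pmf does not exceed the observed pmf (with the usual relative tolerance on
# the comparison), capped at 1.
binom_p_two_sided <- function(k, n, p0) {
  d0 <- stats::dbinom(k, n, p0) * (1 + 1e-07)
  min(1, sum(stats::dbinom(0:n, n, p0)[stats::dbinom(0:n, n, p0) <= d0]))
}

binom_p_lower <- function(k, n, p0) sum(stats::dbinom(0:k, n, p0))
binom_p_upper <- function(k, n, p0) sum(stats::dbinom(k:n, n, p0))

# One-tailed toward the observed side of p0: the rejection asks whether the
# observed fraction is too far from the model's prediction on the side where
# it actually lies. An observation exactly at p0 takes the lower tail
# (either tail exceeds 0.5 there, so the model is never excluded).
binom_p_one_sided <- function(k, n, p0) {
  if (k / n <= p0) binom_p_lower(k, n, p0) else binom_p_upper(k, n, p0)
}

#' Test the extreme differentiation models against primed-gene counts
#'
#' Three models predict the sex composition of primed genes: the "female"
#' model (a fraction `model_extreme_fraction`, default 90%, of primed genes
#' are female-primed), the "male" model (90% male-primed), and the
#' "balanced" model (50/50). The female and male models are tested with
#' one-tailed exact binomial tests (toward the observed side of the
#' prediction), the balanced model with a two-tailed exact binomial test.
#' Any model with p below `alpha_model` is excluded. If all three are
#' excluded, an intermediate (biased) model is selected, its direction given
#' by the majority sex; if exactly one model survives it is selected; if
#' several survive the outcome is indeterminate, with the survivors listed.
#'
#' @param n_male,n_female Gene-level counts of male- and female-primed genes.
#' @param cfg A [threshold_config()] (supplies `model_extreme_fraction` and
#'   `alpha_model`).
#' @return A list of class `model_test`: counts, `p_female_model`,
#'   `p_male_model`, `p_balanced`, `excluded`, `surviving`, `selected`.
#' @export
test_models <- function(n_male, n_female, cfg = threshold_config()) {
  n <- n_male + n_female
  if (n < 1) stop("no primed genes: model tests need n_male + n_female >= 1")
  p0 <- cfg$model_extreme_fraction
  p_female <- binom_p_one_sided(n_female, n, p0)
  p_male <- binom_p_one_sided(n_male, n, p0)
  p_balanced <- binom_p_two_sided(n_female, n, 0.5)
  ps <- c(female = p_female, male = p_male, balanced = p_balanced)
  excluded <- names(ps)[ps < cfg$alpha_model]
  surviving <- setdiff(names(ps), excluded)
  selected <- if (length(surviving) == 0) {
    if (n_male > n_female) "male_biased"
    else if (n_female > n_male) "female_biased"
    else "indeterminate"
  } else if (length(surviving) == 1) surviving else "indeterminate"
  structure(list(n_male = n_male, n_female = n_female,
                 p_female_model = p_female, p_male_model = p_male,
                 p_balanced = p_balanced, excluded = excluded,
                 surviving = surviving, selected = selected,
                 model_extreme_fraction = p0, alpha = cfg$alpha_model),
            class = "model_test")
}

#' @export
print.model_test <- function(x, ...) {
  cat(sprintf("model_test: %d male-primed vs %d female-primed genes\n",
              x$n_male, x$n_female))
  cat(sprintf("  p(female %.0f%%) = %.4g, p(male %.0f%%) = %.4g, p(balanced) = %.4g\n",
              100 * x$model_extreme_fraction, x$p_female_model,
              100 * x$model_extreme_fraction, x$p_male_model, x$p_balanced))
  cat(sprintf("  excluded: %s; selected: %s\n",
              if (length(x$excluded)) paste(x$excluded, collapse = ", ")
              else "none", x$selected))
  invisible(x)
}

#' Two-sided exact test of sex x priming independence
#'
#' The 2x2 contingency table of primed vs not-primed genes in the male and
#' female marker lists (actual gene counts, not percentages), tested with the
#' two-sided exact test on the hypergeometric null (Fisher's exact test,
#' probability-mass method): the p-value sums the probabilities of all tables
#' with the observed margins whose probability does not exceed the observed
#' table's. A significant result means sex and priming are not independent —
#' the two programs are unequally represented in the progenitor.
#'
#' @param primed_m,notprimed_m Male-marker genes primed / not primed.
#' @param primed_f,notprimed_f Female-marker genes primed / not primed.
#' @return The two-sided p-value. A zero margin gives p = 1 with a warning.
#' @export
test_independence <- function(primed_m, notprimed_m, primed_f, notprimed_f) {
  stopifnot(primed_m >= 0, notprimed_m >= 0, primed_f >= 0, notprimed_f >= 0)
  N <- primed_m + notprimed_m + primed_f + notprimed_f
  if (N < 1) stop("empty table")
  K <- primed_m + primed_f          # primed margin
  M <- primed_m + notprimed_m       # male margin
  if (K == 0 || K == N || M == 0 || M == N) {
    warning("zero margin in 2x2 table; independence p-value is 1")
    return(1)
  }
  support <- max(0, K - (N - M)):min(K, M)
  dens <- stats::dhyper(support, M, N - M, K)
  d0 <- stats::dhyper(primed_m, M, N - M, K) * (1 + 1e-07)
  min(1, sum(dens[dens <= d0]))
}

#' Full bias-model report for a priming analysis
#'
#' Combines [test_models()] on the primed-gene counts with
#' [test_independence()] on the primed-vs-marker 2x2 table.
#'
#' @param pr A `priming_result` from [priming_analysis()].
#' @param cfg A [threshold_config()].
#' @return A list of class `model_report`: the `model_test`, the
#'   independence p-value, and the underlying counts.
#' @export
bias_report <- function(pr, cfg = threshold_config()) {
  mt <- test_models(pr$n_male, pr$n_female, cfg)
  p_ind <- test_independence(pr$n_male, pr$n_male_markers - pr$n_male,
                             pr$n_female, pr$n_female_markers - pr$n_female)
  structure(list(method = pr$method, lineage = pr$lineage,
                 model_test = mt, p_independence = p_ind,
                 n_male_markers = pr$n_male_markers,
                 n_female_markers = pr$n_female_markers,
                 pct_male_primed = 100 * pr$n_male /
                   max(1, pr$n_male_markers),
                 pct_female_primed = 100 * pr$n_female /
                   max(1, pr$n_female_markers)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model_report [%s, %s]\n", x$lineage, x$method))
  print(x$model_test)
  cat(sprintf("  %.1f%% of %d male markers primed; %.1f%% of %d female markers primed\n",
              x$pct_male_primed, x$n_male_markers,
              x$pct_female_primed, x$n_female_markers))
  cat(sprintf("  sex x priming independence p = %.4g\n", x$p_independence))
  invisible(x)
}
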