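#' Compare two sample groups for every transcript cluster
#'
#' The atomic operation every list recipe composes. For each retained cluster
#' a two-sided two-sample t-test on the log2 replicate values (pooled variance
#' by default, Welch optional via `cfg$var_equal`) gives the p-value; the
#' fold change is reported on the linear scale with the signed
#' convention: for d = mean_a - mean_b, FC = 2^d when d >= 0 and -2^(-d)
#' otherwise, so |FC| >= 1 always and the "between -1.5 and 1.5" identity
#' window reads literally. Calls:
#' \describe{
#'   \item{higher}{p < p_cutoff and FC >= fc_cutoff}
#'   \item{lower}{p < p_cutoff and FC <= -fc_cutoff}
#'   \item{identical}{p > p_cutoff and |FC| < fc_cutoff}
#'   \item{neither}{anything else (boundary cases included)}
#' }
#' Degenerate zero-variance rows: equal means give p = 1, unequal means p = 0
#' (the t-statistic's limits), so the call is decided by the fold change.
#'
#' @param study A filtered [expression_study()].
#' @param group_a,group_b Group descriptors from [grp()].
#' @param cfg A [threshold_config()].
#' @param samples Optional replacement sample sheet (used internally by the
#'   permutation machinery); defaults to the study's own.
#' @return A data.frame of class `comparison_calls` with one row per cluster:
#'   cluster_id, gene_symbol, mean_a, mean_b, fold_change, p_value, call.
#' @export
compare_groups <- function(study, group_a, group_b, cfg = threshold_config(),
                           samples = NULL) {
  if (is.null(samples)) samples <- study$samples
  ia <- resolve_group(samples, group_a)
  ib <- resolve_group(samples, group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop(sprintf("groups must have >=2 replicates (got %d and %d)",
                 length(ia), length(ib)))
  tt <- row_ttest(study$matrix[, ia, drop = FALSE],
                  study$matrix[, ib, drop = FALSE],
                  var_equal = cfg$var_equal)
  d <- tt$mean_a - tt$mean_b
  fc <- ifelse(d >= 0, 2^d, -2^(-d))
  call <- rep("neither", length(d))
  call[tt$p < cfg$p_cutoff & fc >= cfg$fc_cutoff] <- "higher"
  call[tt$p < cfg$p_cutoff & fc <= -cfg$fc_cutoff] <- "lower"
  call[tt$p > cfg$p_cutoff & abs(fc) < cfg$fc_cutoff] <- "identical"
  out <- data.frame(cluster_id = rownames(study$matrix),
                    gene_symbol = study$clusters$gene_symbol,
                    mean_a = tt$mean_a, mean_b = tt$mean_b,
                    fold_change = fc, p_value = tt$p, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  class(out) <- c("comparison_calls", "data.frame")
  out
}

# Vectorised two-sample t-test over matrix rows. Zero-variance convention:
# p = 1 when the means are equal, p = 0 when they differ.
row_ttest <- function(a, b, var_equal = TRUE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se2 <- va / na + vb / nb
    se <- sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se == 0
  if (any(zero)) p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  list(mean_a = ma, mean_b = mb, t = tstat, p = p, df = df)
}

#' Extract the clusters with a wanted call
#'
#' @param calls A `comparison_calls` table from [compare_groups()].
#' @param wanted One of "higher", "lower", "identical", "neither".
#' @return A [gene_list()] whose recipe records the comparison.
#' @export
call_set <- function(calls, wanted = c("higher", "lower", "identical",
                                       "neither")) {
  wanted <- match.arg(wanted)
  hit <- calls$call == wanted
  step <- list(type = "compare", a = attr(calls, "group_a"),
               b = attr(calls, "group_b"), wanted = wanted)
  gene_list(name = sprintf("%s [%s vs %s]", wanted,
                           grp_label(attr(calls, "group_a")),
                           grp_label(attr(calls, "group_b"))),
            cluster_ids = calls$cluster_id[hit],
            gene_symbols = calls$gene_symbol[hit],
            recipe = list(steps = list(step)))
}

#' Write a comparison-call table to delimited text
#'
#' @param calls A `comparison_calls` table.
#' @param file Output path.
#' @export
write_calls <- function(calls, file) {
  utils::write.table(as.data.frame(calls), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
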