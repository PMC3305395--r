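#' Hierarchical clustering of arrays
#'
#' Clusters the sample profiles of a filtered study. The default — Ward's
#' method on squared Euclidean distances — is the configuration under which
#' the arrays cluster primarily by lineage and secondarily by sex and stage;
#' average linkage with Euclidean distance and complete linkage with
#' Pearson's dissimilarity (1 - r between sample profiles) are the
#' alternates.
#'
#' @param study A filtered [expression_study()].
#' @param linkage One of "ward", "average", "complete".
#' @param metric One of "squared_euclidean", "euclidean",
#'   "pearson_dissimilarity".
#' @return An [stats::hclust] dendrogram with sample ids as labels.
#' @export
cluster_arrays <- function(study,
                           linkage = c("ward", "average", "complete"),
                           metric = c("squared_euclidean", "euclidean",
                                      "pearson_dissimilarity")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  if (ncol(study$matrix) < 2) stop("clustering needs at least 2 samples")
  d <- switch(metric,
    squared_euclidean = stats::dist(t(study$matrix))^2,
    euclidean = stats::dist(t(study$matrix)),
    pearson_dissimilarity = stats::as.dist(1 - stats::cor(study$matrix)))
  if (all(d == 0))
    warning("all pairwise distances are zero; degenerate dendrogram")
  # ward.D on pre-squared Euclidean distances is the classic Ward criterion
  method <- switch(linkage, ward = "ward.D", average = "average",
                   complete = "complete")
  stats::hclust(d, method = method)
}

#' Export a dendrogram in Newick format
#'
#' @param hc An [stats::hclust] object.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(hc, file) {
  ape::write.tree(ape::as.phylo(hc), file = file)
  invisible(file)
}

#' Per-gene ANOVA sources of variation
#'
#' Fits a main-effects ANOVA (no interactions) to every gene over the given
#' design factors and aggregates the per-factor F ratios by mean and median
#' across genes. Each factor's F compares the fit with and without that
#' factor against the full-model residual. A reference row for the residual
#' (F = 1 by definition) is appended. The dominant source of variation in
#' this study design is lineage, then sex, then stage.
#'
#' @param study A filtered [expression_study()].
#' @param factors Design factors (columns of the sample sheet).
#' @return A list of class `variation_report`: `summary` (data.frame factor,
#'   df, mean_F, median_F, ordered by mean_F) and `F` (genes x factors
#'   matrix of per-gene F ratios).
#' @export
sources_of_variation <- function(study,
                                 factors = c("lineage", "sex", "stage")) {
  samples <- study$samples
  for (f in factors) {
    lev <- unique(samples[[f]])
    if (length(lev) < 2)
      stop(sprintf("factor '%s' has fewer than 2 levels", f))
  }
  fdat <- as.data.frame(lapply(samples[factors], factor))
  full_form <- stats::as.formula(paste("~", paste(factors, collapse = " + ")))
  X <- stats::model.matrix(full_form, fdat)
  Y <- t(study$matrix)                       # samples x genes
  fit_full <- stats::lm.fit(X, Y)
  rss_full <- colSums(fit_full$residuals^2)
  df_e <- nrow(X) - fit_full$rank
  if (df_e <= 0)
    stop("no residual degrees of freedom: the design has unreplicated cells")
  Fmat <- matrix(NA_real_, nrow = nrow(study$matrix), ncol = length(factors),
                 dimnames = list(rownames(study$matrix), factors))
  dfs <- integer(length(factors))
  for (i in seq_along(factors)) {
    red <- setdiff(factors, factors[i])
    Xr <- if (length(red))
      stats::model.matrix(stats::as.formula(
        paste("~", paste(red, collapse = " + "))), fdat)
    else stats::model.matrix(~1, fdat)
    fit_red <- stats::lm.fit(Xr, Y)
    rss_red <- colSums(fit_red$residuals^2)
    df_f <- fit_full$rank - fit_red$rank
    dfs[i] <- df_f
    Fmat[, i] <- ((rss_red - rss_full) / df_f) / (rss_full / df_e)
  }
  summary <- data.frame(factor = factors, df = dfs,
                        mean_F = colMeans(Fmat),
                        median_F = apply(Fmat, 2, stats::median),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$mean_F), ]
  summary <- rbind(summary,
                   data.frame(factor = "residual", df = df_e, mean_F = 1,
                              median_F = 1))
  rownames(summary) <- NULL
  structure(list(summary = summary, F = Fmat, df_error = df_e),
            class = "variation_report")
}

#' @export
print.variation_report <- function(x, ...) {
  cat("sources of variation (per-gene main-effects ANOVA):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
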