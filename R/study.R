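#' Analysis thresholds and tuning parameters
#'
#' Bundles every cutoff used downstream: the per-comparison significance and
#' fold-change cutoffs, the expression floor applied before all analysis, the
#' permutation settings for list-level FDR, and the parameters of the
#' biased-differentiation model tests.
#'
#' @param p_cutoff Per-comparison p-value cutoff for a difference call and
#'   (exceeded) for an identity call. Default 0.05.
#' @param fc_cutoff Linear-scale fold-change cutoff (signed convention, so a
#'   difference call needs |FC| >= `fc_cutoff` and an identity call needs
#'   |FC| < `fc_cutoff`). Must be > 1. Default 1.5.
#' @param expression_floor log2 intensity a transcript cluster must exceed
#'   (strictly) to be considered expressed. Default 6.
#' @param min_replicates_over_floor Number of replicates of at least one
#'   (lineage, sex, stage) group that must exceed the floor. Default 2 (of 3);
#'   for other replicate counts use `ceiling(2/3 * n_rep)` via
#'   [filter_clusters()].
#' @param n_permutations Label permutations for list-level FDR. Default 200.
#' @param fdr_acceptable Largest acceptable list-level FDR. Default 0.20.
#' @param model_extreme_fraction The fraction of primed genes the extreme
#'   (single-pathway) differentiation models predict for their sex.
#'   Default 0.90.
#' @param alpha_model Exclusion threshold for the model tests and the
#'   independence test. Default 0.05.
#' @param var_equal Use the pooled-variance two-sample t-test (`TRUE`,
#'   default) or Welch's unequal-variance test.
#'
#' @return An object of class `threshold_config` (a validated list).
#' @export
threshold_config <- function(p_cutoff = 0.05, fc_cutoff = 1.5,
                             expression_floor = 6,
                             min_replicates_over_floor = 2,
                             n_permutations = 200, fdr_acceptable = 0.20,
                             model_extreme_fraction = 0.90,
                             alpha_model = 0.05, var_equal = TRUE) {
  stopifnot(p_cutoff > 0, p_cutoff < 1,
            alpha_model > 0, alpha_model < 1,
            fc_cutoff > 1,
            fdr_acceptable > 0, fdr_acceptable <= 1,
            model_extreme_fraction > 0.5, model_extreme_fraction < 1,
            min_replicates_over_floor >= 1,
            n_permutations >= 1)
  structure(list(p_cutoff = p_cutoff, fc_cutoff = fc_cutoff,
                 expression_floor = expression_floor,
                 min_replicates_over_floor = min_replicates_over_floor,
                 n_permutations = n_permutations,
                 fdr_acceptable = fdr_acceptable,
                 model_extreme_fraction = model_extreme_fraction,
                 alpha_model = alpha_model, var_equal = var_equal),
            class = "threshold_config")
}

LINEAGES <- c("supporting", "interstitial_stromal", "germ", "endothelial")
SEXES <- c("XX", "XY")

#' Construct an expression study
#'
#' The central container: a log2 intensity matrix (transcript clusters x
#' samples), sample annotations and transcript-cluster annotations. Most users
#' build one via [load_study()] or [simulate_study()].
#'
#' @param matrix Numeric matrix of log2 intensities; rownames are transcript
#'   cluster ids, colnames sample ids.
#' @param samples data.frame with columns `sample_id`, `lineage`
#'   (one of supporting, interstitial_stromal, germ, endothelial, other),
#'   `sex` (XX/XY), `stage` (ordered factor or character), `replicate`.
#' @param clusters data.frame with columns `cluster_id`, `gene_symbol`,
#'   `annotation_quality` ("best"/"other") and optionally `is_control`.
#' @param stages Optional character vector giving stage order; defaults to the
#'   sorted unique stages (E-day labels sort correctly).
#'
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(matrix, samples, clusters, stages = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix of log2 intensities")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  clusters <- as.data.frame(clusters, stringsAsFactors = FALSE)
  need_s <- c("sample_id", "lineage", "sex", "stage", "replicate")
  if (!all(need_s %in% names(samples)))
    stop("sample sheet must have columns: ", paste(need_s, collapse = ", "))
  need_c <- c("cluster_id", "gene_symbol", "annotation_quality")
  if (!all(need_c %in% names(clusters)))
    stop("annotation must have columns: ", paste(need_c, collapse = ", "))
  if (!"is_control" %in% names(clusters)) clusters$is_control <- FALSE
  samples[need_s[1:4]] <- lapply(samples[need_s[1:4]], as.character)
  samples$replicate <- as.integer(samples$replicate)
  clusters[need_c] <- lapply(clusters[need_c], as.character)
  clusters$gene_symbol[is.na(clusters$gene_symbol)] <- ""

  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  dup <- clusters$cluster_id[duplicated(clusters$cluster_id)]
  if (length(dup)) stop("duplicate cluster id(s): ", paste(unique(dup), collapse = ", "))
  key <- with(samples, paste(lineage, sex, stage, replicate))
  if (anyDuplicated(key))
    stop("duplicate (lineage, sex, stage, replicate) combination: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))

  miss_col <- setdiff(colnames(matrix), samples$sample_id)
  if (length(miss_col))
    stop("matrix column(s) missing from sample sheet: ",
         paste(miss_col, collapse = ", "))
  miss_row <- setdiff(rownames(matrix), clusters$cluster_id)
  if (length(miss_row))
    stop("matrix row(s) missing from annotation: ",
         paste(utils::head(miss_row, 10), collapse = ", "))

  # align annotations to the matrix; extra annotation rows are dropped
  samples <- samples[match(colnames(matrix), samples$sample_id), , drop = FALSE]
  clusters <- clusters[match(rownames(matrix), clusters$cluster_id), , drop = FALSE]
  rownames(samples) <- NULL
  rownames(clusters) <- NULL
  if (is.null(stages)) stages <- sort(unique(samples$stage))
  structure(list(matrix = matrix, samples = samples, clusters = clusters,
                 stages = stages, filtered = FALSE),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d transcript clusters x %d samples%s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (isTRUE(x$filtered)) " (filtered)" else ""))
  cat(sprintf("  lineages: %s\n", paste(unique(x$samples$lineage), collapse = ", ")))
  cat(sprintf("  stages:   %s\n", paste(x$stages, collapse = " < ")))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$matrix)

#' Read a study from its three delimited text files
#'
#' @param matrix_file Tab-delimited: first column transcript cluster id,
#'   header row of sample ids, decimal log2 intensities.
#' @param sample_sheet Delimited text with columns sample_id, lineage, sex,
#'   stage, replicate.
#' @param annotation_file Delimited text with columns cluster_id, gene_symbol,
#'   annotation_quality and optionally is_control.
#' @param sep Field separator, default tab.
#' @return A validated [expression_study()].
#' @export
load_study <- function(matrix_file, sample_sheet, annotation_file, sep = "\t") {
  for (f in c(matrix_file, sample_sheet, annotation_file))
    if (!file.exists(f)) stop("file not found: ", f)
  raw <- utils::read.table(matrix_file, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric value '%s' at cluster %s, sample %s",
                   vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                   colnames(vals)[bad[1, 2]]))
  }
  rownames(num) <- ids
  samples <- utils::read.table(sample_sheet, sep = sep, header = TRUE,
                               stringsAsFactors = FALSE, quote = "")
  clusters <- utils::read.table(annotation_file, sep = sep, header = TRUE,
                                stringsAsFactors = FALSE, quote = "")
  if ("is_control" %in% names(clusters)) {
    ctl <- as.logical(clusters$is_control) |
      clusters$is_control %in% c("1", "yes", "TRUE", "true")
    keep <- !ctl %in% TRUE
    dropped <- clusters$cluster_id[!keep]
    clusters <- clusters[keep, , drop = FALSE]
    num <- num[!rownames(num) %in% dropped, , drop = FALSE]
    if (length(dropped))
      message(length(dropped), " control probe(s) removed at load")
  }
  expression_study(num, samples, clusters)
}

#' Write a study back to the three-file text format
#'
#' Inverse of [load_study()]; numbers are written with full precision so a
#' round trip reproduces the matrix bit-exactly for finite decimal inputs.
#'
#' @param study An [expression_study()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the three file paths.
#' @export
write_study <- function(study, dir, prefix = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mf <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  sf <- file.path(dir, paste0(prefix, "_samples.tsv"))
  af <- file.path(dir, paste0(prefix, "_annotation.tsv"))
  df <- data.frame(cluster_id = rownames(study$matrix),
                   format(study$matrix, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$samples, sf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$clusters, af, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = mf, samples = sf, annotation = af))
}

#' Transcript-cluster inclusion filter
#'
#' Retains exactly the clusters that (a) carry best-grade annotation
#' (perfect-match cross-hybridization category, or grade A/B on the older
#' platform), (b) have a non-empty gene symbol, and (c) exceed the expression
#' floor (strictly, log2 > 6 by default) in at least
#' `min_replicates_over_floor` replicates of at least one
#' (lineage, sex, stage) sample group. Idempotent; intensity values of
#' retained clusters are untouched. With replicate counts other than 3 the
#' per-group requirement generalises to `ceiling(2/3 * n_rep)`.
#'
#' @param study An [expression_study()].
#' @param cfg A [threshold_config()].
#' @return The filtered study.
#' @export
filter_clusters <- function(study, cfg = threshold_config()) {
  mat <- study$matrix
  grp <- with(study$samples, paste(lineage, sex, stage, sep = "/"))
  keep_expr <- rep(FALSE, nrow(mat))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    n_rep <- length(cols)
    need <- if (n_rep == 3) cfg$min_replicates_over_floor
            else max(cfg$min_replicates_over_floor, ceiling(2 / 3 * n_rep))
    if (n_rep < need)
      stop(sprintf("group %s has %d replicate(s); %d required over the floor",
                   g, n_rep, need))
    over <- rowSums(mat[, cols, drop = FALSE] > cfg$expression_floor)
    keep_expr <- keep_expr | (over >= need)
  }
  keep <- keep_expr &
    study$clusters$annotation_quality == "best" &
    nzchar(study$clusters$gene_symbol)
  out <- study
  out$matrix <- mat[keep, , drop = FALSE]
  out$clusters <- study$clusters[keep, , drop = FALSE]
  rownames(out$clusters) <- NULL
  out$filtered <- TRUE
  out
}

#' Map transcript cluster ids to gene symbols
#'
#' @param study An [expression_study()].
#' @param cluster_ids Character vector of cluster ids.
#' @return Character vector of symbols (empty string where unannotated).
#' @export
cluster_symbols <- function(study, cluster_ids) {
  study$clusters$gene_symbol[match(cluster_ids, study$clusters$cluster_id)]
}

# resolve a (lineage, sex, stage) descriptor to sample-sheet rows
resolve_group <- function(samples, group) {
  stopifnot(all(c("lineage", "sex", "stage") %in% names(group)))
  idx <- which(samples$lineage == group$lineage &
               samples$sex == group$sex &
               samples$stage == group$stage)
  if (!length(idx))
    stop(sprintf("no samples for group (%s, %s, %s)",
                 group$lineage, group$sex, group$stage))
  idx
}

#' Group descriptor
#'
#' @param lineage,sex,stage Coordinates of a sample group.
#' @return A named list usable wherever a group descriptor is expected.
#' @export
grp <- function(lineage, sex, stage) {
  list(lineage = lineage, sex = sex, stage = stage)
}

grp_label <- function(g) paste(g$sex, g$lineage, g$stage, sep = " ")
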