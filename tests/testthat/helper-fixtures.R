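# Deterministic fixture builders shared across test files.

# A study built from explicit group means: every (lineage, sex, stage) group
# gets 3 replicates at mean + c(-0.1, 0, 0.1), so within-group sd is exactly
# 0.1 and equal-mean groups give t = 0, p = 1 without any RNG.
#
# group_means: genes x groups matrix; columns named "lineage/sex/stage".
make_group_study <- function(group_means, stages = NULL,
                             gene_symbols = NULL,
                             rep_offsets = c(-0.1, 0, 0.1)) {
  keys <- strsplit(colnames(group_means), "/", fixed = TRUE)
  samples <- do.call(rbind, lapply(seq_along(keys), function(i) {
    k <- keys[[i]]
    data.frame(lineage = k[1], sex = k[2], stage = k[3],
               replicate = seq_along(rep_offsets),
               sample_id = paste(k[2], k[1], k[3], seq_along(rep_offsets),
                                 sep = "."),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(group_means)
  mat <- matrix(NA_real_, n, nrow(samples))
  for (j in seq_len(ncol(group_means))) {
    cols <- (j - 1) * length(rep_offsets) + seq_along(rep_offsets)
    mat[, cols] <- outer(group_means[, j], rep_offsets, `+`)
  }
  rownames(mat) <- if (is.null(rownames(group_means)))
    sprintf("TC%03d", seq_len(n)) else rownames(group_means)
  colnames(mat) <- samples$sample_id
  if (is.null(gene_symbols)) gene_symbols <- sprintf("Gene%03d", seq_len(n))
  clusters <- data.frame(cluster_id = rownames(mat),
                         gene_symbol = gene_symbols,
                         annotation_quality = "best",
                         stringsAsFactors = FALSE)
  expression_study(mat, samples, clusters, stages = stages)
}

# Column keys for a full 4-lineage x 2-sex design at given stages.
full_design_keys <- function(stages) {
  g <- expand.grid(lineage = c("supporting", "interstitial_stromal", "germ",
                               "endothelial"),
                   sex = c("XX", "XY"), stage = stages,
                   stringsAsFactors = FALSE)
  paste(g$lineage, g$sex, g$stage, sep = "/")
}

# A genes x groups matrix of constant baseline over the full design.
baseline_means <- function(n_genes, stages, baseline = 8) {
  keys <- full_design_keys(stages)
  matrix(baseline, n_genes, length(keys), dimnames = list(NULL, keys))
}

# Small simulated studies are expensive enough to share across tests.
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$small_sim)) {
    spec <- simulation_spec(n_genes = 1200,
                            plants = c(sex_specific = 40,
                                       lineage_enriched = 40,
                                       lineage_depleted = 40,
                                       male_primed_similar = 40,
                                       female_primed_similar = 40,
                                       leydig_contaminant = 40),
                            seed = 424242)
    sim <- simulate_study(spec)
    sim$filtered <- filter_clusters(sim$study)
    .fixture_env$small_sim <- sim
  }
  .fixture_env$small_sim
}
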