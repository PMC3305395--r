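#' Simulation specification
#'
#' Describes a synthetic sorted-population study: the factorial design
#' (4 lineages x 2 sexes x 3 stages x 3 replicates by default, 72 arrays),
#' per-gene log2 baselines, homoscedastic Gaussian replicate noise on the
#' log2 scale, and rosters of planted genes whose group means follow known
#' pattern templates. The defaults are the desk-scale study conditions used
#' throughout the package: 5000 genes, baseline N(8, 1), noise sd 0.25,
#' planted effect 2 log2 units, about 2% of genes per pattern, 10% of genes
#' carrying a duplicate transcript cluster. Planted genes draw their
#' baselines from N(9, 0.5) truncated at 8 — pattern templates emulate
#' well-expressed marker genes, which keeps the depleted templates above the
#' expression floor in their reference groups.
#'
#' Pattern templates (delta = `effect`, germ-cell priming runs E11.5 to
#' E13.5):
#' \describe{
#'   \item{sex_specific}{+delta in XY supporting cells at E12.5 only.}
#'   \item{lineage_enriched}{+delta in supporting cells of both sexes at
#'     E12.5 (sex-independent enrichment).}
#'   \item{lineage_depleted}{-delta in germ cells of both sexes at E12.5.}
#'   \item{sex_independent_progenitor}{+delta in supporting cells of both
#'     sexes at E11.5.}
#'   \item{male_primed_similar}{germ cells: both sexes at +delta at E11.5;
#'     XY stays at +delta, XX decays to baseline by E13.5.}
#'   \item{male_primed_intermediate}{both sexes at +delta at E11.5 (midway
#'     between the final levels); XY rises to +2 delta, XX falls to baseline
#'     by E13.5, so each divergence arm carries the full delta.}
#'   \item{female_primed_similar, female_primed_intermediate}{sex-mirrored.}
#'   \item{depleted_primed}{germ cells at -delta in both sexes at E11.5; XY
#'     stays depleted, XX returns to baseline by E13.5 (male variant).}
#'   \item{leydig_contaminant}{+delta in XY interstitium and XY endothelial
#'     cells at E12.5 and E13.5 (the steroidogenic co-sorting pattern).}
#'   \item{dimorphic_multilineage}{+delta in XY supporting and XY
#'     interstitial cells at E13.5.}
#' }
#'
#' @param n_genes Number of genes (before duplicate clusters).
#' @param stages Ordered stage labels; the first is the progenitor stage.
#' @param n_replicates Replicates per (lineage, sex, stage) group.
#' @param baseline_mean,baseline_sd Per-gene log2 baseline distribution.
#' @param noise_sd Replicate noise sd (log2).
#' @param effect Planted effect size delta (log2).
#' @param plants Named integer vector: planted genes per pattern. Set to
#'   `c()` for a pure-noise study.
#' @param duplicate_cluster_rate Fraction of genes given a second transcript
#'   cluster (same symbol, same group means, independent noise).
#' @param structure_sd Named numeric `c(lineage=, sex=, stage=)`: sd of
#'   per-gene factor-level offsets applied to unplanted genes, for studies
#'   carrying global design structure (all zero in the default list-recovery
#'   conditions).
#' @param priming_lineage Lineage carrying the priming plants.
#' @param seed RNG seed (< 2^31).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 5000,
                            stages = c("E11.5", "E12.5", "E13.5"),
                            n_replicates = 3,
                            baseline_mean = 8, baseline_sd = 1,
                            noise_sd = 0.25, effect = 2,
                            plants = c(sex_specific = 100,
                                       lineage_enriched = 100,
                                       lineage_depleted = 100,
                                       sex_independent_progenitor = 100,
                                       male_primed_similar = 100,
                                       male_primed_intermediate = 100,
                                       female_primed_similar = 100,
                                       female_primed_intermediate = 100,
                                       depleted_primed = 100,
                                       leydig_contaminant = 100,
                                       dimorphic_multilineage = 100),
                            duplicate_cluster_rate = 0.10,
                            structure_sd = c(lineage = 0, sex = 0,
                                             stage = 0),
                            priming_lineage = "germ",
                            seed = 20120401) {
  known <- c("sex_specific", "lineage_enriched", "lineage_depleted",
             "sex_independent_progenitor", "male_primed_similar",
             "male_primed_intermediate", "female_primed_similar",
             "female_primed_intermediate", "depleted_primed",
             "leydig_contaminant", "dimorphic_multilineage")
  if (length(plants)) {
    bad <- setdiff(names(plants), known)
    if (length(bad)) stop("unknown pattern(s): ", paste(bad, collapse = ", "))
    if (sum(plants) > n_genes) stop("more planted genes than genes")
  }
  stopifnot(noise_sd > 0, length(stages) >= 2, n_replicates >= 2,
            seed == as.integer(seed))
  structure(list(n_genes = n_genes, stages = stages,
                 n_replicates = n_replicates, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 effect = effect, plants = plants,
                 duplicate_cluster_rate = duplicate_cluster_rate,
                 structure_sd = structure_sd,
                 priming_lineage = priming_lineage,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Pattern template: group-mean offsets (relative to the gene's baseline) for
# every (lineage, sex, stage) group, as a named numeric vector keyed
# "lineage/sex/stage".
pattern_offsets <- function(pattern, spec, groups) {
  d <- spec$effect
  st <- spec$stages
  start <- st[1]
  mid <- if (length(st) >= 3) st[2] else NULL
  end <- st[length(st)]
  pl <- spec$priming_lineage
  off <- stats::setNames(numeric(nrow(groups)),
                         paste(groups$lineage, groups$sex, groups$stage,
                               sep = "/"))
  put <- function(lineage, sex, stage, value) {
    key <- paste(lineage, sex, stage, sep = "/")
    off[key] <<- value
  }
  # Every divergence arm of a primed template carries the full effect d:
  # "similar" genes start at the retained level d and the losing sex falls
  # by d; "intermediate" genes start midway (d) between final levels 0 and
  # 2d, so the retaining sex activates by d while the losing sex represses
  # by d.
  primed <- function(retain, lose, similar) {
    e_r <- if (similar) d else 2 * d
    for (s in c(retain, lose)) put(pl, s, start, d)
    if (!is.null(mid)) {
      put(pl, retain, mid, if (similar) d else 1.5 * d)
      put(pl, lose, mid, d / 2)
    }
    put(pl, retain, end, e_r)
    put(pl, lose, end, 0)
  }
  switch(pattern,
    sex_specific = put("supporting", "XY", "E12.5", d),
    lineage_enriched = for (s in SEXES) put("supporting", s, "E12.5", d),
    lineage_depleted = for (s in SEXES) put(pl, s, "E12.5", -d),
    sex_independent_progenitor =
      for (s in SEXES) put("supporting", s, start, d),
    male_primed_similar = primed("XY", "XX", TRUE),
    male_primed_intermediate = primed("XY", "XX", FALSE),
    female_primed_similar = primed("XX", "XY", TRUE),
    female_primed_intermediate = primed("XX", "XY", FALSE),
    depleted_primed = {
      for (s in SEXES) put(pl, s, start, -d)
      if (!is.null(mid)) { put(pl, "XY", mid, -d); put(pl, "XX", mid, -d / 2) }
      put(pl, "XY", end, -d); put(pl, "XX", end, 0)
    },
    leydig_contaminant = {
      late <- setdiff(st, start)
      for (stg in late) {
        put("interstitial_stromal", "XY", stg, d)
        put("endothelial", "XY", stg, d)
      }
    },
    dimorphic_multilineage = {
      put("supporting", "XY", end, d)
      put("interstitial_stromal", "XY", end, d)
    },
    stop("unknown pattern: ", pattern))
  off
}

#' Simulate a sorted-population expression study with known ground truth
#'
#' Group means are built from the gene's baseline plus its pattern template
#' (plus factor-structure offsets for unplanted genes when `structure_sd` is
#' nonzero); replicate values add independent Gaussian noise. Deterministic
#' under the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list: `study` (an unfiltered [expression_study()]), `truth`
#'   (data.frame gene_symbol, pattern, n_clusters), `spec`.
#' @export
simulate_study <- function(spec = simulation_spec()) {
  set.seed(spec$seed)
  groups <- expand.grid(lineage = LINEAGES, sex = SEXES,
                        stage = spec$stages, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  gkey <- paste(groups$lineage, groups$sex, groups$stage, sep = "/")
  n_grp <- nrow(groups)
  samples <- groups[rep(seq_len(n_grp), each = spec$n_replicates), ]
  samples$replicate <- rep(seq_len(spec$n_replicates), times = n_grp)
  samples$sample_id <- paste(samples$sex, samples$lineage, samples$stage,
                             samples$replicate, sep = ".")
  rownames(samples) <- NULL

  n <- spec$n_genes
  syms <- sprintf("Sim%05d", seq_len(n))
  pattern <- rep("null", n)
  if (length(spec$plants)) {
    idx <- 1L
    for (p in names(spec$plants)) {
      k <- spec$plants[[p]]
      pattern[idx:(idx + k - 1L)] <- p
      idx <- idx + k
    }
  }
  planted <- pattern != "null"
  base <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)
  if (any(planted))
    base[planted] <- pmax(8, stats::rnorm(sum(planted), 9, 0.5))

  # group-mean matrix (genes x groups)
  gm <- matrix(base, nrow = n, ncol = n_grp)
  colnames(gm) <- gkey
  for (p in unique(pattern[planted])) {
    off <- pattern_offsets(p, spec, groups)
    rows <- which(pattern == p)
    gm[rows, ] <- gm[rows, ] + rep(off[gkey], each = length(rows))
  }
  if (any(spec$structure_sd != 0) && any(!planted)) {
    nulls <- which(!planted)
    for (fac in c("lineage", "sex", "stage")) {
      sd_f <- spec$structure_sd[[fac]]
      if (is.na(sd_f) || sd_f == 0) next
      levs <- unique(groups[[fac]])
      offs <- matrix(stats::rnorm(length(nulls) * length(levs), 0, sd_f),
                     nrow = length(nulls),
                     dimnames = list(NULL, levs))
      gm[nulls, ] <- gm[nulls, ] + offs[, groups[[fac]]]
    }
  }

  dup <- stats::runif(n) < spec$duplicate_cluster_rate
  gene_of_cluster <- c(seq_len(n), which(dup))
  cluster_id <- c(sprintf("TC%05d", seq_len(n)),
                  sprintf("TC%05db", which(dup)))
  ord <- order(gene_of_cluster, cluster_id)
  gene_of_cluster <- gene_of_cluster[ord]
  cluster_id <- cluster_id[ord]

  col_group <- match(paste(samples$lineage, samples$sex, samples$stage,
                           sep = "/"), gkey)
  mean_mat <- gm[gene_of_cluster, col_group, drop = FALSE]
  mat <- mean_mat + stats::rnorm(length(mean_mat), 0, spec$noise_sd)
  rownames(mat) <- cluster_id
  colnames(mat) <- samples$sample_id

  clusters <- data.frame(cluster_id = cluster_id,
                         gene_symbol = syms[gene_of_cluster],
                         annotation_quality = "best",
                         is_control = FALSE, stringsAsFactors = FALSE)
  truth <- data.frame(gene_symbol = syms, pattern = pattern,
                      n_clusters = as.integer(1 + dup),
                      baseline = base, stringsAsFactors = FALSE)
  study <- expression_study(mat, samples, clusters, stages = spec$stages)
  list(study = study, truth = truth, spec = spec)
}

#' Swap the sex labels of a study
#'
#' Relabels XX as XY and vice versa in the sample sheet, leaving the data
#' untouched: every downstream male list on the relabelled study must equal
#' the corresponding female list on the original (label-swap equivariance).
#'
#' @param study An [expression_study()].
#' @return The relabelled study.
#' @export
swap_sex_labels <- function(study) {
  study$samples$sex <- ifelse(study$samples$sex == "XY", "XX", "XY")
  study
}

#' Write a simulated study and its ground truth to disk
#'
#' Emits the three standard input files plus the ground-truth table.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return Invisibly, the file paths.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  paths <- write_study(sim$study, dir, prefix)
  tf <- file.path(dir, paste0(prefix, "_truth.tsv"))
  utils::write.table(sim$truth, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, truth = tf))
}
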