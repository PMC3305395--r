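structure_sim <- function() {
  if (is.null(.fixture_env$structure_sim)) {
    spec <- simulation_spec(n_genes = 1000, plants = c(),
                            structure_sd = c(lineage = 1.0, sex = 0.5,
                                             stage = 0.25),
                            seed = 31415)
    .fixture_env$structure_sim <- filter_clusters(simulate_study(spec)$study)
  }
  .fixture_env$structure_sim
}

test_that("identical samples merge first; a duplicated sample is its own neighbour", {
  st <- structure_sim()
  dup <- st
  dup$matrix <- cbind(dup$matrix, dup$matrix[, 1])
  colnames(dup$matrix)[ncol(dup$matrix)] <- "dup"
  extra <- dup$samples[1, ]
  extra$sample_id <- "dup"; extra$replicate <- 99L
  dup$samples <- rbind(dup$samples, extra)
  hc <- cluster_arrays(dup)
  first <- hc$merge[1, ]
  merged <- hc$labels[-first]
  expect_setequal(merged, c(colnames(st$matrix)[1], "dup"))
  expect_equal(hc$height[1], 0)
})

test_that("strong lineage structure is recovered by a 4-cluster Ward cut", {
  st <- structure_sim()
  for (metric in c("squared_euclidean", "pearson_dissimilarity")) {
    linkage <- if (metric == "squared_euclidean") "ward" else "complete"
    hc <- cluster_arrays(st, linkage, metric)
    cut4 <- stats::cutree(hc, 4)
    tab <- table(cut4, st$samples$lineage)
    expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1))
  }
})

test_that("Pearson-dissimilarity clustering ignores per-sample affine rescaling", {
  st <- structure_sim()
  sc <- st
  scale_f <- seq(0.5, 2, length.out = ncol(sc$matrix))
  shift <- seq(-3, 3, length.out = ncol(sc$matrix))
  sc$matrix <- sweep(sweep(sc$matrix, 2, scale_f, `*`), 2, shift, `+`)
  a <- cluster_arrays(st, "complete", "pearson_dissimilarity")
  b <- cluster_arrays(sc, "complete", "pearson_dissimilarity")
  expect_equal(a$height, b$height, tolerance = 1e-8)
  expect_identical(a$merge, b$merge)
})

test_that("the dendrogram is invariant under sample reordering", {
  st <- structure_sim()
  perm <- rev(seq_len(ncol(st$matrix)))
  st2 <- st
  st2$matrix <- st2$matrix[, perm]
  st2$samples <- st2$samples[perm, ]
  a <- cluster_arrays(st)
  b <- cluster_arrays(st2)
  expect_equal(sort(a$height), sort(b$height), tolerance = 1e-8)
})

test_that("Newick export round-trips through ape", {
  st <- structure_sim()
  hc <- cluster_arrays(st)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, colnames(st$matrix))
})

test_that("sources of variation rank lineage over sex over stage", {
  st <- structure_sim()
  sv <- sources_of_variation(st)
  m <- setNames(sv$summary$mean_F, sv$summary$factor)
  expect_gt(m[["lineage"]], m[["sex"]])
  expect_gt(m[["sex"]], m[["stage"]])
  md <- setNames(sv$summary$median_F, sv$summary$factor)
  expect_gt(md[["lineage"]], md[["sex"]])
})

test_that("per-gene F ratios match a per-gene ANOVA fit", {
  st <- structure_sim()
  sv <- sources_of_variation(st)
  dat <- data.frame(lineage = factor(st$samples$lineage),
                    sex = factor(st$samples$sex),
                    stage = factor(st$samples$stage))
  for (i in c(1, 50, 500)) {
    dat$y <- st$matrix[i, ]
    # the design is balanced, so sequential and drop-one F coincide
    aof <- stats::anova(stats::lm(y ~ lineage + sex + stage, dat))
    expect_equal(unname(sv$F[i, ]),
                 aof[c("lineage", "sex", "stage"), "F value"],
                 tolerance = 1e-8)
  }
})

test_that("null data give central-F behaviour and effect scaling is monotone", {
  spec0 <- simulation_spec(n_genes = 1500, plants = c(), seed = 2718)
  st0 <- filter_clusters(simulate_study(spec0)$study)
  sv0 <- sources_of_variation(st0)
  df2 <- sv0$df_error
  expect_equal(mean(sv0$F[, "lineage"]), df2 / (df2 - 2), tolerance = 0.1)
  ks <- stats::ks.test(sv0$F[, "lineage"],
                       function(q) stats::pf(q, 3, df2))
  expect_lt(unname(ks$statistic), 0.05)
  # doubling the lineage effect raises the lineage F
  spec2 <- simulation_spec(n_genes = 400, plants = c(),
                           structure_sd = c(lineage = 0.5, sex = 0,
                                            stage = 0), seed = 555)
  spec3 <- simulation_spec(n_genes = 400, plants = c(),
                           structure_sd = c(lineage = 1.0, sex = 0,
                                            stage = 0), seed = 555)
  f2 <- sources_of_variation(filter_clusters(simulate_study(spec2)$study))
  f3 <- sources_of_variation(filter_clusters(simulate_study(spec3)$study))
  expect_gt(mean(f3$F[, "lineage"]), mean(f2$F[, "lineage"]))
})

test_that("degenerate designs produce informative errors", {
  st <- structure_sim()
  one_sex <- st
  keep <- one_sex$samples$sex == "XY"
  one_sex$samples <- one_sex$samples[keep, ]
  one_sex$matrix <- one_sex$matrix[, keep]
  expect_error(sources_of_variation(one_sex), "sex")
  single <- st
  single$matrix <- single$matrix[, 1, drop = FALSE]
  single$samples <- single$samples[1, ]
  expect_error(cluster_arrays(single), "2 samples")
})
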