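test_that("simulation is bit-identical under a fixed seed", {
  spec <- simulation_spec(n_genes = 200, seed = 7,
                          plants = c(sex_specific = 10))
  a <- simulate_study(spec)
  b <- simulate_study(spec)
  expect_identical(a$study$matrix, b$study$matrix)
  expect_identical(a$truth, b$truth)
  c <- simulate_study(simulation_spec(n_genes = 200, seed = 8,
                                      plants = c(sex_specific = 10)))
  expect_false(identical(a$study$matrix, c$study$matrix))
})

test_that("group means follow the pattern templates when noise is negligible", {
  spec <- simulation_spec(n_genes = 50, noise_sd = 1e-09,
                          plants = c(male_primed_similar = 5,
                                     depleted_primed = 5,
                                     leydig_contaminant = 5),
                          duplicate_cluster_rate = 0, seed = 123)
  sim <- simulate_study(spec)
  st <- sim$study
  gmean <- function(cluster, lineage, sex, stage) {
    idx <- st$samples$lineage == lineage & st$samples$sex == sex &
      st$samples$stage == stage
    mean(st$matrix[cluster, idx])
  }
  tr <- sim$truth
  base <- tr$baseline
  cl_of <- function(pattern) which(tr$pattern == pattern)[1]
  i <- cl_of("male_primed_similar"); cl <- st$clusters$cluster_id[i]
  expect_equal(gmean(cl, "germ", "XY", "E11.5"), base[i] + 2, tolerance = 1e-6)
  expect_equal(gmean(cl, "germ", "XX", "E11.5"), base[i] + 2, tolerance = 1e-6)
  expect_equal(gmean(cl, "germ", "XY", "E13.5"), base[i] + 2, tolerance = 1e-6)
  expect_equal(gmean(cl, "germ", "XX", "E13.5"), base[i], tolerance = 1e-6)
  expect_equal(gmean(cl, "supporting", "XY", "E11.5"), base[i],
               tolerance = 1e-6)
  i <- cl_of("depleted_primed"); cl <- st$clusters$cluster_id[i]
  expect_equal(gmean(cl, "germ", "XY", "E13.5"), base[i] - 2, tolerance = 1e-6)
  expect_equal(gmean(cl, "germ", "XX", "E13.5"), base[i], tolerance = 1e-6)
  i <- cl_of("leydig_contaminant"); cl <- st$clusters$cluster_id[i]
  expect_equal(gmean(cl, "interstitial_stromal", "XY", "E13.5"), base[i] + 2,
               tolerance = 1e-6)
  expect_equal(gmean(cl, "endothelial", "XY", "E12.5"), base[i] + 2,
               tolerance = 1e-6)
  expect_equal(gmean(cl, "endothelial", "XX", "E13.5"), base[i],
               tolerance = 1e-6)
})

test_that("a no-plant study has no structure beyond noise", {
  spec <- simulation_spec(n_genes = 300, plants = c(), seed = 11)
  sim <- simulate_study(spec)
  expect_true(all(sim$truth$pattern == "null"))
  st <- filter_clusters(sim$study)
  # group means stay within a few noise standard errors of the baselines
  gl <- lineage_enriched(st, "supporting", "XY", "E12.5",
                         mode = "sex_specific")
  expect_lte(length(gl$cluster_ids), 2)
})

test_that("duplicate transcript clusters share symbols and template means", {
  spec <- simulation_spec(n_genes = 400, duplicate_cluster_rate = 0.5,
                          plants = c(sex_specific = 20), seed = 31)
  sim <- simulate_study(spec)
  st <- sim$study
  expect_identical(nrow(st$matrix),
                   as.integer(sum(sim$truth$n_clusters)))
  dups <- grep("b$", st$clusters$cluster_id, value = TRUE)
  expect_gt(length(dups), 100)
  primary <- sub("b$", "", dups)
  expect_identical(cluster_symbols(st, dups), cluster_symbols(st, primary))
  # same group means, different noise
  expect_false(identical(st$matrix[dups[1], ], st$matrix[primary[1], ]))
})

test_that("the three-file round trip preserves a simulated study", {
  spec <- simulation_spec(n_genes = 60, plants = c(sex_specific = 5),
                          seed = 5)
  sim <- simulate_study(spec)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, "sim")
  st <- load_study(file.path(dir, "sim_matrix.tsv"),
                   file.path(dir, "sim_samples.tsv"),
                   file.path(dir, "sim_annotation.tsv"))
  expect_equal(st$matrix, sim$study$matrix)
  truth <- utils::read.table(file.path(dir, "sim_truth.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  expect_identical(truth$pattern, sim$truth$pattern)
})

test_that("recovery scoring has the right endpoints", {
  truth <- data.frame(gene_symbol = sprintf("G%02d", 1:20),
                      pattern = rep(c("sex_specific", "null"), each = 10),
                      stringsAsFactors = FALSE)
  planted <- truth$gene_symbol[1:10]
  perfect <- score_recovery(truth, "sex_specific", planted)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fpr, 0)
  everything <- score_recovery(truth, "sex_specific", truth$gene_symbol)
  expect_equal(everything$sensitivity, 1)
  expect_equal(everything$fpr, 1)
  nothing <- score_recovery(truth, "sex_specific", character(0))
  expect_equal(nothing$sensitivity, 0)
  expect_equal(nothing$fpr, 0)
})

test_that("unknown plant patterns and oversized rosters are rejected", {
  expect_error(simulation_spec(plants = c(bogus = 5)), "bogus")
  expect_error(simulation_spec(n_genes = 10,
                               plants = c(sex_specific = 50)),
               "more planted")
})
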