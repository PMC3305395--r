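# Group-mean fixture across the priming stages for germ cells; the other
# lineages sit at baseline so enrichment steps can be exercised too.
priming_fixture <- function(genes) {
  stages <- c("E11.5", "E13.5")
  means <- baseline_means(length(genes), stages)
  key <- function(l, s, st) paste(l, s, st, sep = "/")
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    for (nm in names(g)) {
      parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
      means[i, key("germ", parts[1], parts[2])] <- g[[nm]]
    }
  }
  make_group_study(means, stages = stages)
}

test_that("the maintained/repressed pattern is primed; symmetric repression is not", {
  st <- priming_fixture(list(
    # gene 1: classic male-primed (equal high at start, XX falls)
    c("XX E11.5" = 10, "XY E11.5" = 10, "XY E13.5" = 10, "XX E13.5" = 8),
    # gene 2: repressed identically in both sexes -> removed by the
    # differential-repression exclusion
    c("XX E11.5" = 10, "XY E11.5" = 10, "XY E13.5" = 8, "XX E13.5" = 8),
    # gene 3: constant -> fails the repression step
    c("XX E11.5" = 10, "XY E11.5" = 10, "XY E13.5" = 10, "XX E13.5" = 10)))
  pm <- find_primed(st, "germ", "E11.5", "E13.5", "male")
  expect_setequal(pm$cluster_ids, "TC001")
  # gene 2 fails step 2 (no dimorphism at the end) *and* the exclusion;
  # check the exclusion alone by giving it end-stage dimorphism
  st2 <- priming_fixture(list(
    c("XX E11.5" = 12, "XY E11.5" = 12, "XY E13.5" = 10, "XX E13.5" = 8)))
  expect_length(find_primed(st2, "germ", "E11.5", "E13.5",
                            "male")$cluster_ids, 0)
})

test_that("the enriched method adds lineage-specificity requirements", {
  # primed pattern but expressed at the same level in supporting cells at
  # the start -> passes all_primed, fails enriched_primed
  stages <- c("E11.5", "E13.5")
  means <- baseline_means(1, stages)
  key <- function(l, s, st) paste(l, s, st, sep = "/")
  for (s in c("XX", "XY")) {
    means[1, key("germ", s, "E11.5")] <- 10
    means[1, key("supporting", s, "E11.5")] <- 10
  }
  means[1, key("germ", "XY", "E13.5")] <- 10
  means[1, key("germ", "XX", "E13.5")] <- 8
  st <- make_group_study(means, stages = stages)
  expect_length(find_primed(st, "germ", "E11.5", "E13.5", "male",
                            method = "all_primed"), 1)
  expect_length(find_primed(st, "germ", "E11.5", "E13.5", "male",
                            method = "enriched_primed"), 0)
})

test_that("the depleted method finds genes kept repressed by one sex", {
  stages <- c("E11.5", "E13.5")
  means <- baseline_means(2, stages)
  key <- function(l, s, st) paste(l, s, st, sep = "/")
  # gene 1: depleted in germ cells of both sexes at the start; XX activates
  # by the end, XY stays depleted -> male depleted-primed
  for (s in c("XX", "XY")) means[1, key("germ", s, "E11.5")] <- 6.3
  means[1, key("germ", "XY", "E13.5")] <- 6.3
  means[1, key("germ", "XX", "E13.5")] <- 8
  # gene 2: activates in both sexes -> removed by the exclusion
  for (s in c("XX", "XY")) means[2, key("germ", s, "E11.5")] <- 6.3
  means[2, key("germ", "XY", "E13.5")] <- 7.6
  means[2, key("germ", "XX", "E13.5")] <- 9
  st <- make_group_study(means, stages = stages)
  dp <- find_primed(st, "germ", "E11.5", "E13.5", "male",
                    method = "depleted_primed")
  expect_setequal(dp$cluster_ids, "TC001")
})

test_that("level tags separate similar, intermediate, and conflicted symbols", {
  stages <- c("E11.5", "E13.5")
  means <- baseline_means(4, stages)
  key <- function(l, s, st) paste(l, s, st, sep = "/")
  primed_shape <- function(i, start_level) {
    for (s in c("XX", "XY")) means[i, key("germ", s, "E11.5")] <<- start_level
    means[i, key("germ", "XY", "E13.5")] <<- 10
    means[i, key("germ", "XX", "E13.5")] <<- 8
  }
  primed_shape(1, 10)   # flat in XY -> similar
  primed_shape(2, 9)    # rises 2-fold in XY -> intermediate
  primed_shape(3, 10)   # duplicate clusters of one gene, one similar ...
  primed_shape(4, 9)    # ... one intermediate -> gene counted as other
  st <- make_group_study(means, stages = stages,
                         gene_symbols = c("Flat", "Rise", "Both", "Both"))
  pm <- find_primed(st, "germ", "E11.5", "E13.5", "male")
  expect_setequal(pm$cluster_ids, c("TC001", "TC002", "TC003", "TC004"))
  lv <- classify_level(st, pm, "germ", "XY", "E11.5", "E13.5")
  expect_identical(unname(lv$cluster_tags[c("TC001", "TC002")]),
                   c("similar", "intermediate"))
  tags <- setNames(lv$gene_tags$tag, lv$gene_tags$gene_symbol)
  expect_identical(tags[["Flat"]], "similar")
  expect_identical(tags[["Rise"]], "intermediate")
  expect_identical(tags[["Both"]], "other")
  # tag counts partition the primed genes
  expect_identical(nrow(lv$gene_tags), gene_level_count(pm))
})

test_that("a symbol with one categorised and one uncategorised cluster keeps its category", {
  stages <- c("E11.5", "E13.5")
  means <- baseline_means(2, stages)
  key <- function(l, s, st) paste(l, s, st, sep = "/")
  for (i in 1:2) {
    for (s in c("XX", "XY")) means[i, key("germ", s, "E11.5")] <- 10
    means[i, key("germ", "XY", "E13.5")] <- 10
    means[i, key("germ", "XX", "E13.5")] <- 8
  }
  # second cluster: nudge the XY start so the start-vs-end call is neither
  # identical nor higher (a 1.4-fold, p-ambiguous shape)
  means[2, key("germ", "XY", "E11.5")] <- 10.55
  means[2, key("germ", "XX", "E11.5")] <- 10.55
  st <- make_group_study(means, stages = stages,
                         gene_symbols = c("Mix", "Mix"))
  pm <- find_primed(st, "germ", "E11.5", "E13.5", "male")
  expect_setequal(pm$cluster_ids, c("TC001", "TC002"))
  lv <- classify_level(st, pm, "germ", "XY", "E11.5", "E13.5")
  # the nudged cluster's start-vs-end call is "neither" (significant but
  # sub-1.5-fold), leaving it uncategorised
  expect_identical(lv$cluster_tags[["TC002"]], "other")
  expect_identical(lv$gene_tags$tag[lv$gene_tags$gene_symbol == "Mix"],
                   "similar")
})

test_that("primed lists sit inside their marker denominators", {
  sim <- small_sim()
  st <- sim$filtered
  for (method in c("all_primed", "enriched_primed")) {
    pr <- priming_analysis(st, "germ", "E11.5", "E13.5", method = method)
    expect_length(intersect(pr$male_primed$cluster_ids,
                            pr$female_primed$cluster_ids), 0)
    expect_true(all(pr$male_primed$cluster_ids %in%
                      pr$male_markers$cluster_ids))
    expect_true(all(pr$female_primed$cluster_ids %in%
                      pr$female_markers$cluster_ids))
  }
  # extra constraints only remove: enriched method within the all method
  all_m <- find_primed(st, "germ", "E11.5", "E13.5", "male",
                       method = "all_primed")
  enr_m <- find_primed(st, "germ", "E11.5", "E13.5", "male",
                       method = "enriched_primed")
  expect_true(all(enr_m$cluster_ids %in% all_m$cluster_ids))
  enr_d <- marker_denominator(st, "germ", "E13.5", "male",
                              method = "enriched_primed")
  all_d <- marker_denominator(st, "germ", "E13.5", "male",
                              method = "all_primed")
  expect_true(all(enr_d$cluster_ids %in% all_d$cluster_ids))
})
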