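# Hand-built fixture over the full design at one stage: group means chosen so
# set membership can be worked out by hand.
signature_fixture <- function() {
  means <- baseline_means(5, "E12.5")
  key <- function(l, s) paste(l, s, "E12.5", sep = "/")
  # gene 1: enriched in XY supporting only
  means[1, key("supporting", "XY")] <- 10
  # gene 2: high in XY supporting AND XY germ (fails lineage specificity)
  means[2, key("supporting", "XY")] <- 10
  means[2, key("germ", "XY")] <- 10
  # gene 3: uniform
  # gene 4: enriched in supporting cells of both sexes (sex-independent)
  means[4, key("supporting", "XY")] <- 10
  means[4, key("supporting", "XX")] <- 10
  # gene 5: depleted in germ cells of both sexes
  means[5, key("germ", "XY")] <- 6.2
  means[5, key("germ", "XX")] <- 6.2
  make_group_study(means, stages = "E12.5")
}

test_that("sex-specific enrichment needs every intersection to hold", {
  st <- signature_fixture()
  gl <- lineage_enriched(st, "supporting", "XY", "E12.5",
                         mode = "sex_specific")
  expect_setequal(gl$cluster_ids, "TC001")
  # the XY-supporting+XY-germ gene fails the supporting-vs-germ comparison
  expect_false("TC002" %in% gl$cluster_ids)
})

test_that("sex-independent lists require XX/XY identity in the focal lineage", {
  st <- signature_fixture()
  enr <- lineage_enriched(st, "supporting", stage = "E12.5",
                          mode = "sex_independent")
  expect_setequal(enr$cluster_ids, "TC004")
  dep <- lineage_depleted(st, "germ", stage = "E12.5",
                          mode = "sex_independent")
  expect_setequal(dep$cluster_ids, "TC005")
})

test_that("planted signatures are recovered and enriched/depleted stay disjoint", {
  sim <- small_sim()
  st <- sim$filtered
  enr <- lineage_enriched(st, "supporting", "XY", "E12.5",
                          mode = "sex_specific")
  planted <- sim$truth$gene_symbol[sim$truth$pattern == "sex_specific"]
  expect_gte(mean(planted %in% enr$gene_symbols), 0.9)
  dep <- lineage_depleted(st, "supporting", "XY", "E12.5",
                          mode = "sex_specific")
  expect_length(intersect(enr$cluster_ids, dep$cluster_ids), 0)
  # the sex-independent list is a subset of each sex's lineage-higher set
  si <- lineage_enriched(st, "supporting", stage = "E12.5",
                         mode = "sex_independent")
  for (s in c("XX", "XY")) {
    for (ol in c("interstitial_stromal", "germ", "endothelial")) {
      calls <- compare_groups(st, grp("supporting", s, "E12.5"),
                              grp(ol, s, "E12.5"))
      expect_true(all(si$cluster_ids %in%
                        calls$cluster_id[calls$call == "higher"]))
    }
  }
})

test_that("swapping the sex labels maps XY lists onto XX lists exactly", {
  sim <- small_sim()
  st <- sim$filtered
  sw <- swap_sex_labels(st)
  a <- lineage_enriched(st, "supporting", "XY", "E12.5",
                        mode = "sex_specific")
  b <- lineage_enriched(sw, "supporting", "XX", "E12.5",
                        mode = "sex_specific")
  expect_setequal(a$cluster_ids, b$cluster_ids)
  pm <- find_primed(st, "germ", "E11.5", "E13.5", "male")
  pf <- find_primed(sw, "germ", "E11.5", "E13.5", "female")
  expect_setequal(pm$cluster_ids, pf$cluster_ids)
})

test_that("Leydig deduction needs both the interstitial and endothelial conditions", {
  means <- baseline_means(3, "E13.5")
  key <- function(l, s) paste(l, s, "E13.5", sep = "/")
  # gene 1: the co-sorting contaminant (XY interstitium + XY endothelium)
  means[1, key("interstitial_stromal", "XY")] <- 10
  means[1, key("endothelial", "XY")] <- 10
  # gene 2: high only in the XY interstitium
  means[2, key("interstitial_stromal", "XY")] <- 10
  st <- make_group_study(means, stages = "E13.5")
  gl <- leydig_genes(st, "E13.5")
  expect_setequal(gl$cluster_ids, "TC001")

  sim <- small_sim()
  ly <- leydig_genes(sim$filtered, "E13.5")
  planted <- sim$truth$gene_symbol[sim$truth$pattern == "leydig_contaminant"]
  expect_gte(mean(planted %in% ly$gene_symbols), 0.9)
  nulls <- sim$truth$gene_symbol[sim$truth$pattern == "null"]
  expect_lte(mean(nulls %in% ly$gene_symbols), 0.02)
})

test_that("subtract_list removes members and records provenance", {
  sim <- small_sim()
  st <- sim$filtered
  endo <- lineage_enriched(st, "endothelial", "XY", "E13.5",
                           mode = "sex_specific")
  ly <- leydig_genes(st, "E13.5")
  pruned <- subtract_list(endo, ly)
  expect_length(intersect(pruned$cluster_ids, ly$cluster_ids), 0)
  last <- pruned$recipe$steps[[length(pruned$recipe$steps)]]
  expect_identical(last$type, "subtract")
  expect_true(last$skip_in_permutation)

  disjoint <- gene_list("none", character(0), character(0),
                        list(steps = list()))
  expect_setequal(subtract_list(endo, disjoint)$cluster_ids,
                  endo$cluster_ids)
  expect_length(subtract_list(endo, endo)$cluster_ids, 0)
})

test_that("missing groups produce an informative error", {
  means <- baseline_means(2, "E13.5")
  st <- make_group_study(means, stages = "E13.5")
  keep <- st$samples$lineage != "endothelial"
  st$samples <- st$samples[keep, ]
  st$matrix <- st$matrix[, keep, drop = FALSE]
  expect_error(leydig_genes(st, "E13.5"), "endothelial")
})

test_that("dimorphic genes are counted once, in the highest-overlap category", {
  means <- baseline_means(4, "E13.5")
  key <- function(l, s) paste(l, s, "E13.5", sep = "/")
  # clusters 1 and 2 share a symbol: one dimorphic in supporting only, the
  # other in supporting and germ -> the gene lands in the 2-way cell
  means[1, key("supporting", "XY")] <- 10
  means[2, key("supporting", "XY")] <- 10
  means[2, key("germ", "XY")] <- 10
  # cluster 3: its own gene, dimorphic in two lineages
  means[3, key("supporting", "XY")] <- 10
  means[3, key("interstitial_stromal", "XY")] <- 10
  st <- make_group_study(means, stages = "E13.5",
                         gene_symbols = c("Dup1", "Dup1", "Solo", "Quiet"))
  ov <- dimorphic_overlaps(st, "E13.5")
  gc <- ov$gene_category
  expect_identical(gc$category[gc$gene_symbol == "Dup1"], "germ+supporting")
  expect_identical(gc$n_lineages[gc$gene_symbol == "Dup1"], 2L)
  expect_identical(gc$category[gc$gene_symbol == "Solo"],
                   "interstitial_stromal+supporting")
  expect_false("Quiet" %in% gc$gene_symbol)

  # no dimorphism at all -> empty tables
  quiet <- make_group_study(baseline_means(3, "E13.5"), stages = "E13.5")
  ov0 <- dimorphic_overlaps(quiet, "E13.5")
  expect_identical(nrow(ov0$overlap), 0L)
})

test_that("the shared-pair signature keeps convergent two-lineage genes only", {
  means <- baseline_means(3, "E13.5")
  key <- function(l, s) paste(l, s, "E13.5", sep = "/")
  # gene 1: identical high level in XX supporting and XX stroma, dimorphic
  # in both, above the other two lineages
  means[1, key("supporting", "XX")] <- 10
  means[1, key("interstitial_stromal", "XX")] <- 10
  # gene 2: dimorphic in supporting only
  means[2, key("supporting", "XX")] <- 10
  st <- make_group_study(means, stages = "E13.5")
  gl <- shared_pair_signature(st, "E13.5", "XX",
                              c("supporting", "interstitial_stromal"))
  expect_setequal(gl$cluster_ids, "TC001")
})
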