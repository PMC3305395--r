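#!/usr/bin/env Rscript

# Global structure diagnostics on a study carrying factor structure
# (lineage >> sex >> stage): hierarchical clustering of the 72 arrays and
# the per-gene ANOVA sources of variation.

library(lineageprime)
dir.create("results", showWarnings = FALSE)

spec <- simulation_spec(n_genes = 2000, plants = c(),
                        structure_sd = c(lineage = 1.0, sex = 0.5,
                                         stage = 0.25),
                        seed = 20120402)
study <- filter_clusters(simulate_study(spec)$study)

hc <- cluster_arrays(study)        # Ward's method, squared Euclidean
write_dendrogram_newick(hc, "results/02_array_dendrogram.nwk")
cut4 <- cutree(hc, 4)
tab <- table(cluster = cut4, lineage = study$samples$lineage)
print(tab)
pure <- all(apply(tab, 1, function(r) sum(r > 0)) == 1)
cat(sprintf("4-cluster Ward cut recovers the four lineages exactly: %s\n",
            pure))

sv <- sources_of_variation(study)
print(sv)
write.table(sv$summary, "results/02_sources_of_variation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Lineage dominates the F-ratio ranking, then sex, then stage —\n",
    "the expected hierarchy for sorted gonadal populations spanning\n",
    "the sex-determination window.\n", sep = "")
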