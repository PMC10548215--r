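#!/usr/bin/env Rscript

# Multivariate structure of the ground-reference traits: pairwise Pearson
# correlations (mean-imputed), correlation-matrix PCA and UPGMA clustering of
# accession means.

suppressMessages(library(canopyspec))

design <- read.csv("results/design.csv")
traits <- read.csv("results/traits.csv")

corr <- correlation_analysis(traits)
cat(sprintf("corr(N, C:N) = %.3f, corr(log E, log gsw) = %.3f (n = %d)\n",
            corr$r["N", "CN"], corr$r["log_E", "log_gsw"], corr$n))
cat(sprintf("%d of %d trait pairs significant at alpha = 0.01\n",
            (sum(corr$significant) - ncol(corr$r)) / 2,
            choose(ncol(corr$r), 2)))
write.csv(as.data.frame(corr$r), "results/trait_correlations.csv")

am <- accession_mean_traits(traits, design)
pc <- trait_pca(am)
top <- names(sort(abs(pc$rotation[, 1]), decreasing = TRUE))[1:2]
cat(sprintf("Trait PCA: PC1 %.0f%%, PC2 %.0f%% of variance; top PC1 loadings: %s\n",
            100 * pc$variance_fraction[1], 100 * pc$variance_fraction[2],
            paste(top, collapse = ", ")))
write.csv(data.frame(component = seq_along(pc$variance_fraction),
                     variance_fraction = pc$variance_fraction),
          "results/trait_pca_variance.csv", row.names = FALSE)

cl <- cluster_accessions(am, k = 2)
agree <- max(mean((cl$clusters == 1) == (am$treatment == "N1")),
             mean((cl$clusters == 2) == (am$treatment == "N1")))
cat(sprintf("UPGMA k=2 cut agrees with treatment for %.0f%% of accession means\n",
            100 * agree))
dendrogram_newick(cl, "results/trait_dendrogram.nwk")
cat("wrote results/trait_correlations.csv, results/trait_pca_variance.csv, results/trait_dendrogram.nwk\n")
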