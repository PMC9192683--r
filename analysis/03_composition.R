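#!/usr/bin/env Rscript
# Stage 3: community composition across the simulated habitats: square-root
# Bray-Curtis dissimilarities, one-way PERMANOVA (999 permutations) with
# pairwise tests, multivariate-dispersion check, nMDS ordination and the
# Venn partition of phenotype pools.

library(incidiv)

seed <- 20190527
data_dir <- "results/data"
out_dir <- "results/composition"

files <- list.files(data_dir, pattern = "_long\\.csv$", full.names = TRUE)
counts <- lapply(files, read_count_table, dialect = "long")
names(counts) <- sub("_long\\.csv$", "", basename(files))

res <- run_composition(counts, out_dir, n_perm = 999, seed = seed)

cat(sprintf("\nPERMANOVA: pseudo-F = %.2f (df %d, %d), p = %.3f (%d permutations)\n",
            res$permanova$pseudo_F, res$permanova$df_between,
            res$permanova$df_within, res$permanova$p_perm,
            res$permanova$n_perm))
if (!is.null(res$permanova$pairwise)) {
  cat("Pairwise tests:\n"); print(res$permanova$pairwise, digits = 3)
}
cat(sprintf("Dispersion check: F = %.2f, p = %.3f\n", res$dispersion$F,
            res$dispersion$p_perm))
cat(sprintf("nMDS stress: %.3f\n", res$nmds$stress))
cat("\nVenn partition of phenotype pools:\n")
cat("  totals:", paste(names(res$venn$totals), res$venn$totals,
                       collapse = ", "), "\n")
cat("  shared by all:", res$venn$shared_all,
    " unique:", paste(names(res$venn$unique), res$venn$unique,
                      collapse = ", "), "\n")
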