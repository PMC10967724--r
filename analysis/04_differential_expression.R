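#!/usr/bin/env Rscript

# Step 4: the differential-expression chain.
#
# Quantile normalization -> log2 -> moderated t per age against the day-6
# reference -> Benjamini-Hochberg FDR -> linear fold changes ->
# significance at FC >= 1.5 and p <= 0.05 -> fold-change bins, Venn
# decomposition of the three DEG sets, and ANOVA-filtered Ward clustering
# (uncentered absolute Pearson distance) of the 16 samples.

suppressPackageStartupMessages(library(euglenaGravitax))

in_dir <- "results/expression"
out_dir <- "results/de"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

expr_df <- read_tsv_table(file.path(in_dir, "expression_matrix.tsv"))
mat <- as.matrix(expr_df[, -1])
rownames(mat) <- expr_df$transcript_id
grp_df <- read_tsv_table(file.path(in_dir, "sample_groups.tsv"))
groups <- setNames(grp_df$group, grp_df$sample)
truth <- read_tsv_table(file.path(in_dir, "truth.tsv"))

de <- run_de_contrasts(mat, groups, reference_group = "6d",
                       test_groups = c("5d", "9d", "11d"))

for (g in names(de$results)) {
  r <- de$results[[g]]
  write_tsv_table(r, file.path(out_dir, paste0("de_", g, "_vs_6d.tsv")))
  tru <- truth[truth$group == g, ]
  sens <- mean(r$significant[tru$is_de])
  cat(sprintf("%s vs 6d: %d significant (FC >= 1.5, p <= 0.05); ",
              g, sum(r$significant)))
  cat(sprintf("planted-truth sensitivity %.1f%%\n", 100 * sens))
  b <- de$bins[[g]]
  cat("  bins:", paste(names(b$bins), b$bins, collapse = ", "),
      sprintf("| up/down %d/%d\n", b$up, b$down))
}

write_json_sidecar(list(bins = de$bins, cutoffs = de$cutoffs,
                        prior = de$prior),
                   file.path(out_dir, "bins.json"))
write_json_sidecar(de$venn, file.path(out_dir, "venn.json"))
cat("Venn: union", de$venn$union_size, "| specific:",
    paste(names(de$venn$specific), de$venn$specific, collapse = ", "),
    "| shared by all three:", de$venn$triple, "\n")

# clustering leg: ANOVA filter (p <= 0.05) then Ward on uncentered
# absolute Pearson distance
cs <- cluster_samples(mat, groups)
cat(sprintf("clustering used %d ANOVA-filtered transcripts\n",
            cs$n_transcripts_used))
dendrogram_newick(cs$hclust, file.path(out_dir, "dendrogram.nwk"))
cl <- cutree(cs$hclust, 4)
cat("4-cluster cut by age group:\n")
print(table(groups[names(cl)], cl))
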