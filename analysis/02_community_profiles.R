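#!/usr/bin/env Rscript
# Step 2: amplicon-based community profiles.
#
# Computes relative abundances per domain, Good's coverage and alpha
# diversity per sample, and converts relative abundances into absolute
# marker-copy concentrations anchored on the per-sample qPCR totals.

suppressPackageStartupMessages(library(fermquant))

ind <- "results/analysis/inputs"
out <- "results/analysis/amplicon"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

si <- read_sample_info(file.path(ind, "sample_info.tsv"))

for (dom in c("bacteria", "fungi")) {
  counts <- read_count_matrix(file.path(ind, paste0("amplicon_", dom, ".tsv")))
  rel <- relative_abundance(counts, scope = dom)
  abs_ab <- absolute_marker_abundance(rel, si, dom)
  write_feature_matrix(rel, file.path(out, paste0("relative_", dom, ".tsv")))
  write_feature_matrix(abs_ab, file.path(out, paste0("absolute_", dom, ".tsv")))

  div <- do.call(rbind, lapply(colnames(counts), function(s) {
    d <- diversity_indices(counts, s)
    data.frame(sample_id = s, domain = dom,
               goods_coverage = goods_coverage(counts, s),
               richness = d[["richness"]], shannon = d[["shannon"]],
               chao1 = d[["chao1"]])
  }))
  write.table(div, file.path(out, paste0("diversity_", dom, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: Good's coverage %.2f-%.2f%%, richness %d-%d\n", dom,
              100 * min(div$goods_coverage), 100 * max(div$goods_coverage),
              min(div$richness), max(div$richness)))
  cat(sprintf("%s absolute totals track qPCR: max |colsum/qPCR - 1| = %.2g\n",
              dom, max(abs(colSums(abs_ab) /
                             si[[paste0("qpcr_", dom)]][match(colnames(abs_ab),
                                                              si$sample_id)] - 1))))
}
cat("Wrote community profiles to", out, "\n")
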