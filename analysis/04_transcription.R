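#!/usr/bin/env Rscript
# Step 4: spike-in-normalized transcription.
#
# Computes per-gene RPKM, derives spike-in scale factors against the day-60
# reference sample, applies them, and summarizes expression per taxon: read
# shares, normalized totals, and totals relative to the reference sample's
# grand total (the scale on which the fermentation's transcriptional
# collapse after meju removal is visible).

suppressPackageStartupMessages(library(fermquant))

ind <- "results/analysis/inputs"
out <- "results/analysis/transcription"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

reg <- read_genome_registry(file.path(ind, "genome_registry.tsv"))
ann <- read_gene_annotations(file.path(ind, "gene_annotations.tsv"), reg)
si <- read_sample_info(file.path(ind, "sample_info.tsv"))
counts <- read_count_matrix(file.path(ind, "mrna.tsv"))

ref <- si$sample_id[si$day == 60][1]
expr <- rpkm(counts, ann, si)
factors <- spikein_scale_factors(si, ref)
norm <- normalize_expression(expr, factors, reference_sample = ref)

write_feature_matrix(expr, file.path(out, "rpkm.tsv"))
write_feature_matrix(norm, file.path(out, "rpkm_normalized.tsv"))
yaml::write_yaml(list(reference_sample = ref,
                      scale_factors = as.list(factors)),
                 file.path(out, "normalization.yaml"))

shares <- relative_expression_by_taxon(counts, ann)
totals <- taxon_expression_totals(norm, ann)
ref_scaled <- scale_to_reference_sample(totals, ref)
write_feature_matrix(shares, file.path(out, "taxon_shares.tsv"))
write_feature_matrix(totals, file.path(out, "taxon_totals_normalized.tsv"))
write_feature_matrix(ref_scaled, file.path(out, "taxon_totals_ref_scaled.tsv"))

cat("Reference sample:", ref, "\n")
cat("Spike-in scale factors:\n")
print(round(factors, 4))
cat("Total normalized expression relative to day 60:\n")
print(round(colSums(ref_scaled), 4))
cat("Wrote expression tables to", out, "\n")
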