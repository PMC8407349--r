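#' RPKM expression from gene-level mRNA counts
#'
#' Reads per kilobase of coding sequence per million mapped reads:
#' `count / (length_bp / 1000) / (total_mapped / 1e6)`, with the
#' per-sample denominator taken from `sample_info$total_mrna_mapped_reads`
#' — the mRNA reads mapped to the reference genomes, excluding spike-in
#' reads.
#'
#' @param counts Gene-by-sample mRNA count matrix.
#' @param annotations Gene annotation data.frame with `gene_id`,
#'   `genome_id`, `length_bp` (and optionally KO/KEGG columns).
#' @param sample_info data.frame with `sample_id` and
#'   `total_mrna_mapped_reads`.
#' @return An un-normalized [expr_matrix()].
#' @export
rpkm <- function(counts, annotations, sample_info) {
  validate_counts(counts)
  check_annotations(annotations, rownames(counts))
  if (!all(c("sample_id", "total_mrna_mapped_reads") %in% names(sample_info))) {
    stop("sample_info needs sample_id and total_mrna_mapped_reads")
  }
  idx <- match(colnames(counts), sample_info$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) missing from sample_info: ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  }
  totals <- sample_info$total_mrna_mapped_reads[idx]
  cs <- colSums(counts)
  if (any(totals < cs)) {
    stop("total_mrna_mapped_reads smaller than column sum for sample(s): ",
         paste(colnames(counts)[totals < cs], collapse = ", "))
  }
  if (any(totals == 0 & cs > 0)) {
    stop("zero total mapped reads with nonzero counts in sample(s): ",
         paste(colnames(counts)[totals == 0 & cs > 0], collapse = ", "))
  }
  len_kb <- annotations$length_bp[match(rownames(counts), annotations$gene_id)] / 1000
  denom <- ifelse(totals > 0, totals / 1e6, 1)  # all-zero samples stay zero
  vals <- sweep(counts / len_kb, 2, denom, "/")
  expr_matrix(vals, normalized = FALSE)
}

check_annotations <- function(annotations, gene_ids) {
  needed <- c("gene_id", "genome_id", "length_bp")
  if (!all(needed %in% names(annotations))) {
    stop("annotations need columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(annotations$gene_id)) stop("duplicate gene_id in annotations")
  if (any(annotations$length_bp <= 0)) stop("length_bp must be > 0")
  missing <- setdiff(gene_ids, annotations$gene_id)
  if (length(missing)) {
    stop("gene(s) missing from annotations: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  }
  invisible(annotations)
}

#' Spike-in scale factors for cross-sample expression comparison
#'
#' A constant mass of spike-in RNA was added to every sample, so a sample
#' whose sequenced spike fraction is low must have had a large total mRNA
#' pool. Factors bring every sample onto the reference sample's scale:
#' with `variant = "fraction"` (default),
#' `factor(s) = (spike(ref)/total(ref)) / (spike(s)/total(s))`;
#' with `variant = "raw_count"`, `factor(s) = spike(ref) / spike(s)`.
#' The reference sample's factor is 1 by construction.
#'
#' @param sample_info data.frame with `sample_id`, `spike_in_reads` and
#'   `total_mrna_mapped_reads`.
#' @param reference_sample Sample id the factors are relative to.
#' @param variant `"fraction"` (spike read fraction; robust to library-size
#'   differences) or `"raw_count"` (raw spike read numbers).
#' @return Named positive numeric vector of per-sample factors.
#' @export
spikein_scale_factors <- function(sample_info, reference_sample,
                                  variant = c("fraction", "raw_count")) {
  variant <- match.arg(variant)
  needed <- c("sample_id", "spike_in_reads", "total_mrna_mapped_reads")
  if (!all(needed %in% names(sample_info))) {
    stop("sample_info needs columns: ", paste(needed, collapse = ", "))
  }
  if (!reference_sample %in% sample_info$sample_id) {
    stop("reference sample not found: ", reference_sample)
  }
  zero <- sample_info$sample_id[sample_info$spike_in_reads <= 0]
  if (length(zero)) {
    stop("zero spike-in reads in sample(s): ", paste(zero, collapse = ", "),
         "; spike normalization undefined")
  }
  sp <- stats::setNames(as.numeric(sample_info$spike_in_reads),
                        sample_info$sample_id)
  if (variant == "fraction") {
    tot <- stats::setNames(as.numeric(sample_info$total_mrna_mapped_reads),
                           sample_info$sample_id)
    frac <- sp / tot
    factors <- frac[reference_sample] / frac
  } else {
    factors <- sp[reference_sample] / sp
  }
  names(factors) <- sample_info$sample_id
  factors
}

#' Apply spike-in scale factors to an expression matrix
#'
#' Multiplies each sample column by its factor and records the factors and
#' reference on the result. Re-normalizing an already-normalized matrix is
#' an error.
#'
#' @param expr An un-normalized [expr_matrix()].
#' @param factors Named per-sample factors from [spikein_scale_factors()].
#' @param reference_sample Recorded on the output.
#' @return A normalized [expr_matrix()].
#' @export
normalize_expression <- function(expr, factors, reference_sample = NULL) {
  if (!inherits(expr, "expr_matrix")) stop("expr must be an expr_matrix")
  if (is_normalized(expr)) {
    stop("expression matrix is already spike-normalized")
  }
  missing <- setdiff(colnames(expr), names(factors))
  if (length(missing)) {
    stop("no scale factor for sample(s): ", paste(missing, collapse = ", "))
  }
  f <- factors[colnames(expr)]
  if (any(f <= 0)) stop("scale factors must be positive")
  vals <- sweep(unclass_profile(expr), 2, f, "*")
  expr_matrix(vals, normalized = TRUE, scale_factors = f,
              reference_sample = reference_sample)
}

#' Per-taxon shares of mapped mRNA reads
#'
#' Sums gene counts by genome and divides by the sample total:
#' `share(G, s) = sum_{g in G} count(g, s) / colsum(s)`. Shares sum to one
#' per sample; all-zero samples are carried through flagged.
#'
#' @param counts Gene-by-sample mRNA count matrix.
#' @param annotations Gene annotation data.frame mapping `gene_id` to
#'   `genome_id`.
#' @return An [abund_profile()]-style relative matrix (genome x sample).
#' @export
relative_expression_by_taxon <- function(counts, annotations) {
  validate_counts(counts)
  check_annotations(annotations, rownames(counts))
  genome <- annotations$genome_id[match(rownames(counts), annotations$gene_id)]
  by_genome <- rowsum(counts, group = genome, reorder = TRUE)
  cs <- colSums(by_genome)
  nz <- cs > 0
  vals <- by_genome
  vals[, nz] <- sweep(by_genome[, nz, drop = FALSE], 2, cs[nz], "/")
  vals[, !nz] <- 0
  abund_profile(as.matrix(vals), kind = "relative", scope = "all",
                empty_samples = colnames(counts)[!nz])
}

#' Per-taxon totals of (normalized) expression
#'
#' Sums an expression matrix by genome, giving one expression total per
#' taxon and sample — the headline quantity tracked over the fermentation.
#'
#' @param expr An [expr_matrix()].
#' @param annotations Gene annotation data.frame mapping `gene_id` to
#'   `genome_id`.
#' @return Genome-by-sample numeric matrix.
#' @export
taxon_expression_totals <- function(expr, annotations) {
  if (!inherits(expr, "expr_matrix")) stop("expr must be an expr_matrix")
  check_annotations(annotations, rownames(expr))
  genome <- annotations$genome_id[match(rownames(expr), annotations$gene_id)]
  as.matrix(rowsum(unclass_profile(expr), group = genome, reorder = TRUE))
}

#' Scale per-taxon expression totals to a reference sample's grand total
#'
#' Expresses every taxon-sample total relative to the summed expression of
#' the reference sample (the day-60 sample in the ganjang study):
#' `output(G, s) = total(G, s) / sum_G total(G, ref)`. The reference
#' sample's column sums to 1 by construction.
#'
#' @param totals Genome-by-sample matrix of normalized expression totals.
#' @param reference_sample Sample id whose grand total defines the unit.
#' @return Matrix of the same shape, on the reference-relative scale.
#' @export
scale_to_reference_sample <- function(totals, reference_sample) {
  stopifnot(is.matrix(totals))
  if (!reference_sample %in% colnames(totals)) {
    stop("reference sample not found: ", reference_sample)
  }
  grand <- sum(totals[, reference_sample])
  if (grand <= 0) {
    stop("reference sample ", reference_sample, " has zero total expression")
  }
  totals / grand
}
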