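#' Relative abundance from a count table
#'
#' Divides each sample column by its total. All-zero samples are kept as
#' all-zero columns and flagged in the `empty_samples` attribute of the
#' result rather than dropped.
#'
#' @param counts Nonnegative integer feature-by-sample matrix.
#' @param scope Domain label carried on the result (`"all"`, `"bacteria"`,
#'   `"fungi"`); purely descriptive here.
#' @return An [abund_profile()] of kind `"relative"`.
#' @export
relative_abundance <- function(counts, scope = "all") {
  validate_counts(counts)
  cs <- colSums(counts)
  vals <- counts
  nz <- cs > 0
  vals[, nz] <- sweep(counts[, nz, drop = FALSE], 2, cs[nz], "/")
  vals[, !nz] <- 0
  abund_profile(vals, kind = "relative", scope = scope,
                empty_samples = colnames(counts)[!nz])
}

#' Good's coverage of a sample
#'
#' `1 - n1 / N`, where `n1` is the number of features seen exactly once and
#' `N` the sample's read total: the estimated probability that one more read
#' would belong to an already-observed feature.
#'
#' @param counts Count matrix.
#' @param sample Sample identifier (column name).
#' @return Coverage fraction in `[0, 1]`.
#' @export
goods_coverage <- function(counts, sample) {
  validate_counts(counts)
  x <- counts_column(counts, sample)
  n <- sum(x)
  if (n < 1) stop("sample ", sample, " has no reads; coverage undefined")
  1 - sum(x == 1) / n
}

counts_column <- function(counts, sample) {
  if (!sample %in% colnames(counts)) stop("unknown sample: ", sample)
  counts[, sample]
}

#' Alpha-diversity indices of a sample
#'
#' Observed richness (features with nonzero count), the Shannon index
#' `-sum p_i ln p_i` (natural log, over nonzero proportions), and the
#' bias-corrected Chao1 richness estimate
#' `S_obs + n1 (n1 - 1) / (2 (n2 + 1))`, `n1`/`n2` being singleton and
#' doubleton counts.
#'
#' @inheritParams goods_coverage
#' @return Named numeric: `richness`, `shannon`, `chao1`.
#' @export
diversity_indices <- function(counts, sample) {
  validate_counts(counts)
  x <- counts_column(counts, sample)
  n <- sum(x)
  if (n < 1) stop("sample ", sample, " has no reads; diversity undefined")
  p <- x[x > 0] / n
  n1 <- sum(x == 1)
  n2 <- sum(x == 2)
  c(
    richness = sum(x > 0),
    shannon = -sum(p * log(p)),
    chao1 = sum(x > 0) + n1 * (n1 - 1) / (2 * (n2 + 1))
  )
}

#' Absolute marker-gene abundance from relative abundance and qPCR
#'
#' Scales each sample's within-domain relative abundances by the sample's
#' domain-specific qPCR total, yielding absolute marker-copy concentrations
#' (copies/ml). Columns of the result sum to the sample's qPCR value.
#'
#' @param rel A relative [abund_profile()] for one domain.
#' @param sample_info data.frame with `sample_id` and `qpcr_bacteria` /
#'   `qpcr_fungi` columns (copies/ml).
#' @param domain `"bacteria"` or `"fungi"` — selects the qPCR anchor.
#' @return An [abund_profile()] of kind `"marker_copies_per_ml"`.
#' @export
absolute_marker_abundance <- function(rel, sample_info, domain) {
  domain <- match.arg(domain, c("bacteria", "fungi"))
  if (!inherits(rel, "abund_profile") || profile_kind(rel) != "relative") {
    stop("rel must be a relative abund_profile")
  }
  q <- qpcr_lookup(sample_info, colnames(rel), domain)
  vals <- sweep(unclass_profile(rel), 2, q, "*")
  abund_profile(vals, kind = "marker_copies_per_ml", scope = domain,
                empty_samples = attr(rel, "empty_samples"))
}

qpcr_lookup <- function(sample_info, sample_ids, domain) {
  col <- paste0("qpcr_", domain)
  if (!all(c("sample_id", col) %in% names(sample_info))) {
    stop("sample_info needs columns sample_id and ", col)
  }
  idx <- match(sample_ids, sample_info$sample_id)
  bad <- sample_ids[is.na(idx) | is.na(sample_info[[col]][idx])]
  if (length(bad)) {
    stop("missing ", col, " value for sample(s): ", paste(bad, collapse = ", "))
  }
  stats::setNames(sample_info[[col]][idx], sample_ids)
}
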