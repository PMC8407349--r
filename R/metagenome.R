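#' Genome-size-normalized relative abundance from shotgun counts
#'
#' Shotgun reads accrue in proportion to genome size times cell density, so
#' raw mapped-read shares over-represent large genomes. Dividing each
#' genome's count by its size before renormalizing recovers cell-proportion
#' shares: `value(g, s) = (count/size_g) / sum_{g' in scope}(count/size)`.
#'
#' @param counts Genome-by-sample count matrix of mapped shotgun reads.
#' @param genomes Genome registry data.frame (see [ganjang_genomes()]).
#' @param scope `"all"`, `"bacteria"` or `"fungi"`: the genome set over
#'   which shares are computed.
#' @return An [abund_profile()] of kind `"relative"` restricted to `scope`.
#' @export
size_normalized_relative_abundance <- function(counts, genomes,
                                               scope = c("all", "bacteria", "fungi")) {
  scope <- match.arg(scope)
  validate_counts(counts)
  unknown <- setdiff(rownames(counts), genomes$genome_id)
  if (length(unknown)) {
    stop("genome(s) absent from registry: ", paste(unknown, collapse = ", "))
  }
  keep <- rownames(counts)
  if (scope != "all") {
    dom <- genomes$domain[match(keep, genomes$genome_id)]
    keep <- keep[dom == scope]
    if (!length(keep)) stop("no genomes of domain ", scope, " in counts")
  }
  sizes <- genomes$genome_size_bp[match(keep, genomes$genome_id)]
  dens <- counts[keep, , drop = FALSE] / sizes
  cs <- colSums(dens)
  nz <- cs > 0
  vals <- dens
  vals[, nz] <- sweep(dens[, nz, drop = FALSE], 2, cs[nz], "/")
  vals[, !nz] <- 0
  abund_profile(vals, kind = "relative", scope = scope,
                empty_samples = colnames(counts)[!nz])
}

#' Absolute genome density from relative abundance, qPCR and copy numbers
#'
#' Converts within-domain relative abundances into genomes/ml by anchoring
#' on the domain's qPCR marker-copy total and correcting for per-genome
#' marker copy numbers. The correct division depends on what the relative
#' profile measures:
#'
#' * `rel_measures = "cells"` (genome-size-normalized shotgun profiles,
#'   which estimate cell proportions): the qPCR copy pool is attributed by
#'   each genome's implied copy share, giving
#'   `value(g, s) = rel(g, s) * qpcr(s) / sum_j rel(j, s) * marker_copies_j`
#'   — division by the profile-weighted mean copy number. This is the exact
#'   inverse of the observation model; it reduces to dividing by
#'   `marker_copies_g` whenever all genomes in the domain share one copy
#'   number.
#' * `rel_measures = "marker_copies"` (amplicon profiles, which are already
#'   marker-copy shares): `value(g, s) = rel(g, s) * qpcr(s) /
#'   marker_copies_g`, the per-genome division.
#'
#' `rel` must be scoped to `domain`; a profile of a different scope is
#' rejected rather than silently renormalized.
#'
#' @param rel A relative [abund_profile()] with scope equal to `domain`.
#' @param sample_info data.frame with `sample_id` and the per-domain qPCR
#'   columns (copies/ml).
#' @param genomes Genome registry data.frame with `marker_copies`.
#' @param domain `"bacteria"` or `"fungi"`.
#' @param rel_measures What the relative profile's shares measure:
#'   `"cells"` (default; size-normalized shotgun) or `"marker_copies"`
#'   (amplicon).
#' @return An [abund_profile()] of kind `"genomes_per_ml"`.
#' @export
absolute_genome_abundance <- function(rel, sample_info, genomes, domain,
                                      rel_measures = c("cells", "marker_copies")) {
  domain <- match.arg(domain, c("bacteria", "fungi"))
  rel_measures <- match.arg(rel_measures)
  if (!inherits(rel, "abund_profile") || profile_kind(rel) != "relative") {
    stop("rel must be a relative abund_profile")
  }
  if (profile_scope(rel) != domain) {
    stop("rel has scope '", profile_scope(rel), "' but domain is '", domain,
         "'; compute the relative profile within the domain first")
  }
  idx <- match(rownames(rel), genomes$genome_id)
  if (anyNA(idx)) {
    stop("genome(s) absent from registry: ",
         paste(rownames(rel)[is.na(idx)], collapse = ", "))
  }
  mc <- genomes$marker_copies[idx]
  if (anyNA(mc)) {
    stop("marker_copies missing for: ",
         paste(rownames(rel)[is.na(mc)], collapse = ", "))
  }
  q <- qpcr_lookup(sample_info, colnames(rel), domain)
  r <- unclass_profile(rel)
  if (rel_measures == "cells") {
    mbar <- colSums(r * mc)  # profile-weighted mean copies per sample
    denom <- ifelse(mbar > 0, mbar, 1)  # empty samples stay all-zero
    vals <- sweep(sweep(r, 2, q, "*"), 2, denom, "/")
  } else {
    vals <- sweep(r, 2, q, "*") / mc
  }
  abund_profile(vals, kind = "genomes_per_ml", scope = domain,
                empty_samples = attr(rel, "empty_samples"))
}

#' Restrict and renormalize a relative profile to one domain
#'
#' Helper that subsets an all-domain relative profile to the genomes of one
#' domain and renormalizes the columns, the form [absolute_genome_abundance()]
#' expects. Algebraically, correcting all genomes and then renormalizing the
#' domain gives the same result as renormalizing first and then correcting.
#'
#' @inheritParams absolute_genome_abundance
#' @return A relative [abund_profile()] scoped to `domain`.
#' @export
restrict_to_domain <- function(rel, genomes, domain) {
  domain <- match.arg(domain, c("bacteria", "fungi"))
  if (!inherits(rel, "abund_profile") || profile_kind(rel) != "relative") {
    stop("rel must be a relative abund_profile")
  }
  dom <- genomes$domain[match(rownames(rel), genomes$genome_id)]
  if (anyNA(dom)) {
    stop("genome(s) absent from registry: ",
         paste(rownames(rel)[is.na(dom)], collapse = ", "))
  }
  sub <- unclass_profile(rel)[dom == domain, , drop = FALSE]
  if (!nrow(sub)) stop("no genomes of domain ", domain, " in profile")
  cs <- colSums(sub)
  nz <- cs > 0
  sub[, nz] <- sweep(sub[, nz, drop = FALSE], 2, cs[nz], "/")
  sub[, !nz] <- 0
  abund_profile(sub, kind = "relative", scope = domain,
                empty_samples = colnames(sub)[!nz])
}
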