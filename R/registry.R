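#' Genome registry of the ganjang reference community
#'
#' The 17 reference genomes (10 high-quality MAGs and 7 isolate genomes)
#' that represent the major ganjang (Korean soy sauce) microbiota: genome
#' size, domain, and the number of 16S rRNA (bacteria) or ITS (fungi) marker
#' gene copies per genome. These three columns are the backbone of every
#' quantification step: genome size removes the shotgun sampling bias,
#' marker copy number removes the amplicon/qPCR bias.
#' `marker_copies_estimated` flags copy numbers inferred from the closest
#' complete relative rather than read off the genome itself.
#'
#' @param path Optional path to a registry TSV with columns `genome_id`,
#'   `taxon_label`, `domain`, `source`, `genome_size_bp`, `marker_copies`,
#'   `marker_copies_estimated`. Defaults to the bundled ganjang registry.
#' @return A data.frame, one row per genome.
#' @export
ganjang_genomes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ganjang_genomes.tsv", package = "fermquant")
  }
  read_genome_registry(path)
}

#' @rdname ganjang_genomes
#' @export
read_genome_registry <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("genome_id", "domain", "genome_size_bp", "marker_copies")
  missing <- setdiff(needed, names(g))
  if (length(missing)) {
    stop("genome registry ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(g$genome_id)) stop("duplicate genome_id in registry")
  if (!all(g$domain %in% c("bacteria", "fungi"))) {
    stop("registry domain must be 'bacteria' or 'fungi'")
  }
  if (any(g$genome_size_bp <= 0)) stop("genome_size_bp must be > 0")
  if (any(g$marker_copies < 1)) stop("marker_copies must be >= 1")
  g
}

#' Filter metagenome-assembled genomes on assembly quality
#'
#' Keeps bins whose CheckM-style completeness and contamination meet the
#' quality thresholds used to admit MAGs into the reference set
#' (completeness >= 90%, contamination <= 5% by default; both boundaries
#' inclusive). Input order is preserved.
#'
#' @param records data.frame with columns `genome_id`, `completeness`
#'   (percent, 0-100) and `contamination` (percent, >= 0).
#' @param min_completeness,max_contamination Inclusive thresholds in percent.
#' @return The subset of `records` meeting both thresholds, original order.
#' @export
filter_high_quality_mags <- function(records, min_completeness = 90,
                                     max_contamination = 5) {
  stopifnot(is.data.frame(records),
            all(c("genome_id", "completeness", "contamination") %in% names(records)))
  if (any(records$completeness < 0 | records$completeness > 100)) {
    stop("completeness must lie in [0, 100]")
  }
  if (any(records$contamination < 0)) stop("contamination must be >= 0")
  assert_scalar_number(min_completeness, "min_completeness", min = 0)
  if (min_completeness > 100) stop("min_completeness must be <= 100")
  assert_scalar_number(max_contamination, "max_contamination", min = 0)
  keep <- records$completeness >= min_completeness &
    records$contamination <= max_contamination
  records[keep, , drop = FALSE]
}

#' @rdname filter_high_quality_mags
#' @param path Path to a MAG-quality TSV (`genome_id`, `completeness`,
#'   `contamination`).
#' @export
read_mag_quality <- function(path) {
  q <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("genome_id", "completeness", "contamination")
  if (!all(needed %in% names(q))) {
    stop("MAG quality table ", path, " needs columns: ",
         paste(needed, collapse = ", "))
  }
  q
}

#' Fraction of reads mapped to the reference genome set
#'
#' @param mapped_reads,total_reads Read counts; `0 <= mapped <= total`,
#'   `total >= 1`.
#' @return `mapped_reads / total_reads`.
#' @export
mapping_rate <- function(mapped_reads, total_reads) {
  assert_scalar_number(mapped_reads, "mapped_reads", min = 0)
  assert_scalar_number(total_reads, "total_reads", min = 1)
  if (mapped_reads > total_reads) {
    stop("mapped_reads (", mapped_reads, ") exceeds total_reads (",
         total_reads, ")")
  }
  mapped_reads / total_reads
}
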