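#' Specify one taxon of a simulated fermentation community
#'
#' Each taxon carries the genome facts the quantification chain corrects for
#' (genome size, marker copy number) and the population-dynamic parameters
#' that generate its trajectory: logistic growth from `initial_density`
#' toward `carrying_capacity` while the meju (fermented soybean brick)
#' substrate is in the brine, then first-order exponential decay after the
#' bricks are removed. `activity` gives a per-phase transcription multiplier
#' so expression changes can be decomposed into abundance versus activity.
#'
#' @param genome_id Genome identifier.
#' @param domain `"bacteria"` or `"fungi"`.
#' @param genome_size_bp Genome size in bp (> 0).
#' @param marker_copies 16S rRNA (bacteria) or ITS (fungi) copies per genome
#'   (>= 1).
#' @param initial_density Genomes/ml at day 0 (> 0).
#' @param growth_rate Logistic growth rate, 1/day (>= 0).
#' @param carrying_capacity Genomes/ml (> 0).
#' @param decay_rate Post-removal decay rate, 1/day (>= 0).
#' @param gene_count Number of protein-coding genes to simulate (>= 1).
#' @param activity Named numeric: transcription multiplier per phase
#'   (`meju_in`, `meju_out`), each >= 0.
#' @return A list of class `"sim_taxon"`.
#' @export
sim_taxon <- function(genome_id, domain, genome_size_bp, marker_copies,
                      initial_density, growth_rate = 0.15,
                      carrying_capacity = initial_density,
                      decay_rate = 0.05, gene_count = 50L,
                      activity = c(meju_in = 1, meju_out = 0.2)) {
  domain <- match.arg(domain, c("bacteria", "fungi"))
  assert_scalar_number(genome_size_bp, "genome_size_bp", min = 0, strict = TRUE)
  assert_scalar_number(marker_copies, "marker_copies", min = 1)
  assert_scalar_number(initial_density, "initial_density", min = 0, strict = TRUE)
  assert_scalar_number(growth_rate, "growth_rate", min = 0)
  assert_scalar_number(carrying_capacity, "carrying_capacity", min = 0, strict = TRUE)
  assert_scalar_number(decay_rate, "decay_rate", min = 0)
  assert_scalar_number(gene_count, "gene_count", min = 1)
  if (!all(c("meju_in", "meju_out") %in% names(activity))) {
    stop("activity must name phases 'meju_in' and 'meju_out'")
  }
  if (any(activity < 0)) stop("activity multipliers must be >= 0")
  structure(
    list(
      genome_id = genome_id, domain = domain,
      genome_size_bp = genome_size_bp, marker_copies = marker_copies,
      initial_density = initial_density, growth_rate = growth_rate,
      carrying_capacity = carrying_capacity, decay_rate = decay_rate,
      gene_count = as.integer(gene_count), activity = activity
    ),
    class = "sim_taxon"
  )
}

#' Parameters for a synthetic fermentation time course
#'
#' Bundles the taxa, sampling days, observation depths and noise settings
#' that define one simulated study. Days must be strictly increasing;
#' `meju_removal_day` splits them into the `meju_in` and `meju_out` phases.
#'
#' Per-gene expression weights are drawn once per gene from a lognormal
#' (heavy-tailed) distribution with parameters `expr_weight_meanlog` /
#' `expr_weight_sdlog` and frozen across samples; gene lengths are lognormal
#' around a typical microbial coding-sequence length. The spike-in is
#' modeled at the read-fraction level: a sample's spike read fraction is
#' `spike_mass / (spike_mass + spike_mass_fraction_scale * T_s)` where `T_s`
#' is the sample's total transcript mass (transcript weight times gene
#' length in kb, summed over genes).
#'
#' @param taxa List of [sim_taxon()] specs.
#' @param sample_days Strictly increasing integer days (>= 0).
#' @param meju_removal_day Day the meju bricks leave the brine (default 60).
#' @param depths Named list of reads/sample: `amplicon`, `metagenome`,
#'   `mrna`.
#' @param spike_mass Constant spike-in RNA mass added per sample
#'   (micrograms; > 0).
#' @param spike_mass_fraction_scale Converts total transcript mass into the
#'   same mass units as `spike_mass` (> 0).
#' @param qpcr_cv Coefficient of variation of the lognormal qPCR noise
#'   (>= 0; 0 = noiseless).
#' @param gene_length_meanlog,gene_length_sdlog Lognormal parameters of
#'   simulated gene lengths in bp.
#' @param expr_weight_meanlog,expr_weight_sdlog Lognormal parameters of the
#'   frozen per-gene expression weights.
#' @param unannotated_frac Fraction of genes left without a KO assignment.
#' @param seed Integer seed; all layers derive child seeds from it.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(taxa, sample_days, meju_removal_day = 60,
                       depths = list(amplicon = 5e4, metagenome = 2e5, mrna = 2e5),
                       spike_mass = 2,
                       spike_mass_fraction_scale = 5e-6,
                       qpcr_cv = 0.1,
                       gene_length_meanlog = log(900),
                       gene_length_sdlog = 0.35,
                       expr_weight_meanlog = 0,
                       expr_weight_sdlog = 1.2,
                       unannotated_frac = 0.2,
                       seed = 1L) {
  if (!length(taxa)) stop("at least one taxon required")
  if (!all(vapply(taxa, inherits, logical(1), "sim_taxon"))) {
    stop("taxa must be a list of sim_taxon() specs")
  }
  ids <- vapply(taxa, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) stop("duplicate genome_id among taxa")
  if (!length(sample_days) || any(sample_days < 0)) {
    stop("sample_days must be nonnegative")
  }
  if (any(diff(sample_days) <= 0)) {
    stop("sample_days must be strictly increasing")
  }
  for (nm in c("amplicon", "metagenome", "mrna")) {
    if (is.null(depths[[nm]])) stop("depths must name '", nm, "'")
    assert_scalar_number(depths[[nm]], paste0("depths$", nm), min = 0)
  }
  assert_scalar_number(spike_mass, "spike_mass", min = 0, strict = TRUE)
  assert_scalar_number(spike_mass_fraction_scale, "spike_mass_fraction_scale",
                       min = 0, strict = TRUE)
  assert_scalar_number(qpcr_cv, "qpcr_cv", min = 0)
  assert_scalar_number(unannotated_frac, "unannotated_frac", min = 0)
  if (unannotated_frac >= 1) stop("unannotated_frac must be < 1")
  structure(
    list(
      taxa = taxa, sample_days = as.integer(sample_days),
      meju_removal_day = meju_removal_day, depths = depths,
      spike_mass = spike_mass,
      spike_mass_fraction_scale = spike_mass_fraction_scale,
      qpcr_cv = qpcr_cv,
      gene_length_meanlog = gene_length_meanlog,
      gene_length_sdlog = gene_length_sdlog,
      expr_weight_meanlog = expr_weight_meanlog,
      expr_weight_sdlog = expr_weight_sdlog,
      unannotated_frac = unannotated_frac,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

# Fixed community-composition weights for the default ganjang scenario:
# marker-copy-share of each genome in the domain total at day 0 (w0) and at
# the day-60 peak (wk). Chosen once to echo the observed succession
# (Tetragenococcus / Chromohalobacter / Idiomarinaceae / Halomonas dominant
# at peak; Bacillus prominent only early; Debaryomyces the dominant fungus).
.ganjang_weights <- list(
  w0 = c(KG1 = 0.15, KG2 = 0.10, KG3 = 0.10, KG4 = 0.03, KG5 = 0.07,
         KG6 = 0.08, KG7 = 0.05, KG8 = 0.04, KG9 = 0.08, KG10 = 0.03,
         KG11 = 0.12, KG12 = 0.05, KG13 = 0.06, KG14 = 0.04,
         KG15 = 0.5, KG16 = 0.3, C11 = 0.2),
  wk = c(KG1 = 0.02, KG2 = 0.02, KG3 = 0.02, KG4 = 0.01, KG5 = 0.01,
         KG6 = 0.12, KG7 = 0.005, KG8 = 0.04, KG9 = 0.12, KG10 = 0.005,
         KG11 = 0.30, KG12 = 0.12, KG13 = 0.18, KG14 = 0.03,
         KG15 = 0.1, KG16 = 0.2, C11 = 0.7)
)

#' Default simulation parameters for the ganjang reference community
#'
#' Builds a [sim_params()] object for the 17-genome ganjang registry over
#' the standard ganjang sampling days (0, 20, 40, 60, 90, 180; meju bricks removed at
#' day 60). Initial densities and carrying capacities are scaled so that
#' the domain-total marker-copy concentrations match the qPCR anchors of the
#' study: about 1e6 (bacteria) and 1e4 (fungi) copies/ml at day 0, rising to
#' about 4.8e7 and 4.6e5 copies/ml at day 60, then falling after brick
#' removal.
#'
#' @param seed Integer seed.
#' @param qpcr_cv qPCR noise CV (default 0.1; set 0 for noiseless anchors).
#' @param gene_count Genes per genome (default 50).
#' @param depths Reads/sample per layer, as in [sim_params()].
#' @param registry Genome registry data.frame (defaults to the bundled one).
#' @param ... Further arguments passed to [sim_params()].
#' @return A `"sim_params"` object.
#' @export
ganjang_sim_params <- function(seed = 1L, qpcr_cv = 0.1, gene_count = 50L,
                               depths = list(amplicon = 5e4, metagenome = 2e5,
                                             mrna = 2e5),
                               registry = ganjang_genomes(), ...) {
  anchors <- list(
    bacteria = c(day0 = 1e6, peak = 4.8e7),
    fungi = c(day0 = 1e4, peak = 4.6e5)
  )
  w0 <- .ganjang_weights$w0
  wk <- .ganjang_weights$wk
  taxa <- lapply(seq_len(nrow(registry)), function(i) {
    g <- registry[i, ]
    a <- anchors[[g$domain]]
    sim_taxon(
      genome_id = g$genome_id, domain = g$domain,
      genome_size_bp = g$genome_size_bp, marker_copies = g$marker_copies,
      initial_density = a[["day0"]] * w0[[g$genome_id]] / g$marker_copies,
      growth_rate = 0.15,
      carrying_capacity = a[["peak"]] * wk[[g$genome_id]] / g$marker_copies,
      decay_rate = 0.05,
      gene_count = gene_count
    )
  })
  sim_params(taxa, sample_days = c(0L, 20L, 40L, 60L, 90L, 180L),
             meju_removal_day = 60, depths = depths, qpcr_cv = qpcr_cv,
             seed = seed, ...)
}
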