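#' Configure a quantification pipeline run
#'
#' Exactly one of `inputs` (paths to existing tables) or `sim` (a
#' [sim_params()] object; the run then generates its own inputs) must be
#' supplied.
#'
#' @param outdir Output directory (created if absent).
#' @param sim Optional [sim_params()] object: simulate the inputs.
#' @param inputs Optional named list of paths: `amplicon_bacteria`,
#'   `amplicon_fungi`, `metagenome`, `mrna`, `sample_info`,
#'   `genome_registry`, `gene_annotations`, and optionally `mag_quality`
#'   and `ko_overrides`.
#' @param meju_removal_day Day the meju bricks leave the brine (default 60);
#'   defines the phase split.
#' @param reference_sample Sample id anchoring the spike-in factors and the
#'   reference-relative expression scale; defaults to the sample taken on
#'   `meju_removal_day` (else the last sample).
#' @param spike_norm `"fraction"` or `"raw_count"` (see
#'   [spikein_scale_factors()]).
#' @param min_completeness,max_contamination MAG-quality thresholds.
#' @param digits Significant digits for numeric table output (default 6);
#'   `NA` writes full precision.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir, sim = NULL, inputs = NULL,
                            meju_removal_day = 60, reference_sample = NULL,
                            spike_norm = c("fraction", "raw_count"),
                            min_completeness = 90, max_contamination = 5,
                            digits = 6) {
  spike_norm <- match.arg(spike_norm)
  if (is.null(sim) == is.null(inputs)) {
    stop("supply exactly one of 'sim' (simulator parameters) or 'inputs' (paths)")
  }
  if (!is.null(sim) && !inherits(sim, "sim_params")) {
    stop("sim must be a sim_params() object")
  }
  if (!is.null(inputs)) {
    needed <- c("amplicon_bacteria", "amplicon_fungi", "metagenome", "mrna",
                "sample_info", "genome_registry", "gene_annotations")
    missing <- setdiff(needed, names(inputs))
    if (length(missing)) {
      stop("inputs must name: ", paste(missing, collapse = ", "))
    }
    absent <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(absent)) {
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
    }
  }
  structure(
    list(outdir = outdir, sim = sim, inputs = inputs,
         meju_removal_day = meju_removal_day,
         reference_sample = reference_sample, spike_norm = spike_norm,
         min_completeness = min_completeness,
         max_contamination = max_contamination, digits = digits),
    class = "pipeline_config"
  )
}

default_reference_sample <- function(sample_info, meju_removal_day) {
  hit <- sample_info$sample_id[sample_info$day == meju_removal_day]
  if (length(hit)) hit[1] else sample_info$sample_id[nrow(sample_info)]
}

#' Run the full quantification pipeline
#'
#' Executes simulate (optional) -> amplicon quantification -> metagenome
#' quantification -> spike-normalized expression -> functional aggregation,
#' writing every result table as TSV plus a YAML manifest (inputs,
#' parameters, per-stage dimensions, and an md5 checksum for every output
#' file). Identical configuration and seed produce byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`truth` in sim
#'   mode, abundance profiles, expression matrices, functional profiles)
#'   and `files` (named vector of written paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dg <- config$digits
  files <- character()
  put <- function(x, name) {
    path <- file.path(outdir, name)
    if (is.matrix(x)) write_feature_matrix(x, path, digits = dg)
    else write_tsv_table(x, path)
    files[[name]] <<- path
    path
  }

  # ---- stage: obtain inputs -------------------------------------------
  if (!is.null(config$sim)) {
    ds <- simulate_dataset(config$sim)
    fixture_paths <- write_simulated_dataset(ds, file.path(outdir, "inputs"),
                                             digits = dg)
    files <- c(files, fixture_paths)
    registry <- ganjang_registry_from_params(config$sim)
    annotations <- ds$truth$genes
    sample_info <- ds$sample_info
    amp_b <- ds$amplicon$bacteria
    amp_f <- ds$amplicon$fungi
    mg_counts <- ds$metagenome
    mrna_counts <- ds$mrna$counts
    mag_quality <- NULL
  } else {
    inp <- config$inputs
    registry <- read_genome_registry(inp$genome_registry)
    annotations <- read_gene_annotations(inp$gene_annotations, registry)
    sample_info <- read_sample_info(inp$sample_info)
    amp_b <- read_count_matrix(inp$amplicon_bacteria)
    amp_f <- read_count_matrix(inp$amplicon_fungi)
    mg_counts <- read_count_matrix(inp$metagenome)
    mrna_counts <- read_count_matrix(inp$mrna)
    mag_quality <- if (!is.null(inp$mag_quality)) read_mag_quality(inp$mag_quality)
    ds <- NULL
  }

  ref <- config$reference_sample
  if (is.null(ref)) {
    ref <- default_reference_sample(sample_info, config$meju_removal_day)
  }
  if (!ref %in% sample_info$sample_id) {
    stop("reference sample not found among samples: ", ref)
  }

  # ---- stage: MAG quality filter --------------------------------------
  if (!is.null(mag_quality)) {
    kept_mags <- filter_high_quality_mags(mag_quality,
                                          config$min_completeness,
                                          config$max_contamination)$genome_id
    src <- if ("source" %in% names(registry)) registry$source else
      rep("isolate", nrow(registry))
    drop <- registry$genome_id[src == "MAG" &
                                 !registry$genome_id %in% kept_mags]
    if (length(drop)) {
      registry <- registry[!registry$genome_id %in% drop, , drop = FALSE]
      mg_counts <- mg_counts[!rownames(mg_counts) %in% drop, , drop = FALSE]
      keep_genes <- !annotations$genome_id %in% drop
      annotations <- annotations[keep_genes, , drop = FALSE]
      mrna_counts <- mrna_counts[rownames(mrna_counts) %in% annotations$gene_id,
                                 , drop = FALSE]
    }
  }

  # ---- stage: amplicon ------------------------------------------------
  rel_amp <- list(bacteria = relative_abundance(amp_b, scope = "bacteria"),
                  fungi = relative_abundance(amp_f, scope = "fungi"))
  abs_amp <- lapply(c(bacteria = "bacteria", fungi = "fungi"), function(dom) {
    absolute_marker_abundance(rel_amp[[dom]], sample_info, dom)
  })
  div <- do.call(rbind, lapply(c("bacteria", "fungi"), function(dom) {
    m <- if (dom == "bacteria") amp_b else amp_f
    do.call(rbind, lapply(colnames(m), function(s) {
      if (sum(m[, s]) < 1) {
        return(data.frame(sample_id = s, domain = dom, reads = 0L,
                          richness = NA_real_, shannon = NA_real_,
                          chao1 = NA_real_, goods_coverage = NA_real_))
      }
      d <- diversity_indices(m, s)
      data.frame(sample_id = s, domain = dom, reads = sum(m[, s]),
                 richness = d[["richness"]], shannon = d[["shannon"]],
                 chao1 = d[["chao1"]], goods_coverage = goods_coverage(m, s))
    }))
  }))

  put(unclass_profile(rel_amp$bacteria), "amplicon_relative_bacteria.tsv")
  put(unclass_profile(rel_amp$fungi), "amplicon_relative_fungi.tsv")
  put(unclass_profile(abs_amp$bacteria), "amplicon_absolute_bacteria.tsv")
  put(unclass_profile(abs_amp$fungi), "amplicon_absolute_fungi.tsv")
  put(div, "diversity.tsv")

  # ---- stage: metagenome ----------------------------------------------
  rel_mg_all <- size_normalized_relative_abundance(mg_counts, registry, "all")
  rel_mg <- lapply(c(bacteria = "bacteria", fungi = "fungi"), function(dom) {
    restrict_to_domain(rel_mg_all, registry, dom)
  })
  abs_mg <- lapply(c(bacteria = "bacteria", fungi = "fungi"), function(dom) {
    absolute_genome_abundance(rel_mg[[dom]], sample_info, registry, dom)
  })
  put(unclass_profile(rel_mg_all), "metagenome_relative_all.tsv")
  put(unclass_profile(rel_mg$bacteria), "metagenome_relative_bacteria.tsv")
  put(unclass_profile(rel_mg$fungi), "metagenome_relative_fungi.tsv")
  put(unclass_profile(abs_mg$bacteria), "metagenome_absolute_bacteria.tsv")
  put(unclass_profile(abs_mg$fungi), "metagenome_absolute_fungi.tsv")

  # ---- stage: metatranscriptome ---------------------------------------
  expr_raw <- rpkm(mrna_counts, annotations, sample_info)
  factors <- spikein_scale_factors(sample_info, ref, config$spike_norm)
  expr_norm <- normalize_expression(expr_raw, factors, reference_sample = ref)
  shares <- relative_expression_by_taxon(mrna_counts, annotations)
  totals <- taxon_expression_totals(expr_norm, annotations)
  ref_scaled <- scale_to_reference_sample(totals, ref)
  put(unclass_profile(expr_raw), "expression_rpkm.tsv")
  put(unclass_profile(expr_norm), "expression_normalized.tsv")
  put(unclass_profile(shares), "taxon_expression_shares.tsv")
  put(totals, "taxon_expression_totals.tsv")
  put(ref_scaled, "taxon_expression_reference_scaled.tsv")
  yaml::write_yaml(
    list(reference_sample = ref, spike_norm = config$spike_norm,
         scale_factors = as.list(factors)),
    file.path(outdir, "expression_normalization.yaml")
  )
  files[["expression_normalization.yaml"]] <-
    file.path(outdir, "expression_normalization.yaml")

  # ---- stage: functional ----------------------------------------------
  fp2 <- kegg_category_expression(expr_norm, annotations, "level2")
  fp3 <- kegg_category_expression(expr_norm, annotations, "level3")
  put(fp2$values, "kegg_level2.tsv")
  put(fp3$values, "kegg_level3.tsv")
  put(data.frame(sample_id = names(fp2$unannotated),
                 unannotated_rpkm = as.numeric(fp2$unannotated)),
      "kegg_unannotated.tsv")
  ko_set <- sort(unique(annotations$ko_id[!is.na(annotations$ko_id) &
                                            annotations$ko_id != ""]))
  attribution <- taxon_pathway_attribution(expr_norm, annotations, ko_set)
  put(attribution, "attribution.tsv")
  presence <- pathway_presence(annotations, registry)
  pres_codes <- ifelse(presence$present, "P", "A")
  pres_codes[presence$provenance == "curated_override"] <-
    paste0(pres_codes[presence$provenance == "curated_override"], "*")
  put(data.frame(ko_id = rownames(pres_codes), pres_codes,
                 check.names = FALSE), "pathway_presence.tsv")

  # ---- manifest -------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("fermquant")),
    mode = if (is.null(config$sim)) "files" else "simulate",
    seed = if (!is.null(config$sim)) config$sim$seed,
    reference_sample = ref,
    spike_norm = config$spike_norm,
    meju_removal_day = config$meju_removal_day,
    mag_thresholds = list(min_completeness = config$min_completeness,
                          max_contamination = config$max_contamination),
    stages = list(
      amplicon = list(bacteria_taxa = nrow(amp_b), fungi_taxa = nrow(amp_f),
                      samples = ncol(amp_b)),
      metagenome = list(genomes = nrow(mg_counts), samples = ncol(mg_counts)),
      metatranscriptome = list(genes = nrow(mrna_counts),
                               samples = ncol(mrna_counts)),
      functional = list(level2 = nrow(fp2$values), level3 = nrow(fp3$values),
                        kos = length(ko_set))
    ),
    outputs = lapply(stats::setNames(nm = names(files)), function(nm) {
      list(path = basename(files[[nm]]),
           md5 = unname(tools::md5sum(files[[nm]])))
    })
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(
    truth = if (!is.null(ds)) ds$truth,
    sample_info = sample_info, registry = registry,
    annotations = annotations,
    amplicon = list(relative = rel_amp, absolute = abs_amp, diversity = div),
    metagenome = list(relative_all = rel_mg_all, relative = rel_mg,
                      absolute = abs_mg),
    expression = list(rpkm = expr_raw, normalized = expr_norm,
                      factors = factors, shares = shares, totals = totals,
                      reference_scaled = ref_scaled),
    functional = list(level2 = fp2, level3 = fp3, attribution = attribution,
                      presence = presence),
    files = files
  ))
}

# In sim mode the registry is implied by the simulation parameters.
ganjang_registry_from_params <- function(params) {
  do.call(rbind, lapply(params$taxa, function(tx) {
    data.frame(genome_id = tx$genome_id, taxon_label = tx$genome_id,
               domain = tx$domain, source = "isolate",
               genome_size_bp = tx$genome_size_bp,
               marker_copies = tx$marker_copies,
               marker_copies_estimated = "no", stringsAsFactors = FALSE)
  }))
}

#' Write a simulated dataset as pipeline input tables
#'
#' Emits the ground-truth table, the four observation-layer count tables,
#' the per-sample metadata, gene annotations, genome registry and a YAML
#' file echoing every simulation parameter and the seed.
#'
#' @param ds A [simulate_dataset()] result.
#' @param dir Output directory.
#' @param digits Significant digits for numeric output.
#' @return Named character vector of written file paths.
#' @export
write_simulated_dataset <- function(ds, dir, digits = 6) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- ds$truth
  paths <- character()
  w <- function(x, name) {
    p <- file.path(dir, name)
    if (is.matrix(x)) write_feature_matrix(x, p, digits = digits)
    else write_tsv_table(x, p)
    paths[[file.path(basename(dir), name)]] <<- p
  }
  truth_long <- data.frame(
    sample_id = rep(colnames(truth$density), each = nrow(truth$density)),
    genome_id = rep(rownames(truth$density), times = ncol(truth$density)),
    genomes_per_ml = as.vector(truth$density)
  )
  w(truth_long, "truth.tsv")
  if (!is.null(ds$amplicon$bacteria)) w(ds$amplicon$bacteria, "amplicon_bacteria.tsv")
  if (!is.null(ds$amplicon$fungi)) w(ds$amplicon$fungi, "amplicon_fungi.tsv")
  w(ds$metagenome, "metagenome.tsv")
  w(ds$mrna$counts, "mrna.tsv")
  w(ds$sample_info, "sample_info.tsv")
  ann <- truth$genes
  ann$ko_id[is.na(ann$ko_id)] <- ""
  ann$kegg_level2[is.na(ann$kegg_level2)] <- ""
  ann$kegg_level3[is.na(ann$kegg_level3)] <- ""
  w(ann[c("gene_id", "genome_id", "length_bp", "ko_id",
          "kegg_level2", "kegg_level3")], "gene_annotations.tsv")
  w(ganjang_registry_from_params(truth$params), "genome_registry.tsv")
  params <- truth$params
  yaml::write_yaml(
    list(seed = params$seed,
         sample_days = params$sample_days,
         meju_removal_day = params$meju_removal_day,
         depths = params$depths,
         spike_mass = params$spike_mass,
         spike_mass_fraction_scale = params$spike_mass_fraction_scale,
         qpcr_cv = params$qpcr_cv,
         gene_length_meanlog = params$gene_length_meanlog,
         gene_length_sdlog = params$gene_length_sdlog,
         expr_weight_meanlog = params$expr_weight_meanlog,
         expr_weight_sdlog = params$expr_weight_sdlog,
         unannotated_frac = params$unannotated_frac,
         taxa = lapply(params$taxa, function(tx) {
           tx$activity <- as.list(tx$activity)
           unclass(tx)
         })),
    file.path(dir, "sim_params.yaml")
  )
  paths[[file.path(basename(dir), "sim_params.yaml")]] <-
    file.path(dir, "sim_params.yaml")
  paths
}

#' Build a small packaged test dataset
#'
#' Simulates the 17-genome ganjang reference community over the six
#' sampling days (0, 20, 40, 60, 90, 180) at depths small enough for
#' continuous testing (10^4 amplicon and 5x10^4 shotgun/mRNA reads per
#' sample, ~50 genes per genome) and writes all pipeline input tables,
#' including the synthetic MAG-quality table, to `dir`.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Named list of input paths suitable for
#'   `pipeline_config(inputs = ...)`; the simulated dataset is attached as
#'   attribute `"dataset"`.
#' @export
make_fixture <- function(dir, seed = 1L) {
  params <- ganjang_sim_params(
    seed = seed,
    depths = list(amplicon = 1e4, metagenome = 5e4, mrna = 5e4)
  )
  ds <- simulate_dataset(params)
  write_simulated_dataset(ds, dir)
  mq <- system.file("extdata", "mag_quality_synthetic.tsv", package = "fermquant")
  file.copy(mq, file.path(dir, "mag_quality.tsv"), overwrite = TRUE)
  inputs <- list(
    amplicon_bacteria = file.path(dir, "amplicon_bacteria.tsv"),
    amplicon_fungi = file.path(dir, "amplicon_fungi.tsv"),
    metagenome = file.path(dir, "metagenome.tsv"),
    mrna = file.path(dir, "mrna.tsv"),
    sample_info = file.path(dir, "sample_info.tsv"),
    genome_registry = file.path(dir, "genome_registry.tsv"),
    gene_annotations = file.path(dir, "gene_annotations.tsv"),
    mag_quality = file.path(dir, "mag_quality.tsv")
  )
  attr(inputs, "dataset") <- ds
  inputs
}

#' Read pipeline input tables
#'
#' `read_sample_info()` validates the per-sample metadata (day, phase, qPCR
#' anchors, spike-in reads, total mapped mRNA reads);
#' `read_gene_annotations()` validates the gene table and its genome
#' references against the registry.
#'
#' @param path TSV path.
#' @param registry Genome registry data.frame used to validate
#'   `genome_id` references.
#' @return A data.frame.
#' @export
read_sample_info <- function(path) {
  si <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "day", "qpcr_bacteria", "qpcr_fungi",
              "spike_in_reads", "total_mrna_mapped_reads")
  missing <- setdiff(needed, names(si))
  if (length(missing)) {
    stop("sample_info ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(si$sample_id)) stop("duplicate sample_id in ", path)
  if (any(si$day < 0)) stop("day must be >= 0 in ", path)
  num_ok <- c("qpcr_bacteria", "qpcr_fungi", "spike_in_reads",
              "total_mrna_mapped_reads")
  for (col in num_ok) {
    if (any(si[[col]] < 0, na.rm = TRUE)) stop(col, " must be >= 0 in ", path)
  }
  si
}

#' @rdname read_sample_info
#' @export
read_gene_annotations <- function(path, registry = NULL) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  needed <- c("gene_id", "genome_id", "length_bp")
  missing <- setdiff(needed, names(ann))
  if (length(missing)) {
    stop("gene annotations ", path, " lack columns: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in ", path)
  if (any(ann$length_bp <= 0)) stop("length_bp must be > 0 in ", path)
  if (!is.null(registry)) {
    bad <- setdiff(ann$genome_id, registry$genome_id)
    if (length(bad)) {
      stop("gene annotations reference genome(s) absent from registry: ",
           paste(bad, collapse = ", "))
    }
  }
  ann
}
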