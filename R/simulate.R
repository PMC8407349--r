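# Forward model of the fermentation time course and its four observation
# layers. Every sampling step draws from a child seed of params$seed so the
# layers are independent yet jointly reproducible.

# Numerically stable logistic trajectory N(t); reduces to N0 when r = 0.
logistic_density <- function(t, n0, r, k) {
  n0 * k / (n0 + (k - n0) * exp(-r * t))
}

# Minimal internal KEGG-style annotation vocabulary used when simulating
# gene tables: KO id -> level-2 category and level-3 pathway. Identifiers
# follow the KO naming shape; the assignment is synthetic.
kegg_reference <- function() {
  tab <- rbind(
    c("Carbohydrate metabolism", "Glycolysis / Gluconeogenesis", "K00845,K01810,K00850,K00134,K00873"),
    c("Carbohydrate metabolism", "Pentose phosphate pathway", "K00036,K01783"),
    c("Carbohydrate metabolism", "Fructose and mannose metabolism", "K00847,K01809"),
    c("Carbohydrate metabolism", "Galactose metabolism", "K00849,K01785"),
    c("Carbohydrate metabolism", "Pyruvate metabolism", "K00016,K00158,K01512,K04072"),
    c("Energy metabolism", "Oxidative phosphorylation", "K00330,K00241,K02297,K02827"),
    c("Energy metabolism", "Citrate cycle (TCA cycle)", "K01647,K01902,K00031"),
    c("Amino acid metabolism", "Glycine, serine and threonine metabolism", "K00600"),
    c("Amino acid metabolism", "Valine, leucine and isoleucine degradation", "K00166"),
    c("Amino acid metabolism", "Phenylalanine metabolism", "K00274"),
    c("Amino acid metabolism", "Lysine degradation", "K01582"),
    c("Amino acid metabolism", "Arginine and proline metabolism", "K01581"),
    c("Lipid metabolism", "Fatty acid degradation", "K00632,K00249"),
    c("Lipid metabolism", "Glycerolipid metabolism", "K00864,K00005"),
    c("Nucleotide metabolism", "Purine metabolism", "K00088"),
    c("Nucleotide metabolism", "Pyrimidine metabolism", "K00762"),
    c("Translation", "Ribosome", "K02863,K02886,K02926"),
    c("Membrane transport", "ABC transporters", "K02032,K10112"),
    c("Membrane transport", "Phosphotransferase system (PTS)", "K02777,K02791"),
    c("Signal transduction", "Two-component system", "K07636,K07666")
  )
  kos <- strsplit(tab[, 3], ",", fixed = TRUE)
  data.frame(
    ko_id = unlist(kos),
    kegg_level2 = rep(tab[, 1], lengths(kos)),
    kegg_level3 = rep(tab[, 2], lengths(kos)),
    stringsAsFactors = FALSE
  )
}

#' Simulate the true state of a fermentation time course
#'
#' Generates per-taxon genome densities and per-gene transcript weights for
#' every sampling day. Each taxon follows logistic growth
#' `N(t) = K N0 e^{rt} / (K + N0 (e^{rt} - 1))` while the meju bricks are in
#' the brine (`t <= meju_removal_day`) and exponential decay
#' `N(t) = N(t_rm) e^{-d (t - t_rm)}` afterward. The transcript weight of
#' gene `g` (of taxon `i`) in sample `s` is
#' `density(s, i) * activity(i, phase(s)) * w_g`, with `w_g` a lognormal
#' per-gene weight drawn once and frozen across samples. Gene lengths and KO
#' annotations are drawn alongside and returned as a gene table.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `"synthetic_truth"`: a list with `density`
#'   (taxon x sample matrix, genomes/ml), `transcript_weight` (gene x sample
#'   matrix), `genes` (data.frame: gene_id, genome_id, length_bp, ko_id,
#'   kegg_level2, kegg_level3, expr_weight), `samples` (data.frame:
#'   sample_id, day, phase), `params` and `seed`.
#' @export
simulate_timecourse <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  days <- params$sample_days
  sample_ids <- sprintf("d%03d", days)
  phase <- ifelse(days <= params$meju_removal_day, "meju_in", "meju_out")
  taxa <- params$taxa
  ids <- vapply(taxa, `[[`, character(1), "genome_id")

  density <- matrix(0, nrow = length(taxa), ncol = length(days),
                    dimnames = list(ids, sample_ids))
  t_rm <- params$meju_removal_day
  for (i in seq_along(taxa)) {
    tx <- taxa[[i]]
    n_rm <- logistic_density(t_rm, tx$initial_density, tx$growth_rate,
                             tx$carrying_capacity)
    density[i, ] <- ifelse(
      days <= t_rm,
      logistic_density(days, tx$initial_density, tx$growth_rate,
                       tx$carrying_capacity),
      n_rm * exp(-tx$decay_rate * (days - t_rm))
    )
  }

  genes <- with_local_seed(child_seed(params$seed, "genes"), {
    ko_pool <- kegg_reference()
    per_taxon <- lapply(taxa, function(tx) {
      n <- tx$gene_count
      len <- pmax(100L, round(stats::rlnorm(n, params$gene_length_meanlog,
                                            params$gene_length_sdlog)))
      w <- stats::rlnorm(n, params$expr_weight_meanlog, params$expr_weight_sdlog)
      ko <- rep(NA_character_, n)
      has_ko <- stats::runif(n) >= params$unannotated_frac
      ko[has_ko] <- sample(ko_pool$ko_id, sum(has_ko), replace = TRUE)
      data.frame(
        gene_id = sprintf("%s_g%03d", tx$genome_id, seq_len(n)),
        genome_id = tx$genome_id, length_bp = len, ko_id = ko,
        expr_weight = w, stringsAsFactors = FALSE
      )
    })
    g <- do.call(rbind, per_taxon)
    idx <- match(g$ko_id, ko_pool$ko_id)
    g$kegg_level2 <- ko_pool$kegg_level2[idx]
    g$kegg_level3 <- ko_pool$kegg_level3[idx]
    g[c("gene_id", "genome_id", "length_bp", "ko_id",
        "kegg_level2", "kegg_level3", "expr_weight")]
  })

  activity <- vapply(taxa, function(tx) tx$activity[phase], numeric(length(phase)))
  if (length(phase) == 1L) activity <- matrix(activity, nrow = 1L)
  # activity: sample x taxon; transcript weight = density * activity * w_g
  tw <- matrix(0, nrow = nrow(genes), ncol = length(days),
               dimnames = list(genes$gene_id, sample_ids))
  taxon_of <- match(genes$genome_id, ids)
  for (s in seq_along(days)) {
    tw[, s] <- density[cbind(taxon_of, s)] * activity[s, taxon_of] *
      genes$expr_weight
  }

  structure(
    list(
      density = density,
      transcript_weight = tw,
      genes = genes,
      samples = data.frame(sample_id = sample_ids, day = days, phase = phase,
                           stringsAsFactors = FALSE),
      params = params,
      seed = params$seed
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d taxa, %d genes, %d samples (days %s; seed %d)\n",
    nrow(x$density), nrow(x$genes), nrow(x$samples),
    paste(x$samples$day, collapse = ", "), x$seed
  ))
  invisible(x)
}

taxa_of_domain <- function(truth, domain) {
  doms <- vapply(truth$params$taxa, `[[`, character(1), "domain")
  ids <- vapply(truth$params$taxa, `[[`, character(1), "genome_id")
  ids[doms == domain]
}

marker_copies_of <- function(truth) {
  ids <- vapply(truth$params$taxa, `[[`, character(1), "genome_id")
  stats::setNames(vapply(truth$params$taxa, `[[`, numeric(1), "marker_copies"), ids)
}

genome_sizes_of <- function(truth) {
  ids <- vapply(truth$params$taxa, `[[`, character(1), "genome_id")
  stats::setNames(vapply(truth$params$taxa, `[[`, numeric(1), "genome_size_bp"), ids)
}

multinomial_columns <- function(weights, depth, seed, layer_name) {
  # weights: feature x sample nonnegative matrix; one multinomial draw/sample
  counts <- matrix(0L, nrow = nrow(weights), ncol = ncol(weights),
                   dimnames = dimnames(weights))
  with_local_seed(seed, {
    for (s in seq_len(ncol(weights))) {
      w <- weights[, s]
      tot <- sum(w)
      if (tot <= 0) {
        stop("all-zero ", layer_name, " weights in sample ",
             colnames(weights)[s])
      }
      counts[, s] <- stats::rmultinom(1, size = depth, prob = w / tot)[, 1]
    }
  })
  counts
}

#' Sample amplicon marker-gene counts from a simulated community
#'
#' Draws per-sample read counts multinomially over the taxa of one domain
#' with probabilities proportional to `density * marker_copies` — the
#' copy-number bias that amplicon sequencing carries and that the
#' quantification chain must undo. Column sums equal `depth`.
#'
#' @param truth A [simulate_timecourse()] result.
#' @param domain `"bacteria"` or `"fungi"`.
#' @param depth Reads per sample (>= 0; defaults to `params$depths$amplicon`).
#' @return Integer taxon-by-sample count matrix (feature kind
#'   `"amplicon_taxon"`).
#' @export
sample_amplicon_counts <- function(truth, domain,
                                   depth = truth$params$depths$amplicon) {
  stopifnot(inherits(truth, "synthetic_truth"))
  domain <- match.arg(domain, c("bacteria", "fungi"))
  assert_scalar_number(depth, "depth", min = 0)
  ids <- taxa_of_domain(truth, domain)
  if (!length(ids)) stop("no taxa of domain ", domain)
  w <- truth$density[ids, , drop = FALSE] * marker_copies_of(truth)[ids]
  counts <- multinomial_columns(
    w, depth, child_seed(truth$seed, paste0("amplicon_", domain)),
    paste0(domain, " amplicon")
  )
  structure(counts, feature_kind = "amplicon_taxon",
            class = c("matrix", "array"))
}

#' Sample genome-mapped shotgun metagenome counts
#'
#' Per-sample multinomial counts over all taxa with probabilities
#' proportional to `density * genome_size_bp`: larger genomes soak up more
#' shotgun reads at equal cell density, the bias genome-size normalization
#' removes. Column sums equal `depth`.
#'
#' @inheritParams sample_amplicon_counts
#' @param depth Reads per sample (defaults to `params$depths$metagenome`).
#' @return Integer genome-by-sample count matrix (feature kind `"genome"`).
#' @export
sample_metagenome_counts <- function(truth,
                                     depth = truth$params$depths$metagenome) {
  stopifnot(inherits(truth, "synthetic_truth"))
  assert_scalar_number(depth, "depth", min = 0)
  w <- truth$density * genome_sizes_of(truth)[rownames(truth$density)]
  counts <- multinomial_columns(w, depth, child_seed(truth$seed, "metagenome"),
                                "metagenome")
  structure(counts, feature_kind = "genome", class = c("matrix", "array"))
}

#' Sample mRNA read counts with a constant-mass spike-in
#'
#' Models the sequencing of a library in which a constant spike-in RNA mass
#' was added to every sample before extraction. The sample's total
#' transcript mass is `T_s = sum_g transcript_weight(s, g) * length_kb(g)`;
#' the spike read fraction is
#' `f_s = spike_mass / (spike_mass + c * T_s)` with
#' `c = params$spike_mass_fraction_scale`. Spike reads are
#' `Binomial(depth, f_s)`; the remaining reads are multinomial over genes
#' with probabilities proportional to `transcript_weight * length_kb`
#' (longer, more active genes attract more reads).
#'
#' @inheritParams sample_amplicon_counts
#' @param depth Reads per sample (>= 1; defaults to `params$depths$mrna`).
#' @param spike_mass Spike-in mass per sample (> 0; defaults to
#'   `params$spike_mass`).
#' @return A list with `counts` (integer gene-by-sample matrix, feature kind
#'   `"gene"`) and `spike_reads` (named integer vector per sample); for each
#'   sample `colSums(counts) + spike_reads == depth`.
#' @export
sample_metatranscriptome_counts <- function(truth,
                                            depth = truth$params$depths$mrna,
                                            spike_mass = truth$params$spike_mass) {
  stopifnot(inherits(truth, "synthetic_truth"))
  assert_scalar_number(depth, "depth", min = 1)
  if (!is.numeric(spike_mass) || length(spike_mass) != 1L || spike_mass <= 0) {
    stop("spike_mass must be a single positive number")
  }
  len_kb <- truth$genes$length_bp / 1000
  w <- truth$transcript_weight * len_kb
  cc <- truth$params$spike_mass_fraction_scale
  t_s <- colSums(w)
  f_s <- spike_mass / (spike_mass + cc * t_s)
  samples <- colnames(truth$transcript_weight)
  counts <- matrix(0L, nrow = nrow(w), ncol = ncol(w), dimnames = dimnames(w))
  spike <- stats::setNames(integer(length(samples)), samples)
  with_local_seed(child_seed(truth$seed, "mrna"), {
    for (s in seq_along(samples)) {
      spike[s] <- stats::rbinom(1, size = depth, prob = f_s[s])
      rest <- depth - spike[s]
      if (rest > 0) {
        if (t_s[s] <= 0) {
          # no transcripts: every non-spike read is impossible; force spike
          spike[s] <- as.integer(depth)
        } else {
          counts[, s] <- stats::rmultinom(1, rest, w[, s] / t_s[s])[, 1]
        }
      }
    }
  })
  list(
    counts = structure(counts, feature_kind = "gene",
                       class = c("matrix", "array")),
    spike_reads = spike
  )
}

#' Simulate qPCR marker-copy totals per sample
#'
#' For each domain, the true total marker-copy concentration
#' `sum_i density(s, i) * marker_copies_i` (copies/ml) is perturbed by a
#' multiplicative lognormal error with mean 1 and coefficient of variation
#' `params$qpcr_cv`. A domain with no taxa yields 0.
#'
#' @inheritParams sample_amplicon_counts
#' @return data.frame with columns `sample_id`, `qpcr_bacteria`,
#'   `qpcr_fungi` (copies/ml).
#' @export
simulate_qpcr <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cv <- truth$params$qpcr_cv
  mc <- marker_copies_of(truth)
  totals <- sapply(c("bacteria", "fungi"), function(dom) {
    ids <- taxa_of_domain(truth, dom)
    if (!length(ids)) return(rep(0, ncol(truth$density)))
    colSums(truth$density[ids, , drop = FALSE] * mc[ids])
  })
  totals <- matrix(totals, ncol = 2,
                   dimnames = list(colnames(truth$density),
                                   c("bacteria", "fungi")))
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    eps <- with_local_seed(child_seed(truth$seed, "qpcr"), {
      matrix(stats::rlnorm(length(totals), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog), ncol = 2)
    })
    totals <- totals * eps
  }
  data.frame(
    sample_id = rownames(totals),
    qpcr_bacteria = totals[, "bacteria"],
    qpcr_fungi = totals[, "fungi"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Simulate every observation layer of a fermentation study
#'
#' Convenience wrapper running [simulate_timecourse()] and all four
#' observation layers, and assembling the per-sample metadata table that the
#' quantification functions consume.
#'
#' @param params A [sim_params()] object.
#' @return A list with `truth`, `amplicon` (list `bacteria`/`fungi` count
#'   matrices), `metagenome` (count matrix), `mrna` (list `counts`,
#'   `spike_reads`), `qpcr` (data.frame) and `sample_info` (data.frame with
#'   `sample_id`, `day`, `phase`, `qpcr_bacteria`, `qpcr_fungi`,
#'   `spike_in_reads`, `total_mrna_mapped_reads`).
#' @export
simulate_dataset <- function(params) {
  truth <- simulate_timecourse(params)
  amplicon <- list(
    bacteria = if (length(taxa_of_domain(truth, "bacteria"))) {
      sample_amplicon_counts(truth, "bacteria")
    },
    fungi = if (length(taxa_of_domain(truth, "fungi"))) {
      sample_amplicon_counts(truth, "fungi")
    }
  )
  metagenome <- sample_metagenome_counts(truth)
  mrna <- sample_metatranscriptome_counts(truth)
  qpcr <- simulate_qpcr(truth)
  sample_info <- data.frame(
    truth$samples,
    qpcr_bacteria = qpcr$qpcr_bacteria[match(truth$samples$sample_id,
                                             qpcr$sample_id)],
    qpcr_fungi = qpcr$qpcr_fungi[match(truth$samples$sample_id,
                                       qpcr$sample_id)],
    spike_in_reads = as.integer(mrna$spike_reads[truth$samples$sample_id]),
    total_mrna_mapped_reads = as.integer(colSums(mrna$counts)[truth$samples$sample_id]),
    stringsAsFactors = FALSE
  )
  list(truth = truth, amplicon = amplicon, metagenome = metagenome,
       mrna = mrna, qpcr = qpcr, sample_info = sample_info)
}
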