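test_that("zero growth and decay rates leave densities constant", {
  p <- two_taxon_params(growth_rate = c(0, 0), decay_rate = c(0, 0))
  truth <- simulate_timecourse(p)
  expect_true(all(truth$density == truth$density[, 1]))
})

test_that("logistic trajectory saturates at the carrying capacity", {
  tx <- sim_taxon("A", "bacteria", 3e6, 5, initial_density = 1e6,
                  growth_rate = 0.5, carrying_capacity = 4.8e7,
                  decay_rate = 0)
  p <- sim_params(list(tx), sample_days = c(0L, 55L), meju_removal_day = 60,
                  qpcr_cv = 0, seed = 1)
  truth <- simulate_timecourse(p)
  expect_equal(unname(truth$density["A", 2]), 4.8e7, tolerance = 1e-6)
})

test_that("logistic closed form matches an independent ODE integration", {
  # frozen from deSolve::ode of dN/dt = r N (1 - N/K), N0 = 1e6, r = 0.1,
  # K = 1e9 at t = 20 (rtol 1e-12)
  tx <- sim_taxon("A", "bacteria", 3e6, 5, initial_density = 1e6,
                  growth_rate = 0.1, carrying_capacity = 1e9, decay_rate = 0)
  p <- sim_params(list(tx), sample_days = c(0L, 20L), qpcr_cv = 0, seed = 1)
  truth <- simulate_timecourse(p)
  expect_equal(unname(truth$density["A", 2]), 7342146.727248,
               tolerance = 1e-7)
})

test_that("densities decay exponentially after meju removal", {
  p <- two_taxon_params(growth_rate = c(0, 0), decay_rate = c(0.1, 0.1),
                        sample_days = c(0L, 60L, 90L, 120L))
  truth <- simulate_timecourse(p)
  expect_equal(unname(truth$density[, "d090"]),
               unname(truth$density[, "d060"]) * exp(-0.1 * 30))
  expect_equal(unname(truth$density[, "d120"]),
               unname(truth$density[, "d060"]) * exp(-0.1 * 60))
  expect_identical(truth$samples$phase, c("meju_in", "meju_in",
                                          "meju_out", "meju_out"))
})

test_that("invalid simulation parameters are rejected", {
  tx <- sim_taxon("A", "bacteria", 3e6, 5, 1e6)
  expect_error(sim_params(list(tx), sample_days = c(0L, 10L, 10L)),
               "strictly increasing")
  expect_error(sim_params(list(tx), sample_days = c(20L, 10L)),
               "strictly increasing")
  expect_error(sim_taxon("A", "bacteria", 3e6, 5, 1e6, growth_rate = -0.1),
               "growth_rate")
  expect_error(sim_taxon("A", "bacteria", 3e6, 5, 1e6, decay_rate = -1),
               "decay_rate")
  expect_error(sim_taxon("A", "bacteria", 0, 5, 1e6), "genome_size_bp")
  expect_error(sim_taxon("A", "bacteria", 3e6, 0, 1e6), "marker_copies")
})

test_that("amplicon counts carry the marker-copy bias", {
  p <- two_taxon_params(marker_copies = c(10, 1),
                        depths = list(amplicon = 1e5, metagenome = 1e4,
                                      mrna = 1e4))
  truth <- simulate_timecourse(p)
  counts <- sample_amplicon_counts(truth, "bacteria")
  expect_equal(unname(colSums(counts)), rep(1e5, 3))
  # expected proportion of taxon 1 is 10/11; allow 3 binomial SE
  p1 <- 10 / 11
  se <- sqrt(p1 * (1 - p1) / 1e5)
  obs <- counts["T1", ] / colSums(counts)
  expect_true(all(abs(obs - p1) < 3 * se))
})

test_that("amplicon sampling handles degenerate depths and single taxa", {
  p <- two_taxon_params()
  truth <- simulate_timecourse(p)
  expect_true(all(sample_amplicon_counts(truth, "bacteria", depth = 0) == 0))

  tx <- sim_taxon("only", "fungi", 2e7, 3, 1e4)
  p1 <- sim_params(list(tx), sample_days = c(0L, 10L), qpcr_cv = 0, seed = 5)
  t1 <- simulate_timecourse(p1)
  counts <- sample_amplicon_counts(t1, "fungi", depth = 500)
  expect_equal(unname(counts["only", ]), rep(500, 2))
  expect_error(sample_amplicon_counts(t1, "bacteria"), "no taxa")
})

test_that("all-zero density vectors are rejected with the sample named", {
  tx <- list(sim_taxon("A", "bacteria", 3e6, 5, 1e6, growth_rate = 0,
                       decay_rate = 50))
  p <- sim_params(tx, sample_days = c(0L, 60L, 1000L), qpcr_cv = 0, seed = 1)
  truth <- simulate_timecourse(p)
  truth$density["A", "d1000"] <- 0  # force an exactly-extinct sample
  expect_error(sample_amplicon_counts(truth, "bacteria", depth = 10), "d1000")
})

test_that("metagenome counts carry the genome-size bias", {
  # sizes from the Tetragenococcus KG11 and Alteromonadaceae KG8 genomes
  p <- two_taxon_params(genome_size_bp = c(2.4e6, 4.9e6),
                        depths = list(amplicon = 1e4, metagenome = 2e5,
                                      mrna = 1e4))
  truth <- simulate_timecourse(p)
  counts <- sample_metagenome_counts(truth)
  p1 <- 2.4 / (2.4 + 4.9)
  se <- sqrt(p1 * (1 - p1) / 2e5)
  obs <- counts["T1", ] / colSums(counts)
  expect_true(all(abs(obs - p1) < 3 * se))

  # equal sizes and densities: symmetric in expectation
  p2 <- two_taxon_params(depths = list(amplicon = 1e4, metagenome = 2e5,
                                       mrna = 1e4))
  t2 <- simulate_timecourse(p2)
  c2 <- sample_metagenome_counts(t2)
  expect_true(all(abs(c2["T1", ] / colSums(c2) - 0.5) < 3 * sqrt(0.25 / 2e5)))

  # depth 1: exactly one nonzero cell per sample
  c3 <- sample_metagenome_counts(t2, depth = 1)
  expect_equal(unname(colSums(c3 > 0)), rep(1L, ncol(c3)))
})

test_that("spike-in read fraction follows the constant-mass mixture", {
  p <- two_taxon_params(depths = list(amplicon = 1e4, metagenome = 1e4,
                                      mrna = 2e5))
  truth <- simulate_timecourse(p)
  res <- sample_metatranscriptome_counts(truth)
  expect_equal(unname(colSums(res$counts) + res$spike_reads),
               rep(2e5, ncol(res$counts)))
  # expected spike fraction from the mixture model
  len_kb <- truth$genes$length_bp / 1000
  t_s <- colSums(truth$transcript_weight * len_kb)
  f <- p$spike_mass / (p$spike_mass + p$spike_mass_fraction_scale * t_s)
  se <- sqrt(f * (1 - f) / 2e5)
  expect_true(all(abs(res$spike_reads / 2e5 - f) < 3 * se))
  # equal transcript pools => equal expected spike reads (3 binomial SE)
  expect_true(all(abs(res$spike_reads - mean(res$spike_reads)) <
                    3 * sqrt(2e5 * f[1] * (1 - f[1])) + 3))
})

test_that("doubling the transcript pool halves the spike odds", {
  p <- two_taxon_params()
  truth <- simulate_timecourse(p)
  len_kb <- truth$genes$length_bp / 1000
  t_s <- sum(truth$transcript_weight[, 1] * len_kb)
  f1 <- p$spike_mass / (p$spike_mass + p$spike_mass_fraction_scale * t_s)
  f2 <- p$spike_mass / (p$spike_mass + p$spike_mass_fraction_scale * 2 * t_s)
  expect_equal(f2 / (1 - f2), (f1 / (1 - f1)) / 2, tolerance = 1e-12)
})

test_that("a sample with no transcripts yields only spike reads", {
  tx <- sim_taxon("A", "bacteria", 3e6, 5, 1e6, growth_rate = 0,
                  decay_rate = 0,
                  activity = c(meju_in = 1, meju_out = 0))
  p <- sim_params(list(tx), sample_days = c(0L, 90L), qpcr_cv = 0, seed = 2,
                  depths = list(amplicon = 1e3, metagenome = 1e3, mrna = 1e4))
  truth <- simulate_timecourse(p)
  res <- sample_metatranscriptome_counts(truth)
  expect_equal(unname(res$spike_reads[["d090"]]), 1e4)
  expect_true(all(res$counts[, "d090"] == 0))
})

test_that("spike mass must be positive", {
  p <- two_taxon_params()
  truth <- simulate_timecourse(p)
  expect_error(sample_metatranscriptome_counts(truth, spike_mass = 0),
               "positive")
})

test_that("noiseless qPCR equals the marker-copy-weighted density sum", {
  p <- two_taxon_params(marker_copies = c(5, 10),
                        initial_density = c(1e6, 2e6))
  truth <- simulate_timecourse(p)
  q <- simulate_qpcr(truth)
  expect_equal(q$qpcr_bacteria, rep(1e6 * 5 + 2e6 * 10, 3))  # 2.5e7 by hand
  expect_equal(q$qpcr_fungi, rep(0, 3))
})

test_that("single noiseless bacterium gives density times copy number", {
  tx <- sim_taxon("A", "bacteria", 3e6, 5, 1e6, growth_rate = 0,
                  decay_rate = 0)
  p <- sim_params(list(tx), sample_days = 0L, qpcr_cv = 0, seed = 9)
  q <- simulate_qpcr(simulate_timecourse(p))
  expect_equal(q$qpcr_bacteria, 5e6)
})

test_that("qPCR noise has approximately unit mean and the requested CV", {
  tx <- sim_taxon("A", "bacteria", 3e6, 1, 1e6, growth_rate = 0,
                  decay_rate = 0)
  p <- sim_params(list(tx), sample_days = as.integer(seq(0, 4995, by = 5)),
                  qpcr_cv = 0.2, seed = 31)
  q <- simulate_qpcr(simulate_timecourse(p))
  ratio <- q$qpcr_bacteria / 1e6
  expect_equal(mean(ratio), 1, tolerance = 0.02)
  expect_equal(sd(ratio), 0.2, tolerance = 0.05)
})

test_that("a fixed seed reproduces every layer bit-identically", {
  p <- ganjang_sim_params(seed = 17, depths = list(amplicon = 2e3,
                                                   metagenome = 5e3,
                                                   mrna = 5e3))
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(d1$truth$density, d2$truth$density)
  expect_identical(d1$truth$genes, d2$truth$genes)
  expect_identical(d1$amplicon$bacteria, d2$amplicon$bacteria)
  expect_identical(d1$metagenome, d2$metagenome)
  expect_identical(d1$mrna, d2$mrna)
  expect_identical(d1$qpcr, d2$qpcr)
})

test_that("with all biases equal, count proportions converge to density", {
  taxa <- lapply(1:4, function(i) {
    sim_taxon(paste0("T", i), "bacteria", 3e6, 4,
              initial_density = i * 1e5, growth_rate = 0, decay_rate = 0)
  })
  p <- sim_params(taxa, sample_days = 0L, qpcr_cv = 0, seed = 8,
                  depths = list(amplicon = 1e6, metagenome = 1e6, mrna = 1e4))
  truth <- simulate_timecourse(p)
  target <- (1:4) / 10
  for (counts in list(sample_amplicon_counts(truth, "bacteria"),
                      sample_metagenome_counts(truth))) {
    obs <- counts[, 1] / sum(counts[, 1])
    se <- sqrt(target * (1 - target) / 1e6)
    expect_true(all(abs(obs - target) < 3 * se))
  }
})

test_that("truth densities are nonnegative with at least one positive taxon", {
  p <- ganjang_sim_params(seed = 4)
  truth <- simulate_timecourse(p)
  expect_true(all(truth$density >= 0))
  expect_true(all(colSums(truth$density) > 0))
  expect_true(all(truth$transcript_weight >= 0))
})
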