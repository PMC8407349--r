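mini_expr_fixture <- function() {
  counts <- matrix(c(10L, 6L, 0L,
                     20L, 0L, 4L), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    genome_id = c("A", "A", "B"),
                    length_bp = c(1000L, 500L, 2000L),
                    ko_id = c("K1", "K2", "K1"),
                    kegg_level2 = c("c1", "c2", "c1"),
                    kegg_level3 = c("p1", "p2", "p1"),
                    stringsAsFactors = FALSE)
  si <- data.frame(sample_id = c("s1", "s2"),
                   spike_in_reads = c(100L, 50L),
                   total_mrna_mapped_reads = c(1e6L, 2e6L))
  list(counts = counts, ann = ann, si = si)
}

test_that("RPKM matches its definition on unit cases", {
  fx <- mini_expr_fixture()
  e <- rpkm(fx$counts, fx$ann, fx$si)
  expect_equal(unname(e["g1", "s1"]), 10)        # 10 / 1kb / 1M
  expect_equal(unname(e["g2", "s2"]), 0)
  expect_equal(unname(e["g3", "s2"]), 4 / 2 / 2) # 4 reads, 2 kb, 2M mapped
  # 6 reads, 500 bp, 2e6 total -> 6 / 0.5 / 2 = 6
  si6 <- transform(fx$si, total_mrna_mapped_reads = c(2e6L, 2e6L))
  expect_equal(unname(rpkm(fx$counts, fx$ann, si6)["g2", "s1"]), 6)
})

test_that("RPKM equals a brute-force double loop on random matrices", {
  withr::with_seed(404, {
    for (i in 1:50) {
      nf <- sample(3:20, 1); ns <- sample(2:6, 1)
      counts <- rand_counts(nf, ns)
      ann <- rand_gene_annotations(rownames(counts))
      totals <- colSums(counts) + sample(0:100, ns, replace = TRUE)
      si <- data.frame(sample_id = colnames(counts),
                       total_mrna_mapped_reads = totals)
      got <- rpkm(counts, ann, si)
      want <- oracle_rpkm(counts,
                          ann$length_bp[match(rownames(counts), ann$gene_id)],
                          totals)
      expect_equal(strip(got), want, tolerance = 1e-12,
                   ignore_attr = "class")
    }
  })
})

test_that("RPKM rejects inconsistent read totals", {
  fx <- mini_expr_fixture()
  si_small <- transform(fx$si, total_mrna_mapped_reads = c(5L, 5L))
  expect_error(rpkm(fx$counts, fx$ann, si_small), "smaller than")
})

test_that("spike-in scale factors follow the constant-mass algebra", {
  si <- data.frame(sample_id = c("r", "a", "b"),
                   spike_in_reads = c(100L, 100L, 50L),
                   total_mrna_mapped_reads = c(1e6L, 1e6L, 1e6L))
  f <- spikein_scale_factors(si, "r")
  expect_equal(unname(f[["r"]]), 1)    # reference is always 1
  expect_equal(unname(f[["a"]]), 1)    # identical spike fraction
  expect_equal(unname(f[["b"]]), 2)    # half the fraction -> twice the pool
  # raw-count variant ignores library size
  si2 <- transform(si, total_mrna_mapped_reads = c(1e6L, 2e6L, 1e6L))
  f2 <- spikein_scale_factors(si2, "r", variant = "raw_count")
  expect_equal(unname(f2), c(1, 1, 2))
  expect_error(spikein_scale_factors(transform(si, spike_in_reads = c(10L, 0L, 5L)), "r"),
               "a")
})

test_that("normalization applies factors once and records them", {
  fx <- mini_expr_fixture()
  e <- rpkm(fx$counts, fx$ann, fx$si)
  ones <- c(s1 = 1, s2 = 1)
  expect_equal(strip(normalize_expression(e, ones)), strip(e))
  f <- spikein_scale_factors(fx$si, "s1")
  en <- normalize_expression(e, f, reference_sample = "s1")
  expect_equal(strip(en), strip(e) %*% diag(unname(f[colnames(e)])),
               ignore_attr = TRUE)
  expect_error(normalize_expression(en, f), "already")
})

test_that("the spike chain is invariant to a sample's sequencing depth", {
  # scaling one sample's gene counts, spike reads and totals by c leaves its
  # normalized expression unchanged
  fx <- mini_expr_fixture()
  for (c_fac in c(2L, 5L, 10L)) {
    counts2 <- fx$counts
    counts2[, "s2"] <- counts2[, "s2"] * c_fac
    si2 <- fx$si
    si2$spike_in_reads[2] <- si2$spike_in_reads[2] * c_fac
    si2$total_mrna_mapped_reads[2] <- si2$total_mrna_mapped_reads[2] * c_fac
    base <- normalize_expression(rpkm(fx$counts, fx$ann, fx$si),
                                 spikein_scale_factors(fx$si, "s1"), "s1")
    scaled <- normalize_expression(rpkm(counts2, fx$ann, si2),
                                   spikein_scale_factors(si2, "s1"), "s1")
    expect_equal(strip(scaled), strip(base), tolerance = 1e-9)
  }
})

test_that("per-taxon read shares sum the right genes", {
  fx <- mini_expr_fixture()
  sh <- relative_expression_by_taxon(fx$counts, fx$ann)
  expect_equal(unname(sh[, "s1"]), c(1, 0))          # A: 10+6, B: 0
  expect_equal(unname(sh[, "s2"]), c(20, 4) / 24)
  expect_equal(unname(colSums(sh)), c(1, 1))
  # 30 vs 70 reads split across two genomes
  m37 <- matrix(c(30L, 70L), 2, 1, dimnames = list(c("g1", "g3"), "s"))
  sh37 <- relative_expression_by_taxon(m37, fx$ann)
  expect_equal(unname(sh37[, 1]), c(0.3, 0.7))
  # single-genome sample: share 1
  one <- matrix(c(3L, 7L), 2, 1, dimnames = list(c("g1", "g2"), "s"))
  ann_one <- fx$ann[1:2, ]
  expect_equal(unname(relative_expression_by_taxon(one, ann_one)["A", 1]), 1)
  # permuting gene order leaves shares unchanged
  perm <- fx$counts[c(3, 1, 2), ]
  expect_equal(strip(relative_expression_by_taxon(perm, fx$ann)),
               strip(sh))
})

test_that("reference scaling normalizes to the reference grand total", {
  totals <- matrix(c(6, 4, 3, 2), 2, 2,
                   dimnames = list(c("A", "B"), c("ref", "s2")))
  out <- scale_to_reference_sample(totals, "ref")
  expect_equal(sum(out[, "ref"]), 1)
  expect_equal(sum(out[, "s2"]), 0.5)  # half the reference total
  expect_error(scale_to_reference_sample(totals, "nope"), "nope")
  totals0 <- totals; totals0[, "ref"] <- 0
  expect_error(scale_to_reference_sample(totals0, "ref"), "zero")
})

test_that("normalized per-taxon totals track true transcript mass", {
  # phase-dependent activity: correlation must survive the activity shift
  cors <- replicate(10, NA_real_)
  for (i in 1:10) {
    p <- ganjang_sim_params(seed = 100 + i, qpcr_cv = 0,
                            depths = list(amplicon = 1e3, metagenome = 1e3,
                                          mrna = 1e6))
    truth <- simulate_timecourse(p)
    mr <- sample_metatranscriptome_counts(truth)
    si <- data.frame(sample_id = truth$samples$sample_id,
                     spike_in_reads = as.integer(mr$spike_reads),
                     total_mrna_mapped_reads = as.integer(colSums(mr$counts)))
    expr <- rpkm(mr$counts, truth$genes, si)
    en <- normalize_expression(expr, spikein_scale_factors(si, "d060"), "d060")
    totals <- taxon_expression_totals(en, truth$genes)
    true_mass <- rowsum(truth$transcript_weight, truth$genes$genome_id)
    cors[i] <- cor(as.vector(totals), as.vector(true_mass[rownames(totals), ]))
  }
  expect_true(all(cors > 0.95))
})
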