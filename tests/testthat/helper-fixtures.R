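# Small parameter builders shared across tests.

two_taxon_params <- function(marker_copies = c(5, 5),
                             genome_size_bp = c(3e6, 3e6),
                             initial_density = c(1e6, 1e6),
                             growth_rate = c(0, 0), decay_rate = c(0, 0),
                             carrying_capacity = initial_density,
                             domain = c("bacteria", "bacteria"),
                             sample_days = c(0L, 30L, 90L),
                             activity = list(c(meju_in = 1, meju_out = 1),
                                             c(meju_in = 1, meju_out = 1)),
                             gene_count = 10L, seed = 42L, qpcr_cv = 0, ...) {
  taxa <- lapply(1:2, function(i) {
    sim_taxon(paste0("T", i), domain[i], genome_size_bp[i], marker_copies[i],
              initial_density[i], growth_rate[i], carrying_capacity[i],
              decay_rate[i], gene_count, activity[[i]])
  })
  sim_params(taxa, sample_days = sample_days, qpcr_cv = qpcr_cv,
             seed = seed, ...)
}

make_rel_profile <- function(vals, scope = "bacteria") {
  abund_profile(vals, kind = "relative", scope = scope)
}

# drop class/unit attributes, keep dims: for value-only comparisons
strip <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}
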