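# Brute-force reference implementations, kept deliberately naive (explicit
# loops, no shared code with the package) so they can serve as independent
# oracles.

oracle_rpkm <- function(counts, length_bp, totals) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (g in seq_len(nrow(counts))) {
    for (s in seq_len(ncol(counts))) {
      out[g, s] <- counts[g, s] / (length_bp[g] / 1000) / (totals[s] / 1e6)
    }
  }
  out
}

oracle_goods <- function(x) {
  singletons <- 0
  for (v in x) if (v == 1) singletons <- singletons + 1
  1 - singletons / sum(x)
}

oracle_shannon <- function(x) {
  n <- sum(x)
  h <- 0
  for (v in x) {
    if (v > 0) h <- h - (v / n) * log(v / n)
  }
  h
}

oracle_chao1 <- function(x) {
  s_obs <- sum(x > 0)
  n1 <- sum(x == 1)
  n2 <- sum(x == 2)
  s_obs + n1 * (n1 - 1) / (2 * (n2 + 1))
}

oracle_kegg_sums <- function(expr_vals, labels) {
  cats <- sort(unique(labels[!is.na(labels)]))
  out <- matrix(0, length(cats), ncol(expr_vals),
                dimnames = list(cats, colnames(expr_vals)))
  for (g in seq_len(nrow(expr_vals))) {
    if (is.na(labels[g])) next
    for (s in seq_len(ncol(expr_vals))) {
      out[labels[g], s] <- out[labels[g], s] + expr_vals[g, s]
    }
  }
  out
}

oracle_attribution <- function(expr_vals, ko, genome, kid, sample) {
  sel <- which(!is.na(ko) & ko == kid)
  total <- sum(expr_vals[sel, sample])
  genomes <- sort(unique(genome[sel]))
  fr <- numeric(length(genomes))
  names(fr) <- genomes
  if (total <= 0) return(fr)
  for (i in seq_along(genomes)) {
    fr[i] <- sum(expr_vals[sel[genome[sel] == genomes[i]], sample]) / total
  }
  fr
}

# Random small fixtures used by the oracle-equivalence tests.
rand_counts <- function(nf, ns, lambda = 5) {
  m <- matrix(rpois(nf * ns, lambda), nf, ns,
              dimnames = list(paste0("f", seq_len(nf)),
                              paste0("s", seq_len(ns))))
  # guarantee at least one read per sample so coverage/diversity are defined
  for (s in seq_len(ns)) if (sum(m[, s]) == 0) m[1, s] <- 1L
  storage.mode(m) <- "integer"
  m
}

rand_gene_annotations <- function(gene_ids, n_genomes = 3, n_ko = 6,
                                  unannotated = 0.25) {
  ko <- sample(c(sprintf("K%05d", seq_len(n_ko)), NA),
               length(gene_ids), replace = TRUE,
               prob = c(rep((1 - unannotated) / n_ko, n_ko), unannotated))
  lev2 <- ifelse(is.na(ko), NA,
                 paste0("cat", (match(ko, sprintf("K%05d", seq_len(n_ko))) %% 3) + 1))
  data.frame(
    gene_id = gene_ids,
    genome_id = sample(paste0("G", seq_len(n_genomes)), length(gene_ids),
                       replace = TRUE),
    length_bp = sample(300:3000, length(gene_ids), replace = TRUE),
    ko_id = ko, kegg_level2 = lev2, kegg_level3 = lev2,
    stringsAsFactors = FALSE
  )
}
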