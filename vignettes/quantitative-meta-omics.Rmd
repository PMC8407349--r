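---
title: "Quantitative genome-centered meta-omics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genome-centered meta-omics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermquant)
```

## The quantification problem

Sequencing-based community profiles are compositional: amplicon, shotgun
and mRNA read counts each measure a *biased share* of an unknown total.
In a fermentation time course — here modeled on ganjang, a Korean soy
sauce fermented by soaking meju (fermented soybean) bricks in brine —
three biases matter:

* **Marker copy number.** A bacterial genome carries 1–10+ copies of the
  16S rRNA gene (fungi: ITS), so amplicon counts and qPCR totals
  over-represent high-copy taxa.
* **Genome size.** Shotgun reads accrue in proportion to genome size times
  cell density; a 24 Mb yeast genome soaks up ten times the reads of a
  2.4 Mb bacterium at equal density.
* **Total mRNA mass.** RPKM is per *million mapped reads*, so it says
  nothing about how much transcription happened per ml of sample. A
  constant mass of foreign spike-in RNA added to every sample before
  extraction calibrates that: a sample in which the spike is a small read
  fraction had a large mRNA pool.

`fermquant` implements the corrections that undo each bias, anchored on a
reference registry of 17 genomes (10 high-quality metagenome-assembled
genomes and 7 isolate genomes) with known sizes and marker copy numbers,
and a synthetic data generator that *produces* each bias from known ground
truth so the whole chain can be validated end to end.

## The synthetic community model

### Population trajectories

Each taxon follows logistic growth while the meju bricks are in the brine
(`t <= meju_removal_day`, default day 60) and first-order decay after
their removal:

$$N(t) = \frac{K N_0 e^{rt}}{K + N_0\,(e^{rt}-1)}, \qquad t \le t_{rm};
\qquad N(t) = N(t_{rm})\, e^{-d\,(t-t_{rm})}, \qquad t > t_{rm}.$$

This is the simplest interpretable model that reproduces the observed
rise-then-fall shape: growth saturating on a finite substrate, then decay
once the substrate leaves the system. The implementation uses the
numerically stable form $N_0 K / (N_0 + (K-N_0)e^{-rt})$, which reduces to
$N_0$ exactly at $r = 0$; tests cross-check it against a numerical ODE
integration.

`ganjang_sim_params()` scales initial densities and carrying capacities so
the *domain-total marker-copy concentrations* hit the ganjang qPCR
anchors: about $10^6$ (bacteria) and $10^4$ (fungi) copies/ml at day 0,
rising to about $4.8\times10^7$ and $4.6\times10^5$ copies/ml at day 60.
The fixed composition weights echo the observed succession
(*Tetragenococcus*, *Chromohalobacter*, Idiomarinaceae and *Halomonas*
dominant at peak; *Bacillus* prominent only early; *Debaryomyces* the
dominant fungus). Defaults `growth_rate = 0.15`/day and
`decay_rate = 0.05`/day give near-saturation by day 60 and a ~25-fold
decline by day 90+90 — rates a microbiologist would call a fast brine
fermentation and a slow die-off.

### Observation layers

* **Amplicon**: per sample, reads are multinomial over the domain's taxa
  with probability $\propto N_i \times m_i$ ($m_i$ = marker copies).
* **Shotgun**: multinomial over all taxa with probability
  $\propto N_i \times G_i$ ($G_i$ = genome size).
* **mRNA + spike-in**: gene $g$ of taxon $i$ has transcript weight
  $w_{sg} = N_i(s) \times a_i(\text{phase}(s)) \times u_g$, where
  $a_i$ is a per-phase activity multiplier (default 1 while bricks are
  in, 0.2 after) and $u_g$ a per-gene lognormal weight (meanlog 0,
  sdlog 1.2) drawn **once** and frozen across samples — so expression
  changes decompose cleanly into abundance versus activity. With total
  transcript mass $T_s = \sum_g w_{sg}\,\ell_g$ (lengths in kb), the
  spike read fraction is $f_s = M/(M + cT_s)$ for spike mass $M$
  (default 2, the micrograms added per sample in the emulated protocol)
  and mass-scale $c$ (`spike_mass_fraction_scale`, default 5e-6, chosen
  so the spike occupies a few percent of reads at peak biomass and
  dominates only when the community collapses — at day 180 roughly half
  the reads are spike, which is exactly what a constant-mass spike does
  when biomass falls three orders of magnitude). Spike reads are
  $\mathrm{Binomial}(\text{depth}, f_s)$; the rest are multinomial over
  genes with probability $\propto w_{sg}\,\ell_g$.
* **qPCR**: the true domain total $\sum_i N_i m_i$ times a lognormal
  error with mean 1 and CV `qpcr_cv` (default 0.1, a typical
  between-assay CV for triplicate qPCR means; the simulator emits one
  noisy mean per sample rather than replicates, since the replicate
  structure is not part of the quantification chain).

One user seed drives everything; each layer draws from a deterministically
derived child seed, so layers are reproducible yet mutually independent.
Gene lengths are lognormal around 900 bp (sdlog 0.35, floored at 100 bp),
about right for microbial coding sequences; ~20% of genes are left without
a KO so the unannotated-mass bookkeeping is exercised.

### What the generator does *not* emulate

No read-level simulation (no sequencing errors, chimeras, mapping
ambiguity), no taxonomic misclassification, no extraction-efficiency
differences between taxa, no rRNA carry-over into mRNA libraries, no
compositional interaction between domains in the amplicon layer (bacteria
and fungi are sequenced as separate pools, as in the emulated protocol).
Passing recovery tests therefore demonstrate that the *arithmetic* of the
correction chain is right under the stated observation model — not that
real libraries satisfy that model.

## The quantification chains

### Amplicon

Relative abundance is the column-normalized count share. Coverage and
diversity use the standard amplicon trio, each independently verifiable:
Good's coverage $1 - n_1/N$; Shannon $-\sum p_i \ln p_i$ (natural log —
the base must be fixed for testability, and `ln` is the convention of the
ecology packages this feeds into); bias-corrected Chao1
$S_{obs} + n_1(n_1-1)/(2(n_2+1))$. Absolute marker abundance multiplies
the within-domain relative abundance by the sample's domain qPCR total,
conserving it: columns of the output sum to the qPCR value.

### Metagenome

`size_normalized_relative_abundance()` divides each genome's count by its
genome size before renormalizing, converting read shares into cell
shares. The MAG quality filter keeps bins with completeness $\ge 90$% and
contamination $\le 5$% (both boundaries inclusive, and both configurable;
the boundary convention is stated explicitly so it is testable).

`absolute_genome_abundance()` converts a within-domain relative profile
into genomes/ml anchored on the domain qPCR total $Q_s$. The correct
copy-number division depends on what the profile's shares measure, and the
function makes that explicit:

* For a **cell-share** profile (size-normalized shotgun), the exact
  inverse of the observation model attributes the copy pool by each
  genome's *implied copy share*:
  $\hat N_g = r_{gs} Q_s / \sum_j r_{js} m_j$ — division by the
  profile-weighted mean copy number. Dividing by $m_g$ itself instead
  would inflate low-copy taxa by the ratio of the mean to their own copy
  number (up to ~60% in the 17-genome registry); the package therefore
  uses the weighted-mean form as its default. When every genome in the
  domain shares one copy number the two coincide.
* For a **copy-share** profile (amplicon), per-genome division is exact:
  $\hat N_g = r_{gs} Q_s / m_g$, available as
  `rel_measures = "marker_copies"`.

Both conversions renormalize *within domain* before anchoring, because the
qPCR assays are domain-specific — the only dimensionally consistent
reading. Restricting an all-domain profile to one domain and renormalizing
commutes with the conversion (an algebraic identity the tests exercise).

### Metatranscriptome

RPKM is `count / (length/1000) / (total_mapped/1e6)`, with the denominator
taken from the per-sample *mapped mRNA reads excluding spike-in* — the
reading of "per million mapped reads" that keeps the unit independent of
spike dosage. Spike factors default to the **fraction variant**,
$(s_{ref}/T_{ref})/(s_s/T_s)$, which is invariant to library size; the
raw-count variant $s_{ref}/s_s$ is available behind
`variant = "raw_count"` since the protocol description is ambiguous
between the two (they coincide when library sizes are equal). A sample
whose counts, spike reads and totals are all scaled by any $c>0$ has
identical normalized expression — the depth-invariance property the
acceptance suite checks to 1e-9. Normalization is recorded on the object
and applying it twice is an error. The reference sample defaults to the
day-60 sample (peak biomass, the scale used for the reference-relative
totals); `scale_to_reference_sample()` divides per-taxon normalized totals
by the reference sample's grand total, so the reference column sums to 1.

### Functional profiles

`kegg_category_expression()` sums normalized RPKM over genes sharing a
KEGG annotation at level 2, level 3 or KO. The annotation schema carries
one label per gene and level, so level-2 sums plus the separately reported
unannotated mass reconstruct the per-sample total exactly (the
conservation invariant). Where an upstream annotation assigns one gene to
several pathways, it must be expressed as the gene's primary label;
duplicating rows would break conservation and is deliberately not
supported. `taxon_pathway_attribution()` computes, per KO and sample, each
genome's fraction of the KO's total expression — the pie-chart quantity —
with zero-total cells marked `defined = FALSE` and zero fractions rather
than NaN. Attribution is invariant to rescaling a sample's expression.
`pathway_presence()` reduces annotations to a KO-by-genome
presence/absence matrix with per-cell provenance; curation overrides
(standing in for manual BLASTP curation) flip individual cells and are
recorded as `curated_override`.

## Pipeline and reproducibility

`run_pipeline()` chains the stages over either simulated or file inputs,
writes every table as UTF-8 TSV (6 significant digits by default;
`digits = NA` for full precision) plus a YAML manifest with parameters,
per-stage dimensions and an md5 checksum per output. Identical
configuration and seed give byte-identical outputs. Schema violations and
cross-file identifier mismatches (gene to genome, genome to registry) are
reported with the offending identifiers. `make_fixture()` packages a
17-genome, 6-sample dataset at test-friendly depths ($10^4$ amplicon,
$5\times10^4$ shotgun/mRNA reads per sample, ~50 genes per genome).

The bundled MAG-quality table is a synthetic stand-in (the per-bin values
are not published): it is constructed so 10 of 15 bins pass the
thresholds, with one bin exactly on the 90%/5% boundary to pin the
inclusive convention.

## Validation scale and known limitations

The test suite validates recovery at full community scale — 17 genomes, 6
sampling days, $2\times10^5$ shotgun and $5\times10^4$ amplicon reads per
sample, 20 replicate seeds — where the worst-case per-taxon median density
error (taxa at $\ge 1$% within-domain density) is ~2%. Deeper layers
(e.g. $10^6$ mRNA reads) are used only where a property needs them.

Limitations worth keeping in mind: absolute abundances inherit qPCR's
accuracy (amplification-efficiency bias is not modeled, only lognormal
noise); genome-size normalization assumes one genome copy per cell (no
polyploidy or replication-fork effects); RPKM totals per taxon weight
genes by length, so taxa with unusual length distributions compare
imperfectly; and the spike-in chain assumes extraction treats spike and
sample RNA identically — the normalization operates at the read-fraction
level, which is the layer the correction itself lives on.

```{r example}
params <- ganjang_sim_params(seed = 1, qpcr_cv = 0,
                             depths = list(amplicon = 1e4, metagenome = 5e4,
                                           mrna = 5e4))
truth <- simulate_timecourse(params)
counts <- sample_metagenome_counts(truth)
q <- simulate_qpcr(truth)
si <- data.frame(sample_id = q$sample_id, qpcr_bacteria = q$qpcr_bacteria,
                 qpcr_fungi = q$qpcr_fungi)
reg <- ganjang_genomes()
rel <- restrict_to_domain(
  size_normalized_relative_abundance(counts, reg, "all"), reg, "bacteria")
dens <- absolute_genome_abundance(rel, si, reg, "bacteria")
round(dens[1:5, 1:3])          # genomes/ml
round(truth$density[1:5, 1:3]) # ground truth
```
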