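---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models implemented in
`splicestress`, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical and design choices that were genuinely open.
It states no empirical result that the test suite does not itself compute.

## Study design assumed throughout

A panel of genetic lines (default 38), each contributing exactly one
control and one infected RNA-seq sample. Per gene and sample, an upstream
quantifier (MISO-like) has produced isoform ratios and per-isoform assigned
read counts; per intron-retention event and sample, counts of
retention-supporting reads (exon–intron boundary plus intron body, `k_r`)
and splicing-supporting reads (exon–exon junction, `k_s`). Coordinates are
0-based half-open everywhere; minus-strand genes store features in
transcription order so "5′ end" is strand-aware.

## Isoform diversity and the distance-based splicing test

**Filtering.** An isoform is kept if it has more than `min_reads` (default
1) assigned reads in at least `min_sample_frac` (default 0.9) of the
samples. Survivors' ratios are renormalized per sample; genes left with a
single isoform are excluded from testing but retained for entropy (where
they contribute H = 0).

**Entropy.** Shannon entropy in nats (natural log — the diversity
convention of the vegan family, configurable by transforming the output);
`0·log 0 = 0`. The per-line shift summary counts genes with
`ΔH > ε` and `ΔH < −ε` with `ε = 1e-9`: ratios are continuous, so exact
ties occur only for genuinely unchanged vectors and `ε` merely absorbs
floating-point noise. The isoform-number × condition (× resistance class)
stratification is summarized by stratum means, and the optional class
contrast is a two-factor least-squares fit per stratum
(`entropy ~ condition + class` on per-sample means); it is reported but is
not part of any acceptance property.

**Distance test.** Per gene, samples are points in the isoform-ratio
simplex and the test is a two-group PERMANOVA with Euclidean distance:
`SSB/SST` is the effect size, pseudo-F the statistic, and the p-value is
the permutation tail probability with the add-one correction
`(count + 1)/(n_perm + 1)` (never exactly zero; default `n_perm = 10000`).
Euclidean distance is the package's choice — the method family this test
belongs to is distance-based but no single metric is canonical; the
implementation accepts any sample × isoform matrix, so a user can transform
ratios beforehand. The homogeneity companion computes each sample's
distance to its group centroid once and permutes those distances between
groups (the dispersion-permutation strategy of `vegan::permutest` on
`betadisper` objects). This scheme is exact in exchangeability of the
distances, not of the raw data, and is known to run slightly liberal at
very small group sizes; the acceptance suite therefore checks its type-I
error binomially rather than by distributional KS. The significance flag is
`homogeneity p > 0.05` AND `BH-adjusted p < 0.05` AND
`effect size > threshold`. The threshold default is 0.1, with 0.2 available
by argument: both values circulate in analyses of this kind and neither is asserted
as canonical.

## Effective lengths and the permutation G-test

Effective length is `Σ L_i p_i` per gene, sample, and feature (transcript,
5′UTR, CDS, 3′UTR), plus the three transcript-minus-feature variants used
to attribute a shift to one feature. Deltas (infected − control, per line)
are classified as increase/decrease/unchanged with `eps_bp = 1e-6`:
the data contain exact zeros (single-isoform genes, ratio-stable genes) and
any genuine change is orders of magnitude above this tolerance. The
"unchanged" tolerance is the package's choice; "did not change" has no
standard numeric definition.

The null for the category proportions is generated by re-assigning
infection status: mode `"full"` re-pairs the 2n samples at random into n
pseudo control/infected pairs (the literal reading of "randomly assigning
infection status to the samples"); mode `"within_line"` swaps each line's
two labels, the paired variant that coincides with full shuffling up to
pairing in a 1 + 1 design. `"full"` is the default: under within-line swaps
the unchanged category is invariant (deltas only change sign), which pins
one degree of freedom and makes the df = 2 chi-square reference
inapplicable. Expected counts are the permutation-mean proportions (pooled
across pseudo-lines in full mode, per line in swap mode), `G = 2 Σ O ln(O/E)`
with `O = 0` terms contributing zero and zero expectations floored at 0.5
with a warning (the statistic is undefined at `E = 0`), df = 2, and a Bonferroni threshold across line × feature tests.

*Calibration caveat.* The chi-square reference treats the per-line category
counts as multinomial. Two features of real (and realistic synthetic) data
violate that: genes whose delta is deterministically zero (single-isoform
genes) contribute a constant to the unchanged category, and heterogeneous
per-gene tie probabilities make the counts Poisson-binomial, whose variance
is smaller than multinomial. Both push the test conservative — an
acceptable direction for a screening statistic, but the reason the
acceptance calibration drives the test with an iid-genes null world (where
the multinomial assumption holds and the p-values are uniform). Users
comparing against the Bonferroni threshold on heterogeneous data should
read the p-values as conservative.

**3′UTR mechanism classes.** For a multi-isoform gene:
no 3′UTR length diversity → `NoAnnotatedDiff/Ambiguous`; differing 3′UTR
exon counts → `Splicing`; equal exon counts with a common start and
differing ends → `Alternate3Poly`; everything else is pooled with the
first class (the same pooling the motivating analysis used). The classes
are exhaustive and mutually exclusive by construction.

## Intron retention: PSI posteriors and Bayes factors

PSI gets a conjugate `Beta(prior + k_r', prior + k_s')` posterior with a
uniform `Beta(1, 1)` prior per condition — uninformative, and the spirit of
MISO's defaults without re-implementing its read-generative model. When
event geometry and read length supply the number of distinct read start
positions per category, effective counts `k' = k / positions` correct the
unequal opportunity of junction vs intron-body reads; otherwise raw counts
are used. An event with `k_r + k_s = 0` is flagged uncovered, never
imputed.

Evidence for a PSI change is the Savage–Dickey density ratio at
`ΔPSI = 0`: the prior density of the difference of two independent uniform
variables at 0 is exactly 1 (triangular density), and the posterior density
at 0 is a Gaussian-kernel estimate from Monte-Carlo draws of the two Beta
posteriors (bandwidth `bw.nrd0`, the standard rule). `E[ΔPSI]` is exact
(difference of Beta means); only the BF is Monte-carlo, and its propagated
standard error is reported. With `n_mc` below 1000 the function warns. When
the two posteriors barely overlap the kernel estimate at 0 underflows and
the BF becomes astronomically large; such values mean "effectively
infinite evidence" and should not be read quantitatively. The independent
check used in the tests is the exact overlap integral
`f_Δ(0) = ∫ f_inf(t) f_ctrl(t) dt` by quadrature.

Significance is `BF > 10` and `|ΔPSI| > 0.2`; `ΔPSI` is always
infected − control. Recurrence tabulates per event the lines significant up
and down and the `≥ k`-line lists; `k` is a parameter with no canonical
default (recurrence analyses of this kind commonly use 4 or 5 lines). The
expected multi-set overlap of recurrent event lists is
`N · Π(n_i / N)` under independent uniform draws, with a simulated tail
probability (add-one corrected) replacing an exact multi-set test.

## sQTL positional and element enrichment

Variants are assigned to their nearest gene and kept within 10 kb (the
"local" window). The composite metagene axis maps the upstream flank to
`[-1, 0)`, the length-normalized body to `[0, 1]`, and the downstream flank
to `(1, 2]`; flanks are scaled by the flank width so each segment has unit
length and the binned density integrates to 1 over the domain. Defaults:
100 body bins and 100 flank bins (100 bp per flank bin at the 10 kb flank).
The intron axis is built the same way around the nearest intron (donor =
0, acceptor = 1, exonic flanks of 300 bp by default).

Null sets match the sQTL allele-frequency histogram exactly in bins of
width 0.02 on minor allele frequency, sampled without replacement within a
set from non-sQTL variants (with replacement across sets). The bin width is the package's
choice of what "similar allele frequency spectrum" means and is
configurable, as is the question of replacement. Element
enrichment counts a variant once however many hexamer matches cover it;
`z = (obs − mean_null)/sd_null` with the empirical add-one p alongside (the
z is undefined and reported `NA` when the null sd is zero).

Hexamer scanning returns every exact, possibly overlapping match
(`Biostrings::matchPattern` per motif); `N` never matches.

## Intron characterization

GC content is `(G + C)/(A + C + G + T)` with N excluded from the
denominator and `NA` for all-N input. Group comparisons are one-tailed
Welch t-tests (on log2 values for lengths); two zero-variance groups with
equal means return p = 0.5 by convention with a warning. ChIP signal is
RPKM (`count / ((length/1000)(libsize/1e6))`), quantile-normalized across
samples with ties averaged (tied values receive the mean of their tied
ranks' target quantiles), then standardized to mean 0 and sample (n−1) sd 1
within each event's exon–intron–exon triplet per sample — removing the 5′→3′
polymerase decay before retained and spliced events are compared. Standardizing per
event-triplet or per region across samples are both defensible readings of
"per event"; per-event pooling is the default, `scope = "region"` the
alternative. Note the quantile-normalization identities (identical sorted
columns, idempotence) hold exactly only for tie-free data.

The uORF test keeps uORFs shorter than 201 bp, computes per line the
proportion of increased-ΔPSI introns overlapping ≥ 1 uORF and the same for
decreased introns, logit-transforms with the continuity correction
`p' = (x + 0.5)/(n + 1)` (proportions of 0 or 1 occur at small per-line counts), and runs a paired
one-tailed t-test across lines (alternative: increased > decreased). Because
the uORF overlap of a given intron is a genomic constant, lines are not
independent replicates of it — the paired test's information is bounded by
the number of distinct recurrent events, which is why the power analysis
in the acceptance suite uses several hundred planted events.

## The synthetic world

The generator (`sim_config()` defaults in parentheses) emulates:

- **Gene models** (200 genes) on one synthetic chromosome: 2–8 exons,
  lognormal exon (~250 bp) and intron (~100 bp, heavy tail) lengths,
  1–4 isoforms with `transcript = 5′UTR + CDS + 3′UTR` exactly; the CDS is
  shared within a gene (UTR isoforms of one ORF), 5′UTRs vary widely. Each
  multi-isoform gene's 3′UTR set is built to fall deterministically into
  one of the three mechanism classes, with frequencies matching the class
  proportions reported for the fly annotation this design emulates
  (387 : 1138 : 2208 of 3733 multi-isoform genes).
- **Isoform ratios** (38 lines × 2 conditions): Dirichlet draws around a
  gene mean with concentration 60 — the precision of ratio estimates at
  ~200 assigned reads plus moderate inter-line variation. Responders (30%
  of genes) give their longest-5′UTR isoform a baseline mean usage drawn
  from (0.25, 0.4)·(2/K) and add exactly `responder_utr5_shift = 0.1` usage
  after infection, other isoforms scaling down; concentration is multiplied
  by 0.95 in the infected state. This construction was chosen over a
  "random baseline, proportional shift" design after analysis showed the
  latter plants effects of arbitrarily small size, which no threshold-gated
  test chain can recover at a stated power: the absolute usage gain bounds
  the planted effect size away from zero, the sub-uniform baseline makes
  the shift entropy-raising for every isoform count, and the near-neutral
  dispersion keeps the homogeneity gate from rejecting true responders.
  The concentration reduction is kept mild for the same reason: a Dirichlet
  mean shift toward evenness already raises dispersion
  (`Var ∝ 1 − Σm²`), and a strong extra reduction makes the planted
  responders fail the homogeneity prerequisite by construction.
- **Retention counts** (500 events): coverage Poisson(50) per event and
  sample — the simplest over-dispersion-free model consistent with
  binomial read sampling — `k_r ~ Binomial(n, PSI)`. 20% of events carry
  `ΔPSI = +0.4/−0.4` (62% up, the observed 535:331 direction ratio), half
  of them in every line, the rest in a random ~30% of lines. Baseline PSI
  is Beta(2, 5) for null events and uniform on (0.05, 0.45)/(0.55, 0.95)
  for up/down-planted events so the planted delta is realisable without
  heavy clipping.
- **Variants** (60,000, of which 6,000 sQTLs): background uniform over gene
  bodies ± 10 kb, allele frequencies from a low-frequency-skewed spectrum
  (0.5·Beta(0.7, 2)); 20% of sQTLs are placed within 100 bp upstream of a
  random splice donor, and all sQTLs have their element-membership odds
  multiplied by 1.15. Because donor windows lie inside element-dense gene
  bodies, the observed element-overlap z reflects both plants together;
  the sQTL sizes (6,000/60,000) were set so the 1.15 odds multiplier alone
  is comfortably above the 3-sd detection bar.
- **Sequences and elements**: uniform base composition at GC 0.43 per gene
  body; the element catalogue is a fixed, deterministic set of 330
  hexamers (every 12th of the lexicographic enumeration — the same per-base
  coverage as a published enhancer set of that size, without shipping one).
- **uORFs**: `uorf_enrichment` is defined as the multiplier on the odds
  that an intron overlaps ≥ 1 uORF, and the generator realizes that
  definition exactly — the overlap indicator is drawn per intron (base rate
  0.25; enriched for planted increased-retention introns), planted uORFs
  sit fully inside their intron and under the length filter, and background
  uORFs are confined to exons. Anything looser (uniform placement) dilutes
  the planted odds through incidental overlap and makes the stated
  multiplier unrecoverable.

What the generator does **not** emulate: raw reads, alignment or
quantification error (ratios are true Dirichlet draws, not estimates),
linkage disequilibrium or genotype structure beyond allele-frequency
spectra, overdispersed coverage, multi-chromosome genomes, per-line indel
length adjustments, and correlated gene regulation. A green
parameter-recovery test therefore establishes that the statistics recover
the effects they were designed for under their own assumptions — not that
those assumptions hold in any particular dataset.

## Determinism and seeds

Every generator derives fixed offsets from `config$seed` and restores the
caller's RNG state afterwards; identical seeds give bit-identical objects
and written files. The retention truth (which introns are planted) is
derived from the seed alone, so the variant/uORF generator and the count
generator agree on the planted set without sharing state.

## Known limitations

- The Savage–Dickey BF saturates (numerically explodes) for well-separated
  posteriors; treat large values as categorical evidence.
- The G-test's chi-square reference is conservative on heterogeneous gene
  sets (see above); the permutation null proportions themselves are
  returned so users can form fully permutation-based judgements.
- The homogeneity permutation test runs slightly liberal below ~8 samples
  per group.
- The distance test shares one permutation draw across genes for speed;
  p-values remain marginally valid and genes remain exchangeable, but
  extreme joint statements across genes (e.g., the minimum p) inherit the
  shared draw.
- sQTL discovery itself is out of scope: sQTL flags are inputs.
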