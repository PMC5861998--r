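---
title: "Models and methods behind morphoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind morphoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscan)
```

# Scope

Antisense morpholino oligomers (MOs) are 23--25-base neutral-backbone
oligonucleotides used to knock down genes in embryos, typically by
hybridizing the translation start or a splice site of their target
pre-mRNA. Two side effects complicate their use: an innate-immune
transcriptional response whose intensity grows with the GC content of the
injected oligomer, and widespread off-target mis-splicing at transcripts
that happen to carry short stretches complementary to the MO. morphoscan
packages the computational machinery needed to study both effects:

* ungapped antiparallel complementarity scanning with wobble-aware run
  extension (`scan_for_offtargets`, `longest_complementary_run`);
* annotation-free intron clustering from split-read junction counts,
  percent-spliced-in (PSI) quantification, and per-cluster
  differential-splicing tests (`cluster_introns`, `compute_psi`,
  `test_differential_splicing`);
* enrichment statistics for MO complementarity and transcript decay at
  mis-spliced junctions against bootstrap and Mann-Whitney nulls
  (`match_vs_missplice_enrichment`);
* 1:1 hybridization kinetics for biolayer-interferometry-style sensorgrams
  (`fit_kinetics`) and the injected-dose concentration calculator
  (`injection_concentration`);
* a synthetic-data generator with recorded ground truth
  (`generate_transcriptome`, `plant_offtarget_sites`,
  `simulate_junction_counts`, `simulate_expression`) and an end-to-end
  orchestrator (`run_pipeline`).

The package deliberately stops short of read alignment, annotation-guided
isoform quantification, thermodynamic (nearest-neighbor) hybridization
models, and gene-ontology enrichment; those belong to upstream aligners
and downstream annotation tools.

# Complementarity model

A duplex "run" is a stretch of consecutive paired bases when the MO
(written 5'→3') is laid antiparallel against a target RNA or DNA (also
5'→3'). Watson-Crick pairs are MO A : target U/T, T:A, G:C, C:G. With
wobble pairing enabled, MO G : target U/T and MO T : target G also pair —
guanine pairs thymine or uracil in either duplex orientation, a
non-canonical interaction whose thermodynamic stability is close to
Watson-Crick. The scan is **ungapped**: no bulges or interior loops, which
matches how minimum-inactivating-length arguments about antisense reagents
are framed. Runs live on diagonals of the pairing matrix between the
reversed MO and the target, and a run is *maximal* when bounded by a
non-pairing position or a sequence end.

Design choices worth knowing:

* The reporting threshold (`min_run`, default 8) applies to the
  Watson-Crick run only. The wobble-extended length of the same alignment
  frame is always reported alongside (`wobble_run_length`) but never used
  for thresholding, so wobble evidence can be inspected without changing
  the hit set.
* In `transcriptome` mode only the orientation in which the MO is
  antisense to the transcript is scanned; `genome` mode scans both
  strands and reports minus-strand hits in plus-strand coordinates.
* Overlapping runs on a target are merged and only the maximal run of an
  overlap family is reported; two maximal runs separated by at least one
  mismatch remain distinct hits.
* All coordinates are 0-based half-open internally. The STAR junction
  dialect (1-based inclusive) is converted at the I/O boundary.
* Hit-to-splice-site distance is the gap between the run interval and the
  site (0 when the site falls inside the run); the conventional reporting
  window is 75 bp, and hits outside it are flagged rather than dropped.
* Interspersed single mismatches are not tolerated: the scan records
  consecutive runs only. Alignments mixing mismatches and wobble pairs
  over ~20 bp, which occasionally matter in practice, would need a
  different scoring scheme and are a possible extension.

The packaged `study_morpholinos()` and `study_rna_oligos()` fixtures are
the five MO sequences and four biotin-tagged RNA probes used in the
*Xenopus tropicalis* Brachyury knockdown study this package models; they
drive the worked examples. The 5' poly(A) stretch in the RNA probes is
the linker to the biotin tag and is scanned like any other residue — it
cannot extend complementary runs against the C/G/T-rich MO ends, as the
worked examples confirm.

# Donor-consensus matching

Vertebrate donor splice sites share the motif (C/A)AG|GUAAGU across the
exon|intron boundary. `build_donor_pwm` builds a position weight matrix
from 9-mer donor windows (positions −3..+6) weighted by split-read
support, excluding windows under a support threshold (default 10 reads);
the consensus is the per-column argmax with ties collapsed to IUPAC
letters. The width of 9 is a convention covering the high-information
positions on both sides of the boundary and is configurable.
`mo_consensus_match` reports how many consecutive bases of an MO pair the
consensus treated as RNA — splice-blocking MOs designed against real donor
sites typically pair the *consensus* over 7 bases, which is why they are
predisposed to splice-related off-target effects.

# Intron clustering, PSI, and the differential test

Junctions (introns defined by split reads) are clustered by shared donor
or acceptor coordinates per contig and strand, after removing introns
longer than 0.5 Mb; clusters need at least 7 supporting reads in total.
Junctions whose strand is unknown cluster separately from stranded ones
at the same coordinates. PSI is a junction's count divided by its
cluster's total in that sample — absent (`NA`), not zero, when the
cluster has no reads in that sample. For testing, a junction must carry
at least 7 reads in *every* sample of *every* condition; junctions that
fail stay in PSI denominators so PSI remains a usage fraction of the
whole cluster. These thresholds (7 cluster reads, 0.5 Mb, 7 reads per
sample, CPM > 1, background of ≥ 20 reads) are the defaults of the
annotation-free splicing analysis the package models, and all are
configurable arguments.

The per-cluster test models per-sample junction counts as
Dirichlet-multinomial with a cluster-specific concentration θ estimated
by maximum likelihood (usage proportions via softmax, θ on the log
scale, BFGS). The null shares one usage vector across conditions; the
alternative gives each condition its own vector with a common θ; twice
the log-likelihood-ratio is referred to a chi-squared distribution with
(C−1)(J−1) degrees of freedom, and Benjamini-Hochberg FDR is computed
across tested clusters. When a condition has fewer than two replicates
the test falls back to a G-test on pooled counts. Single-junction
clusters are skipped with a flag. The minimal/maximal PSI events of a
significant cluster follow the rule used for heatmap reporting: the max
event is the junction with the largest condition-mean PSI change
(leftmost on ties); the min event is the most negative change only when
it lies at least 1.5 cluster SDs below the mean change, and may be
absent. The 1.5-SD rule is evaluated within each cluster's change
distribution (an across-cluster variant would also be defensible; the
within-cluster reading keeps the rule local and is what the reporting
convention suggests).

**Calibration.** The chi-squared reference is asymptotic. With 10
replicates per condition the null p-values are uniform to within what a
Kolmogorov-Smirnov test can detect at a thousand clusters (this is the
package's uniformity property test). With 3 replicates per condition —
the design the synthetic generator mirrors — the test is mildly
anticonservative in the tail (roughly twice the nominal rate at p =
0.05), a known small-sample behavior of likelihood-ratio tests with
estimated concentration parameters. BH-adjusted discovery fractions on
null data remain at or below the nominal FDR in the package's acceptance
checks, but single-cluster p-values near conventional thresholds should
be read with this inflation in mind; a parametric bootstrap would be the
remedy where exactness matters.

TMM normalization follows the standard trimmed-mean-of-M-values recipe
(30% trim on M-values, 5% on A-values, precision weights, reference =
sample whose upper quartile is closest to the mean upper quartile,
factors normalized to geometric mean 1) and agrees with the edgeR
implementation to 1e-6 in the test suite; the CPM filter keeps junctions
averaging more than one count per million.

# Enrichment statistics

Two questions are asked of the blocked (mis-spliced) junction set against
a background of active junctions (≥ 20 split reads by default): whether
blocked junctions carry longer consecutive MO matches (with ≥ 10
consecutive bases as the headline feature), and whether their genes'
transcript levels are more often reduced below 67% of control. Each
feature is summarized as observed versus expected counts — the
expectation from 1,000 bootstrap resamples (with replacement, same set
size) of the background — plus a Mann-Whitney rank test on the underlying
values. The bootstrap is seed-deterministic and serialized with its seed,
resample count, and thresholds. Sampling *without* replacement would give
slightly narrower intervals; with-replacement resampling is the
conventional bootstrap and the default. The "reduced below 67%" feature
is evaluated on the fold-change point estimate, not its confidence
interval, matching how transcript-level color bands are usually defined.
Raw and BH-adjusted p-values are reported across the feature family.

`mann_whitney_u` enumerates the exact null distribution of U (midranks
for ties) when the pooled sample size is at most 12, and otherwise uses
the normal approximation with tie and continuity corrections. The exact
path is enumerated rather than delegated so that tied data still get
exact p-values; the test suite checks it against an independent
pair-counting permutation oracle and the approximation against
`wilcox.test` and Monte-Carlo permutations.

`transcript_foldchange` is deliberately plain plumbing for synthetic
matrices: median-of-ratios size factors, fold change of normalized
condition means, a Wald-style p-value (normal reference on the log2-scale
two-sample statistic), BH FDR, and the ≥ 1.5-fold / FDR ≤ 10% and < 67%
flags. Genes averaging ≤ 7 raw fragments in the control condition are
removed, mirroring the count floor used for differential-expression
analyses of embryo transcriptomes. It stands in for a full
negative-binomial differential-expression model, which is out of scope.

# Hybridization kinetics

The 1:1 interaction model: association follows
$R(t) = R_\mathrm{eq}\,(1 - e^{-k_\mathrm{obs} t})$ with
$k_\mathrm{obs} = k_\mathrm{on} C + k_\mathrm{off}$ and
$R_\mathrm{eq} = R_\mathrm{max}\, C / (C + K_d)$; dissociation decays as
$e^{-k_\mathrm{off} t}$. Association and dissociation phases are fitted
by unweighted nonlinear least squares (`minpack.lm`) with self-starting
values: baseline from the first response, amplitude from the range, rate
from the log-linearized early slope, and bounded restarts over rate
scales. $k_\mathrm{on}$ is the ordinary-least-squares slope of
$k_\mathrm{obs}$ against concentration (the intercept re-estimates
$k_\mathrm{off}$ and is reported as a diagnostic); the kinetic $K_d$ is
$k_\mathrm{off}/k_\mathrm{on}$ exactly as stored. The equilibrium $K_d$
is fitted from plateau responses via $R = R_\mathrm{max} C/(K_d + C)$;
plateau-isotherm fitting was chosen over full-trace global fitting for
transparency — on noiseless simulated data the two $K_d$ routes agree to
1e-6 relative, which is the package's self-consistency check.
$k_\mathrm{obs}$ must be non-decreasing in concentration; violations
warn. Mass-transport limitation and bivalent binding are outside the 1:1
model.

`mo_molecular_weight` uses a flat 340 Da per morpholino residue (a
25-mer is 8,500 Da); per-base monomer masses can be supplied. Under this
convention `injection_concentration(0.75, 25, 0.8)` — 0.75 ng of a
25-mer into a 0.8 mm spherical zygote — gives ≈ 329 nM, reproducing the
~300 nM working estimate for an effective knockdown dose, and that
concentration sits more than a thousandfold above sub-nanomolar
target-site affinities: the kinetic argument for why off-target
hybridization at 8-base sites is essentially unavoidable at working
doses.

# The synthetic-data generator

The generator emulates the statistical structure of a morphant
RNA-seq experiment, not its sequence content:

* **Transcriptome** — random multi-exon pre-mRNAs (2--4 exons of 80--250
  bp, introns of 150--600 bp, background GC 0.40) whose donor 9-mers are
  sampled around the CAGGTAAGT consensus at 0.85 per-column fidelity and
  whose introns end in AG. Splice-site positions are recorded as truth.
* **Planted off-target sites** — exact reverse complements of MO
  subsequences substituted at requested positions, optionally extended
  by wobble-compatible bases; flanks are set to non-pairing residues and
  the realized run is re-verified by the scanner, so the planted truth
  is guaranteed, not merely intended.
* **Junction counts** — each intron becomes a two-junction cluster
  (canonical donor plus a cryptic donor sharing the acceptor).
  Per-sample usage is Dirichlet around the condition mean
  (concentration 200), cluster totals are negative binomial (dispersion
  0.02) at the configured depth, and counts are multinomial within the
  cluster — exactly the Dirichlet-multinomial family the test assumes.
  In the MO condition, canonical usage at blocked donors drops on the
  logit scale by `beta_block * plogis(run_length - 8) * dose`, so
  blocking strength grows with complementarity length and falls
  monotonically with dose reduction; a fixed PSI drop can be requested
  instead for power studies. Intron retention is not represented as
  such; the cryptic junction absorbs the rerouted mass (a retention
  pseudo-junction would be an alternative encoding).
* **Expression** — immune genes get a log2 fold change of
  `beta * max(0, gc - 40)/25 * (dose/8) * stage_weight` plus Gaussian
  noise, encoding the empirical hinge at 40% GC, the dose scaling at the
  8 ng single-MO assay dose, and intensification with developmental
  stage (weights 0.5 / 1 / 1.5 for neurula, mid- and late tailbud). The
  slope is illustrative, not a measured quantity. Mis-spliced genes can
  receive a transcript decay factor. Three replicates per condition
  mirror the biological-triplicate design.

The replication tightness (Dirichlet concentration 200, NB dispersion
0.02, 85% canonical usage) describes deeply sequenced, well-replicated
junction data; noisier settings are a function argument away. What
passing tests on these data do **not** show: robustness to alignment
artifacts, annotation errors, overlapping gene structures, or biological
usage heterogeneity beyond the Dirichlet — real data are messier than
this generator in all four respects.

**Problem sizes.** The packaged checks run the null type-I study on a
500-gene transcriptome (≈ 1,000 clusters), the power study on 30 planted
clusters at a fixed 0.3 PSI drop and depth 200 (recovering ≥ 90% at FDR
10%), kinetic recovery across truths from 0.1 to 100 nM at 1% noise, and
scanner-oracle equivalence on 100 random sequences up to 2 kb. These
sizes were chosen to make the Monte-Carlo assertions stable at test
time.

# Interfaces

MOs are accepted as FASTA or `name<TAB>sequence` text
(`read_sequences`); hits export as BED6 plus a TSV with wobble length and
splice-site distance (`export_hits`); junction tables read from
STAR-style or BED-like TSVs (`read_junction_table`); sensorgrams read
from CSV (`read_sensorgrams`); every truth record serializes to JSON with
its seed (`write_truth`). The exported functions compose the whole
pipeline (`run_pipeline` shows the canonical chaining), so scripted use
replaces a dedicated command-line binary.

```{r example}
mos <- study_morpholinos()
rnas <- study_rna_oligos()
longest_complementary_run(mos$t_splice, rnas$t_target)$length
longest_complementary_run(mos$t_splice, rnas$dtymk_offtarget)$length
mo_consensus_match(mos$cMO)
round(injection_concentration(0.75, 25, 0.8))
```

# Known limitations

* The differential test's chi-squared reference is anticonservative at
  2--3 replicates per condition (see Calibration above).
* The scan is ungapped and mismatch-free; mixed mismatch/wobble
  alignments are not scored.
* The equilibrium fit assumes plateau responses were reached; truncated
  association phases bias $K_d$ upward.
* The generator's two-junction clusters cannot express multi-way
  competition among more than one cryptic site per intron.
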