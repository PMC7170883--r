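---
title: "Methods: models, parameters and design choices in hearvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in hearvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hearvar` implements a multi-level design linking genetic variation in a
hearing gene to language outcomes: pedigree-based variant prioritization,
copy-number consensus calling, cohort phenotype construction, additive and
gene-by-hearing interaction association, variance-component gene-based
testing, enrichment statistics, and mouse behavioural scoring. This
vignette is the package's account of the models behind each step, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish.
The exported functions (plus this vignette) are the package's interface;
every analysis below is a few function calls on plain data frames read from
standard formats (VCF, BED, PED, TSV).

## Coordinates

All internal intervals are 0-based half-open `[start, end)`, the BED
convention; VCF and SNP-array positions are 1-based. The conversion is
centralized in `vcf_pos_to_interval()`: a variant at position `p` with
reference allele of length `L` occupies `[p − 1, p − 1 + L)`. Keeping a
single audited conversion avoids the classic off-by-one family of bugs;
round-trip tests on both formats pin the convention down.

## Allele-sharing scan

Under a fully penetrant dominant model, every affected pedigree member
carries one copy of the founder haplotype. At a biallelic SNP this implies
an *obligate sharing* condition: some allele must be present in every
affected genotype. `snp_sharing_compatible()` tests exactly that, and
`sharing_scan()` smooths the per-SNP indicator into maximal runs of at
least `min_run` (default 3) consecutive compatible SNPs, reported as
intervals spanning the outermost compatible SNPs.

This deliberately replaces multipoint identity-by-descent inference. The
scan's role in the pipeline is only to supply an inclusion mask for the
variant cascade, so exact IBD probabilities buy nothing; an explicit
per-SNP test is fully auditable and testable against planted truth.
Two consequences of this design are worth stating:

- **Missing genotypes are permissive.** A missing call imposes no
  constraint, and a fully missing SNP is vacuously compatible. A filter
  mask should not lose the causal region to missingness; the cost is that
  regions may extend slightly beyond the true haplotype.
- **Unaffected (married-in) genotypes are ignored.** Unaffected members
  cannot refute sharing *among the affecteds*; any rule that lets an
  unaffected homozygote veto a candidate allele either mis-classifies
  monomorphic reference sites as incompatible or breaks monotonicity
  (masking one genotype could then flip a compatible SNP to incompatible).
  Using affecteds only keeps the test monotone under genotype removal —
  a property the test suite fuzzes directly.

Boundaries differ from a likelihood-based multipoint analysis by
construction; with the default marker density (1 SNP / 50 kb in the
simulator) the planted region is recovered with Jaccard ≈ 0.98. Recovery
is scored against the best-matching reported region
(`region_recovery_jaccard`): with `min_run = 3`, short spurious runs
elsewhere in the genome are expected by chance (roughly half of random
SNPs are compatible in a five-affected pedigree) and are harmless to the
cascade, so they should not dilute the recovery score.

## CNV consensus

Sample-level QC (`cnv_sample_qc`) applies the standard intensity metrics:
LRR SD < 0.35, BAF drift < 0.002 and |waviness| < 0.04 for the
confidence-score caller, LRR SD < 0.3 and BAF SD < 0.15 for the
Bayes-factor caller. All inequalities in this module are strict, taking
the stated `<`/`>` bounds literally; boundary values fail, and every
violated criterion is named in the output.

`consensus_calls()` implements the high-confidence rule: a consensus
requires one call from each caller, same state, each with ≥ 3 supporting
SNPs and score strictly above 10 on its own caller's metric (the
conservative reading of "confidence value or log Bayes Factor of > 10" —
both members must pass), reciprocal overlap ≥ 50 % each way, interval =
innermost boundaries. When overlaps are many-to-many, pairs are assigned
greedily by descending product of the two overlap fractions with a
leftmost tie-break, so the output is deterministic and independent of
input order; each call enters at most one consensus. "Spanning" the
centromere or telomeres is implemented as *any overlap* with a
user-supplied mask BED — stricter than a literal "span", and configurable
by editing the mask. The whole operation is verified against an
independent all-pairs brute-force filter on hundreds of random call sets.

## Variant prioritization cascade

`shared_variants()` keeps variants carried (≥ 1 alternate allele) by both
sequenced members with PHRED site quality ≥ 20 (boundary included).
`filter_cascade()` then applies, in a fixed order with per-stage
accounting: position inside a shared region; consequence in {frameshift,
missense, canonical splice, stop/start gain/loss} ("non-synonymous" maps
to the missense class; canonical splice sites come from the annotation
table, not recomputation); absence from each frequency database in turn,
where "absent" means no record *or* a recorded MAF of exactly 0. Database
matching is by exact `(chrom, pos, ref, alt)` key — positional matching
would discard novel alleles at known sites. Counts are non-increasing and
the final set equals the one-shot conjunction of all predicates
(order-independence and oracle equality are property-tested).

## Cohort phenotypes

Inclusion filters (`cohort_filter`) keep children of British ethnicity
born after 32 weeks gestation with birth weight above 1500 g and at least
one analysis phenotype present; the common-variant mode additionally
excludes nonverbal IQ below 65 and any air-conduction threshold above
40 dB HL (overt pathology that would confound language association).
Boundaries are strict and missing filter fields exclude, which makes the
filter idempotent.

Derived hearing phenotypes: `min_low()` is the across-ear minimum of the
0.5 kHz air-conduction threshold; `min_mid()` averages 1/2/4 kHz per ear
(complete triples only) before taking the across-ear minimum — the
average-then-minimum order matches the phenotype's definition as a
per-ear hearing level.

DLD classification (`classify_dld`): cases score ≤ mean − 1 SD on
comprehension, or < mean − 1 SD on both checklist fluency and syntax,
without autism-spectrum evidence and without hearing impairment (any
1/2/4 kHz threshold above 20 dB HL — the only operational impairment
definition available). Controls score strictly above the cohort mean on
all three language measures with nonverbal IQ > 80 and no ASD/SEN flag.
"Above expected levels" is operationalized as strictly above the cohort
mean — the least arbitrary anchor where no quantitative definition is
given; the z-scoring statistics are computed on the filtered cohort and
can be supplied explicitly. Individuals missing a defining measure are
excluded rather than guessed, and the three labels partition the cohort.

Carrier contrasts (`carrier_contrast`) report the mean difference,
Cohen's d with *pooled* SD (the two-group default; the d formula behind
published values of this kind is often unstated, so d is verified
structurally — sign, affine invariance — rather than against any printed
value) with a normal-approximation 95 % CI, and for binary measures the
relative risk with a log-scale CI; a zero non-carrier risk leaves the RR
undefined and reported as such.

## Association statistics

`snp_qc()` applies sample filters first (call rate ≥ 95 %, autosomal
heterozygosity within mean ± 3 SD), then SNP filters (MAF ≥ 5 %,
missingness ≤ 5 %, Hardy-Weinberg chi-square p ≥ 5 × 10⁻⁷, and — when
case/control labels are given — no differential missingness at Fisher
exact p < 10⁻⁵; that threshold is unstated in the design and defaults to
the common array-QC convention, configurable). A printed "call rate of
< 5 %" exclusion is read as missingness > 5 %: the literal reading would
*retain* almost entirely missing SNPs. HWE uses the 1-df chi-square,
which is analytically checkable and amply sharp at a 5 × 10⁻⁷ threshold.

Tag selection (`greedy_tag`) uses composite LD — squared Pearson
correlation of dosages, no phasing — and a greedy cover: repeatedly pick
the SNP tagging the most uncovered neighbours at r² ≥ 0.8 (position-order
tie-break), so that every non-tag SNP is tagged and no two tags are
mutually redundant; both properties are re-verified post hoc on every
output.

`assoc_additive()` is the slope test of trait on dosage (OLS, or logistic
for binary traits, with perfect-separation flagging); `fit_interaction()`
fits `Y = b0 + b1·ADD + b2·COV1 + b3·ADD×COV1 + e` by OLS and reports all
four Wald tests — `b3` is the gene-by-hearing signal. All p-values are
two-sided Wald with no genomic control; multiple testing uses Bonferroni
within association families (`bonferroni()`), and Benjamini–Hochberg only
inside enrichment (`enrich_fisher_fdr`, one-sided Fisher exact per term).

### The variance-component gene test

`skat_test()` aggregates weighted variant effects within a gene:

\[ Q = r^\top G W^2 G^\top r, \]

with `r` the residuals of the null model (intercept + covariates), `G` the
dosage submatrix (mean-imputed), and `W = diag(w(MAF))`, default
Beta(1, 25) density weights (the rare-variant convention; flat weights are
available and are what the single-variant oracle test uses). Under the
null, `Q ~ Σ λᵢ χ²₁` with λ the eigenvalues of `σ̂² · W Gᵀ P₀ G W`
(an m × m problem, so cost scales with variants, not samples). The
p-value matches the first four moments of that mixture to a (non)central
chi-square (Liu-style moment matching) rather than integrating the exact
characteristic function: deterministic, dependency-free, and accurate at
the tail probabilities used here (null type-I error is verified by
simulation to be ≈ 0.05 at α = 0.05). Below 50 samples, or if the
approximation fails, a seeded residual-permutation p-value is used
instead. With a single variant and flat weights the statistic reduces
analytically to the score test of the additive model — the package's
dual-route check. Rare/common subsetting (`maf_range`) supports
MAF ≤ 1 % / ≥ 5 % analyses.

`power_variance_explained()` gives power for a variant explaining a
fraction r² of trait variance from the 1-df noncentral chi-square with
`ncp = n·r²/(1 − r²)`, cross-checked against its own seeded simulation.
Published power figures for this design came from an unnamed method and
are not asserted; the two internal routes agree with each other.

## Mouse behavioural scoring

`attenuation_scores()` computes, per subject × task × day × cue cell,

\[ \mathrm{ATT} = 100 \cdot \frac{\text{mean cued ASR}}{\text{mean uncued ASR}}, \]

lower meaning better cue detection; equal means give exactly 100, the
score is invariant to rescaling a cell's amplitudes, and a zero uncued
mean is reported as undefined rather than infinite. `group_compare()`
averages to one score per subject, then runs a one-way ANOVA across
genotypes, or — mirroring the use of simple-tone detection as a hearing
covariate for complex tasks — the group F after the covariate in
`score ~ covariate + group` (Type-II sums of squares). The full
repeated-measures ANCOVA machinery (day × cue within-subject
decomposition, sphericity corrections) is intentionally out of scope:
the package's claims concern between-group effects on synthetic data,
and cell-averaged scores are sufficient and far more testable. A
zero-variance or group-collinear covariate is rejected as a singular
design rather than silently dropped. Directional (one-tailed) contrasts
are left to the caller, since the tail convention per contrast is not
fully specifiable in advance.

`usv_filter()` retains syllables with mean frequency in [35, 110] kHz and
duration in [8, 200] ms (inclusive bounds, the literal reading of
"between") and then removes *both* members of any adjacent pair whose
inter-syllable gap is under 5 ms — the upstream segmenter's behaviour for
such pairs is unspecified, and removing both is the symmetric choice
(`gap_removal = "later"` keeps the earlier one). Gaps are rounded to
microsecond precision before the comparison so floating-point onset
arithmetic cannot blur the 5 ms boundary. Because surviving neighbours'
gaps only grow when syllables are removed, the filter is idempotent.
`usv_summaries()` reports per-genotype means ± SEM of frequency, duration
and volume collapsed across the eight syllable categories.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of `(seed, parameters)` and returns the
planted truth alongside the data, so recovery is scorable exactly.

- `sim_family()`: 12-member, 4-generation pedigree, all descendants of the
  first founder affected; 7 genotyped members (5 affected, 2 married-in).
  One founder haplotype, no recombination within the planted region,
  uniform 50-kb marker spacing, marker MAF uniform on [0.3, 0.5] (high
  enough that incompatible SNPs arise often outside the region and
  spurious runs stay short). The sequencing fixture plants one causal
  stop-gain plus decoys that each fail exactly one cascade predicate.
- `sim_cnv()`: planted consensus pairs and single-criterion decoys in
  separate 2-Mb slots, plus a mask decoy.
- `sim_cohort()`: Hardy-Weinberg genotypes; hearing threshold
  `N(9.96, 5.81²)` dB HL (the non-carrier scale of the motivating data)
  with a +1.2 dB carrier shift at carrier frequency 0.85 %; vocabulary
  from the interaction model with defaults `b0 = 200`, `b1 = 0`,
  `b2 = −0.5`, `b3 = −0.15`, residual SD 20, truncated to the instrument
  range [0, 246]. The default location/noise keep truncation below ~1 % so
  ordinary least squares remains calibrated for the coverage tests (the
  generator warns when parameters push truncation above 10 %, where the
  linear analysis model is knowingly misspecified). Correlated language
  measures (ρ ≈ 0.4–0.5 with vocabulary) feed the DLD classifier; ear-level
  thresholds are constructed so `min_low()` recovers the planted value.
  Default n = 2000 is a desk-scale stand-in for a several-thousand-child
  cohort; the acceptance battery raises it to 5000 for coverage runs.
- `sim_ppi_usv()`: 12/12/11 subjects per genotype; log-normal trial
  amplitudes; a subject-level attenuation target (baseline 55, SD 8) with
  planted deficits of 12 points (≈ 1 between-subject SD) for heterozygotes
  on the low-frequency task and knockouts on the high-frequency task, the
  frequency-specific double dissociation of interest; syllable tables with
  planted per-genotype frequency/duration/volume shifts plus out-of-band,
  out-of-duration and close-pair decoys.

What passing these tests shows: the implementations compute their defined
statistics correctly, the cascade/consensus logic is exactly the stated
predicate logic, and the estimators are calibrated (CI coverage, type-I
error, null uniformity) *under the generators' models*. What it cannot
show: behaviour under real-data pathologies the generators omit —
linkage-disequilibrium structure from a reference panel, genotyping batch
effects, informative missingness, pedigree misspecification, non-normal
trait tails, or the severe ceiling of a real vocabulary checklist. Results
on real cohorts additionally depend on upstream callers and annotation
engines that this package consumes but does not reimplement.

## Numerical conventions

- Inequalities follow their stated symbols; boundary behaviour is tested
  explicitly (gentrain 0.5 retained, QUAL 20 retained, waviness 0.04
  failed, score 10 failed, 32 weeks excluded, 35 kHz retained, 5 ms gap
  retained).
- Ties are broken deterministically (leftmost pair in CNV pairing,
  position order in tag selection), so outputs are order-independent.
- Degenerate inputs error loudly and name the offender: absent samples,
  unannotated variants, constant dosages, rank-deficient designs,
  zero-polymorphic gene sets, cells without both trial conditions.
- Problem sizes in the test suite and acceptance battery (100 cascade
  fixtures, 200 call sets, 100 family replicates, 200 × n = 5000 coverage
  fits, 2000 SKAT null replicates, 2000 null SNPs) were chosen as the
  smallest scales at which the Monte-Carlo error of each check is
  comfortably below its acceptance margin.

## Known limitations

Phasing, recombination modelling, LOD scores and X-chromosome handling are
out of scope for the sharing scan; the CNV module consumes caller output
and does not touch LRR/BAF signals; imputation, population-structure
correction, mixed models and meta-analysis are not provided; the gene test
implements the plain variance-component statistic (no optimal-rho
combination with burden); telomere extents must be supplied via the mask
file.
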