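---
title: "Methods: late mismatch-response extraction and genetic association"
author: "latemmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: late mismatch-response extraction and genetic association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latemmr)
```

## The endophenotype and the analysis chain

In a passive auditory oddball paradigm a frequent *standard* syllable is
occasionally replaced by a rare *deviant*. The evoked mismatch response
(MMR) — the deviant-minus-standard difference wave — indexes automatic
auditory discrimination. Children with normal spelling show negativities
near 200 ms and 400 ms after onset; poor spellers instead show a positivity
of up to about 5 µV between 200 and 600 ms. The package quantifies the
**late component of the MMR** as the mean of the difference wave over an
anterior region of interest (F3, Fz, F4) in the half-open window
[300, 600) ms, in µV, and treats this scalar as a heritable endophenotype
that sits between candidate genetic variants and the spelling phenotype.

The chain is: simulate (or read) continuous EEG → reduce to per-subject MMR
amplitudes → genotype QC → per-SNP additive regression with FDR control →
unweighted polygenic risk score (PRS) and classification comparison →
power. Each stage is exposed as ordinary functions returning classed S3
objects, plus a pipeline driver (`run_pipeline()`) that sequences them and
writes diff-able TSV artifacts.

## The oddball design and its simulation

A block presents 600 stimuli — 510 standards (85%) and 90 deviants (15%) —
pseudorandomized so that **at least two standards separate any two
deviants**, with offset-to-onset inter-stimulus intervals drawn uniformly
in [1450, 1750] ms. Block 1 uses /ga/ (409 ms) as standard and /pa/
(266 ms) as deviant; block 2 swaps the roles. These are the generator
defaults; smaller designs are available through the same arguments and are
what the test-suite uses (20–60 trials per block, 1–2 blocks, 2–12
subjects) to keep runtimes in seconds while exercising identical code
paths.

Deviant placement distributes the "free" standards (those beyond the
mandatory spacing) uniformly over the gaps around deviants, which makes the
feasibility bound explicit: at most `floor((n_total + s) / (s + 1))`
deviants fit with spacing `s`. Infeasible requests error with that bound.

Stimulus onsets are snapped to the 4-ms grid of the decimated (250 Hz)
recording, with the ISI jitter drawn 2 ms inside its bounds so realized
ISIs still respect [1450, 1750] ms. This is a deliberate numerical choice:
it makes epoching alignment exact, so noiseless simulations round-trip
through the full reduction to below 1e-9 µV and linearity/additivity
properties can be asserted at machine precision rather than "approximately".

### ERP composition

Every trial receives a common auditory response; deviant trials on the
frontal ROI channels additionally receive the difference component:

* control morphology: Gaussian negativities centred at 200 ms (σ = 40 ms)
  and 450 ms (σ = 80 ms);
* poor-speller morphology: a Hann-windowed positivity on [200, 600) ms with
  peak `poor_positivity_uv` (default 5 µV);
* genotype effect: for each causal SNP, `dosage × per_allele_shift_uv` is
  added as a **rectangle over exactly [300, 600) ms**. Because the
  quantification window coincides with the rectangle, the injected shift of
  the window mean equals the additive genetic effect by construction — the
  simulation realizes the additive model it is meant to test, and the
  default shifts (+3.0, −1.8, −1.7, −1.5, −1.4 µV per allele for five
  causal SNPs) match the magnitude of reported candidate-SNP effects on the
  late MMR.

Background noise is spectrally shaped (1/f by default) Gaussian noise at
12 µV RMS per channel plus an optional 10 Hz component; mastoids carry
noise only. Artifacts are ±150 µV boxcar transients of 200–400 ms injected
into a configurable fraction of trial windows (default 20%, matching the
observed exclusion rates); their amplitude guarantees detection by the
±80 µV criterion, so rejection *recall* is a sharp, testable property. What
the generator does **not** attempt: realistic source-space topography, eye
movements/EOG, inter-channel noise correlation, or the attention
manipulation — so passing tests certify the statistical machinery, not
physiological fidelity.

### Genotypes and phenotypes

Dosages are drawn per SNP as Binomial(2, p) — Hardy-Weinberg proportions at
risk-allele frequency p (default 0.3, the risk allele oriented to the minor
allele) — with uniform missingness up to 10%. The spelling phenotype is a
latent score (optional genetic liability — by default −0.2 per risk allele
summed over the 20 scored SNPs in the pipeline driver — plus standard
Gaussian noise). Percentiles are computed either within-sample (mid-rank;
default, flags exactly the lowest decile) or against a normal reference
population, which emulates norm-referenced spelling tests where a study
sample can contain more than 10% poor spellers (e.g. 14 of 67). The
liability weight was fixed once at a value giving a modest PRS
discrimination (AUC in the low 0.6s at study size), the regime the method
is meant for.

## ERP reduction

Processing order: re-reference to the mastoid average (A1, A2) → 30 Hz
low-pass → decimation 500→250 Hz → 0.5 Hz high-pass → epoching on
[−200, 1250) ms → baseline correction over [−200, 0) → exclusion of
standards directly following a deviant → artifact rejection → per-condition
averaging → window mean.

**Filters.** Both filters are zero-phase Butterworth (order 4 each way,
forward–backward). The package chose IIR over a windowed-sinc FIR because a
0.5 Hz high-pass at 500 Hz with a −3 dB point controlled to ±10% needs a
kernel of tens of thousands of taps, which is not tractable in a
forward-backward convolution at test scale; a fourth-order IIR achieves the
same controlled response in constant time per sample. Two passes move the
−3 dB point of the cascade off the design cutoff by the factor
`(√2 − 1)^(1/2n)` (≈0.896 for n = 4), so the design cutoff is
pre-compensated analytically and the *realized* −3 dB point — measured from
the squared magnitude response — is attached to every filtered recording
and asserted within ±10% of nominal. The historically reported −3 dB values
of the original acquisition software (26.27 Hz for the 30 Hz low-pass,
0.501 Hz for the high-pass) are treated as validation metadata, not
bit-match targets, since that implementation is unpublished.

**Grids.** All windows are half-open `[start, end)`, times are ms relative
to stimulus onset, and sample indices are 0-based. The epoch sample count
is `floor(span/step)` — 362 samples for [−200, 1250) at 250 Hz — i.e. the
trailing partial step is dropped; [300, 600) then contains exactly 75
samples and [−200, 0) exactly 50.

**Rejection.** Default semantics: a trial is invalid if any channel sample
within any 200-ms window exceeds ±80 µV — for an absolute bound this
reduces to a global amplitude criterion, which is the plain reading of
"above ±80 µV within a sliding window". A peak-to-peak alternative (window
range > 160 µV) is provided for data with slow drifts. Exclusion fractions
are tracked per condition and compared across subjects with a paired t-test
(`compare_exclusion_rates()`), with degenerate zero-variance cases reported
explicitly rather than through a cryptic error.

**Contrast.** The default difference wave pools all valid deviants against
all retained standards across blocks, matching a single per-subject
difference wave; an identity-matched (same-syllable) contrast is available
via `preprocess_config(contrast = "matched")` for analyses that must cancel
acoustic stimulus differences. Whether per-block averaging precedes pooling
is immaterial for the pooled mean only when block trial counts are equal,
so the package pools trials, not block means, and records the trial counts.

**Sliding test.** Group waveform differences are tested in 375 consecutive
3.2-ms windows spanning [0, 1200) ms. At 250 Hz a 3.2-ms window is shorter
than one sample period; windows are therefore defined on the continuous
axis, take the mean of any samples they contain, and inherit the nearest
sample to their centre when empty. This convention reproduces the canonical
375-window count while remaining computable on the 4-ms grid; it is a
documented convention, not a claim about the original computation. Welch's
t is the default (groups of 14 vs 53 are far from variance homogeneity);
the pooled-variance Student variant is a switch.

## Genotype QC and clumping

QC applies, in a fixed order: individual call rate > 0.90 → SNP call rate
> 0.97 → MAF > 0.05 → Hardy-Weinberg equilibrium at α = 0.05 Bonferroni
corrected. The HWE default is the 1-df chi-square without continuity
correction; the conditional exact test is a switch. The Bonferroni m is the
number of SNPs entering the HWE test *in the current dataset*; re-running
QC on filtered output is a no-op except in the boundary case where a
p-value falls between α/m and α/m′ of the shrunken family — with the
packaged panel (27 SNPs) the thresholds differ by < 1e-3 in p, so
idempotency holds everywhere away from that sliver.

LD clumping is the standard greedy procedure: repeatedly index the smallest
association p among unassigned SNPs and absorb all unassigned SNPs with
r² ≥ 0.5 within 250 kb. The index-eligibility p-threshold defaults to 1 so
that an entire candidate panel is clumpable (a GWAS-style 1e-4 index
threshold would retain nothing on a candidate panel). The packaged panel
already lists the 25 *independent* candidate SNPs — the original 30→25
reduction required population LD that the package does not ship — so
clumping is exercised on simulated LD in the tests.

## Association, FDR, and diagnostics

Each SNP is tested by OLS of MMR on dosage adjusted for poor spelling
(optionally also ADD status, for the adjustment comparison), two-sided t
p-values, complete cases per SNP with `n_used` recorded. The candidate
panel (25 SNPs) forms one Benjamini-Hochberg family; the two
MMR-replication SNPs (rs11100040, rs4234898) are adjusted separately,
mirroring their separate replication role. `bh_fdr()` accepts a family size
larger than the supplied vector so published top-hit p-values can be
adjusted within their full family. Influence is screened with Cook's
distance at the conventional 4/n cutoff (configurable), refitting without
flagged points and reporting the effect shift; an exact fit defines D = 0
to avoid the 0/0 in Cook's formula. The QQ confidence envelope uses the
Beta(i, m−i+1) order-statistic quantiles with expectation i/(m+1).

## Prediction

The unweighted PRS sums risk-allele dosages over the candidate-panel SNPs
that carry a literature risk allele — 20 of the 25; SNPs without a reported
risk allele and the two MMR-replication SNPs are excluded — with per-SNP
mean-dosage imputation for missing calls so every subject stays scoreable.
The packaged `risk_allele` column is an explicitly *synthetic* placeholder
(the literature allele table is not redistributed); its structure (which 5
SNPs lack an allele) is what matters for reproducibility of the 20-SNP
score.

Classification of poor spelling is compared across three logistic models —
MMR alone, PRS alone, MMR + PRS — because reclassification statistics
presume fitted risk models; the logistic combiner is the package's choice
where the original combiner is unstated. AUCs are Mann-Whitney with DeLong
intervals (bootstrap optional); continuous NRI uses the standard
`(p_up,ev + p_down,ev)/n_ev + (p_up,ne + p_down,ne)/n_ne` variance and IDI
the paired-difference variance of discrimination slopes. On training data
the combined model's AUC sits at or above the MMR-only AUC even for a noise
PRS (optimism); the tests assert this as a tendency over replicates, never
per run.

## Power

For the F test of one coefficient in a linear model the package solves for
the noncentrality λ at the target power and converts to explained variance
by the calibration `R² = λ/(λ + v)` (`f² = λ/v`). Two solvers: the normal
approximation `√λ = z_(1−α/2) + z_power` and the exact noncentral-F tail;
they agree within 5% for v ≥ 50. The **paper-reproduction preset** is
`u = 1, v = 52` with the normal approximation, which yields 13.1% (α = .05)
and 24.7% (α = .001) detectable explained variance at 80% power, and 18.3%
at α = .01 where 18.2% was printed — no single exact-noncentral-F
configuration reproduces all three printed values, so the preset that
reproduces two exactly and the third within 0.1 pp is shipped and the
residual discrepancy documented rather than asserted away. For prospective
analyses with the actual design (n = 67, SNP + spelling covariate) the
default is `v = 64`.

## Interfaces and reproducibility

EEG interchanges as EDF (16-bit, µV, 1-s records; writer and reader are
in-package) with events as TSV (`onset_ms`, `condition`, `syllable`,
`block`); genotypes as dosage TSV or minimal VCF (GT); phenotypes as TSV;
stage outputs of the pipeline are TSVs plus PDF figures, and a YAML
manifest with MD5 digests makes reruns checkable. All randomness flows from
one root seed through documented child-seed derivation (`child_seed()`), so
any subject/block is independently regenerable. Because EDF quantizes to 16
bits, file round-trips are exact only to the quantization step
(range/65534); exactness properties are therefore stated on in-memory
objects.

## Known limitations

* The simulation is phenomenological: no head model, no electrode
  covariance, no EOG — group and genotype effects enter only through the
  injected difference component.
* The cohort-dependent headline statistics of the motivating study (its
  AUCs, NRI/IDI values, and per-SNP p-values) depend on an unreleased
  67-child dataset; the package reproduces the *procedures* and the
  printed-input quantities (FDR arithmetic, window counts, design counts,
  detectable effect sizes), not those cohort values.
* `hwe_exact_p` enumerates heterozygote counts and is intended for panels,
  not genome-wide use.
* The EDF implementation covers the subset needed here (equal rates, no
  annotations).

## Test problem sizes

The suite simulates small designs (20–60 trials, ≤ 12 subjects, 1–2
blocks) for EEG-path tests; calibration properties run at study-relevant
sizes: 2000 null replicates at n = 67 for type-I error and QQ coverage, 200
replicates at n = 2000 for effect recovery, 5000 simulated SNPs at n = 500
for HWE uniformity, and 1000 random instances for the AUC/brute-force
equivalence. These sizes are the package's chosen compromise between
Monte-Carlo resolution and suite runtime (about a minute).
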