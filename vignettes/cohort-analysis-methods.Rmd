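---
title: "Methods: burden, spectra, hydrophobicity and signature refitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burden, spectra, hydrophobicity and signature refitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcosig)
```

This vignette documents the models, parameter choices and numerical
conventions behind the package, and what its synthetic cohorts do and do
not establish about real data.

## The analysis

The pipeline characterises a cohort of whole-exome somatic variants in
five steps, each a pure function of its inputs.

**Burden.** Every accepted variant (SNVs and indels) counts toward its
sample's mutation total; tumor mutation burden divides that total by the
WES capture size in megabases. Samples, not patients, are the unit of
analysis: cohorts of rare tumors often contain multiple samples per
patient, and subgroup sizes are quoted at the sample level. A
patient-collapsed sensitivity analysis is a one-liner over the per-sample
table (`aggregate(n_mutations ~ patient_id, ...)`) but is not the
default. Two-group comparisons offer Welch's *t* and Mann-Whitney;
per-sample counts are heavy-tailed, and a single hypermutated sample can
leave Welch's *t* insensitive where the rank test is not (the `analysis/`
scripts print both). When both groups are completely tied the rank
statistic sits at its null expectation with zero tie-corrected variance
and the p-value is reported as 1.

**Spectra.** The 12-class spectrum keeps ordered pairs (G>A distinct from
C>T): transition asymmetry between reported strands is itself of
interest. The 96-channel spectrum uses the standard pyrimidine-strand
collapse; channel order is substitution-major (C>A, C>G, C>T, T>A, T>C,
T>G), then 5' base, then 3' base, alphabetical, labelled `A[C>T]G`, so
spectrum files are bit-comparable with COSMIC-style matrices. Contexts
are taken from the input table; variants without a resolvable context
contribute to the 12-class counts only and are reported as
`n_no_context` rather than silently dropped, because requiring a
reference genome would make the pipeline non-portable. Indels are
retained for burden but excluded from spectra and hydrophobicity: the
spectrum and shift statistics are defined over point mutations.

**Consequences.** Raw annotation strings are mapped to six canonical
classes (missense, silent, nonsense, splice, other, unknown); unknown
strings map to `other`, never to `missense`, and the raw string is kept
so the mapping is auditable. Top amino-acid-change rankings break ties by
descending count then lexicographic pair label, so reports are
deterministic.

**Hydrophobicity.** Each missense change scores `Δ = KD(alt) − KD(ref)`
on the Kyte-Doolittle (1982) hydropathy index, shipped as a plain TSV
(isoleucine +4.5 at the top, arginine −4.5 at the bottom). The cohort
statistic pools all missense variants across samples — the natural
reading when the shift is quoted against the total missense count — and
reports the mean Δ, a t-distribution 95% CI, and the paired *t* test of
alternate vs reference indices, which is algebraically the one-sample
test of the deltas against zero (asserted numerically in the tests).
Silent variants contribute Δ = 0 only on request; the default excludes
them. Non-standard residues (stop, B, Z, X, U) are excluded with a
count. Which of the top-10 changes increase hydrophobicity is reported,
not asserted, since top-10 composition depends on tie-breaking.

**Signatures.** Exposures solve the nonnegative least-squares problem
`min ||W x − s||₂, x ≥ 0` where `s` is the sample's spectrum normalised
to frequencies and `W` the 96×K reference (columns sum to 1). The raw
solution is normalised to sum to 1, exposures below `min_exposure = 0.06`
are zeroed in a single pass and the rest renormalised — the thresholding
convention popularised by deconstructSigs-style refitting, which trades a
little sensitivity for far fewer spurious small exposures. Exposures are
the per-signature "probabilities" in [0, 1]; etiology probabilities sum
member-signature exposures through an editable YAML map (aging ←
Signature 1; UV ← 7; MMR ← 6/15/20/26; APOBEC ← 2/13; POLE ← 10; POLH ←
9). Samples with fewer than `min_snv = 50` context-resolved SNVs are
fitted anyway but flagged low-confidence: suppressing them would hide
exactly the low-burden samples a heterogeneous cohort contains (minimum 8
mutations under the default generator). All-zero spectra yield an
NA profile flagged degenerate. The reconstruction cosine is a fit
diagnostic, not a probability.

Because the reference matrix normalises its columns and the spectrum is
normalised before fitting, exposures are invariant to scaling the counts,
and permuting reference columns permutes exposures identically; both are
asserted as properties, and on K ≤ 3 problems the NNLS solution's
residual is checked against exhaustive search over a coarse simplex grid.

## The synthetic cohort generator

The generator exists so every stage is testable end-to-end without
external downloads, and its defaults encode the study conditions the
package was built around: 48 samples from 36 patients (multi-sample
patients never span site groups); 11 face/scalp samples whose spectra
mix UV 0.75 / aging 0.20 / flat 0.05, 33 other-site samples at aging
0.75, and 4 visceral samples with a combined mismatch-repair weight of
0.70; per-sample burden drawn from log-normals truncated below at 8
(face/scalp median 500, dispersion 1.1; others median 38, dispersion
1.0), giving a cohort expectation near 260 mutations/sample with a
face/scalp mean near 925 versus ~65 elsewhere and maxima in the low
thousands; consequence probabilities 0.61 missense / 0.31 silent / 0.03
nonsense / 0.02 splice / 0.03 other; and a target mean KD shift of
+0.924. The mixtures were chosen so the expected transition fraction
(G>A + C>T) is ~0.84, matching the ~85% such cohorts show. The capture
size defaults to 38 Mb, a typical exome footprint. Each variant's
channel is drawn from the group's mixture of reference columns — so
trinucleotide contexts come from the signature model itself, no genome
required — and is reported on the pyrimidine or purine strand with
probability 0.5, which is why G>A and C>T appear in near-equal numbers.

Missense amino-acid pairs are drawn from the table of substitutions
reachable by one nucleotide change under the standard genetic code,
weighted by codon-path multiplicity and exponentially tilted by KD delta
(`w ∝ w₀ e^{βΔ}`, β solved by root-finding in log-space) to hit the
requested mean shift exactly in expectation; requesting a shift outside
the achievable range (roughly ±9) is an error. Tilting to 0 gives an
exactly unbiased null used for the type-I-error check of the shift test.

Every latent draw (channel, strand, class, amino-acid pair, position) is
recorded in a ground-truth object from which the variant table can be
rebuilt exactly (`variants_from_truth()`), and the whole simulation is a
deterministic function of the seed.

**What passing tests show — and don't.** The generator reproduces the
statistical structure the analyses assume: mixture-of-signature spectra,
heavy-tailed burden, fixed consequence proportions, a tilted amino-acid
substitution law. It does not model sequencing error, purity or
clonality, copy number, regional mutation-rate covariates, gene-level
annotation, or correlations between burden and consequence class. Tests
passing on synthetic cohorts therefore validate the estimators and their
implementations, not the biological claims on any particular real
cohort; real analyses should supply a published reference matrix via
`read_signature_matrix()` rather than the synthetic stand-in.

## Numerical choices and problem sizes

Tolerances: signature columns must sum to 1 within 1e-8; exposures sum to
1 within 1e-8 after renormalisation. Ties in rankings break
deterministically as above; degenerate inputs (empty cohorts, all-zero
spectra, singleton groups under Welch's *t*, n = 1 shift vectors) are
flagged rather than erroring where a flag preserves more information.
The test suite exercises convergence properties at the sizes where their
guarantees are comfortably met and the suite stays quick: 10,000 variants
for the law-of-large-numbers spectrum check (total-variation distance
< 0.05), the ~13,000-variant default cohort for the consequence
goodness-of-fit, 5,000 mutations for two-signature exposure recovery
within ±0.05, and 1,000 replicates of 100 null deltas for the shift
test's type-I error (within three binomial standard errors of 0.05).

## Known limitations

The HGVS parser handles substitutions, synonymous and stop-gain forms
only; frameshifts and extensions are deliberately "not parseable" and
leave the record in the `other` class. VCF ingestion is out of scope for
this version (the TSV dialects cover MAF-like exports). Etiology
aggregation by summed exposures is the documented interpretation of
per-etiology probability; refitting tools differ here, so exact exposure
values from other tools are not comparable, only rankings. De novo
signature extraction, bootstrap CIs on exposures, and SBS-v3/indel
signatures are non-goals.
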