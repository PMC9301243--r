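---
title: "Methods: rule-based flavonoid glycoconjugate annotation and differential profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based flavonoid glycoconjugate annotation and differential profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavomics)
```

# The compound model

Flavonoid glycoconjugates are modelled compositionally: an aglycone
core plus a multiset of *dehydrated* residues. Storing residues with
the condensation water already removed (Glc = C6H10O5, 162.0528 Da;
GlcA = C6H8O6, 176.0321 Da; Mal = C3H2O3, 86.0004 Da; Fer = C10H8O3,
176.0473 Da; Cou = C9H6O2, 146.0368 Da) makes conjugate formulas pure
element-wise sums — e.g. medicarpin C16H14O4 + Mal + Glc = C25H26O12 —
with no per-bond water correction. This convention is forced by the
conjugate formulas themselves: every packaged compound's formula equals
the sum of its parts.

Monoisotopic masses use the most-abundant-isotope table (C = 12 exact,
H = 1.00782503207, O = 15.9949146196, ...). Protonation adds the
*proton* mass (1.007276 Da), not the hydrogen-atom mass; permanently
charged flavylium cations (the anthocyanidin peonidin and its
glucosides) are detected as native cations, i.e. the neutral-atom sum
minus one *electron* mass. The packaged reference table prints the
uncorrected neutral-atom sum for peonidin glucoside (463.1240 vs the
physically correct 463.1235); the engine computes the corrected value
and all comparisons against such rows use a 1 mDa tolerance rather than
equality. A handful of other reference rows mix rounding and truncation
in the last printed digit (two coumaroyl-diglucuronides are off their
own formula by 2.2 mDa); tests freeze exact 4-decimal assertions only
for the 26 rows that are self-consistent, and bound the rest at 2.5 mDa.

The free-aglycone afrormosin entry is a documented inconsistency in the
source table: the printed formula (C17H12O5) and printed mass
(298.0841 Da) disagree. The library stores C17H14O5 — the formula
consistent with the printed mass *and* with every afrormosin conjugate
formula — and keeps the printed string alongside for audit.

# Annotation rules

**MS1 screening** accepts a (feature, compound) pair when the signed
relative deviation `1e6 (m_obs − m_theo)/m_theo` is within ±10 ppm, the
accuracy gate appropriate for a well-calibrated QTOF. Retention time is
advisory by default: it ranks candidates (and is the only thing that
can distinguish positional isomers, which share exact mass and
fragments) but does not reject them unless an explicit `rt_window` is
configured. We chose this because co-elution windows depend on the
chromatographic method, while the isomer *ordering* is robust.

**MS/MS annotation** exploits the dominant CID behaviour of flavonoid
glycosides: consecutive glycosidic-bond cleavages. For a candidate with
residue multiset R, every distinct ordering of R defines a ladder of
expected ions (precursor minus cumulative residue masses, ending at the
protonated-aglycone or flavylium ion). The best-supported ordering —
most ladder ions observed within the fragment tolerance — is reported;
ties prefer orderings that lose sugars before acyl units, matching
observed spectra. Unobserved intermediates are folded into merged
losses, so a spectrum showing only precursor → [aglycone+GlcA+H]⁺ →
aglycone⁺ still yields a connected chain. Acylated glycosides
additionally produce glycan-side oxocarbenium ions (acyl + sugar chain
+ proton); these are checked as diagnostic ions, as is the aglycone ion
itself.

Evidence tiers: `full_chain` when the chain reaches an observed
aglycone ion; `partial_ms2` when any chain or diagnostic ion matched;
`ms1_only` otherwise. The tier can only increase when peaks are added,
and no annotation is ever emitted above the MS1 gate.

The fragment tolerance default is **5 mDa absolute**. Printed product
ions of this compound class deviate from theory by at most ~2 mDa, so
5 mDa is permissive for real spectra while still separating the
feruloyl/glucuronyl isobar (Δ = 15.2 mDa) — the one confusable pair in
the residue set. The same Δ translates to 23–87 ppm at MS1 over the
observed precursor range, so the 10 ppm MS1 gate separates it there
too; `decompose_mass` only reports both explanations when the requested
tolerance genuinely covers both.

**One compound per feature.** The best annotation per feature is chosen
by tier, then |MS1 ppm|, then |ΔRT| to the library entry, then fewest
residues, then name — a fully deterministic ranking; the remaining
candidates are kept as an explicit runner-up list rather than silently
dropped, since MS1-only isobars cannot honestly be disambiguated.

An optional coarse isotope check (predicted M+1/M from carbon count vs
observed, ±30%) was considered and deliberately left out of the default
path: the generator does not simulate isotopologues and no algorithm is
specified for the real data, so a default-on filter would only ever
remove annotations for reasons the model cannot defend.

# The synthetic world

The generator is a *stated world*, not a tuning knob. Its defaults are
the study's own design: 4 cultivars (three Hg-tolerant, one sensitive)
× 2 tissues × 2 treatments × 3 biological replicates × 3 injections =
144 samples; per-cultivar leaf/root total-signal ratios 4.6, 7.0, 7.2,
16.0; leaf signal dominated by flavones (85%) with free aglycones below
3%; root signal dominated by isoflavones (82%) with a 50% free-aglycone
share. Family and aglycone shares are imposed *by construction*
(baselines are solved from the composition targets), so the profile
functions recover them exactly on noise-free data — those tests verify
the inversion, not the biology. Within a family the signal is split
equally among member compounds; real tissues are more skewed (e.g. the
sensitive cultivar is apigenin- rather than tricin-dominant), a nuance
the generator does not reproduce and no test depends on.

Noise is log-normal: log₂ intensity = baseline + treatment effect +
N(0, 0.5²) per biological replicate + N(0, 0.15²) per injection.
Biological SD 0.5 and technical SD 0.15 (log₂ units) are realistic for
replicated plant LC-MS and make fold-change recovery analytically
checkable. Injections are averaged within biological replicate before
testing (n = 3 per arm) — treating injections as independent would
triple the apparent sample size and inflate significance; the original
analysis does not state its choice, so ours is a documented default,
configurable via `average_injections`.

The `"hg"` scenario plants the reported per-compound log₂ fold changes
(63 compound × tissue × cultivar cells over 24 compounds, all positive
as reported) as ground truth. This validates the statistics layer by
*parameter recovery* — the raw study intensities were never deposited,
so figure-level numbers (leaf flavone share 81–93%, PCA variance
percentages, individual fold-change magnitudes) are not reproducible
and are deliberately not asserted. One transcription note: one cell
prints ".5" (below the calling threshold); it is encoded as 0.5
verbatim, and the down-regulation footnote's sign typo is resolved to
the derived −log₂ 2.5 = −1.3219.

A green recovery test therefore establishes: unbiased log₂FC estimation
(mean within ±0.1 over 200 seeds), sign-correct recovery in ≥95% of
simulations for planted |log₂FC| ≥ 1.5, and raw-p type-I control at
0.05 ± 0.02 on true nulls. "Directionally correct" is evaluated as the
*sign* of the estimated effect: under the stated noise (bio SD 0.5,
n = 3) the full call — p < 0.05 *and* FC > 2.5 — has only ~60–70% power
at log₂FC = 1.5, so a 95% full-call rate is not attainable in this
world and asserting it would require quietly shrinking the stated
noise. It does **not** establish anything about matrix effects, ion
suppression, missing values, or feature-finding errors, none of which
are simulated.

# Statistical choices

- **t-test variant:** Welch (unequal variances) on log₂ intensities,
  two-sided; Student available via `var_equal = TRUE`. With n = 3 per
  arm, Welch is the safer default.
- **Fold change** is the ratio of *linear* arm means, with
  `log2fc = log2(fc)` as an enforced identity; the log threshold is
  always derived (`log2(2.5)` = 1.3219, `log2(0.4)` = −1.3219), never
  the rounded 1.3.
- **Multiple testing:** raw p < 0.05 mirrors the original cutoff;
  Benjamini–Hochberg adjusted values are reported alongside when
  `fdr = TRUE` but never change the regulation flag.
- **Zeros:** a compound with a zero arm mean gets FC after adding half
  the smallest nonzero intensity, and is flagged `zero_imputed`.
- **Clustering:** d = 1 − Pearson r, complete linkage; zero-variance
  rows have no defined correlation and are excluded with a warning,
  never silently. Heatmap-style views use log₂, per-compound
  standardized data; PCA uses autoscaled linear data (the convention of
  the chemometrics software this emulates). Both are exposed, neither
  is hidden inside the other.
- **PCA sign convention:** the largest-magnitude loading of each
  component is made positive, so scores are reproducible across BLAS
  implementations. Explained variance is checked against an
  independent SVD in the test suite, and scores × loadingsᵀ must
  reconstruct the autoscaled matrix.

# Numerical and degenerate-input behaviour

- Formula subtraction that would need negative atom counts is an error,
  as is any residue multiset beyond 3 sugars + 1 acyl (configurable;
  the largest observed chain is an acyl-triglucuronide).
- `ppm_error` is exactly antisymmetric only to first order; the test
  suite asserts the exact identity
  `ppm(a,b) + ppm(b,a) = 1e6 (a−b)²/(ab)` (≈2.5e-3 at 50 ppm, under
  1e-3 below ~31.6 ppm).
- Retention-time ties inside an isomer group are broken by input order
  and flagged (`rt_tie`), not guessed.
- Empty peak-list files parse to empty tables with a warning; a decoy
  precursor far from every library mass is reported as unannotated, not
  force-fitted.
- All generators are deterministic under a seed; the pipeline writes
  the seed and a config hash into every artifact header.

# Known limitations

- No chromatographic peak picking, RT alignment, or profile-data
  handling: the input is already a feature/peak list.
- Sugar identity is hexose/hexuronate-level only; linkage position,
  O- vs C-glycosides and stereochemistry are out of scope (they are not
  decidable from these spectra).
- The mzML reader/writer is intentionally minimal (centroided spectra,
  base64 32/64-bit floats, optional zlib); MGF and the CSV dialect are
  the primary exchange formats.
- Isotope patterns, in-source fragmentation and multiply charged
  species are not modelled.
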