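---
title: "Designing and quantifying PRM assays with prmassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying PRM assays with prmassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmassay)
```

## The problem

Parallel reaction monitoring (PRM) quantifies a pre-selected set of
tryptic peptides: a quadrupole isolates each precursor and a
high-resolution analyzer records its full fragment spectrum. Absolute
specificity comes from two choices made at design time — the peptide must
be *proteotypic* (it occurs in exactly one protein of the background
proteome) and fully tryptic — and from a spiked-in stable-isotope-labelled
(SIL) copy of every peptide at acquisition time. The endogenous ("light")
peptide is chemically identical to its SIL ("heavy") counterpart, so both
co-elute; the mass shift of the label (Lys +8.014199 Da, Arg +10.008269
Da) separates them in m/z, and the light-to-heavy peak-area ratio is
proportional to the endogenous amount.

`prmassay` implements this workflow end to end for skin antimicrobial
peptide (AMP) panels and for any user-supplied protein set: in-silico
digestion and filtering, uniqueness screening, precursor/fragment m/z
computation, panel export, chromatogram quantification under an explicit
coelution criterion, and nonparametric group comparison. A synthetic-data
generator with known ground truth makes every stage testable offline.

## Mass arithmetic

Peptide masses are monoisotopic throughout — the readout instrument is a
high-resolution Orbitrap, for which average masses would be wrong by
roughly one part in a thousand. The neutral mass is the sum of residue
masses plus one water plus all modification deltas, and

$$ m/z = \frac{M + z\,m_\mathrm{proton}}{z}. $$

Two modifications matter here. Carbamidomethylation (+57.021464 Da) is
applied as a *fixed* modification on every cysteine, reflecting standard
iodoacetamide alkylation during sample preparation. The SIL label sits on
the C-terminal residue that trypsin leaves behind — K or R — so every
y-ion of a heavy peptide is shifted by the label delta while b-ions are
not, a useful diagnostic implemented in `fragment_mz_series()`:

```{r}
light <- peptide_ion("GADVWFK", charge = 2)
heavy <- sil_counterpart(light)
c(light = precursor_mz(light), heavy = precursor_mz(heavy))
head(fragment_mz_series(light), 4)
```

Fragment series are restricted to singly charged b/y ions inside the
acquisition scan range (default 114–1000 m/z, the targeted-MS2 window);
higher fragment charges and neutral losses are out of scope. Precursor
charges are stored per target: the bundled panel uses 2+ throughout
except ALNSIIDVYHK at 3+ (its histidine makes 3+ the observed species, and
only 3+ is consistent with the reference m/z). Computed values are
compared with printed references at 0.005 Th, which covers 2–3-decimal
rounding of the references.

## Digestion and the cleavage-probability model

`score_cleavage_sites()` supports two models. The `strict` model — the
default — is the deterministic convention: cleave after every K/R unless
proline follows. The `keil` model assigns each site a probability from a
bundled context table keyed on the residues at P2, P1 and P1', encoding
the proline block, its WKP/MRP rescues and damping by acidic or stacked
basic context. The table is a versioned data file
(`extdata/trypsin_cleavage_rules.csv`); the first matching specific rule
wins and the default is 1.0.

"Fully cleaved, 5–14 residues" is the selection rule for candidate
peptides: both boundaries must reach probability 1.0 under the chosen
model and no internal site may (i.e. zero missed cleavages), implemented
as `digest_protein()` + `filter_peptides()`. Coordinates are 1-based
inclusive, the native R/IRanges convention. N-terminal methionine is not
treated specially.

Two bundled panel peptides (VPLQQNFQDNQFQGK, 15 aa;
TFVPGCQPGEFTLGNIK, 17 aa) violate the 5–14 window. Explicitly pinned
targets are therefore never silently dropped: `build_panel()` keeps them
and flags the violation in its audit trail.

## Uniqueness screening

The uniqueness screen is an exact substring search of each candidate
against a background proteome, with isoleucine and leucine equated by
default — they are isobaric and indistinguishable by mass spectrometry.
Exact matching is the standard proteotypicity criterion at tryptic
peptide lengths and keeps the screen fully reproducible offline;
mismatch-tolerant homology search is deliberately out of scope. Peptides
surviving the screen but lacking a C-terminal K/R (a protein's terminal
segment) are also dropped: they cannot be SIL-paired.

## Quantification and the coelution criterion

`detect_peak()` is a deliberately simple, fully deterministic picker:
sum the fragment traces, smooth with a 5-point moving average, take the
global maximum as the apex if it clears a signal-to-noise threshold
(default 5, with noise estimated by the median absolute deviation of the
smoothed total), and place boundaries where the smoothed signal falls to
2% of the apex height above baseline. Each fragment is integrated by the
trapezoid rule over those boundaries. For a Gaussian peak the 2% cutoff
captures about 99.5% of the true area.

Detection requires *coelution*: the light apex must lie within
`apex_tolerance` (default 0.1 min, closed boundary — a delta exactly at
the tolerance passes) of the heavy apex, and the boundary intervals must
overlap by at least `min_overlap` (default 0.5) of the shorter interval.
Peaks failing the criterion are excluded, never ratio-ed. The source
experiment does not state numeric thresholds, so both are configuration,
not constants.

The ratio integrates *both* channels over the heavy channel's
boundaries: the SIL spike is constant across samples, so its boundaries
are the better-determined ones, and sharing boundaries cancels
truncation bias in the ratio exactly. Duplicate injections, when marked
with a `replicate` column, are averaged at the ratio level. Undetected
peptides yield `NA` ratios — zero-imputation would fabricate signal and
bias the rank statistics below.

## Group statistics

Ratios are compared across groups with the nonparametric path:
Shapiro–Wilk per group as a gate (delegated to `stats::shapiro.test`;
groups under n = 3 are untestable and force the nonparametric route),
then Kruskal–Wallis with midranks and tie correction

$$ H' = \frac{H}{1 - \sum_t (t^3 - t) / (N^3 - N)}, $$

and Dunn's post hoc z statistics

$$ z_{ij} = \frac{\bar R_i - \bar R_j}
  {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3-t)}{12(N-1)}\right)
  \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}, $$

with two-sided normal p-values, Bonferroni-adjusted over the tested
pairs by default (Holm and unadjusted are available; the source workflow
does not name its adjustment). Stars follow 0.05/0.01/0.001. Both rank
statistics are implemented from these formulas; `stats::kruskal.test`
serves only as an independent cross-check in the test suite, where
agreement is required to 1e-10.

Sparse groups are handled by flagging, not imputation: a pairwise
contrast is `claimable` only when both groups carry at least 3 detected
ratios (configurable). Pairs with an empty group are reported as skipped.

## The synthetic-data generator

`simulate_xics()` is the package's ground-truth instrument. Per
sample/peptide it emits a heavy channel at a fixed spike amplitude
(default 1e5 counts) and a light channel scaled by the true ratio. Both
channels share one apex drawn with retention-time jitter (sd 0.02 min);
fragment traces are scaled copies (default 3 fragments) with independent
multiplicative lognormal amplitude noise (CV 5%) on top of a Poisson
baseline (level 20 counts) — the standard noise anatomy of extracted-ion
chromatograms, chosen to keep intensities positive. Peaks are Gaussian
(sigma 4 s, optional right-tail asymmetry) on a 0.012-min grid over a
0.72-min window. Dropout emits a baseline-only light trace while the SIL
spike stays present, exactly as a missing endogenous peptide looks in a
real run.

What the generator does *not* emulate: chemical interference and
coeluting isobars, retention-time drift across a batch, detector
saturation, and profile-mode spectra. Passing tests therefore demonstrate
the correctness of the computational pipeline under its stated model, not
instrument-level robustness.

`generate_proteome()` plants tryptic peptides into random protein
sequences with an arginine inserted before the planted peptide and a
proline-free following context, so strict digestion provably releases
them — the fixture for digestion/uniqueness round-trips.

## The bundled fixture

`make_paper_fixture()` carries the package's worked example: an
18-peptide panel for 13 skin AMPs with reference m/z, a
healthy-vs-inflamed presence/absence reference (9 of 18 peptides
detectable somewhere), and a three-region profile (GP: gland-poor
forearm, SGR: sebaceous-gland-rich forehead, AGR: apocrine-gland-rich
armpit; 15 samples per region) in which S100A8, LCN2, LACRT and LYZ
peptides are elevated in SGR and dermcidin is flat.

Effect sizes are not numerically published for the regional comparison,
so the fixture is qualitative by design: elevated groups are set 6-fold
above presence level, "low amounts" at 0.15, and regions described as
lacking a peptide are simulated *at the detection limit* — ratio 0.08
with 60% dropout — rather than fully absent. The detection-limit choice
keeps the rank tests defined in sparsely detected groups (a fully empty
group supports no contrast under the no-imputation policy) while
preserving the qualitative absence pattern; magnitudes in the 5–10×
range make the contrasts robustly significant at n = 15.

## Problem sizes and numerical choices

The shipped simulations are sized for a desk run: the two-condition
fixture uses 4 samples per condition, the regional fixture 15 per region
over the six quantifiable peptides (about 100k trace points); the full
simulate–quantify–compare cycle takes a few seconds. Determinism is
end-to-end for a fixed seed; RNG state is saved and restored around
every generator call. Degenerate inputs have defined behaviour: all-zero
traces yield no peak, identical observations yield H = 0 and p = 1, a
missing SIL spike is an explicit error rather than an infinite ratio,
and ties are handled by midranks with the corrections above.

## Limitations

The picker tracks a single dominant peak per trace window and assumes
fragment traces share an acquisition grid (resampling otherwise); no
cross-run retention-time alignment, interference scoring, or
vendor-format reading is attempted. The cleavage-probability table is a
compact context model, not a full empirical kinetics model. Statistics
treat peptides independently; there is no cross-peptide multiplicity
control, matching the one-peptide-at-a-time reporting convention of
targeted assays.
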