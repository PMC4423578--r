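---
title: "MS1 signal provenance: model, reference pipeline and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MS1 signal provenance: model, reference pipeline and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutromer)
```

## The signal model

MS1 data is a function of three axes: m/z, retention time (RT) and
intensity. The package types every intermediate object of the standard
reduction chain and names every reduction applied to it, so that a derived
quantity carries its full provenance.

The scope hierarchy runs molecule → chargite (one charge state) → neutromer
(one isotopic species) → neutroid (one scan's centroided tuple). Orthogonal
to scope, an entity is either a *hull* (its raw profile points) or a
*distribution* (its centroided form), and is a *trace* when extended
through RT. Reductions along RT (`integrated`, `max`, `average`,
`instantaneous`) and along m/z (`deisotoped`, `reduced`) append tags to a
provenance chain; `provenance_label()` renders a chain as a readable term
with the most recent operation outermost, and `parse_provenance()` inverts
it exactly. Validation rejects chains the lexicon does not license: more
than one RT qualifier, `deisotoped` below chargite scope, `reduced` below
molecular scope, or `hull` combined with `distribution`.

Two coordinate conventions had to be fixed where the nomenclature itself is
silent:

* an `integrated` or `average` entity needs an m/z and RT coordinate; we
  use intensity-weighted means, consistent with the centroiding convention
  (the weighted m/z of an `average` projection is the flagged open choice —
  an unweighted mean would be equally defensible);
* ties in `max` go to the earliest scan, making the operator deterministic.

RT is seconds everywhere internally; sequences are 0-based; spans are
half-open where compared.

## The reference detection pipeline

**Centroiding.** Within a scan, 2D peaks are seeded at local intensity
maxima over m/z and extended outward until the intensity drops to zero (or
to the configured floor) or a local minimum is reached. Boundary
local-minimum points are excluded from both neighboring hulls: including
them in either (or both) would double-count intensity or break the
symmetry of the rule, and exclusion makes the per-scan conservation law
exact — the summed neutroid intensity equals the summed intensity of all
hull-assigned points. Plateaus collapse to their leftmost point for
determinism; by extension, every point of an interior minimum plateau acts
as a separator. A hull's centroid m/z is the intensity-weighted mean of its
member points (one- and two-point hulls reduce to the stated special
cases); its intensity is the member sum by default, with apex height
available via `centroider_config(intensity_mode = "apex")` — the sum is the
tested default precisely because it makes conservation exact.

**Trace building.** Scans are processed in order; each neutroid joins the
open trace whose reference m/z is within 7 ppm and nearest in ppm, looking
back one scan or, failing that, two (the gap rule: one missing scan may be
bridged, never two). The reference m/z of a trace is the m/z of its most
recently added neutroid — the alternative of a running weighted mean was
rejected because linking is defined between *neighboring scans'* centroid
positions. When two neutroids in one scan compete for the same trace,
candidate pairs are assigned in ascending ppm order with displaced
candidates reconsidered, which is deterministic under any within-scan
permutation of the input. Culling removes traces with fewer than two
neutroids. Unmatched-forward neutroids are culled only by this length rule;
the bidirectional variant (discarding centroids unmatched to the two
previous *or two next* scans) would require a second pass and is not
implemented.

**Splitting.** A trace is split at any interior local minimum whose
intensity is at most 1/1.3 of the lesser surrounding local maximum,
iteratively, the minimum neutroid joining the right-hand segment (the side
is a convention; the rule does not state one). Segments are re-culled. The
boundary is evaluated as `min <= lesser_max / 1.3` in double precision —
for the canonical boundary case (minimum 10.0 between maxima 13.1 and
13.0), `13/1.3` is exactly 10 in IEEE doubles, so the `<=` comparison
reproduces the rule with no tolerance term. Splitting uses raw neutroid
intensities, no smoothing.

**Envelope grouping.** The unassigned trace of greatest integrated
intensity seeds an envelope; for each candidate charge z in the configured
range, neighbors are collected outward at seed m/z ± k·Δ/z (Δ = 1.003355 Da,
the ¹³C−¹²C mass difference; configurable to 1.0 to reproduce the idealized
"1/z" convention) within 10 ppm and with RT-span overlap ≥ 0.5 of the
shorter span. The z collecting the most members wins, ties to the larger z
(the more parsimonious spacing fit). Deisotoping anchors the summed
per-scan intensity at the monoisotopic m/z — the conventional anchor.
Molecule grouping merges chargites whose implied neutral masses
M = z·(mz₀ − m_p) agree within 10 ppm and that co-elute; the consensus mass
is the intensity-weighted mean. Charge reduction deisotopes first and then
re-coordinates to m/z′ = (M + z*·m_p)/z* at the lowest common charge z*
(whether a reduced molecular distribution should retain isotope structure
at z* is ambiguous; deisotope-first is implemented). Chargites left with
undetermined charge are reported with z = 0 and excluded from molecule
grouping and reduction.

## The simulator and what it does (not) emulate

`simulate_run()` generates profile-mode MS1 runs with exact ground truth:
per molecule, charge and isotope, a Gaussian elution profile sampled at the
scan times and, per scan, a Gaussian m/z peak of width FWHM = m/z / R
sampled on a uniform m/z grid. The grid step is (minimum FWHM)/4, ensuring
at least four points per peak so the centroider is genuinely exercised.
Isotope abundances are either given explicitly or modeled as a Poisson
envelope with rate 0.6 per kDa — a coarse single-rate stand-in for
elemental isotope patterns (roughly the carbon count scaling of peptides).
Isotopic fine structure (isoneutromers) is deliberately collapsed into a
single m/z per neutromer: resolving it would require instrument models far
beyond the Gaussian-FWHM abstraction used here. Elution is pure Gaussian
evaluated within ±4σ of the apex (beyond that the contribution is below
3.4e-4 of the apex and the trace would only be lengthened, not changed);
exponentially-modified tailing is not simulated. Emitted scans contain
only grid points near simulated signal, flanked by explicit zero points so
peak boundaries are well defined; baseline is added to emitted points and
Poisson counting noise is optional and seeded.

Consequently, passing the recovery tests shows the pipeline is exact on
symmetric, well-separated, noise-free peaks; it does not show robustness to
peak tailing, chimeric overlap, baseline drift, or detector saturation —
real-data phenomena outside the simulator's model.

## Validation scenario and problem sizes

The reference scenario (`reference_run_config()`) uses 10 molecules with
masses jittered around an even grid over 410–1850 Da, each at charges 1 and
2 with three isotopes (relative abundances 1 : 0.55 : 0.22), apexes 45 s
apart with σ = 5 s (so elution windows are disjoint), R = 60,000, scan
interval 2 s, noise off. In this regime — pairwise m/z gaps far above
10×FWHM, RT gaps above 4σ — detection is expected to be exact, and the
suite asserts recall = precision = 1 for traces and chargites, centroid
m/z error < 2 ppm (observed ~1e-5 ppm) and integrated intensity within 1%
of truth (observed at machine precision). Property tests run 1000 random
scans against an independent brute-force segmenter and 100 random fixtures
through the conservation laws (tolerance 1e-9 relative); these sizes keep
the whole suite under half a minute on one CPU while exercising every
branch of the segmentation logic.

## Known limitations

* Charge assignment is purely spacing-based; no isotope-pattern (averagine)
  scoring, so single-trace chargites have undetermined charge.
* Overlapping envelopes are not deconvolved in the signal-processing sense;
  co-eluting molecules closer than the grouping tolerance will merge.
* mzML I/O covers MS1 spectra only (profile or centroid); no mzXML or
  vendor formats. Config files for the CLI are JSON.
* The feature table is flat TSV/JSON; no dedicated serialization of the
  typed objects beyond it.
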