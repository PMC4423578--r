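# neutromer

An executable, typed data model for MS1 (precursor-level) LC-MS signal
provenance, together with a reference feature-extraction pipeline and a
ground-truth run simulator.

## The problem

Every quantitative proteomics or metabolomics workflow starts by turning raw
MS1 signal — intensity over m/z and retention time (RT) — into features. The
intermediate objects of that reduction are usually described with ambiguous
colloquial terms ("peak", "feature", "mass trace"), which makes detection
algorithms hard to restate and compare. This package makes a precise
nomenclature for those objects operational: each stage of the pipeline
produces a typed entity, and every reduction of an entity carries a
provenance tag naming the operation applied, so any derived quantity has an
unambiguous, machine-checkable name.

The base terms, from molecular scope downward:

| term | meaning |
|---|---|
| **molecule** | the composite signal across all charge states of one charge-accepting unit (peptide, lipid, ...) |
| **chargite** | that unit's signal at one particular charge state z |
| **neutromer** | the portion of a chargite with a common neutron count (one isotopic species) |
| **neutroid** | an instantaneous centroided neutromer hull: one (m/z, RT, intensity) tuple in one scan |
| **hull / distribution** | the raw-point form of an entity vs its centroided form |
| **trace** | an entity extended through RT |

Qualifier operators reduce entities along either axis:

- RT qualifiers — **integrated** (summed through RT), **max** (slice at the
  RT of greatest intensity), **average** (mean through RT),
  **instantaneous** (slice at one scan's RT);
- m/z qualifiers — **deisotoped** (intensities summed through the isotope
  dimension), **reduced** (charge states combined at the lowest common
  charge state).

Tag chains are validated against the lexicon and round-trip to readable
terms: `c("deisotoped", "integrated")` on a chargite renders as
`integrated deisotoped chargite distribution trace`.

## The reference detection algorithm

The pipeline implements the classic profile-MS1 reduction chain:

1. **Centroiding** — in each scan, local intensity maxima as a function of
   m/z seed 2D peaks; each extends outward until intensity drops to zero or
   a local minimum is reached (separator minima belong to neither neighbor).
   A hull's centroid m/z is the intensity-weighted mean of its points,
   `sum(mz_i * I_i) / sum(I_i)`; a single-point hull keeps its own m/z.
2. **Trace building** — each neutroid within 7 ppm of an open neutromer
   trace from the previous or penultimate scan joins the closest trace (in
   ppm); others open new traces. Traces with a single neutroid are culled.
3. **Splitting** — a trace is split at any interior local intensity minimum
   that is at most 1/1.3 of the lesser of the two surrounding local maxima.
4. **Envelope grouping** — co-eluting traces spaced `1.003355/z` Th apart
   (within 10 ppm) form chargite traces; the charge maximizing member count
   wins. Chargites whose implied neutral masses `M = z*(mz_mono − m_proton)`
   agree within 10 ppm merge into molecular distribution traces.

All thresholds are configuration (`trace_builder_config()`,
`envelope_config()`), defaulting to the values above.

## Worked example

Simulate one molecule of neutral mass 1000 Da at charges 1 and 2 with three
isotopes, run the pipeline, and match against ground truth:

```r
library(neutromer)

mol <- molecule_spec(neutral_mass = 1000.0, charges = c(1L, 2L),
                     elution_apex = 60, elution_sigma = 5, peak_height = 1e5,
                     isotope_abundances = c(1, 0.5, 0.2))
cfg <- simulation_config(list(mol), rt_range = c(30, 90), scan_interval = 2,
                         mz_range = c(400, 1100), noise_model = "none")
sim <- simulate_run(cfg)
sim$run
#> <raw_run> 31 scans (profile mode), 4284 raw points
#>   RT 30.00 .. 90.00 s

res <- detect_features(sim$run)
length(res$traces)           # 6 neutromer traces: 2 charges x 3 isotopes
res$chargites[[1]]
#> <chargite_trace C0001> z=1, 3 neutromer traces, mono m/z 1001.0073
res$molecules[[1]]
#> <molecular_distribution_trace M0001> M = 1000.000000 Da, z = {1,2}

truth_match(res$traces, sim$truth)
#> <truth_match> recall 1.0000, precision 1.0000 (6/6 truth rows)
```

The recovered molecule's consensus neutral mass is exact to the printed
precision, and every simulated isotope trace is found once (recall and
precision 1). Projecting the z = 2 chargite through RT gives its isotope
pattern — one row per neutromer trace, tagged with the operation:

```r
project_rt(res$chargites[[2]], "integrated")
#>         mz rt intensity scan_index isotope_index    entity_kind provenance source_id
#> 1 501.0073 60 3341918.5         NA             0 chargite_trace integrated     C0002
#> 2 501.5090 60 1672632.4         NA             1 chargite_trace integrated     C0002
#> 3 502.0106 60  669722.2         NA             2 chargite_trace integrated     C0002

deisotope(res$chargites[[1]], rt_mode = "integrated")
#>         mz rt intensity scan_index isotope_index    entity_kind            provenance source_id
#> 1 1001.007 60  11357118         NA            NA chargite_trace deisotoped+integrated     C0001
```

The intensities are conserved at every reduction: 11357118 is the summed
intensity of all three z = 1 isotope traces.

## Command line

A thin CLI wraps the same functions (`inst/cli/neutromer`, or call
`neutromer::ms1_cli()`):

```sh
neutromer simulate --config sim.json --out-mzml run.mzML --out-truth truth.tsv
neutromer detect   --in run.mzML --out features.tsv --ppm-tol 7
neutromer project  --in features.tsv --mode integrated --out integrated.tsv
neutromer evaluate --in features.tsv --truth truth.tsv
```

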