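# caudawhip

Tail-strike biomechanics from caudal vertebral morphometrics.

Long-tailed reptiles — prosauropod and diplodocid dinosaurs among the fossils,
monitor lizards and iguanas among the living — taper their tails into a
flexible, whip-like distal segment that can be swung in fast lateral strikes.
`caudawhip` turns a table of per-vertebra measurements (centrum length and
total height, in cm, one row per caudal position) into estimates of how hard
such a tail could hit, and provides the comparative and audit tooling around
that estimate. It is aimed at vertebrate palaeontologists and functional
morphologists working with serial skeletal measurements.

The pipeline is:

1. **Series I/O and imputation.** Measurement tables are read from delimited
   text; interior missing vertebrae are filled with the arithmetic mean of
   their nearest preserved neighbours (linear interpolation across longer
   gaps), and the total tail length *l* is the plain sum of centrum lengths —
   tightly articulating centra leave no room for significant intervertebral
   soft tissue.
2. **Whip segmentation.** The *transition point* (TP) is the first caudal
   position where centrum length strictly exceeds total height; by default
   the crossing must persist to the tail tip, so a single taphonomically
   distorted vertebra cannot fake a crossing. The whip segment is
   [TP, tail tip].
3. **Cone mass model.** The tail is idealised as an elongate cone,
   Vol = (1/3) π r² l, with r half the total height of the cranial-most
   vertebra of the segment, converted to mass at 0.8 kg per 1000 cm³. Soft
   tissue (35.9% muscle + 5.7% skin by volume) enters through a radial
   scaling factor 1/(1 − 0.359 − 0.057) ≈ 1.7, which multiplies the mass by
   its square.
4. **Strike energies.** E = ½ m v² for three scenarios: the whole tail swung
   as one mass, the whole-tail energy transferred through the whiplash at an
   efficiency (default 0.85), and a rapid whiplash strike moving only the
   whip-segment mass. Strike velocities are always explicit inputs.
5. **Comparative table and audit.** Multi-taxon rows (caudal count, lengths,
   whip fraction, energy) and an audit mode that back-solves the velocities
   implied by published energies (v = √(2E/m)) and grades published tables
   for internal arithmetic consistency.

A synthetic-series generator with closed-form ground truth
(`synthetic_series_spec()`, `generate_series()`, `ground_truth()`) makes
every stage testable without any external data.

## Worked example

A small synthetic measurement table ships with the package (30 vertebrae,
two interior gaps, 2% measurement noise; generated by the package's own
generator — it is labelled synthetic and stands in for a real specimen
appendix):

```r
library(caudawhip)

f <- system.file("extdata", "synthetic_demo_series.csv", package = "caudawhip")
series <- impute_missing(read_measurements(f, specimen_id = "demo"))
series
#> Vertebral series: demo
#>   records: 30 (28 preserved, 2 imputed)
#>   summed centrum length (preserved only): 137.9074 cm

seg <- segment_whip(series, find_transition_point(series))
seg
#> Whip segmentation
#>   transition point: Ca20
#>   whip length:  49.4 cm
#>   total length: 148.1 cm
#>   whip fraction: 33.4%

masses <- tail_mass(series, seg, tissue = tissue_model())
masses$whole
#> Cone mass model [whole_tail, with soft tissue]: r = 11.10 cm, l = 148.1 cm -> 44.84 kg
masses$whip
#> Cone mass model [whip_segment, with soft tissue]: r = 2.29 cm, l = 49.4 cm -> 0.6343 kg

evaluate_scenarios(masses, scenario_config("custom", v_whole_m_s = 2,
                                           v_whip_m_s = 12))
#>   ... whole_tail_kJ 0.090, quick_whiplash_kJ 0.046
```

Read: the crossing of centrum length over total height puts the whip at
Ca20, a third of the tail; the soft-tissue cone masses are 44.8 kg (whole
tail) and 0.63 kg (whip); swinging the whole tail at 2 m/s carries 90 J,
and a 12 m/s whiplash about 46 J.

Multi-specimen runs are driven by one config (list or YAML):

```r
run <- run_pipeline(list(
  audit = TRUE,
  specimens = taxon_presets()   # diplodocid + monitor + iguana presets
))
run$comparative
run$audit                        # PASS/FLAG per arithmetic check
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/caudawhip` (`run`, `synth`, `profile` subcommands).

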