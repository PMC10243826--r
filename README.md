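# mejpattern

Spatial pattern analysis of myoendothelial junctions (MEJs) in en face
endothelium.

In resistance arteries, endothelial cells project through holes in the
internal elastic lamina (HIEL) to contact smooth muscle, forming MEJs — the
microdomains where vasodilatory signaling (Kir2.1, PS, Cx40, IK_Ca) is
concentrated. Imaged *en face*, HIEL are dark holes in a hydrazide-stained
elastin sheet. `mejpattern` answers, quantitatively:

* **Where are the HIEL?** For each HIEL center, the minimum Euclidean
  distance *d*ᵢ to a signaling-hub mask (nuclei, ER, or interendothelial
  junctions) is compared against Monte Carlo envelopes — positive control
  (every center within 1 µm of the hub), negative control (1.5–4.5 µm), and
  uniform random placement — using Welch's ANOVA, Brown–Forsythe F\*, and
  pairwise Welch t-tests with Holm–Šidák adjustment (α = 0.05), after
  robust FDR-based outlier removal (ROUT, Q = 1%). The verdict labels the
  field `random`, `hub_associated`, `hub_excluded`, or `inconclusive`.
* **What occupies them?** Marker puncta are assigned to an HIEL when their
  center lies within 0.75 µm of the HIEL center (inclusive, nearest-HIEL,
  deterministic ties), giving percent MEJ occupancy, per-EC counts with the
  identity `overall mean = conditional mean × fraction of ECs with ≥1`, and
  directional co-occupancy (e.g. % of Kir2.1-MEJs also containing PS).
* **Do en face densities predict section counts?** With areal density
  ρ = N/A and section thickness t, the expected HIEL profiles per IEL
  length L is ρ·(d + t)·L — checked against a Monte Carlo sectioning
  oracle that honors the 1-section-per-5-µm sampling rule.
* **Pressure myography.** Myogenic tone 100·(D_pass − D_act)/D_pass,
  percent change vs 20 mmHg, percent dilation
  100·(D_resp − D_pe)/(D_max − D_pe), lipid responses, and NS309
  dose-response assembly.

Because no public imaging dataset accompanies this workflow, the package
ships a synthetic en face generator with known ground truth (Voronoi EC
tessellation, hub masks, HIEL at 9.83 per cell under PC/NC/RAND mechanisms,
marker puncta with configured occupancies), so every stage is testable.

## Worked example

```r
library(mejpattern)

spec  <- field_spec(placement_mode = "PC", hub_kind = "nuclei", seed = 1)
field <- synthesize_field(spec)
field
#> <en_face_field> 492 HIEL (PC vs nuclei), 67 puncta, 50 cells; seed 1

d <- envelope_distances(field$hiel, field$hub,
                        sim_config(n_replicates = 20, seed = 2),
                        spec$px_size_um)
verdict <- compare_groups(d)
verdict
#> <pattern_verdict> label: hub_associated  (alpha = 0.05 )
#>   REAL vs RAND p = 0 | vs PC p = 0.8418 | vs NC p = 0 (Holm-Sidak)
#>   Welch ANOVA p = 0; Brown-Forsythe p = 0; REAL n = 492 (492 after outlier removal)

tidy(verdict)
#> # A tibble: 3 × 4
#>   comparison   p.value p.adjusted significant
#>   <chr>          <dbl>      <dbl> <lgl>
#> 1 REAL_vs_RAND   0          0     TRUE
#> 2 REAL_vs_PC     0.842      0.842 FALSE
#> 3 REAL_vs_NC     0          0     TRUE
```

The field was generated with every HIEL within 1 µm of a nucleus, and the
verdict recovers exactly that: the real distances are indistinguishable from
the positive-control envelope (adjusted p = 0.84) and differ from both the
random and negative-control envelopes, so the label is `hub_associated`. A
`RAND` field instead matches only the random envelope and is labeled
`random` — the conclusion the statistic reaches on the real arteries.

Colocalization and density on the same field:

```r
occupancy(field$hiel, assign_puncta(field$puncta, field$hiel), "PS")
#> # A tibble: 1 × 4
#>   marker     k     n occupancy_pct
#> 1 PS        67   492          13.6

density_regression(field$tess, field$hiel)
#> <hiel_density> mean 9.840 HIEL/EC over 50 cells; slope -0.000242 (p = 0.814)
```

The generator was configured at 13.8% PS occupancy and 9.83 HIEL per EC;
the estimates (13.6%, 9.84) recover both. `autoplot()` methods draw the
group box plots, field maps, and dose-response curves; `run_stage()` drives
the same stages from YAML configs with a reproducibility manifest, and
`inst/cli/mejpattern.R` wraps it for the shell.

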