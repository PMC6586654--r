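# ipetr

Per-particle 3D reconstruction and conformational analysis for flexible
macromolecules imaged by negative-stain electron tomography.

Averaging-based single-particle reconstruction assumes every particle shares
one structure. Antibodies violate that assumption: two Fab arms and an Fc
swing freely around a disordered hinge, and engineered variants (such as the
"hole-hole" homodimer of the knob-into-hole bispecific platform) add further
conformers in which the two halves of the Fc separate into an X shape.
Individual-particle electron tomography (IPET) reconstructs each particle
from its own tilt series instead, and reads conformations off the
per-particle maps. `ipetr` implements that pipeline, plus the simulation
machinery needed to validate every stage by parameter recovery:

* **Simulation** — antibody-like multi-domain phantoms (Y / X / i / bowtie
  classes) with exactly known conformational geometry; tilt series at
  −45°…+45° in 1.5° steps with CTF, per-image translational jitter and
  noise at a chosen SNR.
* **Reconstruction** — ab initio (r-weighted) back-projection, iterative
  translational refinement with an automatic coarse-to-fine filter/mask
  schedule and multigrid start, missing-wedge compensation by
  constraint-set iteration.
* **Resolution** — Fourier shell correlation between odd/even half-maps,
  with the conventional 0.5 and 0.143 threshold crossings
  (FSC(s) = Re Σ F₁F̄₂ / √(Σ|F₁|² Σ|F₂|²) per shell), and a model-to-map
  variant.
* **Docking** — rigid-body fitting of domain models by locally normalised
  cross-correlation (whole-template dock, then leashed per-domain polish
  with density subtraction), with a loop-length connectivity check at
  3.8 Å per residue.
* **Flexibility statistics** — domain mass-centre distances, inter-axis
  angles (Fab–Fab, CH3–CH3, CH2–CH2), CH2-based ensemble superposition,
  and deterministic 1-/2-term Gaussian and 6th-degree polynomial histogram
  fits with range fractions.

File formats: MRC2014 maps and image stacks, plain-text tilt-angle files,
PDB models (via bio3d) with editable chain/residue partition rules, CSV
geometry tables, JSON reports.

## Worked example

Simulate one X-shaped particle at the standard acquisition scale (256 px
windows at 1.48 Å/px binned to 128 px at 2.96 Å), reconstruct it, and
measure its conformation:

```r
library(ipetr)

cfg <- sim_config(box_size = 256, bin_factor = 2, pixel_size = 1.48,
                  jitter_max = 6, noise_sigma = sqrt(2),  # SNR 0.5
                  seed = 101)
ph  <- make_antibody_phantom("X", list(ch3_distance = 90, ch2_angle = 100),
                             config = cfg)
sim <- simulate_tilt_series(ph$volume, cfg)

rec <- refine(sim$series, n_iterations = 6, wedge_every = "final",
              particle_radius_px = 100 / 2.96)
rec
#> <ipet_reconstruction> 128 px map, FSC 0.5 at 33.2 A, 0.143 at 21.7 A, 6 iterations (converged)

err <- sqrt(rowSums(shift_residuals(rec$shifts_px, sim$truth_shifts,
                                    sim$series$angles_deg)^2))
mean(err < 1)
#> [1] 0.9180328

tpl <- phantom_model(phantom_spec("X"))
fit <- fit_multibody(tpl$model, tpl$partition, rec$map,
                     angular_step_deg = 30)
measure_geometry(fit$placed_model, tpl$partition, "X")
#>   fab_fab_distance fab_fab_angle ch3_ch3_distance ch2_ch2_angle class_label
#> 1          84.0916      128.0389         89.56473      99.44303           X
```

The refined shifts recover the simulated jitter (92% of the 61 images
within one pixel at SNR 0.5, after removing the free global-centre gauge),
the half-map FSC puts the map in the range typical of stain tomography of a
150 kDa particle at this noise level, and the blind multi-body dock reads
back the built-in conformation (90 Å CH3–CH3 distance, 100° CH2–CH2 angle,
85 Å / 130° Fab pair) to within ~1 Å and ~2°.

The same measurements run on real data: `read_tilt_series()` takes an MRC
stack plus a `.tlt` file, `read_model()` a PDB with partition rules (default
rules for an intact IgG1 ship in `inst/extdata/`), and
`run_pipeline()` / `inst/cli/ipet.R` orchestrate
simulate→reconstruct→fsc→fit→analyze with per-stage seeds and a checksummed
manifest.

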