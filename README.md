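# trajan

Analysis of protein molecular-dynamics trajectories in multi-model PDB
format, built for the questions that come up when characterizing a
membrane-pump/regulatory-peptide complex (the motivating system is the
sarco/endoplasmic reticulum Ca²⁺-ATPase bound to a phosphorylated
phospholamban-like peptide):

* **Superposition metrics** — Kabsch least-squares alignment, per-frame RMSD
  with independent align/measure selections, per-residue Cα RMSF about the
  iterated mean structure.
* **Secondary structure** — per-residue, per-frame helix/coil assignment
  from the Kabsch–Sander hydrogen-bond energy
  `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) < −0.5 kcal/mol`,
  with geometric amide-H reconstruction.
* **Interface maps** — residue contact occupancy fractions (OF; minimum
  heavy-atom distance ≤ 3.0 Å, pooled frame-weighted over trajectories),
  strict `OF > threshold` classification, phosphate–guanidinium salt-bridge
  distances with monodentate/bidentate denticity, and geometric
  hydrogen-bond persistence (≤ 3.5 Å, ≥ 120°).
* **Domain motion** — rotation angle / centroid displacement of rigid
  domains relative to a reference structure after Cα alignment on a fixed
  core (rotation `acos((tr R − 1)/2)`, displacement measured pre-domain-fit;
  an offset rotation axis recovers the chord length `2·sin(θ/2)·d`).
* **Distance populations** — Cα–Cα distance series, per-trajectory burn-in
  exclusion, and 1-D Gaussian-mixture decomposition by EM (k-means++-style
  seeding, σ floored at 0.05 Å) with BIC selection of the component count
  (`BIC = −2·LL + (3K−1)·ln n`).
* **Synthetic ground truth** — a seeded generator of two-chain toy
  trajectories (`scenario_spec()` / `build_scenario()`) that realizes
  programmed contacts, hydrogen bonds, salt-bridge states, domain motions
  and distance mixtures *geometrically*, so every detector is validated
  through coordinates against known truth.
* **Pipeline** — `run_pipeline()` executes all stages from a YAML config and
  writes a reproducible report bundle (CSV/JSON with seed and thresholds in
  every header, plus an MD5 `MANIFEST.json`).

## Worked example

```r
library(trajan)

spec  <- demo_scenario(seed = 102)      # bundled two-chain study conditions
built <- build_scenario(spec)           # 300 frames x 10 ns, ground truth attached

pump <- select_atoms("A", list(c(130,150), c(315,330), c(340,370), c(426,426),
                               c(795,815), c(831,855), c(895,915),
                               c(933,948), c(966,994)))
pep  <- select_atoms("B", c(1, 52))
oc   <- occupancy_map(built$trajectory, pump, pep, cutoff = 3.0)
head(classify_high_occupancy(oc$a, 0.75), 5)
#>       chain res_seq res_name OF n_frames_total
#> A 796     A     796      ALA  1            300
#> A 800     A     800      ALA  1            300
#> A 807     A     807      ALA  1            300
#> A 833     A     833      ALA  1            300
#> A 837     A     837      ALA  1            300

d <- apply_burn_in(ca_distance_series(built$trajectory, c("A", 139), c("A", 426)), 200)
fit_gmm(d$values, K = 5, seed = 1, n_restarts = 5)
#> <mixture_fit> K = 5, n = 280, BIC = 1832.3
#>   pi = 0.166  mu =   7.549 A  sd =  0.758 A
#>   pi = 0.169  mu =  10.962 A  sd =  0.782 A
#>   pi = 0.286  mu =  20.141 A  sd =  1.506 A
#>   pi = 0.202  mu =  26.965 A  sd =  1.538 A
#>   pi = 0.177  mu =  32.491 A  sd =  1.509 A

crit <- hbond_criteria(c("B", 34, "ND2"), c("A", 801, "O"), h_name = "HD2")
hbond_presence(built$trajectory, crit)$percent_formed
#> [1] 0.8966667
```

The occupancy table flags the residues lining the persistent transmembrane
interface (OF = 1 over all 300 frames). The mixture fit decomposes the
residue-139/426 distance sample into its five programmed subpopulations
(means 7.5/11/20/27/33 Å): the two compact populations correspond to the
domain-contact arrangement, the three wide ones to separated-headpiece
states. The hydrogen bond programmed at p = 0.9 is measured formed in 89.7%
of frames.

## Analysis workflow

The `analysis/` directory holds the numbered drivers of the full study over
the bundled scenario; each regenerates its inputs deterministically from the
fixed seeds and writes small tables under `results/`:

```sh
Rscript analysis/01_simulate.R              # scenario + ground-truth summary
Rscript analysis/02_superposition.R         # RMSD / RMSF
Rscript analysis/03_secondary_structure.R   # helix/coil evolution
Rscript analysis/04_interface.R             # occupancy, salt bridge, H-bond
Rscript analysis/05_domain_motion.R         # rotation/displacement map
Rscript analysis/06_distance_populations.R  # burn-in + GMM decomposition
```

The same study runs as one command through the config-driven pipeline:

```r
cfg <- read_run_config(system.file("extdata", "demo_config.yaml", package = "trajan"))
run_pipeline(cfg, "out/")
```

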