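---
title: "Trajectory analysis of a pump-peptide regulatory complex: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajan)
```

## Scope and model of the data

`trajan` analyses protein molecular-dynamics trajectories stored as
multi-model PDB files. The scientific setting it targets is the
characterization of a membrane-pump/regulatory-peptide complex — e.g. the
sarco/endoplasmic reticulum Ca²⁺-ATPase (SERCA) bound to phosphorylated
phospholamban — where the questions are: how mobile is each domain
(RMSD/RMSF), which residues form the binding interface and how persistently
(contact occupancy), what geometry does a phosphate-guanidinium salt bridge
adopt (denticity), does a named inhibitory hydrogen bond survive
(persistence), where do the cytosolic domains sit on a rotation/displacement
map relative to a reference crystal structure, and which structural
subpopulations coexist in an inter-residue distance distribution
(Gaussian-mixture decomposition).

A trajectory is a stack of coordinate frames over one fixed topology. The
package deliberately supports only the multi-model PDB dialect: it is a
plain-text, self-contained exchange format, and the fixed-column parser can
enforce the contracts the analyses rely on (stable atom order, identical atom
identity across frames, no insertion codes, only blank/'A' altlocs). Binary
MD formats are out of scope. PDB files carry no time axis, so the frame
spacing `dt_ns` is supplied at read time; frame *f* (0-based) maps to
`f * dt_ns` ns. This matters because burn-in exclusion is defined on the time
axis.

Residue numbering is taken verbatim from the PDB `res_seq` field (author
numbering), 1-based, with inclusive ranges, so selections can be written
exactly as residues are cited in the structural literature (e.g. a
transmembrane core "M7 831–855, M8 895–915, M9 933–948, M10 966–994").

## Superposition metrics

Rigid superposition uses the Kabsch algorithm: SVD of the cross-covariance of
the centered point sets, with the reflection corrected through the sign of
the smallest singular value so the result is always a proper rotation.
Collinear point sets (rank-deficient cross-covariance) are rejected.

* `rmsd_series()` aligns each frame on an explicit *alignment selection* and
  measures RMSD over an explicit *measurement selection* without refitting.
  Both phrasings used in practice — "backbone" (N, CA, C, O) and "main-chain
  C-alpha" (CA only) — are expressible because every operation takes its atom
  filter explicitly; nothing is hard-coded.
* `rmsf_per_residue()` reports fluctuations about the *iterated mean
  structure* (align to a provisional reference, average, re-align,
  re-average — two passes), the standard fluctuation definition; aligning to
  frame 0 instead is available by flag. For an atom with isotropic Gaussian
  jitter of σ per coordinate the expectation is `RMSF = σ√3`, which the tests
  verify at σ = 0.5 Å over 2000 frames.
* No mass weighting is applied anywhere: the inputs carry no masses, and all
  published quantities this package mirrors are unweighted.

## Secondary structure

Helix assignment re-implements the Kabsch–Sander electrostatic model: a
backbone C=O⋯H–N pair is hydrogen-bonded when

E = 0.084 · 332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) < −0.5 kcal/mol,

with the amide hydrogen rebuilt geometrically (1.0 Å from N, opposite the
C(i−1)–N–CA bisector) when absent — MD exports often strip hydrogens, and
this is the same reconstruction the original dssp program applies. A residue
is labeled `H` when the i→i+4 bond pattern holds for two consecutive turns
(the minimal α-helix rule); everything else is `C`. Only the two-class
alphabet is distinguished because the downstream use is an α-helix/coil
evolution matrix; 3₁₀/π helices and strands are deliberately lumped into `C`.
Chain breaks (C(i)–N(i+1) > 2.5 Å) act as segment boundaries and are logged.
The −0.5 kcal/mol cutoff and the frame stride are configurable.

On an ideal 12-residue helix built from standard internal coordinates
(φ = −57°, ψ = −47°, trans ω; N–CA 1.458, CA–C 1.525, C–N 1.329 Å) every
i→i+4 bond scores ≈ −2.17 kcal/mol and the assignment is `H` for residues
2–11 with coil termini — the frozen expectation in the test suite, computed
by an independent hand-run of the pattern before the implementation was
trusted.

## Interface analysis

**Occupancy.** A residue of group A contacts group B in a frame when the
minimum heavy-atom distance to any group-B residue is ≤ 3.0 Å (cutoff
configurable). Hydrogens are excluded by default: a 3 Å criterion including
hydrogens would miss most van-der-Waals contacts; an override flag exists
because source publications do not always state the convention. Occupancy
fractions are pooled *frame-weighted* across trajectories (a 10-frame and a
30-frame trajectory with per-trajectory OF 1.0 and 0.5 pool to 0.625);
per-trajectory tables are attached for inspection. Both directions (A vs B,
B vs A) come from the same pair-distance matrix in one pass. The
high-occupancy classification `OF > threshold` is strict exceedance.

**Salt bridge.** Distances are measured from a probe atom (the phosphorus of
a phosphoserine) to named partner atoms (e.g. arginine Cζ, lysine Nζ);
"favorable" means strictly < 6 Å. Denticity counts distinct phosphate
oxygens within 3.5 Å of a guanidinium nitrogen: 0 = none, 1 = monodentate,
≥ 2 = bidentate. The 6 Å favorable cutoff follows the convention of the
studies this mirrors; the 3.5 Å oxygen–nitrogen pairing distance is the
standard salt-bridge contact distance and is exposed as a parameter because
source publications typically leave it unstated.

**Hydrogen bonds.** Geometric criterion: donor-heavy-atom to acceptor
distance ≤ 3.5 Å AND donor–H⋯acceptor angle ≥ 120°, both configurable and
echoed into report headers. The hydrogen is taken from the topology when
named, or reconstructed for backbone amides as above.

## Domain rotation/displacement maps

Every frame is first aligned on the C-alpha atoms of a fixed core selection
(for a P-type pump: the TM helices M7–M10), with the fitted transform applied
to all atoms. Each domain is then Kabsch-fitted to the reference; the
reported rotation is `acos((trace(R) − 1)/2)` folded to [0°, 180°] with the
right-handed unit axis (the arccos form is sign-blind, so the axis sign is
chosen to make the angle non-negative). The displacement is the domain
centroid shift measured **after core alignment but before the domain fit**;
since a rotation about the centroid does not move the centroid, a domain
rotated about an axis offset by d recovers the chord length 2·sin(θ/2)·d,
which the tests verify analytically. The magnitude of the fitted transform's
translation vector is available as an alternative (`translation =
"fit_vector"`) because the displacement convention differs between published
rotation/displacement maps. Domain residue definitions are user-supplied
configuration: published N/P/A-domain boundaries vary between studies, so no
default is hard-coded (only the M7–M10 core default is provided, because
those ranges are stated explicitly wherever this alignment is used). Single
crystal structures are scored as one-frame trajectories. Curation or
clustering of crystal-structure databases is out of scope; cluster labels on
such maps are user-supplied annotations.

## Distance populations

`ca_distance_series()` measures per-frame Cα–Cα distances;
`apply_burn_in()` removes frames with time < burn-in (default workflow:
0.2 µs per trajectory, applied *before* pooling, to avoid bias from the
starting configuration). The pooled sample is decomposed by a 1-D Gaussian
mixture:

* EM with k-means++-style seeded initialization; convergence when the
  log-likelihood changes by < 1e-8, or 500 iterations (non-convergence is
  flagged, not raised);
* component standard deviations floored at 0.05 Å so degenerate spikes
  cannot collapse the likelihood;
* `BIC = −2·LL + (3K − 1)·ln n`, minimized over K = 1..k_max with 5 seeded
  restarts per K and ties broken toward smaller K. Restarts use the standard
  short-run strategy (100 iterations each, best start polished to full
  convergence) — EM's likelihood ascent makes this equivalent in practice and
  much cheaper. `fit_gmm()` with fixed K mirrors published decompositions
  with a stated component count (K = 2 and K = 5 in the motivating study).
* `k_max` is capped at `n/10`: fewer than 10 points per component is not a
  meaningful fit.

The source study reports Gaussian decompositions without naming a fitting
procedure or selection rule; EM + BIC with restarts is this package's
defensible choice, and every hyperparameter is recorded in the JSON output.
The EM inner loop lives in compiled code (`src/em_gmm.cpp`) with seeded
initialization kept in R; an independent mixture implementation (mclust) is
used as a cross-check in the test suite, never as the implementation.

## The synthetic-data generator

The raw trajectories behind the motivating study are not deposited, so
validation runs on seeded synthetic scenarios with programmable ground truth
(`scenario_spec()`, `build_scenario()`). The generator emulates the
*statistical* structure of such data: a rigid multi-helix transmembrane core,
a mobile rigid cytosolic domain on a scripted rotation/translation schedule,
a disordered peptide segment with per-frame Gaussian positional noise,
per-frame contact and hydrogen-bond formation probabilities, salt-bridge
states with given probabilities, and inter-residue distances drawn from
specified Gaussian mixtures.

Two properties make it a real test instrument rather than a label oracle:

* **Events are realized geometrically.** A firing contact places the
  designated atom within 2.8 Å (otherwise ≥ 6.5 Å, straddling the 3.0 Å
  detection cutoff); a present hydrogen bond places the donor group at 2.9 Å
  with linear geometry (absent: 5.5 Å); a salt-bridge state positions an
  actual phosphate group in a bidentate/monodentate/unbound arrangement;
  mixture draws become C-alpha positions. Detectors are therefore exercised
  through coordinates.
* **One global seed, one counter-based substream per program entry.** Adding
  a contact pair does not perturb any other stream, so scenarios can be
  extended without invalidating frozen expectations.

The bundled `demo_scenario()` fixes the study conditions used throughout the
analysis scripts and the demo pipeline: 300 frames at 10 ns per frame
(3 µs per trajectory, so the 200-ns burn-in removes 20 frames), two
trajectories, persistent transmembrane contacts at p = 0.85–0.9, transient
N-terminal contacts at p = 0.2–0.3, hydrogen-bond presence 0.9, salt-bridge
state probabilities 0.20/0.25/0.55 (none/mono/bi, the bidentate-preferred
regime), 2 Å positional noise on the disordered segment, and a five-component
distance mixture with means 7.5/11/20/27/33 Å (σ = 0.8/0.8/1.5/1.5/1.5 Å) —
the compact-vs-separated population structure reported for
phosphorylation-activated pump headpieces. Statistical recovery studies use
larger dedicated samples: occupancy at 2000 frames, mixtures at n = 10000
(two components) and n = 20000 (five components).

What passing these tests shows — and what it does not: the analyses recover
known ground truth embedded in idealized geometry (no solvent, no force
field, no kinetic realism, events independent across frames). Correctness of
the *measurement* pipeline on real MD output follows; the biological
conclusions of any particular study of course do not.

## Numerical choices and degenerate inputs

* Kabsch: < 3 points or collinear inputs are errors; `det(R) = +1` enforced.
* Rotation axis extraction: near 0° the axis is conventional (0,0,1); near
  180° it comes from the symmetric part of R with a fixed sign convention.
* EM: all-identical samples return floored variances with a degeneracy
  warning; n < 10·K is an error; responsibilities are accumulated with a
  per-point underflow guard so arbitrary parameter states keep a finite
  likelihood.
* Burn-in longer than a trajectory is an error (empty series), as is an
  RMSF request on a single frame.
* Pipeline outputs carry the package version, seed and all thresholds in a
  `#` header block; `MANIFEST.json` lists every file with its MD5 hash, and a
  failing stage leaves the partial bundle marked incomplete. With a fixed
  seed the bundle is byte-identical across runs.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run on deliberately compact
instances chosen to make each property measurable with comfortable margins:
20 random 10-point instances against a brute-force rotation-grid oracle;
three 2000-frame occupancy scenarios (binomial bound 3·√(p(1−p)/n)); 20
seeded replicates of the two-component mixture at n = 10⁴ and of the
five-component mixture at n = 2·10⁴; and the full demo pipeline at 2 × 300
frames. These sizes are the package's validation conditions, not limits of
the implementation.
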