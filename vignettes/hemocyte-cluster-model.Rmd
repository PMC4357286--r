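---
title: "Modelling crystal-cell differentiation in sessile hemocyte clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crystal-cell differentiation in sessile hemocyte clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoclust)
```

## The model

`hemoclust` treats a sessile hemocyte cluster as a 2-D packing of disk
cells observed on the live-imaging time grid. Each cell carries a class
(`PLASMATOCYTE`, `INDUCED_CC`, `MATURE_CC`), marker intensities (nuclear
red for all Hml+ cells; cytoplasmic green proportional to the Lz reporter),
an area, a position, a compartment (`SESSILE` or `CIRCULATION`), and RNAi
efficacy multipliers. Time advances in steps of `dt = 1.5` min — the frame
interval of the imaging protocol — so simulator output is directly
renderable as movie frames.

Three processes drive the population:

* **Division.** Each sessile plasmatocyte divides with a per-step
  probability derived from the per-3-hr proportion `p_div_3h = 0.07` via
  the geometric-hazard conversion
  `(1 - p_step)^(180/dt) = 1 - p_window`, so the realized fraction of
  starting plasmatocytes that divide within 3 hr equals the configured
  proportion regardless of the step size (a property the test suite
  checks by simulating at dt = 1.5 and dt = 7.5 min). Daughters receive
  half the parent's area, are placed at the smallest non-overlapping
  offset (ties broken by smallest angle, making placement deterministic
  given the state), and regrow toward the parental target area with time
  constant `tau_regrow = 60` min. Crystal cells never divide, matching
  the complete absence of Lz+ mitoses in the videos.
* **Contact-dependent induction.** A sessile plasmatocyte touching
  `k_eff` Serrate-competent Lz- neighbours is induced with window hazard
  `min(1, notch_eff * beta_contact * k_eff)` per 3 hr, converted to the
  step grid as above. The linear, zero-intercept form is deliberate: the
  probability of being Lz+ rises linearly with contact number, and the
  cluster-disruption result shows induction requires contact at all, so
  the intercept is pinned at zero. Two cells are "in contact" when their
  centre distance is at most `contact_radius_factor = 1.33` times the sum
  of their disk radii; the slack above 1 stands in for the membrane
  interdigitation visible in projected stacks. `beta_contact` is the one
  free mechanistic parameter; `calibrate_beta()` fits it by bisection so
  the mean per-plasmatocyte 3-hr induction proportion matches the
  aggregate target `p_diff_3h = 0.035`. The shipped default (0.0195) is
  the value this calibration returns for the default geometry.
* **Maturation.** After induction the reporter follows a saturating
  exponential `gfp(t) = gfp_max (1 - exp(-t / tau_mat))` with
  `tau_mat = 240` min, the cell's area relaxes toward
  `area0 * (1 + area_gain * gfp/gfp_max)` (`area_gain = 1`, i.e. a mature
  crystal cell roughly doubles its area), and phagocytic capacity is
  `1 - gfp/gfp_max`. The class flips to `MATURE_CC` when gfp crosses
  `gfp_high_threshold = 120`, about 3.7 hr after induction. These laws
  reproduce the monotone trends — GFP rises within a 3-hr video, size and
  GFP correlate strongly, phagocytosis declines with both — without
  asserting magnitudes the source data never printed.

Cells exchange with circulation: sessile cells detach at
`k_detach = 0.01` per 3 hr, and circulating cells re-attach at
`k_attach = 0.99` per 3 hr. The attach default looks large but is the
direct translation of the observed cluster re-establishment: under the
geometric hazard, 0.99/3 hr means 90% of detached cells are sessile again
90 min after a disruption. Because detachment is rare, the baseline
circulating pool stays below ~1% and fold-changes remain dominated by
division and differentiation. Cell death is off by default (no apoptosis
differences were detected in any condition) but available as a rate.

Perturbations map RNAi genetics onto the hazard: `NOTCH_RNAI` scales the
receiving side, `SERRATE_RNAI_ALL` the sending side of every hemocyte,
`SERRATE_RNAI_LZ_ONLY` silences Serrate only in Lz+ cells (which do not
participate in the hazard, hence no effect — the driver-restriction
control), and `DELTA_RNAI` is carried but inert because Serrate, not
Delta, is the operative ligand. `DISRUPTION` empties the sessile
compartment at scheduled times.

## Synthetic imaging and assays

`render_movie()` is a pure function of (trajectory, config, seed): one
frame per snapshot, nuclear blobs as Gaussians (`psf_sigma = 1.6` px),
cytoplasmic green as sharp-edged soft disks (logistic edge 0.4 px),
constant background 10, optional Gaussian read noise (default sd 2) and
Poisson shot noise (default off), written as frame-major 16-bit
multi-page TIFF with a JSON sidecar holding config and ground truth. The
28-µm Z-stack is collapsed to a single projected plane, as the original
scoring was done on projections. Magnification and noise levels are not
stated anywhere in the source material; the defaults (1 µm/px, 128 px
field) are conventions recorded in the config.

`synth_flow_events()` emulates bleeding pooled larvae into a cytometer:
FSC follows cell area, fluorescence channels follow marker intensities
under lognormal noise, a `dead_fraction` of events is PI-positive, and
2%/5% doublets/debris give the gating stage something to remove.
`synth_hemocytometer()` draws Poisson counts with mean
`concentration / (dilution * 1e4)`, the inverse of the printed
`counted x 10^5 cells/ml` conversion.

What the generator does **not** emulate: cell migration within the
cluster (positions are static between divisions and re-attachments),
occlusion and 3-D overlap, depth-dependent PSF, photobleaching,
segmentation-resistant cell shapes, and real FCS binary formats. Passing
tests therefore demonstrate correctness of the measurement pipeline under
these idealized optics, not performance on real microscopy.

## The measurement pipeline

Detection thresholds the red channel at
`background + max(5 * sigma_robust, 20)` (median/MAD background; the
absolute floor takes over on noise-free renders) and splits touching
nuclei by a watershed on the background-subtracted intensity with a
peak-to-saddle tolerance of 8 — needed because a daughter nucleus appears
only ~5–6 px from its parent. Green is measured as the mean grey value
over a small disk (radius 1.6 px) centred on the nuclear centroid; the
small radius keeps the cytoplasmic green of a large neighbouring crystal
cell from bleeding into a plasmatocyte's measurement in the projection.

Linking is greedy nearest-neighbour with a 4-px gate and 2-frame gap
bridging, deterministic ties by (distance, lower track id). A division is
a new track of at least 2 detections starting within 7 px of an existing
track; an induction is the first frame at which a track green-negative
for its first `m = 3` frames exceeds the green threshold for `m`
consecutive frames. Event calling has structural dead times: a division
in the final frame leaves an unlinkable 1-frame daughter, and an
induction needs the GFP rise (~3 frames) plus persistence, so rate
estimates shorten the effective exposure accordingly (1 frame for
divisions, `m + 2` frames for inductions) and truth scoring excludes
events inside those windows. Observed proportions rescale to the 3-hr
reference window geometrically, never linearly.

The criteria a human scorer used to call events on the original videos
are unstated; the automated criteria above are conventions validated
against synthetic ground truth only.

## Statistics

`compare_groups()` reproduces the normality-gated convention: Shapiro-Wilk
per group at the test level, then Student's t (two groups) or one-way
ANOVA with Dunnett's many-to-one comparisons (more), falling back to
Wilcoxon rank-sum or Kruskal-Wallis with Dunn's test. Two conventions are
ours: the two-group non-normal fallback is the rank-sum test (only the
multi-group nonparametric path is named in the source), and Dunn's test is
implemented in-package (rank z statistics with mid-ranks, tie correction,
Bonferroni across the many-to-one family) since no installed package
provides it; it is validated against a hand oracle in the tests. Groups
with fewer than three observations are refused; zero-variance groups are
routed to the nonparametric path.

## The extrapolation recurrence

`extrapolate()` implements
`Lz+(t+1) = Lz+(t) + Lz-(t) * dp` with one step per 3-hr measurement
window (24 hr = 8 steps). Exactly as printed, differentiating cells are
not deducted from the plasmatocyte pool; net plasmatocyte change is
absorbed by the growth model (constant, geometric, or linear over the
horizon; geometric with fold 1.4 is the default). The geometric case has
the closed form `Lz-0 * dp * sum_k fold^(k/n)`, and both must agree with
a literal loop to 1e-9 relative — a property the suite checks on random
inputs. The headline 447-cell extrapolation depends on initial counts
that exist only as bar heights and is not bit-reproducible; the package
instead reproduces the sufficiency inequality. With dp = 0.035 and fold
1.4 over 8 steps the step sum is 9.3118, so the extrapolated increase
covers a measured increase of 256.4 cells for any initial plasmatocyte
count of at least `256.4 / (0.035 * 9.3118) = 786.7` — i.e. 787 cells,
comfortably below a larva's plasmatocyte load.

## Scenario designs and problem sizes

The scenario runner uses sizes chosen to keep every experiment
informative at desk scale: `videos` mirrors the study design exactly
(13 fields of 50 + 6 cells, 3 hr, zero-noise render by default); `rnai`
compares five genotype groups of 12 replicates over 12 hr; `disruption`
runs 20 paired 10-hr replicates, each arm pooling 8 simulated larvae into
one flow sample (bleeding always pools larvae), disrupting the treated
arm every 90 min and both arms once before sampling; `contacts` pools 40
fields by default. For recovering the per-contact hazard slope the
`contacts` scenario offers a `cohort` design — contacts scored at entry,
Lz status at the end of the window — which is free of the class-change
migration across contact bins that the single-snapshot scoring suffers,
and reports a through-origin slope alongside the weighted OLS line, the
stabler estimator at 3-hr event counts.

## Degenerate inputs and numerical choices

Empty clusters are legal states; packing is rejection sampling
(largest-first, restarted up to five times) and fails loudly when the
requested density is infeasible. Identical-valued samples are flagged
degenerate in density summaries and treated as non-normal by the Shapiro
gate; zero-variance correlations are errors, not NaNs. All stochastic
draws run through R's global RNG seeded once per simulation; replicate r
of a scenario perturbs the base seed deterministically
(`seed + 7919 r + 104729 arm`). Rendering clamps to the 16-bit range on
write and round-trips through TIFF to within one grey level.

## Known limitations

Cluster size and position effects are deliberately absent — all clusters
are statistically identical, since the relative importance of those
features cannot be ranked from the available evidence. Detachment and
attachment magnitudes are conventions (only the 90-min re-attachment is
constrained). Lamellocytes, wasp infection, lymph-gland zonation,
sex-specific parameter sets, and pupal dispersal are out of scope. Hml
reporter decay in mature crystal cells exists in the cell model only as a
default-off option appropriate for the nuclear-reporter configuration.
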