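# ehtkit

Quantitative image analysis of the endothelial-to-hematopoietic transition
(EHT) in the zebrafish dorsal aorta. During EHT, hemogenic cells of the
aortic floor bend out of the vessel wall and become pre-hematopoietic stem
cells; characterizing that process quantitatively means measuring the
vessel and its cells, not just looking at them. ehtkit packages the
measurement chain for researchers analyzing confocal stacks of the
aorta–gonad–mesonephros region (or benchmarking such analyses on synthetic
data):

- **Aortic wall unwrapping** — per-slice ring contours fitted to the tube
  wall (`fit_rings`), projection into a 2D cartography with X = axial
  position and Y = arc length around the perimeter (`unwrap`), exact
  back-mapping to 3D (`back_map`), and perimeter measurement
  (`measure_perimeter`).
- **Cell morphometry** — refinement of cell outlines into a joint paving
  (`refine_paving`), moment-ellipse descriptors (`compute_morphometrics`):
  area, elongation = major/minor ellipse diameter ratio, orientation to the
  blood-flow axis in [0°, 180°), cell length along the longest axis;
  neighbor counts (`count_neighbors`) and rule-based classification into
  endothelial / hemogenic / EHT pol+ / EHT pol− types
  (`classify_cell_type`).
- **FRAP** — assembly and normalization of five-phase recordings
  (`assemble_trace`, `normalize_trace`), single-exponential recovery fits
  F(t) = A·(1 − e^(−t·τ)) with mobile fraction A and half-time
  T½ = ln 2 / τ (`fit_recovery`), early recovery slope over the first 30 s
  (`early_slope`), and group comparisons (`summarize_groups`).
- **RNAscope spot statistics** — spot compartment classification
  (`classify_spots`), spots per hemogenic/EHT cell
  (`count_spots_per_cell`), and the 50%/75% attraction distances: the
  smallest distance from hemogenic/EHT cells within which 50%/75% of spots
  lie (`distance_profile`), with cross-segment Pearson correlations
  (`summarize_scene`).
- **Cell counting** — rolling-median removal of single-plane transients
  (`temporal_median`), top-hat segmentation with 3D distance-watershed
  splitting (`segment_objects`), raw-intensity measurement
  (`measure_objects`) and double-/single-positive classification
  (`classify_objects`).
- **qPCR and shared statistics** — ΔΔCt fold changes 2^(−ΔΔCt) with
  Dixon's Q outlier gating of technical triplicates (`delta_delta_ct`,
  `dixon_filter`), exact/approximate rank-sum tests (`wilcoxon_rank_sum`)
  and Pearson correlation with t-test (`pearson_cor`).
- **Synthetic data with ground truth** — generators for every input
  (`make_tube_phantom`, `make_frap_dataset`, `make_spot_scene`,
  `make_flow_timelapse`, `make_ct_table`), each a deterministic function of
  (configuration, seed) with a ledger of true values, so every stage is
  testable without any raw microscopy data.

The `analysis/` directory contains numbered driver scripts
(`01_simulate_phantoms.R` … `06_qpcr.R`) that run each stage on synthetic
data and write their tables under `results/`.

## Worked example

Simulate one noisy FRAP trace (true A = 0.5, τ = 0.01 /s, noise SD 5% of
the pre-bleach level), run the full normalization + fitting chain, and
measure a synthetic aorta's perimeter:

```r
library(ehtkit)

ds  <- make_frap_dataset(frap_sim_config(A_true = 0.5, tau_true = 0.01,
                                         noise_sd = 0.05, n_traces = 1, seed = 7))
fit <- fit_recovery(normalize_trace(ds$traces[[1]]))
fit
#> <frap_fit> A = 0.480, tau = 0.01088 /s, T_half = 63.7 s (rms 0.0432)

ph    <- make_tube_phantom(tube_phantom_config(radius_um = 25,
           segment_length_um = 82.5, pixel_xy_um = 1.08, step_z_um = 1.2,
           n_cells = 0, seed = 1))
rings <- fit_rings(ph$stack, channel = 1,
                   init_circle = c(y = 36, z = 34, r = 25))
rings
#> <ring_set> 77 slice(s), median perimeter 157.11 um

wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p
#> [1] 0.1
```

The fitted mobile fraction (0.480) and half-time (63.7 s, true value
ln 2 / 0.01 ≈ 69.3 s) recover the generating parameters to within the
noise-limited precision; the measured perimeter 157.11 µm agrees with
2π·25 = 157.08 µm to 0.02%; and the rank-sum p for {1,2,3} vs {4,5,6} is
the exact enumeration value 2/20 = 0.1.

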