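# condensateR

Quantitative analysis of stress-induced biomolecular condensates — the
membraneless RNA-protein assemblies that bacteria such as *E. coli* form
around the RNA chaperone Hfq under nitrogen starvation, and their mammalian
relatives (P-bodies). The package bundles, as one tested toolbox, the
bespoke quantitative procedures such a study needs:

- **Single-molecule diffusion states** (`fit_msd`, `pooled_squared_displacements`,
  `fit_three_state`, `fit_two_state`, `detect_stable_foci`,
  `classify_trajectory`, `compute_state_fractions`): per-track MSD fits
  (`MSD = 4Dτ + 4σ²` over lags 1–5, tracks ≥ 7 frames), stable-focus
  detection from localization composites (Laplacian-of-Gaussian,
  `min_sigma = 3`, `max_sigma = 5`, threshold 0.1, kept only with ≥ 10
  trajectories of ≥ 10 frames at ≥ 70% overlap), In / In-out / Out overlap
  classes, and the cumulative squared-displacement mixture
  `P(r², τ) = 1 − Σᵢ αᵢ exp(−r² / ((8/3) Dᵢ τ))` whose weights yield the
  condensate / nucleoid / free fractions
  `F_cond = (N_In + N_InOut)/N_total · (α₁+α₂)`, `F_free = α₃`,
  `F_nucleoid = 1 − F_free − F_cond`.
- **In vivo focus quantitation** (`expand_cell_masks`,
  `global_focus_threshold`, `call_foci`, `focus_background_ratio`,
  `colocalization_spearman`, `fit_frap`): 4-px dilation + convex-hull cell
  boundaries, a global median + 3.5·MAD intensity threshold, local-maximum
  seeded 4-connectivity focus growth (≥ 3 px), per-cell intensity ratios,
  per-cell Spearman colocalization with per-field means, and one-phase
  association FRAP fits (`t½ = ln 2 / k`).
- **In vitro droplet quantitation** (`segment_droplets`, `filter_droplets`,
  `call_phase_separation`): CLAHE → blur → Canny → morphological closing →
  fill, area ≥ 150 px, the five shape filters (circularity ≥ 0.4, axis
  ratio < 1.4, eccentricity < 0.8, solidity > 0.9, extent 0.55–0.95), and
  per-condition phase calls from Otsu thresholds on log-scaled counts and
  areas pooled over all fields.
- **Rifampicin-chase transcript stability** (`normalize_counts`,
  `fit_decay`, `filter_and_classify`, `compare_half_lives`): ERCC spike-in
  normalization (qualifying relative abundance > 5·10⁻⁴), bounded
  `y = a·exp(−t/b)` fits initialized at (0.001, 20), BH q-values, the
  5–65 min measurable window, the four stability-change categories, and the
  Wilcoxon rank-sum genotype comparison.
- **Untemplated poly(A) tails** (`count_terminal_As`, `assign_read_to_gene`,
  `fit_gene_zinb`, `compare_tail_lengths`): terminal-T run counting,
  strand-aware −50/+250 bp 3′-window assignment, per-gene zero-inflated
  negative binomial regression (four condition means, shared inflation and
  overdispersion, ≤ 500 iterations) and Wald condition contrasts.
- **Enrichment statistics** (`quintile_bins`, `term_odds_ratio`,
  `overlap_permutation_test`, `proportion_test`): equally populated effect
  bins, small-sample (+0.5) odds ratios with Yates-corrected chi-square
  p-values, uniform-resampling overlap permutation tests, and the one-sample
  proportion z-test.
- **A synthetic-data generator** (`simulate_trajectories`,
  `render_cell_image`, `render_droplet_field`, `simulate_decay_counts`,
  `simulate_polya_reads`) that produces every input with ground truth
  attached, so each stage is verified by parameter recovery — no external
  data needed.

## Worked example

The numbered scripts under `analysis/` run each pipeline end to end on
synthetic ground truth and write their tables under `results/`. For the
single-molecule stage:

```sh
Rscript analysis/01_single_molecule_tracking.R
```

prints

```
Detected 2 stable foci (planted: 2)
Trajectory overlap classes:

   In InOut   Out
  392   326  1782
Full three-state fit: alpha = (0.265, 0.289, 0.446), D = (0.140, 0.579, 3.134) um^2/s
Two-state fit on 'In' tracks: alpha = 0.921, D = (0.125, 0.278)
Recovered state fractions vs planted truth:
      state planted recovered abs_error
 condensate    0.25     0.253   0.00258
   nucleoid    0.30     0.301   0.00137
       free    0.45     0.446   0.00395
Largest absolute error: 0.004 (displacements analysed: 32589)
```

Both planted foci are found, the mixture weights match the planted state
fractions to within 0.004, and the fitted diffusion coefficients are ~1.5×
the simulation inputs — the expected consequence of fitting
instantaneous-position simulations with the camera-integrated (8/3)Dτ scale
(see the methods vignette). The other drivers report, in the same style,
focus-calling precision/recall, the recovered phase-diagram boundary, the
−14% median half-life shift with its rank-sum p-value, recovered poly(A)
condition means, and the planted enrichment signals.

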