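# collimap

Analysis tools for studying how astroglial gap-junction networks shape
visual function in the mouse superior colliculus (SC). The package covers
the three computational strands of such a study, end to end and fully
tested, for physiologists working with periodic-stimulation intrinsic
optical imaging, dye-coupling histology, and pose-tracked innate behavior:

1. **Functional visual maps.** Periodic stimulation (a bar sweeping at
   f = 1/8 Hz, or a grating rotating at 2 rpm) drives each camera pixel with
   a stimulus-locked response `x(t) = M cos(2πft − Φ) + drift + noise`.
   After slow-component removal, single-frequency Fourier demodulation
   yields per-pixel phase Φ and magnitude M; combining sessions of opposite
   stimulus direction cancels the hemodynamic delay δ and yields retinotopic
   maps (azimuth over 110°, elevation over 60°) and orientation preference
   maps (180°-periodic, analyzed at 1/15 Hz). Maps are registered across
   animals by rigid transforms minimizing circular least squares, averaged
   on the circle, and tested pixel-wise for reproducibility with the
   rank-weighted Moore–Rayleigh statistic
   `R* = |Σ rᵢ e^{iθᵢ}| / n^{3/2}` (Monte-Carlo null, cached and seeded).
   Selective-domain fractions and visual-field coverage quantify how much of
   the structure, and of the visual field, is robustly mapped.
2. **Dye-coupling geometry.** From cell coordinate tables of
   biocytin-filled astroglial networks: directional extents (dorsal /
   ventral / medial / lateral, median or max statistic) relative to the
   tissue surface polyline, isotropy ratios `a/(a+b)`, OLS regressions of
   extent on injection depth, and coupled-cell counts.
3. **Light-induced arrest behavior.** From 25 fps pose-tracking tables:
   likelihood-based cleaning (threshold 0.9, 5-frame smoothing),
   Savitzky–Golay speed, and the speed-modulation index
   `(V_baseline − V_arrest)/V_baseline` from the 1 s pre-flash and
   1–4 s post-flash windows (1 = full stop).

Every stage has a seeded synthetic-data generator that returns its ground
truth, so the whole pipeline is validated by parameter-recovery tests.

## Worked example

```r
library(collimap)

# --- retinotopy round trip at desk scale (64 x 64 px, 5 Hz camera) -------
protocol <- stim_protocol()            # 1/8 Hz sweeps, 30 repeats
truth <- imaging_truth(gradient_position_map(c(64, 64), 110),
                       delay_s = 1.5, noise_sd = noise_sd_for_snr(1, 3),
                       drift_amp = 1, seed = 42)
sessions <- make_retinotopy_sessions(truth, protocol)
demod <- function(m) extract_fourier_component(
  remove_slow_components(m, protocol$f_stim_hz), protocol$f_stim_hz)
map <- retinotopy_from_pair(demod(sessions$forward), demod(sessions$reverse),
                            span_deg = 110, axis = "azimuth")

# --- arrest behavior ------------------------------------------------------
tr <- make_arrest_trajectory(v_baseline_cms = 10, arrest_fraction = 0.75,
                             flash_time_s = 10, duration_s = 20,
                             noise_sd = 1, seed = 42)
speed <- compute_speed(clean_track(tr$track))
m <- arrest_metrics(speed, tr$flash_onsets_s[1])

# --- coupling isotropy ----------------------------------------------------
ratios <- sapply(1:20, function(i) {
  nw <- make_coupling_network(300, 100, 100, injection_depth_um = 1000,
                              seed = i)
  directional_ratio(directional_extents(nw$network, "max"))
})
```

which prints:

```
hemodynamic delay: 1.500 s (planted 1.5 s)
median |position error|: 0.11 deg; 95th percentile: 0.34 deg
V_baseline = 9.86 cm/s, V_arrest = 2.64 cm/s, index = 0.733 (planted 0.75)
dorsal/(dorsal+lateral): 0.503 +/- 0.012 (n = 20)
```

The recovered delay matches the planted hemodynamic delay, position errors
at amplitude SNR 3 stay well inside a visual-field degree, the planted
75% locomotor arrest is recovered by the behavior chain, and deep isotropic
coupling networks sit at the 0.5 isotropy point.

`run_pipeline()` (or `inst/scripts/collimap-cli.R` from a shell) chains all
stages on a synthetic cohort and writes `summary.json` plus a run log;
identical configuration and seed reproduce byte-identical outputs. See the
methods vignette (`vignettes/collimap-methods.Rmd`) for the models,
conventions and design decisions.

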