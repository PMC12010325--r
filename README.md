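# preedge

Tools for analysing high-energy-resolution fluorescence-detected (HERFD)
metal K-edge **pre-edge** spectra and for discriminating candidate structural
models of a metal cluster by **difference-spectrum RMSD ranking**. The
package grew out of the problem of deciding how ammonia binds to the
Mn₄CaO₅ oxygen-evolving complex (OEC) of photosystem II in its S₂ state:
ammonia binding barely moves the absorption edge, but it changes the weak
1s→3d pre-edge features, and those changes — treated-minus-native
difference spectra — can be compared quantitatively against TD-DFT
predictions for every plausible binding geometry.

It is aimed at spectroscopists and computational chemists who have
(a) experimental pre-edge scans (two-column energy/intensity text files) and
(b) calculated per-site transition tables ("stick spectra") for a set of
candidate structures, and who want a reproducible pipeline from raw scans to
a ranked model table.

## What it computes

For the experimental branch: area normalisation, 5-point boxcar binning,
flash-population deconvolution (a 1-flash spectrum is `(1−f)·S2 + f·S1`
with `f ≈ 0.10`; subtracting `f` times the 0-flash spectrum and
renormalising recovers pure S₂), polynomial-spline rising-edge background
removal, and a three-component Voigt deconvolution whose noise-free
reconstruction is used for differencing.

For the calculated branch: per-site stick spectra are broadened with a
unit-area kernel (Gaussian, 1.0 eV FWHM by default), summed over the four
Mn sites, and mapped onto the experimental axis by one global calibration —
an energy shift and an intensity scale (the canonical values for this
system are +35.3 eV and 0.018) fitted once against the untreated reference
and then frozen for every model.

Each candidate model is scored by

RMSD = sqrt( (1/N) Σᵢ ( y\_i,calc − y\_i,exp )² )

between its calculated difference spectrum (model − native) and the
experimental difference spectrum (treated − native), evaluated at N = 240
energies spanning 6538–6544.5 eV. Models whose absolute pre-edge intensity
over 6540–6543 eV exceeds the native reference by more than a configurable
threshold (25 % by default) are flagged by an exclusion screen. A fully
seeded synthetic-data generator emulates the whole measurement (four-site
stick models, sigmoid rising edge, Gaussian noise at SNR ≈ 20, 0.1 eV grid,
10 % S₁ contamination) so the end-to-end pipeline can be validated against
known ground truth.

## Worked example

```r
library(preedge)

res <- run_pipeline(list(
  seed = 7, true_model_id = "B1",
  synth = list(snr = Inf, edge_amplitude = 0, f_contamination = 0),
  bin_window = 1, n_peaks = 0, fit_background = FALSE,
  calibration = list(shift = 35.3, scale = 0.018),
  broaden_grid = "acquisition"))
head(as.data.frame(res$ranking)[, c("model_id", "binding_mode_class", "rmsd", "rank")], 3)
```

```
  model_id binding_mode_class      rmsd rank
1       B1    W1-substitution 0.0000000    1
2       A1    O5-substitution 0.4725729    2
3       E1       Mn1-addition 0.7291035    3
```

This plants binding mode `B1` (ammonia replacing the W1 water on Mn4) in a
noiseless synthetic experiment and runs the full pipeline: the planted model
is ranked first with RMSD 0 (the pipeline is exactly self-consistent in the
noiseless limit), and the nearest competitors are the modes whose difference
signatures most resemble an intensity loss on Mn4 (`A1`, which lowers both
Mn3 and Mn4, and the analogous loss on Mn1 in `E1`). With realistic
noise (`synth = list()`, the SNR ≈ 20 default) the same call preprocesses
both samples, fits the calibration on the native sample (recovering a shift
near 35.3 eV), and writes `ranking.csv`, the experimental difference
spectrum, the effective configuration and a log if `out_dir` is set.

A ready-made file-based example lives in `inst/extdata/` (synthetic data
written in the package's two-column and stick-table dialects); see
`?run_pipeline` for the `inputs` mode that consumes such files.

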