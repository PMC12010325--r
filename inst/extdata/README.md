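# Example data (synthetic)

All files here are generated by the package's own simulator
(`synth_config(seed = 2718, transitions_per_site = 20)`, planted binding
mode C2) and rounded for compactness; none are experimental measurements.

- `synthetic_*_{0,1}flash.xy` — two-column energy/intensity scans for the
  native and ammonia-treated samples (0-flash = S1-dominated, 1-flash =
  S2-dominated with ~10% S1 contamination), SNR ~20, 0.1 eV grid.
- `synthetic_sticks.csv` — per-site calculated transition table for the
  native reference plus the 14 candidate binding modes.

Run the pipeline on them with:

```r
library(preedge)
p <- function(f) system.file("extdata", f, package = "preedge")
res <- run_pipeline(list(inputs = list(
  native_one_flash  = p("synthetic_native_1flash.xy"),
  native_zero_flash = p("synthetic_native_0flash.xy"),
  treated_one_flash  = p("synthetic_nh3_1flash.xy"),
  treated_zero_flash = p("synthetic_nh3_0flash.xy"),
  sticks = p("synthetic_sticks.csv"))))
res$ranking
```
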