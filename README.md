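# peritract

Analysis of peri-tract spatial gene expression and extracellular
recording quality around chronically implanted cortical microelectrodes.

Implanted recording electrodes provoke a foreign body reaction — reactive
astrogliosis, microglial activation, and neuronal loss — concentrated within
a few hundred micrometres of the device tract, and recording quality
declines over the same weeks. `peritract` implements the full analysis
chain that connects the two:

* **Spatial geometry** — spot centroid distances from the tract (point or
  polygon), half-open 100 µm annular bins, the 0–300 µm electrode-site
  cluster, seeded non-overlapping naive-matched sites, and radial
  neuronal-density (100 µm bins) / GFAP-intensity (10 µm bins) profiles.
* **MNA normalization** — every spot in a cluster scaled to the cluster's
  median total UMI count (`scale = median/total`); per-gene MNA = mean of
  normalized counts; depth (≥ 50 000 UMI/spot) and housekeeping-linearity
  (*Gapdh*, *Actb* vs spot totals) quality control.
* **Differential expression** — a negative-binomial conditional exact test
  (method-of-moments dispersions with James–Stein-type shrinkage, exact
  enumeration for small pooled counts, conditional-normal branch above),
  the low-count filter (mean < 1 count/spot in both clusters removed), and
  the significance rule *p* < 0.05 with |log₂ fold change| ≥ 0.6.
* **Recording quality** — common average reference, 500–6000 Hz zero-phase
  band-pass, ±3.5 SD snippet extraction (2.4 ms windows centred on the
  excursion minimum), 0.3–2× noise-floor RMS channel inclusion, and the
  formulas SNR = mean P2P / (6·SD noise), MUA = mean positive minus mean
  negative deflection, LFP = 6·SD of the 60 Hz-notched, 1–300 Hz band-passed
  raw signal, averaged per implant.
* **Biomarker screen** — consolidation of per-timepoint significant gene
  lists (union, max-|LFC| representative with sign), the electrode-site
  gene × sample MNA matrix, per-gene linear regression and gene-set
  principal-component regression against MUA, LFP, SNR, GFAP and neuronal
  density, and top-k candidate selection by the minimum of min–max
  normalized |LFC| and R².
* **Synthetic data** — seeded generators for Visium-like spot lattices with
  planted radial expression effects, spike-plus-noise multichannel
  recordings with known template amplitudes, IHC point sets and intensity
  fields, and multi-sample cohorts with planted gene–metric linear
  relationships, so every stage is testable with known ground truth.

## Worked example

Simulate an implanted and a naive tissue section, compare the 0–300 µm
electrode-site spots against a naive-matched site, and compute recording
metrics from a synthetic 16-channel recording:

```r
library(peritract)

ds_imp <- simulate_spot_dataset(sim_config(grid_shape = c(13, 13), seed = 1))
ds_nai <- simulate_spot_dataset(
  sim_config(grid_shape = c(13, 13), seed = 2),
  panel = within(gene_panel(), effect_amplitude <- 1))  # no tract effect

site  <- select_cluster(ds_imp$spots, ds_imp$tract, rmax_um = 300)
naive <- select_naive_sites(ds_nai$spots, n_sites = 1, radius_um = 300,
                            seed = 3)[[1]]

combined <- cbind(ds_imp$counts[, site$barcodes],
                  ds_nai$counts[, naive$barcodes])
colnames(combined) <- c(paste0("imp_", site$barcodes),
                        paste0("nai_", naive$barcodes))
de <- differential_expression(combined,
                              paste0("imp_", site$barcodes),
                              paste0("nai_", naive$barcodes))
head(de, 5)
#> # A tibble: 5 × 8
#>   gene  mean_norm_A mean_norm_B    lfc        p    p_adj significant neg_log10_p
#>   <chr>       <dbl>       <dbl>  <dbl>    <dbl>    <dbl> <lgl>             <dbl>
#> 1 Gfap        3679.       1446.  1.38  6.29e-29 1.26e-26 TRUE              28.2
#> 2 Lcn2        2289.       1263.  0.891 2.77e-17 2.65e-15 TRUE              16.6
#> 3 Hspb1       2696.       1237.  1.16  3.98e-17 2.65e-15 TRUE              16.4
#> 4 C3          1829.       1096.  0.773 4.74e-12 2.37e-10 TRUE              11.3
#> 5 Snap…        723.       1003. -0.439 2.84e- 8 1.14e- 6 FALSE              7.55
```

The planted markers surface with the expected directions: *Gfap* (8-fold at
the tract, decaying over 150 µm) is the top up-regulated gene with
LFC 1.38 over the 0–300 µm cluster; *Snap25* is down-regulated but at
LFC −0.44 misses the |LFC| ≥ 0.6 cut in this small section, so 4 genes pass
the significance rule. `autoplot(de)` draws the volcano plot.

```r
rec <- simulate_recording(ephys_sim_config(duration_s = 2, seed = 4))
glance(implant_metrics(rec))
#> # A tibble: 1 × 4
#>   snr_avg mua_avg_uv lfp_avg_uv n_included
#>     <dbl>      <dbl>      <dbl>      <int>
#> 1    5.34       69.7       296.         16
```

With the default planted template (100 µV peak-to-peak) over a 3 µV
spike-band noise floor, the recovered SNR of 5.34 sits close to the planted
ratio 100/(6·3) ≈ 5.56, and the LFP amplitude 296 µV tracks 6× the planted
50 µV low-frequency SD. `run_pipeline(pipeline_config(seed = 1), "out/")`
chains every stage — QC, per-timepoint DE against seeded naive sites,
consolidation, and the LFC-vs-R² screen — and writes all tables under
`out/`.

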