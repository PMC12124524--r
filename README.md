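# cohortscreen

Analysis pipeline for multi-donor, multi-drug Cell Painting screens of
induced pluripotent stem cell (iPSC) lines, with responder-stratified
differential proteomics.

## The scientific problem

Drug responses differ between people. One way to study that variability
*in vitro* is to expose a panel of donor-derived iPSC lines to the same
drug panel and quantify each line's morphological response with Cell
Painting — hundreds of per-well image features describing cell and
organelle shape, intensity, and texture. The analysis questions are:

1. **Normalization** — how strongly did a well respond, relative to the
   DMSO (vehicle) controls on its own plate? Each feature is scored as a
   robust Z: `z = (x − µ) / (1.4826 · MAD)` with `µ` the median and
   `MAD` the median absolute deviation of that plate's DMSO wells.
2. **Feature quality** — features unstable under control conditions
   (coefficient of variation > 0.50 across pooled DMSO wells) or
   redundant (|Spearman| > 0.98 with a retained feature) are removed.
3. **Response strength** — the **induction** score of a donor–drug pair
   is the fraction of retained features with `|z| > 2`. A matrix of
   induction values (donors × drugs) summarizes the screen; rows with
   consistently high or low values identify strong and weak responders.
4. **Reproducibility** — replicate assay runs are compared per feature
   with the 1-D Earth Mover Distance between the runs' well-level
   z-score distributions, judged against a DMSO-derived noise band.
   Cytotoxic drugs, which distort morphology and cell counts, fall
   outside the band.
5. **Molecular follow-up** — donors are stratified into high and low
   responders by induction rank, and DIA proteomes of both strata are
   tested per protein for drug-vs-DMSO effects. A protein is a
   responder-interaction hit when the effect is significant in **both**
   strata (`P_high ≤ 0.05` and `P_low ≤ 0.05`) and the strata differ by
   `|log2FC_high − log2FC_low| > 0.263` (1.2-fold).

The package includes a plate-structured synthetic screen generator and a
DIA-style proteome generator with planted ground truth (mechanism-of-
action signatures, responder quartiles, differential proteins), so the
full pipeline is testable without external data.

## Worked example

Simulate a small screen, normalize and filter, compute induction,
stratify responders for one drug, and run the stratified proteomic test:

```r
library(cohortscreen)

cfg <- screen_sim_config(n_donors = 8, n_drugs = 6, n_features = 60,
                         n_moa_classes = 3, cells_per_well = c(50, 80))
gs <- generate_screen(cfg, seed = 1)
gs$table
#> <well_feature_table> level=well, 624 records, 60 features
#> # A tibble: 624 × 69
#>    run_id plate_id    well  donor_id drug_id dose_uM bioreplicate tech_replicate
#>  * <chr>  <chr>       <chr> <chr>    <chr>     <dbl>        <int>          <int>
#>  1 run1   run1_B1_P01 A01   donor01  DMSO          0            1              1
#>  2 run1   run1_B1_P01 A02   donor02  DMSO          0            1              1
#>  3 run1   run1_B1_P01 A03   donor03  DMSO          0            1              1
#> # ℹ 621 more rows ...

z <- robust_z(gs$table)
z <- select_features(z, intersect(feature_names(z),
                                  filter_cov(gs$table)$retained))
z <- select_features(z, filter_spearman(z))

im <- induction(aggregate_features(z, "donor_drug"))
im
#> <induction_matrix> 8 donors x 6 drugs, sigma=2, 60 features
round(im$values[1:4, 1:4], 3)
#>         drug01 drug02 drug03 drug04
#> donor01  0.033  0.033  0.100  0.017
#> donor02  0.183  0.050  0.183  0.200
#> donor03  0.000  0.067  0.133  0.000
#> donor04  0.017  0.183  0.067  0.000

st <- stratify_responders(im, "drug01", k = 2)
st$high; st$low
#> [1] "donor02" "donor05"
#> [1] "donor03" "donor04"

q <- generate_proteome(cfg, gs$truth, c(st$high, st$low), "drug01", seed = 2)
q <- median_normalize(impute_missing(filter_valid(q)))
res <- stratified_differential(q, st$high, st$low, "drug01")
res
#> <stratified_differential> drug01: 5724 proteins, 162 pass p-gate, 62 survive both gates
head(res$surviving, 4)
#> # A tibble: 4 × 8
#>   protein_id fc_high     p_high fc_low      p_low log2fc_high_low pass_p pass_fc
#>   <chr>        <dbl>      <dbl>  <dbl>      <dbl>           <dbl> <lgl>  <lgl>
#> 1 P00076      -0.191 0.0225      0.211 0.0318              -0.402 TRUE   TRUE
#> 2 P00153       0.973 0.000116    0.543 0.00000449           0.430 TRUE   TRUE
#> 3 P00249       0.930 0.00000492  0.447 0.0000465            0.483 TRUE   TRUE
#> 4 P00258       0.989 0.00000212  0.627 0.00226              0.362 TRUE   TRUE
```

Cross-run comparison works analogously: generate two runs from the same
ground truth with different seeds and call
`compare_runs(run_a, run_b)`; the result carries per-(drug, feature)
median EMDs, the DMSO noise band, and the correlation between the two
runs' induction matrices.

## Command-line interface

A thin CLI over the same functions is installed at
`system.file("cli", "cohortscreen.R", package = "cohortscreen")`:

```sh
Rscript cohortscreen.R simulate   --seed 1 --out-dir out
Rscript cohortscreen.R induction  --in out/wells.csv --out-dir out
Rscript cohortscreen.R stratify   --in out/induction.csv --drug drug01 --k 2 --out-dir out
Rscript cohortscreen.R proteomics --intensities intens.csv --annotations ann.csv \
    --high donor02,donor05 --low donor03,donor04 --drug drug01 --out-dir out
```

Subcommands: `simulate | normalize | filter | induction | distances |
correlate | embed | compare-runs | stratify | proteomics`. Global flags:
`--config` (key = value file of thresholds; defaults `cov_max 0.50`,
`spearman_max 0.98`, `induction_sigma 2.0`, `log2fc_min 0.263`,
`p_max 0.05`, `valid_frac 0.333…`), `--seed`, `--out-dir`,
`--log-level`.

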