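# secretomix

Mesenchymal stromal cell (MSC) secretome — the soluble factors plus
extracellular vesicles (EVs) a cell population releases into conditioned
medium — is under active development as a cell-free therapeutic, and
inflammatory priming (e.g. IFNγ) is a common strategy to boost its potency.
Characterizing such a product means integrating three very different assay
layers: multiplex ELISA panels of secreted factors, qPCR-array profiles of
EV-embedded miRNAs, and flow-cytometry readouts of the secretome's effect on
inflamed target cells. `secretomix` implements that integration as a tested,
reusable pipeline for the paired resting-vs-primed donor design, together
with a synthetic-data generator that reproduces the design's detection
structure so every stage has ground-truth recovery tests.

## What it computes

**ELISA layer.** Concentrations (pg/ml) become secreted amounts per million
cells, `amount = conc × dilution × volume × 10⁶ / cells`; an analyte counts
as detected in a condition only when it exceeds its assay threshold in
*every* sample of that condition; detected analytes are tiered by mean
abundance (>100, 10–100, 1–10, ≤1 ng/10⁶ cells) and inter-donor concordance
is summarized as the mean pairwise Pearson R.

**EV-miRNA layer.** Raw Crt tables from a two-panel array are equalized via
the ath-miR-159a spike-in (panel B anchored to panel A), censored at the
amplification limit (Crt > 28 → unamplified), and global-mean normalized:
ΔCrt = Crt − mean(amplified Crt of the sample), relative expression
2^−ΔCrt. The first quartile of expression — the top ⌈n/4⌉ detected miRNAs by
mean relative expression — typically carries >95% of the "genetic message".
Functional categories (cartilage-protective/destructive, macrophage M1/M2)
are scored by **genetic weight**: the category's percent share of the summed
relative expression of all detected miRNAs.

**Contrast layer.** Priming effects are tested per analyte on per-donor
primed/resting ratios with a one-sample t-test against 1, after Grubbs
outlier screening, with calls `up`/`down` (fold > 2, p < 0.05), `trend`
(p < 0.1), `gained`/`lost` (detection changes), or `unchanged`.

**Flow layer.** Background-subtracted MFI fold changes, the CD86/CD163
polarization ratio (M1 vs M2 marker), and VCAM1-positivity ratios for
inflamed chondrocytes.

## Worked example

```r
library(secretomix)

cfg <- synthetic_config(seed = 7)      # 4 donors, 200 factors, 754 miRNAs
res <- run_secretome_pipeline(cfg)

length(res$elisa$amounts$detected$resting)   # 57 factors detected at rest
length(res$mirna$detected$resting)           # 242 miRNAs detected at rest
length(res$mirna$quartile$resting)           # 61 = ceiling(242 / 4)

genetic_weight(res$mirna$expression,
               as.character(res$mirna$quartile$resting), "resting")
#> <genetic_weight_report> subset (resting): 96.18% of the genetic message (61 miRNAs)

res$flow$polarization
#>   condition      cd86 cd163 polarization
#> 1 CTRL           1    1             1
#> 2 INFLAMED       1.45 0.635         2.33
#> 3 INFLAMED_PSEC  1.40 1.15          1.22
#> 4 INFLAMED_SEC   1.55 1.08          1.43
```

The 57 detected factors and the 242-miRNA detected set realize the
configured detection structure exactly; the first-quartile report shows the
heavy-tailed abundance law concentrating ~96% of the message in a quarter of
the detected miRNAs; the polarization table shows the inflamed condition
polarized to M1 (ratio 2.33 here, true fold ratio 1.41/0.74 ≈ 1.9 plus
sampling noise) and its rescue by secretome treatment. An injected 3.71-fold
priming effect on `factor_001` comes back as:

```r
dplyr::filter(res$elisa$contrast, analyte == "factor_001")
#>   analyte        n mean_ratio sd_ratio p_value q_value call
#> 1 factor_001     4       3.85     1.45  0.0295   0.230 up
```

Published annotation tables for the first-quartile EV-miRNAs ship as
fixtures, with each member's reference share of the genetic message:

```r
mac <- read_category_sets(system.file("extdata", "macrophage_categories.csv",
                                      package = "secretomix"))
reference_weight(mac$M2_phenotype, "resting")   # 26.22 (%)
```

A thin command-line front end over the same functions lives at
`inst/cli/secretomix.R` (subcommands `simulate`, `elisa`, `mirna`,
`contrast`, `flow`).

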