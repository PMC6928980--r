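# noisir

Eventfulness analysis of urban road-traffic noise monitoring: the
**intermittency ratio** (IR) on 1-s A-weighted SPL time series, clustering
of monitoring sites by their diurnal IR patterns, and a traffic-flow-based
logistic model that predicts a site's cluster without any acoustic data.

## Who this is for

Environmental-noise and exposure-assessment practitioners who hold
unattended 24-h sound level meter recordings (1-s A-weighted levels) from
urban road sites and want to go beyond `Leq`: to quantify how much of each
hour's acoustic energy is carried by distinct pass-by events — the
component most associated with annoyance and sleep disturbance — and to
classify sites by that eventfulness.

## The metric

For each clock hour with 1-s levels `L_i`, events are the maximal runs of
seconds strictly above the threshold

```
K = Leq,T,tot + C          (C = 3 dB by default)
```

and the intermittency ratio is the share of total energy above `K`:

```
IR = 100 * 10^(0.1*Leq,T,Events) / 10^(0.1*Leq,T,tot)   [%]
```

`IR ~ 0` means steady noise (e.g. a congested multi-lane road's roar);
`IR ~ 100` means the exposure is dominated by distinct pass-bys (a quiet
local street). Each event also gets its start time, duration and sound
exposure level `SEL = 10*log10(sum 10^(0.1*L_i))`.

Downstream, per-site hour-of-day medians form a sites × 24 matrix that is
column-standardized and clustered (complete linkage, DIANA, k-means, PAM;
two groups for sites and for hours), scored with seven validation
measures (connectivity, silhouette, Dunn, APN, AD, ADM, FOM), embedded by
classical MDS, and linked to traffic through
`x = sum over 3 hours of [log10(F_h)]^2` and a binomial logistic model
`P(cluster 2) = 1/(1 + exp(a + b*x))` with analytic (`P = 0.5`) and
empirical (minimum-misclassification) decision thresholds.

## Worked example

No campaign data are redistributable, so the package ships a physically
motivated pass-by simulator (Poisson arrivals on a diurnal flow profile,
moving-point-source pulses over an urban ambient background) used here as
input; with monitoring files use `read_cohort()`/`read_spl_file()`
instead.

```r
library(noisir)

cfg <- pipeline_config(out_dir = "demo_run", seed = 42,
                       sim = sim_config(sites_per_regime = 5,
                                        days_per_site = 2, seed = 42))
bundle <- run_pipeline(cfg)

# one hour of one site:
w <- segment_hours(bundle$cohort$series[["S01_2019-03-04"]])[[9]]
intermittency_ratio(w)
#> <ir_result> S01 2019-03-04 h08: Leq 81.0 dB, K 84.0 dB, IR 31.1%, 168 events
```

At the 08 h rush hour this simulated arterial site is loud
(`Leq = 81 dB`) but only 31% of its energy stands out of the traffic
roar — a low-eventfulness hour. The pipeline's cluster stage then selects
a method by mean validation rank and recovers the two generating regimes
exactly:

```r
bundle$cluster$selection$selected
#> [1] "diana"
table(cluster = bundle$cluster$sites$labels[bundle$cohort$truth$site_id],
      regime = bundle$cohort$truth$regime)
#>        regime
#> cluster arterial local
#>       1        5     0
#>       2        0     5

bundle$classify$fit
#> <logistic_fit> P(cluster 2) = 1/(1 + exp(-81.3 + 4.032 x)); x* = 22.1 [complete separation]
round(bundle$classify$empirical_threshold$threshold, 2)
#> [1] 20.46
```

Cluster 1 is the continuous-noise (arterial) group, cluster 2 the
eventful (local) group. On this small, cleanly separated cohort the
logistic fit reports complete separation, so the decision threshold
`x* = 22.1` comes from the separating midpoint and agrees with the
empirical box-plot-style threshold (20.5): sites whose three-hour flow
parameter `x` exceeds ~21 belong to the continuous-noise cluster. The
test-set confusion summary (both positive-class conventions), MDS
coordinates, Mann-Whitney hour ranking, dendrograms (Newick) and a
heatmap CSV are written under `demo_run/`; `manifest.txt` records the
seed and every decision parameter.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/noisir.R", package = "noisir"))')" \
    run-all --out demo_run --seed 42
```

## Scope notes

Model-based clustering and SOTA are not implemented; the method ranking
covers the four algorithms above. No audio ingestion or A-weighting: the
input is already-weighted 1-s levels in a 4-column text format (date,
time, level, source code; `T` road traffic, `M` masked). See
`vignettes/methods.Rmd` for the model, parameter meanings, generator
assumptions and known limitations.
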