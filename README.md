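# tectogain

Analysis pipeline for extracellular recordings from the mouse early visual
system (superficial superior colliculus, dLGN, LP/pulvinar, parabigeminal
nucleus, V1) under interleaved optogenetic manipulation, built around one
scientific question: when collicular activity is suppressed, does primary
visual cortex lose response *gain*, or does its size tuning change *shape*
— i.e. does surround suppression itself weaken?

The package implements the complete path from filtered voltage traces to
population statistics, plus a mechanistic synthetic-data generator used to
validate every stage closed-loop.

## What it computes

For a unit with direction-averaged evoked responses `R(s)` over stimulus
sizes `s`, the **surround suppression index** is

    SSI = (R_pref − R_large) / R_pref

with `R_pref` the response at the preferred size and `R_large` at the
largest presented size. The **evoked response** of a trial is the mean rate
over the 1 s stimulus window minus the spontaneous rate measured in the
0.5 s preceding onset; units enter the analysis only if their peak
laser-off response reaches 2 Hz. Orientation and direction selectivity are
resultant-vector indices over the direction tuning `R(φ)`:

    OSI = |Σ R(φ) e^{2iφ}| / Σ R(φ)      (= 1 − circular variance)
    DSI = |Σ R(φ) e^{iφ}|  / Σ R(φ)

Spikes are extracted from band-passed traces by 3 × SD threshold
crossings; receptive fields are mapped by spike-triggered averaging of
sparse-noise movies; the test battery gates parametric versus
nonparametric tests on per-group Shapiro–Wilk normality and asks the key
shape question through the laser × size interaction of a two-way ANOVA on
peak-normalised size-tuning curves.

The generator embeds the mechanism under study: subcortical areas follow
ratio-of-Gaussians size tuning whose driven rate the laser simply scales,
while V1 responses arise from a geniculate drive passed through divisive
normalization, `R = D·g / (σ + D·g + pool·g)` — so a size-independent
geniculate gain drop `g < 1` produces a size-dependent cortical effect and
a genuine SSI reduction, and a contrast reduction mimics it.

## Worked example

```r
library(tectogain)

cfg <- sim_config(seed = 1, n_units = c(V1 = 30), n_trials = 5,
                  directions_deg = seq(0, 300, 60), contrasts_pct = 95)
session <- simulate_session(cfg)   # interleaved laser-off/on spike trains
report  <- run_pipeline(session)
print(report)
```

```
<tg_report>
  included units: 30 of 30 
  mean SSI off 0.400 -> on 0.363 (n = 30 suppressed units)
optimal-size response, laser off vs on: paired t-test, statistic = 10.61, p = 1.68e-11, n = 30/30
SSI, laser off vs on (suppressed units): paired t-test, statistic = 1.873, p = 0.0712, n = 30/30
  laser x size interaction: p = 0.0828
```

Reading this: suppressing the simulated collicular input reliably lowers
optimal-size responses (first comparison), and the cohort-mean SSI drops
from 0.400 to 0.363 — at this small cohort and trial count the paired SSI
comparison and the shape interaction are suggestive but not yet
significant; the full-size cohorts used in the validation studies (150
units, 10 trials) detect the shape change with high power. Arithmetic
helpers reproduce published-scale derived values from printed means, e.g.

```r
percent_reduction(17.4, 11.6)   # 33 (% collicular response reduction)
ssi(30.5, 20.0)                 # 0.3443, the SSI of cohort-mean rates
```

A command-line wrapper is installed under `inst/exec/`:

```sh
Rscript inst/exec/tectogain simulate --out sess --seed 3 --units dLGN=8
Rscript inst/exec/tectogain analyze --manifest sess/manifest.json --out rep
Rscript inst/exec/tectogain report --dir rep
```

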