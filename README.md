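# evtgate

Extreme-value modeling of cross-modal (olfacto-visual) sensory
integration in retinal ganglion cell (RGC) spike-rate data.

In zebrafish, olfactory input reaches the retina over the olfacto-retinal
centrifugal pathway and lowers the light threshold at which RGCs respond:
with an odor present, spike rates below the normal response threshold
(~75 spikes/s) become probable. The mean response explains this poorly —
the information sits in the tails. `evtgate` implements the full analysis
for researchers studying such cross-modal modulation:

* **Distribution fitting and selection** — maximum-likelihood fits of the
  Gaussian, two-parameter Weibull and Generalized Pareto (GPD) families;
  a normality battery (Shapiro-Wilk preferred, Kolmogorov-Smirnov and a
  Monte-Carlo-calibrated Lilliefors reported); BIC ranking over a
  sixteen-family catalog, `BIC = k ln n − 2ℓ`, lower is better.
* **Generative sampling** — i.i.d. and random-walk Metropolis-Hastings
  samplers for the fitted laws, truncated to non-negative spike rates.
* **The Weibull tail model** — for the top-n responses `m_1 ≥ … ≥ m_n`
  with anchor `c = max m_j` and offset `δ`, the flipped values
  `t_i = (c + δ) − m_i` are fitted by Weibull maximum likelihood
  (density `(k/λ)(x/λ)^(k−1) exp(−(x/λ)^k)`), and
  `P(extreme ≤ x) = 1 − F_Weibull(c + δ − x)` is read back on the
  response axis. The **sensitivity shift** at threshold `T` is the
  olfaction-minus-control difference of that probability.
* **The indicator function I(x)** — a linear soft-margin SVM
  (`min ‖w‖² + C Σ ξ_i`) or a one-hidden-layer perceptron classifying
  22-dimensional response vectors as with/without olfactory stimulation.
* **A seeded synthetic-data generator** emulating the study conditions
  (22 with-olfaction responses, approximately Gaussian; 29 without,
  heavy-tailed GPD-like; threshold 75 spikes/s), so the entire pipeline
  is testable with no downloads. Its parameters are documented stand-ins,
  not published values.

## Worked example

```r
library(evtgate)

d <- generate_responses(canonical_config(), seed = 1)
d$olfaction
#> response series: olfaction (light 10^-6), 22 bins
#>   spikes/s: 51.87, 55.92, 50.82, 62.98, 56.65, 50.90, 57.44, 58.69 ...

normality_battery(d$control$values)
#> Normality battery (n = 29, alpha = 0.01)
#>                test statistic   p_value reject_at_alpha
#>        shapiro_wilk    0.8721 0.0022465            TRUE
#>  kolmogorov_smirnov    0.2201 0.1028600           FALSE
#>          lilliefors    0.2201 0.0006999            TRUE
#> preferred test: shapiro_wilk -> normality rejected

m_olf  <- fit_tail(d$olfaction$values, n = 3, condition = "olfaction")
m_ctrl <- fit_tail(d$control$values,  n = 3, condition = "control")
m_ctrl
#> Weibull tail model (top 3 of 29, control)
#>   anchor 629.2 spikes/s, offset 0.1449
#>   flipped-axis Weibull: shape k = 0.4693, scale lambda = 56.53

response_probability(m_olf, 75)   # 1
response_probability(m_ctrl, 75)  # 0.05395984
sensitivity_shift(m_olf, m_ctrl, 75)
#> [1] 0.9460402
```

The control series fails normality (Shapiro-Wilk p = 0.002) while the
olfaction series passes, reproducing the study's distributional split.
The olfaction tail model assigns probability 1 to responses at or below
75 spikes/s (all of its extremes sit below threshold), the control tail
model only 0.054, so the sensitivity shift at threshold is +0.95: with
olfaction engaged, sub-threshold responses go from improbable to
probable — the leftward shift of visual sensitivity.

The three full experiments (raw-data tail modeling; tail modeling of
100,000 generated responses per condition by direct and MCMC sampling;
repeated train/test evaluation of the SVM and MLP indicators) run from
one seeded configuration:

```r
reports <- run_all(experiment_config(seed = 101))
reports$experiment3$tables$accuracy
```

`fit_tail()` returns a classed model with the usual verbs: `print()`,
`coef()`, `predict()` (tail CDF at new responses), `plot()` (tuning
curve with the threshold marked), and `simulate()` (draws from the
fitted extreme-response law).

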