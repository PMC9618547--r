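# smacea

Cost-effectiveness modelling of gene-based therapies for spinal muscular
atrophy (SMA) Type I in Australia.

SMA Type I is a severe inherited neuromuscular disease: untreated infants
never sit independently and most die or need permanent assisted ventilation
(PAV) within their first years. Two disease-modifying therapies exist at
extraordinary prices — nusinersen (~A$110,000 per dose, four loading doses
then maintenance every four months for life) and onasemnogene abeparvovec
(AVXS-101, a ~A$3.05M one-time gene-replacement infusion). `smacea` is an R
package for health economists evaluating these therapies: it implements a
five-state Markov cohort model (not sitting/PAV-free → sitting → walking,
PAV, dead) with monthly cycles over a 100-year horizon, survival-based
transition probabilities, discounted cost and QALY accumulation with
half-cycle correction, incremental cost-effectiveness analysis,
deterministic and probabilistic sensitivity analysis, and threshold pricing
for the one-off therapy — plus the Kaplan–Meier reconstruction and
parametric-fitting machinery used to derive the transitions, and synthetic
generators for every external input.

## The model in brief

Patients start in `not_sitting` and move each month with probabilities
drawn from trial survival (`not_sitting` exits, per arm), a ventilated
natural-history cohort (`pav` → death, 0.0146/month), a Weibull
extrapolation of Type II survival for independent sitters
(S(t) = exp(−λ tᵖ), λ = 0.0006, p = 1.9613, t in years), and a
general-population life table for walkers. Trial milestone proportions (8%
sitting by 13 months under nusinersen; 11/12 sitting, 2/12 walking by 24
months under AVXS-101) are allocated uniformly across the trial windows.
Discounted outcomes feed the standard decision statistics:

- ICER = ΔCost / ΔQALY between two strategies (unrounded totals);
- NMB = WTP × QALYs − Cost at a willingness-to-pay threshold;
- threshold price: the ICER is affine in the one-off acquisition price with
  slope 1/ΔE, so price\*(WTP) = WTP·ΔE − (non-acquisition cost difference),
  verified by re-running the model at the solved price.

## Worked example

```r
library(smacea)

spec <- base_case_spec()   # the full packaged parameterisation
run_cea(spec)
#> <sma_cea> per-strategy discounted outcomes
#>    strategy      cost  qaly life_years
#>         SOC   962,759 0.311       3.76
#>  nusinersen 2,527,915 0.538       7.91
#>    AVXS-101 5,029,803 2.225      43.53
#> <sma_icer> nusinersen vs SOC: dCost $1,565,156, dQALY 0.227, ICER $6,897,947/QALY
#> <sma_icer> AVXS-101 vs SOC: dCost $4,067,044, dQALY 1.914, ICER $2,125,347/QALY
#> <sma_icer> AVXS-101 vs nusinersen: dCost $2,501,888, dQALY 1.687, ICER $1,483,313/QALY
```

Reading this: under standard of care a newborn cohort accrues A$962,759 in
discounted healthcare costs and 0.311 QALYs (most patients die within two
years, many after a PAV phase). AVXS-101 moves most of the cohort to the
sitting/walking milestones, adding 1.91 discounted QALYs at an incremental
A$4.07M — about A$2.13M per QALY gained, far above conventional Australian
willingness-to-pay. The threshold analysis asks what the one-off price
would have to be:

```r
threshold_price(spec, wtp = 5e5)
#> <sma_threshold> WTP $5e+05/QALY: not cost-effective at any non-negative price (closed form $-56,868)
```

Sensitivity analysis and reports:

```r
owsa(spec, span = 0.30)                      # tornado table
psa <- run_psa(spec, psa_config(spec, n = 5000, seed = 1))
ceac(psa, wtp_grid = seq(0, 7e6, 5e5))       # acceptability curve
cmd_basecase(spec, "out")                    # CSV reports + manifest
```

A thin command-line wrapper over the report functions ships at
`inst/cli/sma_cea.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sma_cea.R", package="smacea"))')" \
    basecase --out-dir out
```

The full model specification round-trips through a YAML config
(`system.file("extdata", "base_case.yaml", package = "smacea")`), so every
input — costs, utilities, transition probabilities, dosing calendars,
milestone windows — can be edited without touching code.

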