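# mvcjs — multistate hidden-Markov mark-recapture models of pinniped reproduction

`mvcjs` estimates age-, region- and year-specific reproduction of female
Steller sea lions from longitudinal resightings of individually marked
animals, for population ecologists working with mark-resight data in which
the biological state of interest is only partially observable.

A female's reproductive state each season is one of **Prebreeder** (P),
**With-Pup** (B), **With-Juvenile** (J) or **No-Dependent** (N); only B and
J can be confirmed by observation.  The package implements a
multivariate-state Cormack–Jolly–Seber model as a hidden Markov process
over reproductive state × location stratum (rookery/haulout) + Dead, with

- state-dependent resighting probability *p* and conditional offspring
  detection *δ* (a sighted female yields code `B`/`J` with probability
  *p δ*, an uncertain `u` with *p(1−δ)*),
- between-year survival *φ*, reproductive transitions *ψ* with structural
  zeros (P:J, P:N, B:P, J:P, N:P, N:J ≡ 0), and movement constrained by a
  robust-design occasion structure (3 rookery days + 1 pooled haulout
  occasion per year, pooled annual occasions in the early years),
- forward-algorithm maximum likelihood (Rcpp kernel with an adjoint-pass
  analytic gradient), formula-driven parameterisation with fixed-value
  masks, and AIC model selection.

Downstream of the fit: age-specific state proportions by the recursion
*P_i = P_{i−1} ψ_{P:P}*, *B_i = P_{i−1} ψ_{P:B} + B_{i−1} ψ_{B:B} +
J_{i−1} ψ_{J:B} + N_{i−1} ψ_{N:B}*, …; a neonatal-mortality correction
*B_corrected = B / φ_pup3wk(maternal age)* with
*φ_pup3wk = φ_w12² φ_w3*; multivariate-normal parametric-bootstrap
intervals on the link scale; and deterministic Leslie projection
(λ = dominant eigenvalue, r = ln λ) with delta-method confidence
intervals.  A full generative simulator mirrors the observation process so
every stage is testable without field data.

## Worked example

The `analysis/` drivers run the whole workflow on a synthetic population
generated under the study design (1262 females, 7 cohorts, 4 rookeries,
occasions 2001–2019) with rates seeded from the published point estimates:

```sh
Rscript analysis/01_simulate.R   # generate + encode (round-trip checked)
Rscript analysis/02_fit.R        # fit 3 model structures, AIC table
Rscript analysis/03_derived.R    # state proportions, correction, bootstrap
Rscript analysis/04_project.R    # Leslie projection with delta-method CI
```

Output from one run (seed 20260921):

```
marked females:            1262
entering the dataset:      973 (old-cohort females must survive to the 2005 surveys)

         model npar    logLik      AIC     dAIC     weight preferred
1         base   48 -12801.65 25699.30 0.000000 0.69031412      TRUE
2    phi_state   49 -12801.62 25701.23 1.934759 0.26237299     FALSE
3 no_region_bj   47 -12805.33 25704.66 5.360728 0.04731289     FALSE

north age-12: B = 0.611 (0.533-0.682)  J = 0.292  N = 0.096  Bcorr = 0.686
north recruited by age 8: 97.4%
south age-12: B = 0.701 (0.624-0.760)  J = 0.213  N = 0.085  Bcorr = 0.787

north lambda = 1.0012  r = +0.001 (-0.002, +0.004)
south lambda = 1.0063  r = +0.006 (+0.004, +0.009)
```

Reading this: the generating model (`base`) wins the AIC comparison; the
cost-of-reproduction alternative (`phi_state`, survival depending on
reproductive state) gains ~0 log-likelihood for one extra parameter and is
rejected, while dropping the regional contrast on With-Pup:With-Juvenile
(`no_region_bj`) costs 3.7 log-likelihood units — both mirroring the
patterns the model family was built to detect.  The derived age-12
proportions (≈0.6–0.7 with pup, ≈0.2–0.3 with juvenile, ≈0.1 without a
dependent), the ~95% cumulative recruitment by age 8, and growth rates of
a fraction of a percent per year are on the scale reported for this
population.

Programmatic use follows the same stages:

```r
library(mvcjs)
scen <- scenario_from_paper_defaults(seed = 1)
sim  <- simulate_population(scen)
ch   <- encode_histories(sim$sightings, sim$animals, scen$structure)
fit  <- fit_mvcjs(default_model_spec(), ch)
pr   <- state_proportions(psi_schedule(as_parameter_set(fit), "north"),
                          first_recruit_age = 4, max_age = 25)
```

## Package layout

- `R/` — occasion structure & encoding, matrix constructors, likelihood
  (+ `src/forward.cpp`), model specification & fitting, derived
  proportions, Leslie projection, simulator, pipeline.
- `analysis/` — numbered workflow drivers writing tables under `results/`.
- `vignettes/multistate-reproduction.Rmd` — the model, its assumptions,
  design decisions and validation design.
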