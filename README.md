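# ipmcor

Integral projection models (IPMs) with **nonindependent vital rates**.

Classical size-structured IPMs treat survival, reproduction, somatic
growth and offspring size as independent regressions on body size.  In
real populations these processes co-vary: reproducing costs growth, good
years lift growth and fecundity together, and persistently high-quality
individuals do better at everything.  `ipmcor` provides eight vital-rate
model variants that make such dependence explicit, Bayesian machinery to
fit them to individual-level mark–recapture panels, and the demographic
analyses (stochastic growth rates, sensitivities, elasticities) that
quantify what the dependence does to the population.  It is aimed at
population ecologists working with longitudinal individual data of the
Soay-sheep type: one row per individual-year with log body mass,
survival, breeding status, and offspring mass.

## The model family

All variants share four size-dependent vital rates (log body mass $m$):

$$
\begin{aligned}
a' \mid m &\sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}(\beta_{s,0} + \beta_{s,m} m)\right) &\text{survival}\\
r' \mid m &\sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}(\beta_{b,0} + \beta_{b,m} m + \cdot)\right) &\text{reproduction}\\
m' \mid m &\sim N(\beta_{g,0} + \beta_{g,m} m + \cdot,\ \sigma_g^2) &\text{growth}\\
c' \mid m &\sim N(\beta_{h,0} + \beta_{h,m} m,\ \sigma_h^2) &\text{offspring size}
\end{aligned}
$$

and differ in how growth and reproduction are coupled:

* **I1** — vanilla, no coupling;
* **I2 / D2b** — latent year effects $(u_{b,t}, u_{g,t})$, independent
  (I2) or correlated with $\rho$ (D2b);
* **I3 / D3** — lifelong individual effects $(v_{b,j}, v_{g,j})$,
  independent (I3) or correlated with $\psi$ (D3);
* **D1a** — breeding status shifts growth by $\beta_{g|r}$ (marginal
  growth becomes a two-Gaussian mixture with
  $\mathrm{cov}(m', r') = \beta_{g|r}\, b(1-b)$);
* **D1b** — a Gaussian copula with correlation $\alpha$ joins the
  Gaussian growth response to the (continuity-augmented) Bernoulli
  breeding response, leaving both marginals — and hence the projection
  kernel — exactly those of I1;
* **D2a** — an observed annual driver (e.g. winter NAO) enters both
  regressions.

The projection kernel
$k(x'|x) = s(x)\,[\,b(x)\,h(x'|x) + g(x'|x)\,]$ is discretized by the
midpoint rule; models with individual quality carry an extended state
$(m, v_b, v_g)$.  Growth rates come from eigenanalysis (time-invariant
models) or element-selection simulation
$\widehat{\log\lambda_s} = \log(N_L/N_{L_0})/(L-L_0)$ (temporal models);
sensitivities and elasticities from central differencing with common
random numbers.  Fitting is adaptive Metropolis-within-Gibbs with
analytic marginalization of missing breeding records.  See the vignette
(`vignettes/correlated-vital-rates.Rmd`) for the full methods account.

## Worked example

```r
library(ipmcor)

p    <- vr_params()              # Soay-like default parameter set
mesh <- make_mesh(params = p)    # 100 midpoint nodes, auto bounds

# asymptotic growth rate of the vanilla IPM
eigen_log_lambda(build_kernel("I1", p, mesh))
#> <growth_rate_estimate> log lambda = 0.026293358 (eigen)

# stochastic growth rate with strongly correlated year effects
stochastic_log_lambda("D2b", set_params(p, rho = 0.9), mesh, seed = 1)
#> <growth_rate_estimate> log lambda = 0.024607761 (element_selection, se = 0.000788)

# elasticity of the growth intercept
elasticity("I1", p, "beta_g0", mesh)
#> <perturbation_result> beta_g0: sensitivity = 0.916167, elasticity = 1.07087 (eigen)

# simulate a 30-year panel under correlated year effects and re-fit it
recs <- simulate_population("D2b", set_params(p, rho = 0.5),
                            n0 = 300, T_years = 30, seed = 3)
fit  <- fit_ipm("D2b", recs,
                mcmc_config(n_iter = 16000, n_burnin = 6000,
                            n_chains = 2, seed = 1, thin = 2))
fit
#> <posterior_samples> model D2b: 10000 draws x 13 parameters; max Rhat = 1.001 (converged)
s <- posterior_summary(fit)
s[s$parameter %in% c("rho", "nu2_b", "nu2_g"), ]
#>    parameter    mean       sd   q0.025    q0.5  q0.975
#> 11     nu2_b 0.26060 0.080208 0.142051 0.24681 0.45355
#> 12     nu2_g 0.00153 0.000434 0.000876 0.00146 0.00257
#> 13       rho 0.63655 0.120246 0.355397 0.65331 0.82435
```

Reading the output: the vanilla model at these parameters implies ~2.7%
asymptotic annual growth; switching on strongly correlated year effects
lowers the *stochastic* growth rate to ~2.5%.  A 1% change in the growth
intercept moves $\lambda$ by about 1.07% (elasticity > 1: growth is the
dominant lever).  The re-fit of the simulated panel recovers the
generating dependence: the true year-effect correlation 0.5 sits inside
the 95% interval (0.36, 0.82), as do $\nu_b^2 = 0.2025$ and
$\nu_g^2 = 0.0009$.

## Command line

A thin CLI wraps the same functions
(`inst/cli/ipmcor.R <subcommand> <config.yaml>`, subcommands `simulate`,
`fit`, `lambda`, `elasticity`, `study`, `case-study`).  Field data come
in through `read_demography_csv()` (user-supplied column mapping, blank
cells become missingness flags, optional log transform of raw mass) and
`read_nao_monthly()` (CRU-style monthly table, December–March winter
means aligned to the sheep year).

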