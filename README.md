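# rf3kin

Equilibrium-binding and rapid-kinetics analysis of the guanine-nucleotide
cycle of release factor RF3, the ribosome-dependent GTPase that recycles
the class-1 release factors RF1/RF2 after translation termination in
bacteria.

RF3 co-purifies with stoichiometric GDP, so its nucleotide affinities can
only be measured by competition, and its exchange and hydrolysis kinetics
only by stopped-flow fluorescence of mant-labeled nucleotides. `rf3kin`
implements the full analysis chain for such data:

* **Exact competition equilibria** — `solve_competition_equilibrium()`
  solves P + X ⇌ PX (K_d), P + I ⇌ PI (K_I) by monotone root-finding to
  1e-10 relative residual; it is the oracle behind every closed form in
  the package.
* **Tight-binding titration fits** — the ligand-depletion (quadratic)
  isotherm
  ΔF = B_max[(P + x + K_app) − √((P + x + K_app)² − 4Px)]/(2P)
  (`quadratic_isotherm()`, `fit_isotherm()`), the competitive correction
  K_d = K_app/(1 + [I]/K_I) (`correct_for_competitor()`), a
  depletion-aware ratio re-plot whose fitted statistic is the K_d/K_I
  ratio (`replot()`), and a two-site decomposition for biphasic
  titrations (`fit_two_site()`).
* **Stopped-flow transients** — 1–3-exponential fits by variable
  projection with deterministic multi-start (`fit_multiexp()`),
  phase-count selection by nested F-test (`select_n_phases()`), chase
  k_off extraction (`chase_koff()`), half-lives (`halflife()`).
* **Termination-cycle ODE model** — a mass-action network of the RF3
  GTPase cycle with the measured rate constants
  (`build_scheme()`, `simulate_cycle()`, `turnover_comparison()`),
  reproducing the claim that RF2 stimulates nucleotide *turnover*
  (35 vs 0.15 s⁻¹ GDP release) but not GTP hydrolysis itself.
* **Synthetic data** — generators for every input the fitters consume
  (`gen_trace_multiexp()`, `gen_titration()`,
  `gen_release_timecourse()`), driven by a fixture table of all printed
  constants (`make_fixtures()`), with seeded Gaussian noise and replicate
  averaging (`noise_spec()`).

## Worked example

Fit a simulated biexponential mantGTP-binding transient (true rates 34
and 0.35 s⁻¹, amplitude split 0.08/0.92, 1% noise averaged over 5
traces), letting the F-test choose the phase count:

```r
library(rf3kin)
tr  <- gen_trace_multiexp(list(c(0.08, 34), c(0.92, 0.35)), baseline = 0.1,
                          noise = noise_spec(0.01, 5, seed = 42))
fit <- select_n_phases(tr)
fit
#> 2-exponential fit (baseline 0.09935 +/- 0.00069)
#>   phase 1: k = 33.51 +/- 0.83 s-1 (t1/2 0.0207 s), amp 0.08027
#>   phase 2: k = 0.3492 +/- 0.00087 s-1 (t1/2 1.98 s), amp 0.9202
```

Both generating rates are recovered within their uncertainties and the
nested F-test stops at two phases (adding a third gives p = 0.11).

Estimate the mantGTP:GDP affinity ratio from a noiseless competition
titration generated by the exact solver (RF3 pre-loaded 1:1 with GDP,
2 µM each), then convert to an absolute K_d with the known GDP constant:

```r
fx <- get_fixture("fig3A_mantGTP")
cv <- gen_titration(fx, 2 * exp(seq(log(0.025), log(30), length.out = 40)),
                    Bmax = 1, noise = noise_spec(0))
rp <- replot(cv, fixed_total = 2, Bmax = 1)
rp
#> Competition re-plot (association mode)
#>   Kd ratio (varied/fixed) = 4.053
#>   response crosses 0.5 at added ratio 2.526
1000 * 0.005 * rp$half_saturation_ratio   # K_I(GDP) = 5 nM
#> [1] 20.3                                # Kd(mantGTP), nM
100 * occupancy_fraction(10, 4)
#> [1] 71.4                                # % GTP-bound RF3 in vivo
```

The re-plot statistic recovers the generating 4-fold affinity ratio
(note the raw half-saturation abscissa sits at 2.5, not 4 — ligand
depletion by the protein shifts it, which is why the fit, not the
crossing point, carries the estimate), giving K_d(mantGTP) ≈ 20 nM; with
a 10-fold cellular GTP:GDP excess that affinity ratio puts 71.4% of RF3
in the GTP-bound form.

A thin command-line front end over the same functions is in
`inst/cli/rf3kin.R` (subcommands `simulate`, `fit-trace`,
`fit-titration`, `replot`, `occupancy`, `cycle`, `reproduce`).

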