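test_that("competition solver satisfies mass action and conservation", {
  sys <- binding_system(P_total = 2, X_total = 4, I_total = 2,
                        K_d = 0.02, K_I = 0.005)
  eq <- solve_competition_equilibrium(sys)
  # mass-action relations
  expect_lt(abs(eq$PX - eq$P_free * eq$X_free / sys$K_d) / eq$PX, 1e-10)
  expect_lt(abs(eq$PI - eq$P_free * eq$I_free / sys$K_I) / eq$PI, 1e-10)
  # conservation laws
  expect_lt(abs(eq$P_free + eq$PX + eq$PI - sys$P_total) / sys$P_total, 1e-10)
  expect_lt(abs(eq$X_free + eq$PX - sys$X_total) / sys$X_total, 1e-10)
  expect_lt(abs(eq$I_free + eq$PI - sys$I_total) / sys$I_total, 1e-10)
})

test_that("competition solver limits: saturation, symmetry, degenerate inputs", {
  # excess tight label, no competitor: protein fully complexed
  eq <- solve_competition_equilibrium(
    binding_system(P_total = 1, X_total = 100, I_total = 0,
                   K_d = 0.001, K_I = 1))
  expect_rel_equal(eq$PX, 1, 1e-4)
  # identical ligands at identical totals bind identically
  eq <- solve_competition_equilibrium(
    binding_system(P_total = 2, X_total = 3, I_total = 3,
                   K_d = 0.05, K_I = 0.05))
  expect_equal(eq$PX, eq$PI, tolerance = 1e-12)
  # no ligand at all: everything free
  eq <- solve_competition_equilibrium(
    binding_system(P_total = 2, X_total = 0, I_total = 0,
                   K_d = 0.05, K_I = 0.05))
  expect_equal(eq$P_free, 2)
  expect_equal(eq$PX, 0)
})

test_that("solver residuals stay below 1e-10 across a parameter sweep", {
  set.seed(42)
  for (i in 1:50) {
    Pt <- stats::runif(1, 0.01, 10)
    sys <- binding_system(Pt, stats::runif(1, 0, 50), stats::runif(1, 0, 50),
                          10^stats::runif(1, -3, 1), 10^stats::runif(1, -3, 1))
    eq <- solve_competition_equilibrium(sys)
    expect_lt(abs(eq$P_free + eq$PX + eq$PI - Pt) / Pt, 1e-10)
  }
})

test_that("quadratic isotherm has the right limits and shape", {
  expect_equal(quadratic_isotherm(0, P = 1, K_app = 0.5, Bmax = 2), 0)
  # hyperbolic limit when protein is far below K_app
  x <- c(0.1, 0.5, 2, 10)
  quad <- quadratic_isotherm(x, P = 0.001, K_app = 1, Bmax = 1)
  hyp <- x / (x + 1)
  expect_true(all(abs(quad - hyp) / hyp < 0.01))
  # stoichiometric titration: half the sites filled at x = P/2
  expect_equal(quadratic_isotherm(0.5, P = 1, K_app = 1e-9, Bmax = 1), 0.5,
               tolerance = 1e-4)
  # saturation and monotonicity / concavity beyond x = P
  xx <- seq(0.01, 100, length.out = 400)
  y <- quadratic_isotherm(xx, P = 1, K_app = 0.3, Bmax = 1)
  expect_true(all(diff(y) >= 0))
  expect_rel_equal(quadratic_isotherm(1e6, P = 1, K_app = 0.3, Bmax = 1),
                   1, 1e-3)
  above <- xx > 1
  expect_true(all(diff(y[above], differences = 2) <= 1e-12))
})

test_that("isotherm fit round-trips noiseless data and flags saturation", {
  x <- exp(seq(log(0.02), log(10), length.out = 12))
  cv <- titration_curve(x, quadratic_isotherm(x, P = 0.05, K_app = 0.5,
                                              Bmax = 3))
  fit <- fit_isotherm(cv, P = 0.05)
  expect_rel_equal(fit$K_app, 0.5, 1e-6)
  expect_rel_equal(fit$Bmax, 3, 1e-6)
  # saturated from the first point: unidentifiable
  xs <- seq(50, 100, length.out = 8)
  sat <- titration_curve(xs, quadratic_isotherm(xs, P = 0.05, K_app = 0.5))
  expect_error(fit_isotherm(sat, P = 0.05), "unidentifiable")
})

test_that("competitor correction recovers the generating Kd from fitted K_app", {
  expect_equal(correct_for_competitor(1.2, I = 0), 1.2)
  expect_equal(correct_for_competitor(1.2, I = 0.005, K_I = 0.005), 0.6)
  # oracle round trip: exact-solver competitor titration -> K_app -> K_d
  for (Kd in c(0.0025, 0.02, 0.1, 0.5)) {  # Kd/K_I in [0.5, 100]
    I_tot <- 2; K_I <- 0.005; P <- 0.02
    x <- exp(seq(log(0.05), log(5000), length.out = 16))
    dF <- vapply(x, function(xt) {
      solve_competition_equilibrium(binding_system(P, xt, I_tot, Kd, K_I))$PX
    }, numeric(1)) / P
    fit <- fit_isotherm(titration_curve(x, dF), P = P)
    Kd_rec <- correct_for_competitor(fit$K_app, I = I_tot, K_I = K_I)
    expect_rel_equal(Kd_rec, Kd, 0.05)
  }
})

test_that("tight-competition response reduces to the no-depletion form", {
  r <- c(0.1, 0.5, 1, 4, 20)
  # with ligands in vast excess over protein the classical r/(r+rho) holds
  f <- tight_competition_response(r, rho = 4, i = 1e4)
  expect_true(all(abs(f - r / (r + 4)) < 1e-3))
  # equal affinities partition by totals whatever the depletion
  expect_equal(tight_competition_response(1, rho = 1, i = 1), 0.5)
})

test_that("replot recovers the Kd ratio and reports half-saturation", {
  rp <- replot_from_fixture("fig3A_mantGDP")
  expect_rel_equal(rp$half_saturation_ratio, 1, 0.05)
  expect_rel_equal(rp$r_half, 1, 0.05)  # 1:1 ratio at half-saturation
  # unsaturated curve without Bmax is refused
  fx <- get_fixture("fig3A_mantGTP")
  cv <- gen_titration(fx, ratio_grid(2, r_max = 0.5), Bmax = 1,
                      noise = noise_spec(0))
  expect_error(replot(cv, fixed_total = 2), "not saturated")
  # tight-competitor assumption warning
  cv2 <- gen_titration(fx, ratio_grid(2), Bmax = 1, noise = noise_spec(0))
  expect_warning(replot(cv2, fixed_total = 2, Bmax = 1, K_fixed = 0.1),
                 "tight-competitor")
})

test_that("replot closed form matches the exact solver pointwise", {
  # regime: fixed ligand >= 100 K_I, all totals far above K_d
  for (rho in c(2, 10, 50)) {
    K_I <- 0.005; Kd <- rho * K_I; P <- 2; I_tot <- 2
    r <- exp(seq(log(0.05), log(30), length.out = 25))
    f_exact <- vapply(r * I_tot, function(xt) {
      solve_competition_equilibrium(
        binding_system(P, xt, I_tot, Kd, K_I))$PX / P
    }, numeric(1))
    f_closed <- tight_competition_response(r, rho, i = I_tot / P)
    expect_lt(max(abs(f_closed - f_exact)), 0.02)
  }
})

test_that("occupancy fraction matches the saturating-limit formula", {
  expect_equal(occupancy_fraction(10, 4), (10 / 4) / (1 + 10 / 4))
  expect_equal(occupancy_fraction(1, 1), 0.5)
  expect_gt(occupancy_fraction(1e9, 4), 0.999)
  # monotone increasing in the concentration ratio, decreasing in Kd ratio
  r <- seq(0.5, 50, length.out = 20)
  expect_true(all(diff(vapply(r, occupancy_fraction, numeric(1), 4)) > 0))
  rho <- seq(0.5, 50, length.out = 20)
  expect_true(all(diff(vapply(rho, function(p)
    occupancy_fraction(10, p), numeric(1))) < 0))
  # absolute-concentration path agrees in the saturating regime
  f_abs <- occupancy_fraction(concentrations = list(
    RF3 = 0.001, GTP = 100, GDP = 10, Kd_GTP = 0.02, Kd_GDP = 0.005))
  expect_rel_equal(f_abs, occupancy_fraction(10, 4), 1e-3)
})

test_that("two-site fit separates and collapses correctly", {
  x <- exp(seq(log(1e-4), log(50), length.out = 30))
  # 1000-fold separated sites, noiseless: both recovered to < 1%
  cv <- titration_curve(x, 0.5 * x / (x + 0.001) + 0.5 * x / (x + 1))
  fit <- fit_two_site(cv)
  expect_rel_equal(fit$Kd1, 0.001, 0.01)
  expect_rel_equal(fit$Kd2, 1, 0.01)
  expect_rel_equal(fit$fraction1, 0.5, 0.01)
  expect_length(fit$flags, 0)
  # with 2% noise both Kds stay within 15%
  set.seed(11)
  cvn <- titration_curve(x, 0.5 * x / (x + 0.001) + 0.5 * x / (x + 1) +
                           stats::rnorm(length(x), 0, 0.02))
  fn <- fit_two_site(cvn)
  expect_rel_equal(fn$Kd1, 0.001, 0.15)
  expect_rel_equal(fn$Kd2, 1, 0.15)
  # single-site input collapses with a flag
  cv1 <- titration_curve(x, x / (x + 0.05))
  f1 <- fit_two_site(cv1)
  expect_true("collapsed_to_one_site" %in% f1$flags)
  expect_equal(f1$Bmax2, 0)
  expect_rel_equal(f1$Kd1, 0.05, 0.01)
})
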