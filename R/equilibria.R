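#' Describe an RF3 / labeled-nucleotide / competitor mixture
#'
#' A `binding_system` collects the total concentrations and dissociation
#' constants of a three-component competition equilibrium: a protein P
#' (RF3), a fluorescent (mant-labeled) nucleotide X reporting binding via
#' FRET, and an unlabeled competitor I (typically the GDP that co-purifies
#' with RF3 in a 1:1 ratio).
#'
#' @param P_total total protein concentration (µM).
#' @param X_total total labeled-nucleotide concentration (µM).
#' @param I_total total unlabeled-competitor concentration (µM).
#' @param K_d dissociation constant of the labeled nucleotide (µM).
#' @param K_I dissociation constant of the competitor (µM).
#' @return An object of class `binding_system`.
#' @examples
#' binding_system(P_total = 2, X_total = 4, I_total = 2,
#'                K_d = 0.02, K_I = 0.005)
#' @export
binding_system <- function(P_total, X_total, I_total = 0, K_d, K_I = 0.005) {
  stop_if_not_scalar_pos(P_total, "P_total", allow_zero = TRUE)
  stop_if_not_scalar_pos(X_total, "X_total", allow_zero = TRUE)
  stop_if_not_scalar_pos(I_total, "I_total", allow_zero = TRUE)
  stop_if_not_scalar_pos(K_d, "K_d")
  stop_if_not_scalar_pos(K_I, "K_I")
  structure(list(P_total = P_total, X_total = X_total, I_total = I_total,
                 K_d = K_d, K_I = K_I),
            class = "binding_system")
}

#' @export
print.binding_system <- function(x, ...) {
  cat("Competition binding system (concentrations in uM)\n")
  cat(sprintf("  P_total = %g, X_total = %g, I_total = %g\n",
              x$P_total, x$X_total, x$I_total))
  cat(sprintf("  K_d = %g, K_I = %g\n", x$K_d, x$K_I))
  invisible(x)
}

#' Exact mass-action solution of a two-ligand competition equilibrium
#'
#' Solves for the equilibrium concentrations of a mixture in which one
#' protein binds two mutually exclusive ligands,
#' P + X <-> PX (K_d) and P + I <-> PI (K_I).
#' Substituting the mass-action expressions into the ligand conservation
#' laws leaves a single monotone equation in free protein,
#' \deqn{P_f + P_f X_t/(K_d + P_f) + P_f I_t/(K_I + P_f) = P_t,}
#' which is solved by a bracketed root search on `[0, P_total]` followed by
#' Newton polishing. The result satisfies the mass-action relations and all
#' three conservation laws to a relative tolerance of 1e-10 or better; this
#' routine is the ground-truth oracle against which the closed-form
#' titration expressions in this package are validated.
#'
#' @param sys a [binding_system()].
#' @return A named list with components `P_free`, `PX`, `PI`, `X_free`,
#'   `I_free` (all µM).
#' @examples
#' eq <- solve_competition_equilibrium(
#'   binding_system(P_total = 2, X_total = 4, I_total = 2,
#'                  K_d = 0.02, K_I = 0.005))
#' eq$PX + eq$PI + eq$P_free  # = 2, protein conservation
#' @export
solve_competition_equilibrium <- function(sys) {
  stopifnot(inherits(sys, "binding_system"))
  Pt <- sys$P_total; Xt <- sys$X_total; It <- sys$I_total
  Kd <- sys$K_d; KI <- sys$K_I
  out <- function(Pf) {
    Xf <- Xt / (1 + Pf / Kd)
    If <- It / (1 + Pf / KI)
    list(P_free = Pf, PX = Pf * Xf / Kd, PI = Pf * If / KI,
         X_free = Xf, I_free = If)
  }
  if (Pt == 0) return(out(0))
  if (Xt == 0 && It == 0) return(out(Pt))
  g <- function(Pf) Pf + Pf * Xt / (Kd + Pf) + Pf * It / (KI + Pf) - Pt
  Pf <- stats::uniroot(g, c(0, Pt), tol = .Machine$double.eps)$root
  # Newton polish: g is smooth and monotone increasing, so this converges
  # quadratically to machine precision from the uniroot estimate.
  for (i in 1:6) {
    gp <- 1 + Xt * Kd / (Kd + Pf)^2 + It * KI / (KI + Pf)^2
    step <- g(Pf) / gp
    Pf <- min(max(Pf - step, 0), Pt)
    if (abs(step) < 1e-16 * max(Pf, Kd)) break
  }
  res <- abs(g(Pf)) / Pt
  if (is.na(res) || res > 1e-10) {
    stop("competition equilibrium solver failed to reach tolerance 1e-10 (",
         "residual ", signif(res, 3), "); the residual is monotone, so this ",
         "indicates a bracket or tolerance bug", call. = FALSE)
  }
  out(Pf)
}

#' Tight-binding (quadratic) titration isotherm
#'
#' Fluorescence change for a titration in which complex formation depletes
#' the added ligand, so the free concentration cannot be approximated by the
#' added concentration:
#' \deqn{\Delta F = B_{max} \frac{(P + x + K_{app}) -
#'   \sqrt{(P + x + K_{app})^2 - 4 P x}}{2P}.}
#' Evaluated in the numerically stable form
#' \eqn{2 B_{max} x / (S + \sqrt{S^2 - 4 P x})} with
#' \eqn{S = P + x + K_{app}}, which avoids cancellation at large `x`.
#'
#' @param x added ligand concentrations (µM); vectorized.
#' @param P total protein concentration (µM).
#' @param K_app apparent dissociation constant (µM).
#' @param Bmax fluorescence amplitude at saturation (signal units).
#' @return \eqn{\Delta F} at each `x` (same length as `x`).
#' @examples
#' quadratic_isotherm(c(0, 0.5, 50), P = 1, K_app = 0.5, Bmax = 1)
#' @export
quadratic_isotherm <- function(x, P, K_app, Bmax = 1) {
  stop_if_not_scalar_pos(P, "P")
  stop_if_not_scalar_pos(K_app, "K_app")
  if (any(x < 0)) stop("added-ligand concentrations must be non-negative",
                       call. = FALSE)
  S <- P + x + K_app
  Bmax * 2 * x / (S + sqrt(S^2 - 4 * P * x))
}

#' Construct a titration curve
#'
#' @param x added-ligand concentration grid (µM), strictly increasing,
#'   non-negative.
#' @param dF background-subtracted fluorescence change at each `x`.
#' @param sigma optional per-point standard deviation of `dF`, used as
#'   weights by the fitting routines.
#' @param meta optional condition label.
#' @return An object of class `titration_curve` (a data frame).
#' @export
titration_curve <- function(x, dF, sigma = NULL, meta = "") {
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE))
    stop("`x` must be strictly increasing", call. = FALSE)
  if (length(dF) != length(x)) stop("`x` and `dF` lengths differ", call. = FALSE)
  if (!is.null(sigma)) {
    if (length(sigma) != length(x) || any(sigma <= 0))
      stop("`sigma` must be positive and match `x` in length", call. = FALSE)
  }
  out <- data.frame(x = as.numeric(x), dF = as.numeric(dF))
  if (!is.null(sigma)) out$sigma <- as.numeric(sigma)
  structure(out, class = c("titration_curve", "data.frame"), meta = meta)
}

#' Fit the tight-binding isotherm to a titration curve
#'
#' Weighted nonlinear least squares of [quadratic_isotherm()] over
#' `(Bmax, K_app)` with the total protein concentration `P` fixed from the
#' experimental design. Parameters are log-transformed internally so both
#' stay positive; weights are `1/sigma^2` when the curve carries per-point
#' standard deviations and unity otherwise.
#'
#' @param curve a [titration_curve()] with at least 6 points spanning both
#'   sides of the apparent Kd.
#' @param P total protein concentration used in the titration (µM).
#' @return An object of class `isotherm_fit`: a list with `Bmax`, `K_app`,
#'   `P`, `stderr` (named, delta-method on the natural scale),
#'   `residual_norm`, and the underlying `nls` object in `$fit`.
#' @examples
#' x <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10)
#' cv <- titration_curve(x, quadratic_isotherm(x, P = 0.05, K_app = 0.5))
#' fit_isotherm(cv, P = 0.05)
#' @export
fit_isotherm <- function(curve, P) {
  stopifnot(inherits(curve, "titration_curve"))
  stop_if_not_scalar_pos(P, "P")
  if (nrow(curve) < 6)
    stop("need at least 6 titration points", call. = FALSE)
  dFmax <- max(curve$dF)
  if (dFmax <= 0) stop("titration curve carries no positive signal", call. = FALSE)
  if (curve$dF[1] >= 0.95 * dFmax) {
    stop("curve is saturated at the first point: K_app is unidentifiable ",
         "(add points below the apparent Kd)", call. = FALSE)
  }
  w <- if (!is.null(curve$sigma)) 1 / curve$sigma^2 else rep(1, nrow(curve))
  # starting values: amplitude from the plateau, K_app from the half-rise
  B0 <- dFmax * 1.05
  K0 <- max(stats::approx(curve$dF / B0, curve$x, xout = 0.5, ties = "ordered",
                          rule = 2)$y, 1e-6)
  fit <- minpack.lm::nlsLM(
    dF ~ quadratic_isotherm(x, P, exp(lK), exp(lB)),
    data = as.data.frame(curve), weights = w,
    start = list(lK = log(K0), lB = log(B0)),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- stats::coef(fit)
  se_log <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    c(lK = NA_real_, lB = NA_real_)
  })
  structure(list(
    Bmax = unname(exp(cf["lB"])),
    K_app = unname(exp(cf["lK"])),
    P = P,
    stderr = c(K_app = unname(exp(cf["lK"]) * se_log["lK"]),
               Bmax = unname(exp(cf["lB"]) * se_log["lB"])),
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    fit = fit
  ), class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("Tight-binding isotherm fit\n")
  cat(sprintf("  K_app = %.4g uM (se %.2g)\n", x$K_app, x$stderr["K_app"]))
  cat(sprintf("  Bmax  = %.4g    (se %.2g)\n", x$Bmax, x$stderr["Bmax"]))
  cat(sprintf("  P fixed at %g uM; residual norm %.3g\n", x$P, x$residual_norm))
  invisible(x)
}

#' Correct an apparent Kd for a competing ligand
#'
#' A competitor at concentration `I` with dissociation constant `K_I`
#' inflates the apparent dissociation constant of the observed ligand by
#' the standard competitive factor, so the true constant is
#' \deqn{K_d = K_{app} / (1 + I/K_I).}
#' Used to recover nucleotide affinities from titrations of RF3 that
#' carries stoichiometric GDP (K_I = 5 nM) from its purification.
#'
#' @param K_app apparent dissociation constant from the titration fit (µM).
#' @param I competitor concentration (µM).
#' @param K_I competitor dissociation constant (µM); defaults to the GDP
#'   value 0.005 µM.
#' @return The corrected dissociation constant K_d (µM).
#' @examples
#' correct_for_competitor(K_app = 2, I = 2, K_I = 0.005)
#' @export
correct_for_competitor <- function(K_app, I, K_I = 0.005) {
  stop_if_not_scalar_pos(K_app, "K_app")
  stop_if_not_scalar_pos(I, "I", allow_zero = TRUE)
  stop_if_not_scalar_pos(K_I, "K_I")
  K_app / (1 + I / K_I)
}

#' Tight-competition response as a function of the added:fixed ratio
#'
#' Occupancy of the protein by the varied ligand when both the varied and
#' the fixed (pre-bound) ligand bind much more tightly than their free
#' concentrations (K's << concentrations) and total nucleotide exceeds the
#' protein. Writing f for the fractional occupancy by the varied ligand,
#' r for the ratio of varied to fixed ligand totals, i for the ratio of
#' fixed ligand total to protein total and rho for the ratio of the varied
#' ligand's Kd to the fixed ligand's, mass action plus the conservation
#' laws give
#' \deqn{f^2(\rho - 1) + f(\rho i - \rho + 1 + r i) - r i = 0,}
#' solved here for the root in `[0, 1]`. When the ligand totals greatly
#' exceed the protein (no depletion) this reduces to the familiar
#' \eqn{f = r/(r + \rho)}, whose half-saturation sits at r = rho; with
#' stoichiometric pre-loading (i = 1) the half-saturation point moves to
#' \eqn{(1+\rho)/2}, which is why the fit must use the depletion-aware
#' form rather than read rho off the half-saturation point.
#'
#' @param r ratio of varied-ligand total to fixed-ligand total; vectorized.
#' @param rho ratio Kd(varied)/Kd(fixed).
#' @param i ratio of fixed-ligand total to protein total (default 1,
#'   the stoichiometrically pre-loaded design).
#' @return Fractional occupancy of the protein by the varied ligand.
#' @export
tight_competition_response <- function(r, rho, i = 1) {
  stop_if_not_scalar_pos(rho, "rho")
  stop_if_not_scalar_pos(i, "i")
  if (any(r < 0)) stop("`r` must be non-negative", call. = FALSE)
  x <- r * i
  a <- rho - 1
  b <- rho * i - rho + 1 + x
  if (abs(a) < 1e-12) return(x / b)
  # stable quadratic root in [0, 1]: q = -(b + sign(b) sqrt(b^2-4ac))/2
  disc <- sqrt(pmax(b^2 + 4 * a * x, 0))
  f <- 2 * x / (b + disc)         # works for a > 0 and a < 0 (root in [0,1])
  pmin(pmax(f, 0), 1)
}

#' Re-plot analysis of a competition titration
#'
#' Transforms a competition titration onto a ratio axis (varied ligand :
#' fixed ligand, as added) and estimates the ratio of dissociation
#' constants Kd/K_I by least squares on the tight-competition response
#' [tight_competition_response()]. In the classical no-depletion limit the
#' half-saturation of that response equals Kd/K_I; the fitted form also
#' accounts for ligand depletion by the protein, so the returned
#' `half_saturation_ratio` is the Kd-ratio estimate itself, valid in the
#' regime where the fixed ligand's free concentration stays far above its
#' K (the routine warns when `fixed_total < 100 * K_fixed`).
#'
#' Two experiment styles are supported: `"association"` titrates the
#' labeled nucleotide into protein pre-loaded with unlabeled competitor
#' (signal rises), and `"displacement"` titrates unlabeled competitor into
#' a purified protein–labeled-nucleotide complex (signal falls). In both
#' cases the response fitted is the occupancy by the varied species and
#' `half_saturation_ratio` is Kd(varied)/Kd(fixed).
#'
#' @param curve a [titration_curve()]; `x` is the added (varied) ligand (µM).
#' @param fixed_total total concentration of the fixed ligand (µM).
#' @param Bmax saturation amplitude. If `NULL`, taken as the maximum of the
#'   curve, which requires the curve to be saturated (last two responses
#'   within 2% of the maximum); otherwise an error is raised.
#' @param P total protein concentration (µM); defaults to `fixed_total`,
#'   the 1:1 pre-loaded design.
#' @param mode `"association"` or `"displacement"` (see Details).
#' @param K_fixed optional dissociation constant of the fixed ligand (µM),
#'   used only to check the tight-competitor assumption.
#' @return An object of class `replot_result`: list with `ratio_axis`,
#'   `response`, `half_saturation_ratio` (the Kd/K_I estimate),
#'   `r_half` (ratio at which the fitted response crosses 0.5) and
#'   `residual_norm`.
#' @export
replot <- function(curve, fixed_total, Bmax = NULL, P = fixed_total,
                   mode = c("association", "displacement"),
                   K_fixed = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  mode <- match.arg(mode)
  stop_if_not_scalar_pos(fixed_total, "fixed_total")
  stop_if_not_scalar_pos(P, "P")
  if (!is.null(K_fixed) && fixed_total < 100 * K_fixed) {
    warning("fixed_total < 100 * K_fixed: the tight-competitor assumption ",
            "behind the re-plot degrades in this regime", call. = FALSE)
  }
  if (is.null(Bmax)) {
    Bmax <- max(curve$dF)
    # the saturated end of the curve: last points (association, rising) or
    # first points (displacement, starting from the intact complex)
    plateau <- if (mode == "association") utils::tail(curve$dF, 2) else
      utils::head(curve$dF, 2)
    if (any(abs(plateau - Bmax) > 0.02 * Bmax)) {
      stop("Bmax not supplied and the curve is not saturated; supply Bmax ",
           "or extend the titration", call. = FALSE)
    }
  }
  f_obs <- switch(mode,
                  association = curve$dF / Bmax,
                  displacement = 1 - curve$dF / Bmax)
  r <- curve$x / fixed_total
  i <- fixed_total / P
  # weights proportional to 1/var of the normalized response
  w <- if (!is.null(curve$sigma)) (Bmax / curve$sigma)^2 else rep(1, length(r))
  w <- w / mean(w)
  obj <- function(lrho) {
    sum(w * (tight_competition_response(r, exp(lrho), i) - f_obs)^2)
  }
  opt <- stats::optim(log(1), obj, method = "Brent",
                      lower = log(1e-4), upper = log(1e6),
                      control = list(reltol = 1e-14))
  rho <- exp(opt$par)
  r_half <- tryCatch(
    stats::uniroot(function(rr) tight_competition_response(rr, rho, i) - 0.5,
                   c(1e-8, max(r) * 10))$root,
    error = function(e) NA_real_)
  structure(list(ratio_axis = r, response = f_obs,
                 half_saturation_ratio = rho, r_half = r_half,
                 mode = mode, i = i,
                 residual_norm = sqrt(opt$value)),
            class = "replot_result")
}

#' @export
print.replot_result <- function(x, ...) {
  cat(sprintf("Competition re-plot (%s mode)\n", x$mode))
  cat(sprintf("  Kd ratio (varied/fixed) = %.4g\n", x$half_saturation_ratio))
  cat(sprintf("  response crosses 0.5 at added ratio %.4g\n", x$r_half))
  invisible(x)
}

#' Fraction of RF3 in the GTP-bound form at cellular nucleotide levels
#'
#' In the saturating-nucleotide limit (both nucleotides far above their
#' Kd, protein negligible against nucleotide pools) the partition of RF3
#' between GTP- and GDP-bound forms depends only on the concentration
#' ratio r = \[GTP\]/\[GDP\] and the affinity ratio rho = Kd(GTP)/Kd(GDP):
#' \deqn{f_{GTP} = \frac{r/\rho}{1 + r/\rho}.}
#' With the cellular GTP:GDP ratio of at least 10 and the measured 4-fold
#' affinity difference this gives >70% GTP occupancy. If absolute
#' concentrations are supplied the exact competition solver is used
#' instead, which also accounts for sub-saturating nucleotide.
#'
#' @param conc_ratio_GTP_GDP concentration ratio \[GTP\]/\[GDP\].
#' @param Kd_ratio_GTP_GDP affinity ratio Kd(GTP)/Kd(GDP).
#' @param concentrations optional named list with absolute quantities
#'   `RF3`, `GTP`, `GDP`, `Kd_GTP`, `Kd_GDP` (µM); when given, the ratios
#'   are ignored and the exact solver is used.
#' @return Fraction of nucleotide-bound RF3 that carries GTP (0..1).
#' @examples
#' occupancy_fraction(10, 4)  # 0.714...
#' @export
occupancy_fraction <- function(conc_ratio_GTP_GDP, Kd_ratio_GTP_GDP,
                               concentrations = NULL) {
  if (!is.null(concentrations)) {
    cn <- concentrations
    eq <- solve_competition_equilibrium(binding_system(
      P_total = cn$RF3, X_total = cn$GTP, I_total = cn$GDP,
      K_d = cn$Kd_GTP, K_I = cn$Kd_GDP))
    return(eq$PX / (eq$PX + eq$PI))
  }
  stop_if_not_scalar_pos(conc_ratio_GTP_GDP, "conc_ratio_GTP_GDP")
  stop_if_not_scalar_pos(Kd_ratio_GTP_GDP, "Kd_ratio_GTP_GDP")
  z <- conc_ratio_GTP_GDP / Kd_ratio_GTP_GDP
  z / (1 + z)
}
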