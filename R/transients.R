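#' Construct a stopped-flow trace
#'
#' @param t time (s), strictly increasing, starting at >= 0, at least 20
#'   points.
#' @param y signal (arbitrary units), same length as `t`.
#' @param meta condition label.
#' @return An object of class `rf3_trace` (a data frame).
#' @export
as_trace <- function(t, y, meta = "") {
  if (length(t) < 20) stop("a trace needs at least 20 points", call. = FALSE)
  if (t[1] < 0 || is.unsorted(t, strictly = TRUE))
    stop("`t` must be strictly increasing and start at >= 0", call. = FALSE)
  if (length(y) != length(t)) stop("`t` and `y` lengths differ", call. = FALSE)
  structure(data.frame(t = as.numeric(t), y = as.numeric(y)),
            class = c("rf3_trace", "data.frame"), meta = meta)
}

# Variable projection: for fixed rates the baseline and amplitudes enter
# linearly, so they are eliminated by linear least squares and the
# nonlinear search runs over log-rates only.
varpro_design <- function(t, logk) cbind(1, exp(-outer(t, exp(logk))))

varpro_rss <- function(logk, t, y, sw) {
  X <- varpro_design(t, logk) * sw
  fit <- tryCatch(stats::.lm.fit(X, y * sw), error = function(e) NULL)
  if (is.null(fit)) return(.Machine$double.xmax)
  sum(fit$residuals^2)
}

# deterministic multi-start grid: all strictly decreasing n-subsets of
# `n_levels` log-spaced rate levels spanning the observable window,
# plus a spread-out start; returns a list of log-rate vectors
multiexp_starts <- function(n, t, n_levels = 4) {
  t_min <- max(min(t[t > 0]), 1e-6)
  span <- log(c(1 / (10 * max(t)), 10 / t_min))
  levels <- seq(span[1], span[2], length.out = n_levels)
  combs <- utils::combn(rev(levels), n, simplify = FALSE)
  c(combs, list(seq(span[2] - 0.1 * diff(span), span[1] + 0.1 * diff(span),
                    length.out = max(n, 2))[seq_len(n)]))
}

#' Fit a sum of exponentials to a stopped-flow trace
#'
#' Least-squares fit of `y(t) = baseline + sum_{i=1..n} a_i exp(-k_i t)`
#' with the baseline always floated. The search uses variable projection
#' (amplitudes and baseline solved linearly at each rate iterate) over
#' log-rates, started from a deterministic log-spaced grid spanning the
#' observable rate window so that adjacent-rate local minima are escaped;
#' the best start is polished to high precision. Standard errors come from
#' the linearized covariance of the full nonlinear model.
#'
#' @param trace an [as_trace()] object (weights taken as 1).
#' @param n number of exponential phases, 1-3.
#' @param rate_collision_tol relative rate separation below which two
#'   phases are flagged unidentifiable (default 0.05).
#' @return An object of class `multi_exp_fit`: `n`, `phases` (data frame
#'   with `amplitude`, `rate`, `stderr_rate`, `t_half`, sorted fast to
#'   slow), `baseline`, `baseline_se`, `residual_norm`, `sigma`, `aic`,
#'   `flags` (character vector, possibly empty), `fitted`.
#' @examples
#' tr <- gen_trace_multiexp(list(c(1, 0.13)), noise = noise_spec(0, seed = 1))
#' fit_multiexp(tr, 1)$phases$rate
#' @export
fit_multiexp <- function(trace, n, rate_collision_tol = 0.05) {
  stopifnot(inherits(trace, "rf3_trace"))
  if (!n %in% 1:3) stop("`n` must be 1, 2 or 3", call. = FALSE)
  t <- trace$t; y <- trace$y
  sw <- rep(1, length(t))
  if (n == 1) {
    # one-dimensional problem: a single Brent search over the whole
    # observable rate window is global
    t_min <- max(min(t[t > 0]), 1e-6)
    best <- stats::optim(log(1 / max(t)), varpro_rss, t = t, y = y, sw = sw,
                         method = "Brent",
                         lower = log(1 / (100 * max(t))),
                         upper = log(100 / t_min),
                         control = list(maxit = 500, reltol = 1e-14))
  } else {
    starts <- multiexp_starts(n, t)
    fits <- lapply(starts, function(s) {
      stats::optim(s, varpro_rss, t = t, y = y, sw = sw, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-13))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  }
  # polish with Nelder-Mead from the best start (robust near the optimum)
  if (n > 1) {
    best <- stats::optim(best$par, varpro_rss, t = t, y = y, sw = sw,
                         method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-15))
  }
  logk <- best$par
  X <- varpro_design(t, logk)
  lin <- stats::lm.fit(X, y)
  coefs <- lin$coefficients
  baseline <- coefs[1]; amp <- coefs[-1]; k <- exp(logk)
  ord <- order(k, decreasing = TRUE)
  k <- k[ord]; amp <- amp[ord]
  rss <- sum(lin$residuals^2)
  N <- length(y); p <- 2 * n + 1
  sigma2 <- rss / max(N - p, 1)
  # full-model Jacobian: d/d(baseline), d/d(a_i), d/d(k_i)
  E <- exp(-outer(t, k))
  J <- cbind(1, E, -sweep(E * t, 2, amp, `*`))
  cv <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  se <- if (is.null(cv)) rep(NA_real_, p) else sqrt(pmax(diag(cv), 0))
  flags <- character(0)
  if (n > 1) {
    sep <- abs(diff(k)) / k[-n]
    if (any(sep < rate_collision_tol))
      flags <- c(flags, "rate_collision: adjacent rates closer than the collision tolerance; phases unidentifiable")
  }
  if (best$convergence != 0)
    flags <- c(flags, "non_convergence: optimizer did not report convergence")
  structure(list(
    n = n,
    phases = data.frame(amplitude = unname(amp), rate = unname(k),
                        stderr_rate = se[1 + n + seq_len(n)],
                        stderr_amplitude = se[1 + seq_len(n)],
                        t_half = log(2) / unname(k)),
    baseline = unname(baseline), baseline_se = se[1],
    residual_norm = sqrt(rss), sigma = sqrt(sigma2),
    aic = N * log(rss / N) + 2 * (p + 1),
    flags = flags,
    fitted = drop(X %*% coefs)
  ), class = "multi_exp_fit")
}

#' @export
print.multi_exp_fit <- function(x, ...) {
  cat(sprintf("%d-exponential fit (baseline %.4g +/- %.2g)\n",
              x$n, x$baseline, x$baseline_se))
  ph <- x$phases
  for (i in seq_len(nrow(ph))) {
    cat(sprintf("  phase %d: k = %.4g +/- %.2g s-1 (t1/2 %.3g s), amp %.4g\n",
                i, ph$rate[i], ph$stderr_rate[i], ph$t_half[i],
                ph$amplitude[i]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Choose the number of exponential phases by nested F-test
#'
#' Fits 1..`max_n` exponentials and returns the smallest `n` that is not
#' rejected against `n+1` by the extra-sum-of-squares F-test at level
#' `alpha`; AIC for every candidate is reported alongside.
#'
#' @param trace an [as_trace()] object.
#' @param max_n largest phase count to consider (<= 3).
#' @param alpha F-test level (default 0.01).
#' @return The selected `multi_exp_fit`, with a data frame of candidates in
#'   `$selection` (columns `n`, `rss`, `aic`, `p_vs_next`).
#' @export
select_n_phases <- function(trace, max_n = 3, alpha = 0.01) {
  stopifnot(max_n >= 1, max_n <= 3)
  fits <- lapply(seq_len(max_n), function(n) fit_multiexp(trace, n))
  N <- nrow(trace)
  rss <- vapply(fits, function(f) f$residual_norm^2, numeric(1))
  pvals <- rep(NA_real_, max_n)
  chosen <- max_n
  for (n in seq_len(max_n - 1)) {
    df2 <- N - (2 * (n + 1) + 1)
    Fstat <- ((rss[n] - rss[n + 1]) / 2) / (rss[n + 1] / df2)
    pvals[n] <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
    if (pvals[n] > alpha) { chosen <- n; break }
  }
  out <- fits[[chosen]]
  out$selection <- data.frame(
    n = seq_len(max_n), rss = rss,
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    p_vs_next = pvals)
  out
}

#' Dissociation rate constant from a chase experiment
#'
#' A chase experiment mixes a preformed labeled complex with a large
#' excess of unlabeled competitor, so rebinding of the label is negligible
#' and the fluorescence decays single-exponentially with the dissociation
#' rate constant. This is a single-exponential [fit_multiexp()].
#'
#' @param trace an [as_trace()] object.
#' @return A list with `k_off` (s^-1), `stderr`, `t_half` and the full
#'   `multi_exp_fit` in `$fit`.
#' @export
chase_koff <- function(trace) {
  f <- fit_multiexp(trace, 1)
  list(k_off = f$phases$rate[1], stderr = f$phases$stderr_rate[1],
       t_half = f$phases$t_half[1], fit = f)
}

#' Half-life of each fitted phase
#'
#' @param fit a `multi_exp_fit`.
#' @return `log(2) / k_i` for each phase (s), fast to slow.
#' @export
halflife <- function(fit) {
  stopifnot(inherits(fit, "multi_exp_fit"))
  log(2) / fit$phases$rate
}
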