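#' Measurement-noise specification
#'
#' Gaussian noise applied to synthetic signals, expressed as a fraction of
#' the total signal amplitude, with averaging over replicate traces as in
#' stopped-flow practice (recorded time courses are averages of several
#' individual shots).
#'
#' @param sigma_frac standard deviation as a fraction of the total signal
#'   amplitude (default 0.01).
#' @param n_averages number of replicate traces averaged (default 5).
#' @param seed integer seed; identical seeds give identical output. `NULL`
#'   draws from the ambient RNG stream.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_frac = 0.01, n_averages = 5, seed = NULL) {
  stop_if_not_scalar_pos(sigma_frac, "sigma_frac", allow_zero = TRUE)
  if (!is.numeric(n_averages) || n_averages < 1 ||
      n_averages != round(n_averages))
    stop("`n_averages` must be an integer >= 1", call. = FALSE)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(sigma_frac = sigma_frac, n_averages = as.integer(n_averages),
                 seed = seed),
            class = "noise_spec")
}

# additive noise for a signal of total amplitude `amplitude`: the mean of
# n_averages independent Gaussian replicates per point
apply_noise <- function(n_points, amplitude, noise) {
  if (noise$sigma_frac == 0) return(rep(0, n_points))
  sd_eff <- noise$sigma_frac * amplitude
  with_seed(noise$seed, {
    rowMeans(matrix(stats::rnorm(n_points * noise$n_averages, 0, sd_eff),
                    nrow = n_points))
  })
}

#' Logarithmically spaced stopped-flow time grid
#'
#' Stopped-flow instruments oversample early times; the default grid runs
#' from 1 ms to 10 half-lives of the slowest phase, log-spaced.
#'
#' @param k_slowest slowest rate constant of interest (s^-1).
#' @param n number of points (default 500).
#' @param t_min first time point (s; default 0.001).
#' @return A strictly increasing numeric vector of times (s).
#' @export
log_time_grid <- function(k_slowest, n = 500, t_min = 1e-3) {
  stop_if_not_scalar_pos(k_slowest, "k_slowest")
  t_max <- 10 * log(2) / k_slowest
  if (t_max <= t_min) t_max <- t_min * 100
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Simulate a multi-exponential stopped-flow trace
#'
#' Signal model: `baseline + sum_i a_i * exp(-k_i * t)`, plus averaged
#' Gaussian noise scaled to the total amplitude `sum |a_i|`. With
#' `sigma_frac = 0` the closed form is returned exactly.
#'
#' @param phases list of `c(amplitude, rate)` pairs, or a 2-column matrix
#'   (amplitude, rate in s^-1).
#' @param baseline signal offset (signal units).
#' @param grid strictly increasing time grid starting at >= 0 (s); default
#'   [log_time_grid()] for the slowest phase.
#' @param noise a [noise_spec()].
#' @param meta condition label attached to the trace.
#' @return An [as_trace()] object with columns `t`, `y`.
#' @examples
#' tr <- gen_trace_multiexp(list(c(1, 0.13)), baseline = 0.2,
#'                          noise = noise_spec(0, seed = 1))
#' @export
gen_trace_multiexp <- function(phases, baseline = 0, grid = NULL,
                               noise = noise_spec(), meta = "") {
  if (is.matrix(phases)) phases <- asplit(phases, 1)
  if (length(phases) == 0) stop("empty phase list", call. = FALSE)
  amp <- vapply(phases, `[`, numeric(1), 1)
  k <- vapply(phases, `[`, numeric(1), 2)
  if (any(k <= 0)) stop("rates must be positive", call. = FALSE)
  if (is.null(grid)) grid <- log_time_grid(min(k))
  if (length(grid) < 2 || is.unsorted(grid, strictly = TRUE) || grid[1] < 0)
    stop("time grid must be strictly increasing and start at >= 0",
         call. = FALSE)
  y <- baseline + drop(exp(-outer(grid, k)) %*% amp)
  y <- y + apply_noise(length(grid), sum(abs(amp)), noise)
  as_trace(grid, y, meta = meta)
}

#' Simulate an equilibrium competition titration
#'
#' Generates the background-subtracted fluorescence change for titrating a
#' mant-labeled nucleotide into protein pre-loaded with an unlabeled
#' competitor (`style = "association"`), or an unlabeled competitor into a
#' preformed protein-label complex (`style = "displacement"`). Bound-label
#' concentrations come from the exact mass-action solver
#' [solve_competition_equilibrium()], and the FRET signal is linear in the
#' labeled complex: `dF = Bmax * [PX] / P_total`.
#'
#' @param truth a `ground_truth` titration fixture (fields `Kd`, `K_fixed`,
#'   `P_total`, `fixed_total`, `style`), or a list with those fields.
#' @param x_grid added-ligand concentrations (µM), strictly increasing.
#' @param Bmax saturation amplitude (signal units).
#' @param noise a [noise_spec()].
#' @return A [titration_curve()] (with `sigma` set when noise is non-zero).
#' @export
gen_titration <- function(truth, x_grid, Bmax = 1, noise = noise_spec()) {
  p <- if (inherits(truth, "ground_truth")) truth$params else truth
  style <- p$style %||% "association"
  if (any(x_grid < 0)) stop("negative concentrations", call. = FALSE)
  P <- p$P_total; fixed <- p$fixed_total %||% P
  stop_if_not_scalar_pos(P, "P_total")
  bound_label <- vapply(x_grid, function(xt) {
    eq <- if (style == "displacement") {
      # label fixed at `fixed`, unlabeled competitor added at xt
      solve_competition_equilibrium(binding_system(
        P_total = P, X_total = fixed, I_total = xt,
        K_d = p$K_fixed, K_I = p$Kd))
    } else {
      solve_competition_equilibrium(binding_system(
        P_total = P, X_total = xt, I_total = fixed,
        K_d = p$Kd, K_I = p$K_fixed))
    }
    eq$PX
  }, numeric(1))
  dF <- Bmax * bound_label / P
  eps <- apply_noise(length(x_grid), Bmax, noise)
  sig <- if (noise$sigma_frac > 0)
    rep(noise$sigma_frac * Bmax / sqrt(noise$n_averages), length(x_grid))
  titration_curve(x_grid, dF + eps, sigma = sig,
                  meta = if (inherits(truth, "ground_truth"))
                    truth$condition_id else "")
}

#' Simulate a first-order peptide-release time course
#'
#' Fraction of peptidyl-tRNA remaining,
#' `fraction(t) = exp(-(k_release + k_background) * t)`, where
#' `k_background` is the slow spontaneous hydrolysis seen in buffer
#' controls. Noise is Gaussian relative to the unit amplitude.
#'
#' @param k_release factor-catalyzed release rate constant (s^-1, >= 0).
#' @param k_background spontaneous hydrolysis rate constant (s^-1, >= 0).
#' @param grid time grid (s); default log-spaced over the decay.
#' @param noise a [noise_spec()].
#' @return An [as_trace()] object (`y` = fraction remaining).
#' @export
gen_release_timecourse <- function(k_release, k_background = 6e-5,
                                   grid = NULL, noise = noise_spec()) {
  stop_if_not_scalar_pos(k_release, "k_release", allow_zero = TRUE)
  stop_if_not_scalar_pos(k_background, "k_background", allow_zero = TRUE)
  k_tot <- k_release + k_background
  if (is.null(grid)) {
    grid <- if (k_tot > 0) log_time_grid(k_tot, n = 100, t_min = 0.05)
    else seq(1, 3600, length.out = 100)
  }
  y <- exp(-k_tot * grid) + apply_noise(length(grid), 1, noise)
  as_trace(grid, y, meta = "release")
}
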