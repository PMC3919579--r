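#' Ground-truth parameter set for one experimental condition
#'
#' A `ground_truth` entry pairs a condition label with the constants that
#' define it (rates in s^-1, concentrations and dissociation constants in
#' µM, amplitude fractions dimensionless) and a citation of the figure
#' legend or Results sentence the constants were printed in. These entries
#' drive the synthetic-data generators and are the reference values that
#' parameter-recovery tests check against.
#'
#' @param condition_id short text label, e.g. `"fig1A_free_RF3"`.
#' @param model one of `"multi_exp"`, `"chase"`, `"titration"`,
#'   `"release"`, `"scheme"`.
#' @param params named list of constants; rate entries must be positive,
#'   amplitude fractions (element `amps`) must sum to 1.
#' @param source citation string (figure legend / Results sentence).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(condition_id, model, params, source) {
  model <- match.arg(model,
                     c("multi_exp", "chase", "titration", "release", "scheme"))
  stopifnot(is.character(condition_id), nchar(condition_id) > 0,
            is.list(params), is.character(source), nchar(source) > 0)
  rate_names <- grep("^(k|rates)", names(params), value = TRUE)
  # release assays allow zero rates (buffer control / inactive factor)
  rate_names <- setdiff(rate_names, c("k_background", "k_release"))
  for (nm in rate_names) {
    if (!grepl("_err$", nm) && any(params[[nm]] <= 0))
      stop("rate `", nm, "` must be positive in fixture ", condition_id,
           call. = FALSE)
  }
  if (!is.null(params$amps)) {
    if (abs(sum(params$amps) - 1) > 1e-8)
      stop("amplitude fractions must sum to 1 in fixture ", condition_id,
           call. = FALSE)
  }
  structure(list(condition_id = condition_id, model = model,
                 params = params, source = source),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s [%s]\n", x$condition_id, x$model))
  for (nm in names(x$params)) {
    cat(sprintf("  %-16s %s\n", nm, paste(signif(x$params[[nm]], 4),
                                          collapse = ", ")))
  }
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' Fixture table of all printed constants
#'
#' Returns one [ground_truth()] entry per distinct experimental condition
#' whose parameters are printed in the source study's figure legends or
#' Results text: dissociation (chase) rate constants, multi-exponential
#' apparent rates with their amplitude splits, peptide-release rates,
#' relative and absolute equilibrium constants, and the GTPase-cycle rate
#' table. Rates are s^-1, concentrations and K's µM; `*_err` entries carry
#' the printed uncertainties. Amplitude splits that were not printed are
#' declared package assumptions and are marked `amps_assumed = TRUE`.
#'
#' @return A named list of `ground_truth` objects (>= 15 conditions).
#' @examples
#' fx <- make_fixtures()
#' fx$fig1A_free_RF3$params$k_off
#' @export
make_fixtures <- function() {
  fx <- list(

    # --- GDP dissociation kinetics (chase with excess unlabeled nucleotide)
    ground_truth("fig1A_free_RF3", "chase",
      list(k_off = 0.13, k_off_err = 0.01, competitor = "GDP"),
      "Results, GDP dissociation from unbound RF3: 0.13 +/- 0.01 s-1 (Fig 1A)"),
    ground_truth("fig1C_vacant_ribosome", "chase",
      list(k_off = 0.15, k_off_err = 0.05, competitor = "GDP"),
      "Results, mantGDP dissociation from ribosome-bound RF3 ~0.15 s-1 (Fig 1C)"),
    ground_truth("fig1E_vacant_RF2GGA", "chase",
      list(k_off = 0.15, k_off_err = 0.05, competitor = "GTP"),
      "Fig 1E legend, trace 1: 0.15 +/- 0.05 s-1 (vacant ribosomes, single round)"),
    ground_truth("fig1E_preTC", "chase",
      list(k_off = 35, k_off_err = 5, competitor = "GTP"),
      "Fig 1E legend, traces 2-4: 35 +/- 5 s-1 (Pre/PostTC with RF2(GGA))"),
    ground_truth("fig4C_free_RF3_mantGDPNP", "chase",
      list(k_off = 24, k_off_err = 1, competitor = "GDPNP"),
      "Fig 4C legend, single-exponential fit k_off = 24 +/- 1 s-1"),
    ground_truth("fig4D_ribosome_mantGDPNP", "chase",
      list(k_off = 0.025, k_off_err = 0.001, competitor = "GDPNP"),
      "Fig 4D legend, k_off = 0.025 +/- 0.001 s-1 (RF3 on ribosomes)"),

    # --- peptide release time courses (fraction peptidyl-tRNA remaining)
    ground_truth("fig1B_RF2_release", "release",
      list(k_release = 0.9, k_release_err = 0.1, k_background = 6e-5),
      "Fig 1B legend, RF2: k = 0.9 +/- 0.1 s-1"),
    ground_truth("fig1B_RF2GGA_release", "release",
      list(k_release = 1.5e-3, k_release_err = 1e-4, k_background = 6e-5),
      "Fig 1B legend, RF2(GGA): k = (1.5 +/- 0.1) x 10^-3 s-1"),
    ground_truth("fig1B_buffer", "release",
      list(k_release = 0, k_background = 6e-5, k_background_err = 2e-5),
      "Fig 1B legend, buffer control: k = (6 +/- 2) x 10^-5 s-1"),

    # --- nucleotide binding transients (multi-exponential)
    ground_truth("fig2A_free_mantGTP", "multi_exp",
      list(rates = c(34, 0.35), rates_err = c(5, 0.01),
           amps = c(0.08, 0.92), amps_assumed = FALSE),
      "Fig 2A legend, mantGTP: k_app1 = 34 +/- 5, k_app2 = 0.35 +/- 0.01 s-1; major amplitude (>90%) in the slow phase"),
    ground_truth("fig2A_free_mantGDP", "multi_exp",
      list(rates = c(22, 0.18), rates_err = c(2, 0.01),
           amps = c(0.08, 0.92), amps_assumed = FALSE),
      "Fig 2A legend, mantGDP: k_app1 = 22 +/- 2, k_app2 = 0.18 +/- 0.01 s-1"),
    ground_truth("fig2B_preTC_mantGDP", "multi_exp",
      list(rates = c(4.5, 0.5), rates_err = c(0.1, 0.1),
           amps = c(0.87, 0.13), amps_assumed = FALSE),
      "Fig 2B legend, mantGDP on PreTC: k_app1 = 4.5 +/- 0.1 (87% of amplitude), k_app2 = 0.5 +/- 0.1 s-1"),
    ground_truth("fig2B_preTC_mantGTP", "multi_exp",
      list(rates = c(130, 9, 0.3), rates_err = c(2, 1, 0.1),
           amps = c(0.6, 0.3, 0.1), amps_assumed = TRUE),
      "Fig 2B legend, mantGTP on PreTC, three-exponential fit: 130 +/- 2, 9 +/- 1, 0.3 +/- 0.1 s-1 (amplitude split not printed; declared assumption)"),

    # --- equilibrium titrations, relative affinities vs pre-bound GDP
    ground_truth("fig3A_mantGDP", "titration",
      list(Kd = 0.005, K_fixed = 0.005, ratio = 1, P_total = 2,
           fixed_total = 2, style = "association"),
      "Fig 3A, mant-nucleotide into RF3-GDP: half-saturation at 1:1 mantGDP:GDP"),
    ground_truth("fig3A_mantGTP", "titration",
      list(Kd = 0.020, K_fixed = 0.005, ratio = 4, P_total = 2,
           fixed_total = 2, style = "association"),
      "Fig 3A and Results: mantGTP:GDP ratio ~4 at half-saturation; Kd(mantGTP) = 20 nM given K_I(GDP) = 5 nM"),
    ground_truth("fig3A_mantGDPNP", "titration",
      list(Kd = 1.0, K_fixed = 0.005, ratio = 200, P_total = 2,
           fixed_total = 2, style = "association"),
      "Results: Kd(mantGDPNP) > 200-fold above Kd(GDP); stored at the 200-fold bound"),
    ground_truth("fig3B_GTP", "titration",
      list(Kd = 0.015, K_fixed = 0.005, ratio = 3, P_total = 2,
           fixed_total = 2, style = "displacement"),
      "Fig 3B legend, GTP displacing mantGDP: half-saturation ratio 3:1"),
    ground_truth("fig3B_GDPNP", "titration",
      list(Kd = 0.2, K_fixed = 0.005, ratio = 40, P_total = 2,
           fixed_total = 2, style = "displacement"),
      "Fig 3B legend, GDPNP displacing mantGDP: half-saturation ratio 40:1"),
    ground_truth("fig3B_GDPCP", "titration",
      list(Kd = 0.3, K_fixed = 0.005, ratio = 60, P_total = 2,
           fixed_total = 2, style = "displacement"),
      "Fig 3B legend, GDPCP displacing mantGDP: half-saturation ratio 60:1"),

    # --- RF3-mantGDP binding to ribosome complexes (quadratic isotherm)
    ground_truth("fig3C_preTC", "titration",
      list(K_app = 0.5, K_app_err = 0.1, P_total = 0.05, style = "ribosome"),
      "Fig 3C legend, PreTC: apparent Kd = 0.5 +/- 0.1 uM"),
    ground_truth("fig3C_postTC", "titration",
      list(K_app = 0.8, K_app_err = 0.1, P_total = 0.05, style = "ribosome"),
      "Fig 3C legend, PostTC: apparent Kd = 0.8 +/- 0.1 uM"),

    # --- biphasic mantGDPNP titrations: ribosome-bound vs free RF3
    ground_truth("fig4A_vacant_mantGDPNP", "titration",
      list(Kd1 = 0.001, Kd2 = 1.0, f1 = 0.5, style = "two_site"),
      "Fig 4A/B: biphasic titrations; ~1000-fold affinity increase of GDPNP on ribosome-bound RF3 (Kd2 matches free RF3-mantGDPNP)"),
    ground_truth("fig4B_postTC_mantGDPNP", "titration",
      list(Kd1 = 0.001, Kd2 = 1.0, f1 = 0.5, style = "two_site"),
      "Fig 4B: PostTC with RF2; binding constants similar to vacant ribosomes"),

    # --- GTPase cycle (Fig 6 scheme) rate table
    ground_truth("fig5B_GTPase", "scheme",
      list(k_GTP = 0.35, k_GTP_range = c(0.3, 0.4)),
      "Results: GTP hydrolyzed by PostTC-bound RF3 at ~0.3-0.4 s-1 at saturation (Fig 5)"),
    ground_truth("fig6_cycle_rates", "scheme",
      as.list(default_cycle_rates()),
      "Fig 6 scheme; measured rates from Figs 1, 3C, 4C/D and Results, unmeasured association rates set to a generic 10 uM-1 s-1")
  )
  names(fx) <- vapply(fx, function(f) f$condition_id, character(1))
  fx
}

#' Look up one fixture by condition id
#'
#' @param condition_id a condition label present in [make_fixtures()].
#' @return The matching `ground_truth` entry.
#' @export
get_fixture <- function(condition_id) {
  fx <- make_fixtures()
  if (!condition_id %in% names(fx)) {
    stop("unknown fixture `", condition_id, "`; available: ",
         paste(names(fx), collapse = ", "), call. = FALSE)
  }
  fx[[condition_id]]
}

#' Export the fixture table as a flat data frame
#'
#' One row per (condition, parameter) pair, suitable for writing as
#' delimited text or a key/value config.
#'
#' @param fixtures output of [make_fixtures()] (default).
#' @return A data frame with columns `condition_id`, `model`, `parameter`,
#'   `value`, `source`.
#' @export
fixture_table <- function(fixtures = make_fixtures()) {
  rows <- lapply(fixtures, function(f) {
    num <- f$params[vapply(f$params, is.numeric, logical(1))]
    if (length(num) == 0) return(NULL)
    flat <- unlist(num)
    data.frame(condition_id = f$condition_id, model = f$model,
               parameter = names(flat), value = unname(flat),
               source = f$source, row.names = NULL)
  })
  do.call(rbind, rows)
}
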