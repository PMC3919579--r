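#' Read a trace or titration curve from delimited text
#'
#' Accepts 2- or 3-column comma-, tab- or whitespace-delimited text with an
#' optional header. Two columns give a time/signal trace or a
#' concentration/signal titration; a third column is taken as the
#' per-point standard deviation of a titration. The object type is chosen
#' from the header (names containing `time`/`t` vs `conc`/`x`) unless
#' forced with `type`.
#'
#' @param path file path.
#' @param type `"auto"`, `"trace"` or `"titration"`.
#' @return An [as_trace()] or [titration_curve()] object.
#' @examples
#' # synthetic example data shipped with the package
#' cv <- read_table(system.file("extdata",
#'   "fig3A_mantGTP_titration_synthetic.csv", package = "rf3kin"))
#' tr <- read_table(system.file("extdata",
#'   "fig1A_free_RF3_chase_synthetic.csv", package = "rf3kin"))
#' chase_koff(tr)$k_off
#' @export
read_table <- function(path, type = c("auto", "trace", "titration")) {
  type <- match.arg(type)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl(",", lines[[1]])) "," else if (grepl("\t", lines[[1]]))
    "\t" else ""
  first <- strsplit(trimws(lines[[1]]), if (sep == "") "[[:space:]]+" else sep)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.table(text = lines, sep = sep, header = header,
                          strip.white = TRUE)
  if (!ncol(df) %in% 2:3)
    stop("expected 2 or 3 numeric columns, found ", ncol(df), call. = FALSE)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("non-numeric data (ragged rows?) in ", path, call. = FALSE)
  if (type == "auto") {
    nm <- tolower(names(df)[1])
    type <- if (header && grepl("^(t$|t[_ .(]|time)", nm)) "trace"
    else if (header && grepl("^(x|conc|added)", nm)) "titration"
    else if (ncol(df) == 3) "titration"
    else "trace"
  }
  if (type == "trace") {
    as_trace(df[[1]], df[[2]], meta = basename(path))
  } else {
    titration_curve(df[[1]], df[[2]],
                    sigma = if (ncol(df) == 3) df[[3]] else NULL,
                    meta = basename(path))
  }
}

#' Write a trace or titration curve as delimited text
#'
#' The header line carries variable names with units; values are written
#' at full precision so that `read_table(write_table(x))` is
#' value-identical.
#'
#' @param obj an [as_trace()] or [titration_curve()] object.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path, sep = ",") {
  if (inherits(obj, "rf3_trace")) {
    df <- data.frame(`time_s` = obj$t, `signal_au` = obj$y)
  } else if (inherits(obj, "titration_curve")) {
    df <- data.frame(`added_uM` = obj$x, `dF_au` = obj$dF)
    if (!is.null(obj$sigma)) df$sigma_au <- obj$sigma
  } else stop("unsupported object class", call. = FALSE)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Recover every printed constant from synthetic data
#'
#' Runs the full validation loop: for each fixture in [make_fixtures()]
#' that has a printed value, generates synthetic data with the generator
#' for that experiment type and recovers the value with the corresponding
#' fitter, comparing against the printed value at its stated tolerance
#' (the printed uncertainty, or 20% for triphasic fits, 10% for re-plot
#' ratios). Deterministic given `seed`.
#'
#' @param seed integer seed for all synthetic noise.
#' @param n_seeds replicate count for the stochastic (noisy) recoveries;
#'   the recovered value is the median over replicates.
#' @param sigma_frac noise level for the stochastic recoveries.
#' @return A data frame with columns `condition_id`, `quantity`,
#'   `printed`, `recovered`, `tolerance`, `pass`.
#' @export
reproduce_report <- function(seed = 1, n_seeds = 25, sigma_frac = 0.01) {
  fx <- make_fixtures()
  rows <- list()
  add <- function(id, quantity, printed, recovered, tolerance) {
    rows[[length(rows) + 1]] <<- data.frame(
      condition_id = id, quantity = quantity, printed = printed,
      recovered = recovered, tolerance = tolerance,
      pass = is.finite(recovered) & abs(recovered - printed) <= tolerance)
  }

  # analytic: GTP occupancy of cellular RF3
  add("occupancy", "fraction GTP-bound", 0.714,
      occupancy_fraction(10, 4), 0.005)

  # re-plot Kd ratios from exact-solver titrations (noiseless)
  for (id in c("fig3A_mantGTP", "fig3B_GDPNP")) {
    p <- fx[[id]]$params
    grid <- p$fixed_total * exp(seq(log(0.025), log(30), length.out = 40))
    cv <- gen_titration(fx[[id]], grid, Bmax = 1, noise = noise_spec(0))
    rp <- replot(cv, fixed_total = p$fixed_total, Bmax = 1,
                 mode = if (p$style == "displacement") "displacement"
                 else "association")
    add(id, "Kd ratio", p$ratio, rp$half_saturation_ratio, 0.1 * p$ratio)
  }

  # chase dissociation rates (median over noisy replicates)
  chase_ids <- c("fig1A_free_RF3", "fig1C_vacant_ribosome",
                 "fig1E_vacant_RF2GGA", "fig1E_preTC",
                 "fig4C_free_RF3_mantGDPNP", "fig4D_ribosome_mantGDPNP")
  for (id in chase_ids) {
    p <- fx[[id]]$params
    ks <- vapply(seq_len(n_seeds), function(j) {
      tr <- gen_trace_multiexp(list(c(1, p$k_off)),
                               noise = noise_spec(sigma_frac, 5,
                                                  seed + 1000L * j))
      chase_koff(tr)$k_off
    }, numeric(1))
    add(id, "k_off (s-1)", p$k_off, stats::median(ks), p$k_off_err)
  }

  # multi-exponential binding transients
  for (id in c("fig2A_free_mantGTP", "fig2A_free_mantGDP",
               "fig2B_preTC_mantGDP", "fig2B_preTC_mantGTP")) {
    p <- fx[[id]]$params
    n <- length(p$rates)
    rec <- vapply(seq_len(n_seeds), function(j) {
      tr <- gen_trace_multiexp(Map(c, p$amps, p$rates),
                               noise = noise_spec(sigma_frac, 5,
                                                  seed + 2000L * j))
      fit_multiexp(tr, n)$phases$rate
    }, numeric(n))
    med <- apply(matrix(rec, nrow = n), 1, stats::median)
    tol <- if (n == 3) 0.2 * p$rates else pmax(p$rates_err, 1e-12)
    for (i in seq_len(n))
      add(id, sprintf("k_app%d (s-1)", i), p$rates[i], med[i], tol[i])
  }

  # quadratic-isotherm ribosome-binding titrations
  for (id in c("fig3C_preTC", "fig3C_postTC")) {
    p <- fx[[id]]$params
    x <- exp(seq(log(0.02), log(10), length.out = 12))
    kap <- vapply(seq_len(n_seeds), function(j) {
      dF <- quadratic_isotherm(x, p$P_total, p$K_app, 1)
      eps <- with_seed(seed + 3000L * j, stats::rnorm(length(x), 0, 0.02))
      cv <- titration_curve(x, dF + eps)
      fit_isotherm(cv, p$P_total)$K_app
    }, numeric(1))
    add(id, "K_app (uM)", p$K_app, stats::median(kap), p$K_app_err)
  }

  # peptide-release rates
  for (id in c("fig1B_RF2_release", "fig1B_RF2GGA_release")) {
    p <- fx[[id]]$params
    ks <- vapply(seq_len(n_seeds), function(j) {
      tr <- gen_release_timecourse(p$k_release, p$k_background,
                                   noise = noise_spec(0.02, 1,
                                                      seed + 4000L * j))
      fit_multiexp(tr, 1)$phases$rate - p$k_background
    }, numeric(1))
    add(id, "k_release (s-1)", p$k_release, stats::median(ks),
        p$k_release_err)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
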