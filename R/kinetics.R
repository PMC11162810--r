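#' Rate series for NAD(P)H oxidase assays
#'
#' Steady-state initial rates of NAD(P)H consumption (followed by A340)
#' at a grid of substrate concentrations, for one enzyme concentration.
#' Rates may be given directly or derived from A340 slopes via
#' Beer-Lambert with epsilon(NAD(P)H, 340 nm) = 6220 M^-1 cm^-1 and a
#' 1 cm path.
#'
#' @param substrate_conc Substrate concentrations (uM), strictly
#'   positive and distinct.
#' @param initial_rate Initial rates (uM/s), same length.
#' @param enzyme_conc Enzyme concentration (uM).
#' @param substrate_name `"NADH"` or `"NADPH"`.
#' @return A `rate_series` object.
#' @export
rate_series <- function(substrate_conc, initial_rate, enzyme_conc,
                        substrate_name = c("NADPH", "NADH")) {
  substrate_name <- match.arg(substrate_name)
  if (length(substrate_conc) != length(initial_rate)) {
    stop("substrate_conc and initial_rate must have equal length")
  }
  if (any(substrate_conc <= 0)) stop("substrate concentrations must be positive")
  if (anyDuplicated(substrate_conc)) {
    stop("substrate concentrations must be distinct")
  }
  stopifnot(enzyme_conc > 0)
  structure(list(substrate_conc = as.numeric(substrate_conc),
                 initial_rate = as.numeric(initial_rate),
                 enzyme_conc = enzyme_conc,
                 substrate_name = substrate_name),
            class = "rate_series")
}

#' Convert A340 slopes to rates
#'
#' @param slope_per_s Absorbance change per second at 340 nm (positive
#'   for consumption).
#' @param epsilon Molar extinction coefficient (M^-1 cm^-1).
#' @param path_cm Optical path (cm).
#' @return Rate in uM/s.
#' @export
a340_slope_to_rate <- function(slope_per_s, epsilon = 6220, path_cm = 1) {
  abs(slope_per_s) / (epsilon * path_cm) * 1e6
}

#' Fit the Michaelis-Menten model to a rate series
#'
#' Bounded nonlinear least squares of
#' `v = kcat * [E] * [S] / (KM + [S])`
#' (Levenberg-Marquardt, parameters constrained positive; deterministic
#' starting values `KM0 = median [S]`, `Vmax0 = max v`). The fit errors
#' out when KM is unidentifiable because the concentration grid only
#' samples the saturating plateau.
#'
#' @param series A [rate_series()].
#' @return A `kinetic_fit` with `kcat`, `KM` (uM), `efficiency`
#'   (`kcat/KM`, uM^-1 s^-1), standard errors `se_kcat`, `se_KM`,
#'   `se_efficiency`, and the substrate name.
#' @export
fit_michaelis_menten <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  S <- series$substrate_conc
  v <- series$initial_rate
  E <- series$enzyme_conc
  if (length(unique(S)) < 5L) {
    stop("need >= 5 distinct substrate concentrations")
  }
  start <- list(kcat = max(v) / E, KM = stats::median(S))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ kcat * E * S / (KM + S),
                      start = start, lower = c(kcat = 0, KM = 0),
                      data = list(v = v, S = S, E = E),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("Michaelis-Menten fit did not converge (initial guesses kcat0=",
           signif(start$kcat, 3), ", KM0=", signif(start$KM, 3), "): ",
           conditionMessage(e))
    })
  est <- stats::coef(fit)
  if (min(S) > 3 * est[["KM"]]) {
    stop("KM unidentifiable: all substrate concentrations (min ", min(S),
         " uM) lie far above the fitted KM (", signif(est[["KM"]], 3),
         " uM); include sub-KM points")
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kcat = NA_real_, KM = NA_real_))
  kcat <- est[["kcat"]]; KM <- est[["KM"]]
  eff <- kcat / KM
  # first-order (delta-method) SE for the ratio, ignoring covariance
  se_eff <- eff * sqrt((se[["kcat"]] / kcat)^2 + (se[["KM"]] / KM)^2)
  structure(list(kcat = kcat, KM = KM, efficiency = eff,
                 se_kcat = se[["kcat"]], se_KM = se[["KM"]],
                 se_efficiency = se_eff,
                 substrate_name = series$substrate_name, fit = fit),
            class = "kinetic_fit")
}

#' Hand-entered kinetic parameters
#'
#' Wraps published or otherwise externally obtained `kcat`/`KM` values
#' in the same container as [fit_michaelis_menten()] results so they can
#' feed [compare_efficiencies()].
#'
#' @param kcat Turnover number (s^-1).
#' @param KM Michaelis constant (uM).
#' @param substrate_name Substrate label.
#' @param efficiency Catalytic efficiency; defaults to `kcat/KM`, but a
#'   published value may be supplied verbatim.
#' @return A `kinetic_fit` (without standard errors).
#' @export
kinetic_params <- function(kcat, KM, substrate_name = "NADPH",
                           efficiency = kcat / KM) {
  stopifnot(kcat > 0, KM > 0, efficiency > 0)
  structure(list(kcat = kcat, KM = KM, efficiency = efficiency,
                 se_kcat = NA_real_, se_KM = NA_real_,
                 se_efficiency = NA_real_,
                 substrate_name = substrate_name, fit = NULL),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("kinetic_fit (", x$substrate_name, "): kcat = ", signif(x$kcat, 3),
      " s-1, KM = ", signif(x$KM, 3), " uM, kcat/KM = ",
      signif(x$efficiency, 3), " uM-1 s-1\n", sep = "")
  invisible(x)
}

#' Compare catalytic efficiencies between two substrates
#'
#' Reports the fold ratio of `kcat/KM` (always >= 1) and which substrate
#' it favours, plus the `kcat` fold on the same orientation. Folds below
#' the indifference band are reported as no discrimination.
#'
#' @param fit_a,fit_b `kinetic_fit`s (fitted or [kinetic_params()]).
#' @param indifference_fold Efficiency folds below this count as
#'   `"none"` (no substrate preference).
#' @return List with `fold` (efficiency ratio >= 1), `preferred`
#'   (substrate name of the numerator, or `"none"`), `kcat_fold`
#'   (oriented the same way), `direction` (+1 if a over b, -1
#'   otherwise).
#' @examples
#' b2_nadph <- kinetic_params(0.7, 2.1, "NADPH", efficiency = 0.3)
#' b2_nadh <- kinetic_params(0.23, 22, "NADH", efficiency = 0.06)
#' compare_efficiencies(b2_nadph, b2_nadh)$fold  # 5
#' @export
compare_efficiencies <- function(fit_a, fit_b, indifference_fold = 1.5) {
  ea <- fit_a$efficiency; eb <- fit_b$efficiency
  if (ea >= eb) {
    fold <- ea / eb; top <- fit_a; bottom <- fit_b; direction <- 1
  } else {
    fold <- eb / ea; top <- fit_b; bottom <- fit_a; direction <- -1
  }
  list(fold = fold,
       preferred = if (fold < indifference_fold) "none" else top$substrate_name,
       kcat_fold = top$kcat / bottom$kcat,
       direction = direction)
}

#' Fit a Hill binding isotherm
#'
#' Cooperative binding of tRNA monitored through the FMN fluorescence
#' change on titration: `dF = A * [S]^n / (K_half^n + [S]^n)`. With
#' `n = 1` this reduces to a hyperbola of the Michaelis-Menten shape.
#'
#' @param conc Titrant concentrations (uM).
#' @param delta_f Fluorescence change at each concentration.
#' @param fix_n Optional: fix the Hill coefficient (e.g. 1 for the
#'   hyperbolic special case).
#' @return A `binding_fit` with `K_half` (uM), `hill_n`, `amplitude`.
#' @export
fit_hill <- function(conc, delta_f, fix_n = NULL) {
  if (length(conc) != length(delta_f)) stop("conc and delta_f lengths differ")
  if (length(conc) < 6L) stop("need >= 6 titration points")
  if (any(conc < 0)) stop("concentrations must be nonnegative")
  amp0 <- max(delta_f)
  half0 <- stats::approx(delta_f, conc, xout = amp0 / 2, ties = "ordered")$y
  if (is.na(half0)) half0 <- stats::median(conc)
  dat <- list(dF = delta_f, S = conc)
  fit <- tryCatch(
    if (is.null(fix_n)) {
      minpack.lm::nlsLM(dF ~ A * S^n / (K^n + S^n),
                        start = list(A = amp0, K = half0, n = 1.5),
                        lower = c(A = 0, K = 1e-9, n = 0.1), data = dat,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      n <- fix_n
      minpack.lm::nlsLM(dF ~ A * S^n / (K^n + S^n),
                        start = list(A = amp0, K = half0),
                        lower = c(A = 0, K = 1e-9), data = c(dat, list(n = n)),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) stop("Hill fit did not converge: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  structure(list(K_half = est[["K"]],
                 hill_n = if (is.null(fix_n)) est[["n"]] else fix_n,
                 amplitude = est[["A"]], fit = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("binding_fit: K_half = ", signif(x$K_half, 3), " uM, n = ",
      signif(x$hill_n, 3), ", amplitude = ", signif(x$amplitude, 3), "\n",
      sep = "")
  invisible(x)
}

#' Relative dihydrouridine content normalised to adenosine UV
#'
#' LC-MS bookkeeping: the D ion signal of each sample is normalised to
#' its adenosine UV signal (an internal proxy for total tRNA loaded) and
#' expressed as a percentage of the same ratio in a reference sample
#' (wild type = 100% by construction).
#'
#' @param d_signal,adenosine_uv Sample D ion and adenosine UV signals
#'   (vectors of equal length; adenosine must be positive).
#' @param reference_d,reference_adenosine The reference sample's
#'   signals.
#' @param strain Optional sample names.
#' @return data.frame with columns `strain`, `relative_D` (percent of
#'   reference), `normalization`.
#' @examples
#' relative_d_content(c(100, 0), c(50, 50), 100, 50,
#'                    strain = c("WT", "dB1dB2"))
#' @export
relative_d_content <- function(d_signal, adenosine_uv, reference_d,
                               reference_adenosine, strain = NULL) {
  if (length(d_signal) != length(adenosine_uv)) {
    stop("d_signal and adenosine_uv lengths differ")
  }
  if (any(adenosine_uv <= 0) || reference_adenosine <= 0) {
    stop("adenosine UV signals must be positive")
  }
  ref_ratio <- reference_d / reference_adenosine
  if (ref_ratio == 0) stop("reference D/adenosine ratio is zero")
  if (is.null(strain)) strain <- paste0("sample", seq_along(d_signal))
  data.frame(strain = strain,
             relative_D = (d_signal / adenosine_uv) / ref_ratio * 100,
             normalization = "adenosine_UV", stringsAsFactors = FALSE)
}

#' Read a kinetics input table
#'
#' TSV with columns `substrate`, `conc_uM`, `rate`; returns one
#' [rate_series()] per substrate.
#'
#' @param path Path to the TSV.
#' @param enzyme_conc Enzyme concentration (uM) for all series.
#' @return Named list of [rate_series()].
#' @export
read_kinetics_table <- function(path, enzyme_conc) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("substrate", "conc_uM", "rate")
  if (!all(need %in% names(tab))) {
    stop("kinetics table must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(tab, tab$substrate), function(d) {
    rate_series(d$conc_uM, d$rate, enzyme_conc,
                substrate_name = d$substrate[1])
  })
}

#' Write a kinetic-parameter report
#'
#' JSON mirroring a kinetics results table: per substrate, kcat, KM and
#' efficiency with standard errors.
#'
#' @param fits Named list of `kinetic_fit`s.
#' @param path Output JSON path.
#' @export
write_kinetics_report <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    list(substrate = f$substrate_name, kcat_per_s = f$kcat,
         se_kcat = f$se_kcat, KM_uM = f$KM, se_KM = f$se_KM,
         efficiency_per_uM_per_s = f$efficiency,
         se_efficiency = f$se_efficiency)
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(rows)
}
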