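# Isothermal titration calorimetry: single-site (1:1) forward model with a
# displaced-volume perfusion cell, nonlinear least-squares fitting, blank
# (dilution-heat) correction, and derived reaction entropy.

R_GAS <- 8.314462618  # J mol^-1 K^-1

#' Thermodynamic record for a 1:1 complexation
#'
#' Bundles `log K` (molar scale) with the standard reaction quantities and
#' enforces the identities `DrG = -RT ln(10) log K` and `DrG = DrH - T DrS`:
#' supply `log_K` and `dH`, and `dG`/`dS` are derived.
#'
#' @param log_K decadic logarithm of the stability constant (molar scale)
#' @param dH standard reaction enthalpy, kJ mol^-1
#' @param T temperature, K
#' @param se optional named list of standard uncertainties (`log_K`, `dH`)
#' @return object of class `"thermo_record"` with fields `log_K`, `dG`, `dH`
#'   (kJ mol^-1), `dS` (J mol^-1 K^-1), `T`, `se`
#' @examples
#' thermo_record(log_K = 6.024, dH = -15, T = 298.15)  # dS ~ 65 J/(mol K)
#' @export
thermo_record <- function(log_K, dH, T = 298.15, se = NULL) {
  stopifnot(T > 0)
  dG <- -R_GAS * T * log(10) * log_K / 1000          # kJ/mol
  dS <- (dH - dG) * 1000 / T                         # J/(mol K)
  structure(list(log_K = log_K, dG = dG, dH = dH, dS = dS, T = T, se = se),
            class = "thermo_record")
}

#' @export
print.thermo_record <- function(x, ...) {
  cat(sprintf(paste0("log K = %.3f   DrG = %.2f kJ/mol   DrH = %.2f kJ/mol",
                     "   DrS = %.1f J/(mol K)   T = %.2f K\n"),
              x$log_K, x$dG, x$dH, x$dS, x$T))
  invisible(x)
}

#' Reaction entropy from log K and reaction enthalpy
#'
#' `DrS = (DrH + RT ln(10) log K) / T`, the rearranged identity
#' `DrG = DrH - T DrS` with `DrG = -RT ln(10) log K`.
#'
#' @param log_K decadic log stability constant (molar scale)
#' @param dH reaction enthalpy, kJ mol^-1
#' @param T temperature, K
#' @return reaction entropy, J mol^-1 K^-1
#' @export
derive_entropy <- function(log_K, dH, T = 298.15) {
  stopifnot(T > 0)
  (dH * 1000 + R_GAS * T * log(10) * log_K) / T
}

#' Construct a thermogram
#'
#' @param injection_volumes per-injection titrant volumes, dm^3
#' @param heats per-injection heats, J
#' @param V0 cell volume, dm^3
#' @param c_L total receptor concentration in the cell, mol dm^-3
#' @param c_A titrant (syringe) anion concentration, mol dm^-3
#' @param T temperature, K
#' @return object of class `"thermogram"`
#' @export
thermogram <- function(injection_volumes, heats, V0, c_L, c_A, T = 298.15) {
  stopifnot(length(injection_volumes) == length(heats), V0 > 0, T > 0,
            all(injection_volumes > 0))
  structure(list(injection_volumes = as.numeric(injection_volumes),
                 heats = as.numeric(heats), V0 = V0, c_L = c_L, c_A = c_A,
                 T = T),
            class = "thermogram")
}

# Cell compositions after each injection under the displaced-volume
# convention: each aliquot displaces an equal volume of (mixed) cell liquid,
# so pre-injection contents are scaled by (1 - v_i/V0) and the injected moles
# are added; working volume stays V0.
itc_compositions <- function(injection_volumes, V0, c_L, c_A) {
  n <- length(injection_volumes)
  tl <- numeric(n); ta <- numeric(n)
  L <- c_L; A <- 0
  for (i in seq_len(n)) {
    d <- 1 - injection_volumes[i] / V0
    L <- L * d
    A <- A * d + c_A * injection_volumes[i] / V0
    tl[i] <- L; ta[i] <- A
  }
  data.frame(total_L = tl, total_A = ta)
}

#' Simulate a single-site ITC thermogram
#'
#' Forward model: the heat of injection `i` is
#' `Q_i = V0 * dH * ([LA]_i - [LA]_{i-1} (1 - v_i/V0)) + blank`, with complex
#' concentrations from the 1:1 mass balance under the displaced-volume
#' dilution model, plus optional Gaussian noise.
#'
#' @param log_K,dH binding constant (log10, molar) and enthalpy (kJ mol^-1)
#' @param injection_volumes per-injection volumes, dm^3
#' @param V0 cell volume, dm^3 (default 1.4e-3, a VP-ITC cell)
#' @param c_L cell receptor concentration, mol dm^-3
#' @param c_A syringe anion concentration, mol dm^-3
#' @param T temperature, K
#' @param blank constant per-injection offset, J (dilution heat)
#' @param noise_sd Gaussian noise standard deviation, J
#' @param seed optional RNG seed for the noise
#' @return a [thermogram()]
#' @export
simulate_thermogram <- function(log_K, dH, injection_volumes, V0 = 1.4e-3,
                                c_L = 1e-4, c_A = 2e-3, T = 298.15,
                                blank = 0, noise_sd = 0, seed = NULL) {
  q <- itc_model_heats(c(log_K, dH), injection_volumes, V0, c_L, c_A) + blank
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    q <- q + stats::rnorm(length(q), 0, noise_sd)
  }
  thermogram(injection_volumes, q, V0, c_L, c_A, T)
}

itc_model_heats <- function(par, injection_volumes, V0, c_L, c_A) {
  log_K <- par[1L]; dH_J <- par[2L] * 1000
  comps <- itc_compositions(injection_volumes, V0, c_L, c_A)
  K <- 10^log_K
  la <- closed_form_1to1(comps$total_L, comps$total_A, K)
  la_prev <- c(0, la[-length(la)])
  d <- 1 - injection_volumes / V0
  V0 * dH_J * (la - la_prev * d)
}

#' Subtract a blank (titrant-dilution) thermogram
#'
#' @param thermogram a [thermogram()] of the binding experiment
#' @param blank a [thermogram()] of the titrant-into-solvent blank on the
#'   same injection schedule
#' @return the corrected [thermogram()]
#' @export
subtract_blank <- function(thermogram, blank) {
  if (length(thermogram$injection_volumes) != length(blank$injection_volumes)
      || any(abs(thermogram$injection_volumes - blank$injection_volumes) >
             1e-15))
    stop("injection schedules of experiment and blank do not match")
  thermogram$heats <- thermogram$heats - blank$heats
  thermogram
}

#' Fit a single-site model to a thermogram
#'
#' Levenberg--Marquardt least squares of the forward model of
#' [simulate_thermogram()] for `log K` and `DrH`, with the constant blank
#' offset fitted (default) or fixed. The reaction entropy follows from
#' [derive_entropy()]. The Wiseman parameter `c = K * c_L` is reported and
#' flagged when far outside the classically fittable window (about 1--1000).
#'
#' @param tg a [thermogram()] (blank-corrected, or fit the offset)
#' @param start optional `c(log_K, dH)` starting values
#' @param fit_blank fit a constant per-injection offset (default TRUE)
#' @param multistart also start from `log K +/- 1` (default TRUE)
#' @return a [thermo_record()] with standard errors; attributes
#'   `c_parameter`, `c_flag`, `blank`, `ss`, `fitted_heats`, `converged`,
#'   `non_binding` (TRUE when `DrH` is indistinguishable from zero)
#' @export
fit_thermogram <- function(tg, start = NULL, fit_blank = TRUE,
                           multistart = TRUE) {
  stopifnot(inherits(tg, "thermogram"))
  n <- length(tg$heats)
  if (n < 5L) stop("need at least 5 injections")
  if (is.null(start)) {
    dH0 <- sum(tg$heats) / (tg$V0 * tg$c_L) / 1000  # all-bound guess, kJ/mol
    if (!is.finite(dH0) || abs(dH0) < 1e-3) dH0 <- -10
    start <- c(log_K = log10(10 / tg$c_L), dH = dH0)
  }
  resid_fn <- function(par) {
    q <- itc_model_heats(par[1:2], tg$injection_volumes, tg$V0, tg$c_L,
                         tg$c_A)
    b <- if (fit_blank) par[3L] else 0
    tg$heats - q - b
  }
  p0 <- if (fit_blank) c(start, blank = 0) else start
  starts <- list(p0)
  if (multistart)
    for (d in c(-1, 1)) { s <- p0; s[1L] <- s[1L] + d; starts <- c(starts, list(s)) }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("thermogram fit failed to converge")
  par <- best$par
  ss <- best$deviance
  se_all <- fit_param_se(resid_fn, par, ss)
  rec <- thermo_record(log_K = unname(par[1L]), dH = unname(par[2L]),
                       T = tg$T,
                       se = list(log_K = se_all[1L], dH = se_all[2L]))
  cpar <- 10^par[1L] * tg$c_L
  attr(rec, "c_parameter") <- unname(cpar)
  attr(rec, "c_flag") <- cpar < 1 || cpar > 1000
  attr(rec, "blank") <- if (fit_blank) unname(par[3L]) else 0
  attr(rec, "ss") <- ss
  attr(rec, "fitted_heats") <- tg$heats - resid_fn(par)
  attr(rec, "converged") <- best$info %in% 1:4
  # non-binding: the fitted binding signal is lost in the residual noise,
  # or the enthalpy is statistically indistinguishable from zero
  binding_q <- itc_model_heats(par[1:2], tg$injection_volumes, tg$V0,
                               tg$c_L, tg$c_A)
  resid_sd <- sqrt(ss / max(1L, n - length(par)))
  attr(rec, "non_binding") <- max(abs(binding_q)) < 2 * resid_sd ||
    (is.finite(se_all[2L]) && abs(par[2L]) < 2 * se_all[2L])
  rec
}

#' Summarize replicate ITC runs
#'
#' Measurements are typically repeated (e.g. in triplicate); this reports the
#' mean and standard deviation of `log K`, `DrH` and `DrS` across runs.
#'
#' @param records list of [thermo_record()]s
#' @return data frame with rows `log_K`, `dH`, `dS` and columns `mean`, `sd`
#' @export
summarize_itc_replicates <- function(records) {
  g <- function(f) vapply(records, function(r) r[[f]], numeric(1))
  vals <- rbind(log_K = g("log_K"), dH = g("dH"), dS = g("dS"))
  data.frame(mean = rowMeans(vals), sd = apply(vals, 1L, stats::sd))
}
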