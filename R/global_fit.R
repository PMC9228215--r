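# Global multivariate fitting of titration data: stability constants are the
# nonlinear parameters; per-species molar responses (spectra or limiting
# shifts) are linear and solved exactly at each trial by variable projection.

#' Construct a titration response series
#'
#' A bilinear response matrix (channels x titration points): emission or
#' absorbance spectra (channel = wavelength, nm), ellipticity, or per-proton
#' chemical shifts (channel = proton label, values in ppm).
#'
#' @param channels numeric wavelengths (nm) or character proton labels
#' @param volumes cumulative titrant volumes (dm^3), one per point
#' @param values numeric matrix, `length(channels)` x `length(volumes)`
#' @param kind one of `"fluorescence"`, `"absorbance"`, `"cd"`, `"shift"`
#' @param blank optional matching blank series (see [blank_correct()])
#' @return object of class `"response_series"`
#' @export
response_series <- function(channels, volumes, values,
                            kind = c("fluorescence", "absorbance", "cd",
                                     "shift"),
                            blank = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != length(channels) || ncol(values) != length(volumes))
    stop("values must be length(channels) x length(volumes)")
  if (anyDuplicated(channels)) stop("duplicate channels")
  structure(list(channels = channels, volumes = as.numeric(volumes),
                 values = values, kind = kind, blank = blank),
            class = "response_series")
}

#' @export
print.response_series <- function(x, ...) {
  cat(sprintf("%s titration series: %d channels x %d points\n",
              x$kind, length(x$channels), length(x$volumes)))
  invisible(x)
}

#' Subtract an anion-concentration-dependent blank
#'
#' For titrations where the titrant itself contributes to the signal (e.g.
#' solvent emission that depends on iodide concentration), the blank series --
#' recorded on the same channel axis as a function of titrant concentration --
#' is interpolated to each sample point's titrant concentration and
#' subtracted.
#'
#' @param series a [response_series()] to correct
#' @param blank a [response_series()] of the blank; its `volumes` must map to
#'   the same titrant-concentration scale as the sample's (same schedule
#'   geometry)
#' @param conc_series,conc_blank anion concentrations at each point of the
#'   sample and blank series; when omitted, the cumulative volumes are used as
#'   the interpolation coordinate (valid when both were run on the same
#'   schedule)
#' @return the corrected [response_series()]
#' @export
blank_correct <- function(series, blank, conc_series = NULL,
                          conc_blank = NULL) {
  if (!isTRUE(all.equal(series$channels, blank$channels)))
    stop("channel axes of series and blank do not match")
  xs <- if (is.null(conc_series)) series$volumes else conc_series
  xb <- if (is.null(conc_blank)) blank$volumes else conc_blank
  if (min(xs) < min(xb) - 1e-12 || max(xs) > max(xb) + 1e-12)
    stop("sample points outside the blank's concentration range")
  corr <- series$values
  for (j in seq_along(xs)) {
    bj <- apply(blank$values, 1L, function(row)
      stats::approx(xb, row, xout = xs[j], rule = 2)$y)
    corr[, j] <- series$values[, j] - bj
  }
  series$values <- corr
  series$blank <- NULL
  series
}

# Concentration design matrix (points x responsive species).
# spectral: responsive species are those containing L (free A / A2 dark).
# shift: fast exchange -- columns are l * [species] / total_L so that the
# observed shift is the population-weighted average of limiting shifts.
design_matrix <- function(schedule, model, kind, ...) {
  prof <- speciation_profile(schedule, model, ...)
  sp <- model$species
  resp <- sp$l >= 1L
  C <- prof[, resp, drop = FALSE]
  if (kind == "shift") {
    total_L <- schedule_to_compositions(schedule)$total_L
    C <- sweep(C * rep(sp$l[resp], each = nrow(C)), 1L, total_L, "/")
  }
  C
}

# Exact linear least-squares solve of Y ~ S %*% t(C) for S; errors on
# rank-deficient designs.
solve_molar_response <- function(Y, C, nonneg = FALSE) {
  qrC <- qr(C)
  if (qrC$rank < ncol(C))
    stop("ill-conditioned design: speciation matrix is rank-deficient ",
         "(uninformative titration)")
  S <- t(qr.coef(qrC, t(Y)))
  if (nonneg) S[S < 0] <- 0
  S
}

varpro_residual <- function(par, Y, schedule, model, kind, nonneg) {
  m <- set_free_constants(model, par)
  C <- design_matrix(schedule, m, kind)
  S <- solve_molar_response(Y, C, nonneg)
  as.numeric(Y - S %*% t(C))
}

#' Fit stability constants to a full-spectrum titration
#'
#' Global multivariate regression: for trial values of the free `log beta`
#' the species concentration matrix `C` follows from the mass balance, the
#' per-species molar spectra `S` are the exact linear least-squares minimizer
#' of `||Y - S C'||_F` (variable projection), and the nonlinear search over
#' `log beta` is a Levenberg--Marquardt iteration with optional multistart
#' from +/- 1 log-unit perturbations. Constants flagged `fixed` in the model
#' (e.g. a literature anion dimerization constant) are held constant.
#'
#' @param series a `fluorescence` or `absorbance` (or `cd`)
#'   [response_series()]
#' @param schedule the matching [titration_schedule()]
#' @param model an [equilibrium_model()]; its non-fixed `log_beta` values are
#'   the starting estimates
#' @param nonneg constrain molar responses to be non-negative (projection
#'   after the linear solve; sensible for fluorescence only)
#' @param window optional numeric `c(lo, hi)` channel window (nm) to restrict
#'   the fit
#' @param multistart number of starts: 1 = from the model's values only,
#'   otherwise the starts also include each free constant perturbed by +/- 1
#' @param offset include a composition-independent offset channel (a constant
#'   background spectrum); off by default
#' @return object of class `"fit_result"`: `log_beta` (full table with
#'   estimates and `se`), `molar_response` (channels x species),
#'   `residuals`, `ss`, `converged`, `niter`
#' @export
fit_spectral <- function(series, schedule, model, nonneg = FALSE,
                         window = NULL, multistart = 3L, offset = FALSE) {
  if (series$kind == "shift")
    stop("use fit_nmr_shifts() for chemical-shift series")
  Y <- series$values
  if (!is.null(window)) {
    keep <- series$channels >= window[1] & series$channels <= window[2]
    if (!any(keep)) stop("empty channel window")
    Y <- Y[keep, , drop = FALSE]
  }
  fit_bilinear(Y, schedule, model, kind = "spectral", nonneg = nonneg,
               multistart = multistart, offset = offset)
}

#' Fit stability constants to a fast-exchange NMR shift titration
#'
#' Under fast exchange the observed shift of proton `j` is the
#' population-weighted average over receptor-containing species,
#' `delta_obs,j = sum_s l_s [s] delta_{s,j} / total_L`. Free `log beta` and
#' the per-species limiting shifts are fitted by the same variable-projection
#' scheme as [fit_spectral()]. Constant-ligand schedules (receptor present in
#' the titrant at the titrand concentration) are the usual design.
#'
#' @inheritParams fit_spectral
#' @param series a `shift` [response_series()] (channels = proton labels,
#'   values in ppm)
#' @return a `"fit_result"`; `molar_response` holds the limiting shifts (ppm)
#' @export
fit_nmr_shifts <- function(series, schedule, model, multistart = 3L) {
  if (series$kind != "shift") stop("series kind must be 'shift'")
  fit_bilinear(series$values, schedule, model, kind = "shift",
               nonneg = FALSE, multistart = multistart, offset = FALSE)
}

fit_bilinear <- function(Y, schedule, model, kind, nonneg, multistart,
                         offset = FALSE) {
  if (all(apply(Y, 1L, stats::sd) < 1e-14 * (max(abs(Y)) + 1)))
    stop("ill-conditioned design: response has no variance across points")
  free <- !model$complexes$fixed
  npar <- sum(free)
  if (npar == 0L) stop("model has no free constants to fit")
  npts <- ncol(Y)
  if (npts < npar + 2L)
    stop("need at least ", npar + 2L, " titration points")
  kind_int <- if (kind == "shift") "shift" else "spectral"
  if (offset) {
    # constant background handled as an extra all-ones design column
    resid_fn <- function(par) {
      m <- set_free_constants(model, par)
      C <- cbind(design_matrix(schedule, m, kind_int), 1)
      S <- solve_molar_response(Y, C, nonneg = FALSE)
      as.numeric(Y - S %*% t(C))
    }
  } else {
    resid_fn <- function(par)
      varpro_residual(par, Y, schedule, model, kind_int, nonneg)
  }

  start0 <- model$complexes$log_beta[free]
  starts <- list(start0)
  if (multistart > 1L)
    for (k in seq_len(npar))
      for (d in c(-1, 1)) {
        s <- start0; s[k] <- s[k] + d; starts <- c(starts, list(s))
      }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("nonlinear fit failed to converge from all starts")

  par_hat <- best$par
  m_hat <- set_free_constants(model, par_hat)
  C <- design_matrix(schedule, m_hat, kind_int)
  if (offset) C <- cbind(C, offset = 1)
  S <- solve_molar_response(Y, C, nonneg = if (offset) FALSE else nonneg)
  R <- Y - S %*% t(C)
  ss <- sum(R^2)

  se <- fit_param_se(resid_fn, par_hat, ss)
  tab <- m_hat$complexes
  tab$se <- NA_real_
  tab$se[free] <- se
  sp_names <- m_hat$species$name[m_hat$species$l >= 1L]
  colnames(S)[seq_along(sp_names)] <- sp_names

  structure(list(log_beta = tab, molar_response = S, residuals = R, ss = ss,
                 converged = best$info %in% 1:4, niter = best$niter,
                 kind = kind, model = m_hat),
            class = "fit_result")
}

# Asymptotic standard errors from a finite-difference Jacobian at the optimum.
fit_param_se <- function(resid_fn, par, ss) {
  r0 <- resid_fn(par)
  n <- length(r0); p <- length(par)
  J <- matrix(0, n, p)
  h <- pmax(1e-6, abs(par) * 1e-6)
  for (k in seq_len(p)) {
    pp <- par; pp[k] <- pp[k] + h[k]
    pm <- par; pm[k] <- pm[k] - h[k]
    J[, k] <- (resid_fn(pp) - resid_fn(pm)) / (2 * h[k])
  }
  sigma2 <- ss / max(1L, n - p)
  JtJ <- crossprod(J)
  cv <- tryCatch(solve(JtJ) * sigma2, error = function(e) NULL)
  if (is.null(cv)) return(rep(Inf, p))   # singular normal matrix
  sqrt(pmax(0, diag(cv)))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Global %s fit: SS = %.4g, %sconverged (%d iterations)\n",
              x$kind, x$ss, if (x$converged) "" else "NOT ", x$niter))
  tab <- x$log_beta
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  log beta(%d,%d) = %.4f%s\n", tab$l[i], tab$a[i],
                tab$log_beta[i],
                if (tab$fixed[i]) " [fixed]"
                else sprintf(" +/- %.4f", tab$se[i])))
  invisible(x)
}

#' Uncertainties of fitted constants, optionally across replicates
#'
#' Returns the asymptotic standard errors stored in a fit and, when replicate
#' fits are supplied (titrations are typically run in triplicate), the
#' between-replicate mean and standard deviation of each free `log beta`.
#'
#' @param fit a `"fit_result"`
#' @param replicates optional list of further `"fit_result"`s of the same
#'   model
#' @return data frame with one row per free constant: `log_beta`,
#'   `se_asymptotic`, and with replicates `mean_rep`, `sd_rep`
#' @export
estimate_uncertainties <- function(fit, replicates = NULL) {
  free <- !fit$log_beta$fixed
  out <- data.frame(l = fit$log_beta$l[free], a = fit$log_beta$a[free],
                    log_beta = fit$log_beta$log_beta[free],
                    se_asymptotic = fit$log_beta$se[free])
  if (!is.null(replicates)) {
    all_fits <- c(list(fit), replicates)
    mat <- vapply(all_fits, function(f) f$log_beta$log_beta[free],
                  numeric(sum(free)))
    mat <- matrix(mat, nrow = sum(free))
    out$mean_rep <- rowMeans(mat)
    out$sd_rep <- apply(mat, 1L, stats::sd)
  }
  out
}
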