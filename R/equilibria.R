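# Equilibrium models and mass-balance speciation over components L (receptor)
# and A (anion). Concentrations are mol dm^-3 throughout; cumulative formation
# constants beta are dimensioned on the molar scale.

#' Define an equilibrium model over receptor (L) and anion (A)
#'
#' An equilibrium model is a set of complex species `L_l A_a` with cumulative
#' formation constants `beta_{la} = [L_l A_a] / ([L]^l [A]^a)`, supplied as
#' `log10(beta)`. The free components `(1,0)` and `(0,1)` are implicit with
#' `log beta = 0` and must not be listed. A competing anion self-association
#' (dimerization) is expressed as the species `(0,2)`; a receptor--dimer
#' complex as `(1,2)`. Stepwise and cumulative parameterizations of the 1:2
#' species are interconvertible: `log beta_12 = log K(L + A2) + log beta_02`.
#'
#' @param species a data frame (or matrix) with columns `l`, `a`, `log_beta`
#'   and optionally `fixed` (logical; constants held constant during fitting,
#'   e.g. a literature dimerization constant). One row per complex species.
#' @return an object of class `"equilibrium_model"`: a list with the validated
#'   species table (complexes only) and the full stoichiometry used by the
#'   solver (free components first, in lexicographic `(l, a)` order).
#' @examples
#' # 1:1 complex with log K = 4
#' equilibrium_model(data.frame(l = 1, a = 1, log_beta = 4))
#' # 1:1 plus anion dimer (fixed) plus 1:2 complex
#' equilibrium_model(data.frame(l = c(1, 0, 1), a = c(1, 2, 2),
#'                              log_beta = c(4, 2, 5.5),
#'                              fixed = c(FALSE, TRUE, FALSE)))
#' @export
equilibrium_model <- function(species) {
  species <- as.data.frame(species)
  if (!all(c("l", "a", "log_beta") %in% names(species)))
    stop("species must have columns l, a, log_beta")
  if (is.null(species$fixed)) species$fixed <- FALSE
  l <- as.integer(species$l); a <- as.integer(species$a)
  lb <- as.numeric(species$log_beta)
  if (any(l < 0) || any(a < 0)) stop("stoichiometric coefficients must be >= 0")
  if (any(l + a < 1)) stop("each species needs l + a >= 1")
  if (any(l == 1 & a == 0) || any(l == 0 & a == 1))
    stop("free components (1,0) and (0,1) are implicit; do not list them")
  if (anyDuplicated(paste(l, a))) stop("duplicate (l,a) species")
  if (any(!is.finite(lb))) stop("log_beta must be finite")
  ord <- order(l, a)
  complexes <- data.frame(l = l, a = a, log_beta = lb,
                          fixed = as.logical(species$fixed))[ord, , drop = FALSE]
  rownames(complexes) <- NULL
  # full species table: free L, free A, then complexes
  full <- rbind(data.frame(l = c(1L, 0L), a = c(0L, 1L), log_beta = 0,
                           fixed = TRUE),
                complexes)
  full$name <- species_name(full$l, full$a)
  structure(list(complexes = complexes, species = full),
            class = "equilibrium_model")
}

species_name <- function(l, a) {
  nm <- function(count, sym) ifelse(count == 0L, "",
                                    ifelse(count == 1L, sym,
                                           paste0(sym, count)))
  out <- paste0(nm(l, "L"), nm(a, "A"))
  out
}

#' @export
print.equilibrium_model <- function(x, ...) {
  cat("Equilibrium model (components L, A)\n")
  cmp <- x$complexes
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  %-4s log beta(%d,%d) = %g%s\n",
                species_name(cmp$l[i], cmp$a[i]), cmp$l[i], cmp$a[i],
                cmp$log_beta[i], if (cmp$fixed[i]) " [fixed]" else ""))
  invisible(x)
}

#' Replace the free formation constants of a model
#'
#' Utility used by the fitting routines: returns a copy of `model` with the
#' non-fixed `log_beta` values replaced by `log_beta_free` (in species order).
#'
#' @param model an [equilibrium_model()]
#' @param log_beta_free numeric vector, one per non-fixed complex species
#' @return an `equilibrium_model`
#' @export
set_free_constants <- function(model, log_beta_free) {
  free <- !model$complexes$fixed
  if (length(log_beta_free) != sum(free))
    stop("expected ", sum(free), " free constants")
  model$complexes$log_beta[free] <- log_beta_free
  model$species$log_beta[-(1:2)] <- model$complexes$log_beta
  model
}

#' Titration schedule: how titrant additions translate into compositions
#'
#' In `dilution` mode the titrand (initial volume `V0`, receptor concentration
#' `c_L_initial`) is diluted by each aliquot of anion titrant; in
#' `constant-ligand` mode the titrant also contains the receptor at the same
#' concentration, so the total receptor concentration stays constant along the
#' titration (the usual NMR-titration setup).
#'
#' @param V0 initial titrand volume, dm^3
#' @param c_L_initial total receptor concentration in the titrand, mol dm^-3
#' @param c_A_titrant total anion concentration in the titrant, mol dm^-3
#' @param cumulative_added_volumes strictly increasing cumulative titrant
#'   volumes, dm^3 (first entry may be 0 for the pre-addition spectrum)
#' @param mode `"dilution"` or `"constant-ligand"`
#' @param c_L_titrant receptor concentration in the titrant (only used to
#'   validate `constant-ligand` mode, where it must equal `c_L_initial`)
#' @return an object of class `"titration_schedule"`
#' @export
titration_schedule <- function(V0, c_L_initial, c_A_titrant,
                               cumulative_added_volumes,
                               mode = c("dilution", "constant-ligand"),
                               c_L_titrant = NULL) {
  mode <- match.arg(mode)
  v <- as.numeric(cumulative_added_volumes)
  if (!(V0 > 0)) stop("V0 must be positive")
  if (any(diff(v) <= 0)) stop("cumulative volumes must be strictly increasing")
  if (any(v < 0)) stop("volumes must be >= 0")
  if (mode == "constant-ligand") {
    if (is.null(c_L_titrant)) c_L_titrant <- c_L_initial
    if (abs(c_L_titrant - c_L_initial) > 1e-12 * max(c_L_initial, 1e-300))
      stop("constant-ligand mode requires c_L_titrant == c_L_initial")
  }
  structure(list(V0 = V0, c_L_initial = c_L_initial,
                 c_A_titrant = c_A_titrant, c_L_titrant = c_L_titrant,
                 cumulative_added_volumes = v, mode = mode),
            class = "titration_schedule")
}

#' Analytical (total) compositions at each titration point
#'
#' In dilution mode `total_L(i) = c_L_initial * V0 / (V0 + v_i)` and
#' `total_A(i) = c_A_titrant * v_i / (V0 + v_i)`; in constant-ligand mode
#' `total_L` is constant at `c_L_initial` while `total_A` dilutes as above.
#'
#' @param schedule a [titration_schedule()]
#' @return data frame with columns `volume` (dm^3), `total_L`, `total_A`
#'   (mol dm^-3), one row per titration point
#' @export
schedule_to_compositions <- function(schedule) {
  stopifnot(inherits(schedule, "titration_schedule"))
  v <- schedule$cumulative_added_volumes
  Vt <- schedule$V0 + v
  total_A <- schedule$c_A_titrant * v / Vt
  total_L <- if (schedule$mode == "constant-ligand")
    rep(schedule$c_L_initial, length(v))
  else
    schedule$c_L_initial * schedule$V0 / Vt
  data.frame(volume = v, total_L = total_L, total_A = total_A)
}

#' Closed-form 1:1 complex concentration
#'
#' Analytic root of `K (total_L - x)(total_A - x) = x` on the physical branch
#' `0 <= x <= min(total_L, total_A)`. Serves as an independent oracle for the
#' general speciation solver.
#'
#' @param total_L,total_A total concentrations, mol dm^-3
#' @param K stability constant (molar scale), > 0
#' @return the equilibrium complex concentration `[LA]`, mol dm^-3
#' @export
closed_form_1to1 <- function(total_L, total_A, K) {
  stopifnot(K > 0, total_L >= 0, total_A >= 0)
  b <- K * (total_L + total_A) + 1
  # smaller quadratic root, written to avoid cancellation
  disc <- sqrt(b * b - 4 * K^2 * total_L * total_A)
  x <- 2 * K * total_L * total_A / (b + disc)
  pmin(x, pmin(total_L, total_A))
}

#' Solve mass-balance speciation
#'
#' Given total (analytical) concentrations of receptor and anion and an
#' equilibrium model, finds free concentrations `[L]`, `[A]` satisfying both
#' component mass balances, and the concentration of every species
#' `beta * [L]^l * [A]^a`. The solver works in log-free-concentration space by
#' damped Newton iteration with the analytic Jacobian assembled from the
#' stoichiometry matrix (which guarantees positivity and is robust for stiff
#' beta values), and falls back to nested bisection if Newton fails.
#'
#' @param total_L,total_A total concentrations, mol dm^-3 (both >= 0)
#' @param model an [equilibrium_model()]
#' @param tol convergence tolerance on the maximum relative mass-balance
#'   residual (default 1e-12)
#' @param max_iter maximum Newton iterations (default 200)
#' @return a list of class `"speciation_state"`: `free_L`, `free_A`,
#'   `concentrations` (named, every model species including free L and A),
#'   `residual` (max relative mass-balance error), `iterations`, `method`
#' @examples
#' m <- equilibrium_model(data.frame(l = 1, a = 1, log_beta = 4))
#' solve_speciation(1e-4, 1e-4, m)
#' @export
solve_speciation <- function(total_L, total_A, model, tol = 1e-12,
                             max_iter = 200L) {
  stopifnot(inherits(model, "equilibrium_model"))
  if (total_L < 0 || total_A < 0) stop("total concentrations must be >= 0")
  sp <- model$species
  nu <- cbind(L = sp$l, A = sp$a)          # species x components
  lbeta_ln <- sp$log_beta * log(10)
  totals <- c(L = total_L, A = total_A)
  active <- totals > 0
  conc <- numeric(nrow(sp)); names(conc) <- sp$name

  if (!any(active)) {
    return(speciation_state(conc, totals, 0, 0L, "trivial"))
  }

  # restrict to species not involving zero-total components
  keep <- rowSums(nu[, !active, drop = FALSE]) == 0
  nu_a <- nu[keep, active, drop = FALSE]
  lb_a <- lbeta_ln[keep]

  res <- speciate_newton(nu_a, lb_a, totals[active], tol, max_iter)
  if (is.null(res))
    res <- speciate_bisect(nu_a, lb_a, totals[active], tol)
  if (is.null(res))
    stop("speciation solver failed to converge (totals: ",
         format(total_L), ", ", format(total_A), ")")

  conc[keep] <- res$conc
  speciation_state(conc, totals, res$residual, res$iterations, res$method)
}

speciation_state <- function(conc, totals, residual, iterations, method) {
  structure(list(free_L = unname(conc[1L]), free_A = unname(conc[2L]),
                 concentrations = conc, totals = totals,
                 residual = residual, iterations = iterations,
                 method = method),
            class = "speciation_state")
}

#' @export
print.speciation_state <- function(x, ...) {
  cat("Speciation (mol dm^-3):\n")
  print(signif(x$concentrations, 6))
  cat(sprintf("max relative mass-balance residual: %.3g (%s, %d iterations)\n",
              x$residual, x$method, x$iterations))
  invisible(x)
}

# Damped Newton in x = ln(free concentrations). Returns NULL on failure.
speciate_newton <- function(nu, lbeta_ln, totals, tol, max_iter) {
  nc <- ncol(nu)
  x <- log(totals)                              # start at free = total
  calc <- function(x) {
    cs <- exp(lbeta_ln + drop(nu %*% x))
    Tc <- drop(crossprod(nu, cs))               # calculated totals
    list(cs = cs, Tc = Tc)
  }
  st <- calc(x)
  resid <- function(Tc) max(abs(Tc - totals) / totals)
  r <- resid(st$Tc)
  for (it in seq_len(max_iter)) {
    if (r <= tol)
      return(list(conc = full_conc(nu, st$cs), residual = r,
                  iterations = it - 1L, method = "newton"))
    # J_ij = sum_s nu_si nu_sj c_s
    J <- crossprod(nu * sqrt(st$cs))
    step <- tryCatch(solve(J, totals - st$Tc), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # damp: cap the log step, then backtrack on the residual
    cap <- 3 / max(1, max(abs(step)))
    lam <- min(1, cap)
    ok <- FALSE
    for (h in 1:40) {
      xn <- x + lam * step
      stn <- calc(xn)
      rn <- resid(stn$Tc)
      if (is.finite(rn) && rn < r) { ok <- TRUE; break }
      lam <- lam / 2
    }
    if (!ok) return(NULL)
    x <- xn; st <- stn; r <- rn
  }
  NULL
}

full_conc <- function(nu, cs) {
  # cs is ordered as the kept species rows; caller re-expands
  cs
}

# Nested bisection fallback: outer loop on the first active component, inner
# on the second; both calculated totals are increasing in their own free
# concentration.
speciate_bisect <- function(nu, lbeta_ln, totals, tol, n_iter = 200L) {
  nc <- ncol(nu)
  tot_of <- function(free) {
    cs <- exp(lbeta_ln + drop(nu %*% log(free)))
    drop(crossprod(nu, cs))
  }
  if (nc == 1L) {
    lo <- totals * 1e-16; hi <- totals
    for (i in seq_len(n_iter)) {
      mid <- sqrt(lo * hi)
      if (tot_of(mid)[1L] > totals) hi <- mid else lo <- mid
    }
    free <- sqrt(lo * hi)
    cs <- exp(lbeta_ln + drop(nu %*% log(free)))
    r <- max(abs(drop(crossprod(nu, cs)) - totals) / totals)
    if (r > 1e-8) return(NULL)
    return(list(conc = cs, residual = r, iterations = n_iter,
                method = "bisection"))
  }
  inner <- function(f1) {
    lo <- totals[2L] * 1e-16; hi <- totals[2L]
    for (i in seq_len(n_iter)) {
      mid <- sqrt(lo * hi)
      if (tot_of(c(f1, mid))[2L] > totals[2L]) hi <- mid else lo <- mid
    }
    sqrt(lo * hi)
  }
  lo <- totals[1L] * 1e-16; hi <- totals[1L]
  for (i in seq_len(n_iter)) {
    mid <- sqrt(lo * hi)
    if (tot_of(c(mid, inner(mid)))[1L] > totals[1L]) hi <- mid else lo <- mid
  }
  f1 <- sqrt(lo * hi); f2 <- inner(f1)
  cs <- exp(lbeta_ln + drop(nu %*% log(c(f1, f2))))
  r <- max(abs(drop(crossprod(nu, cs)) - totals) / totals)
  if (r > 1e-8) return(NULL)
  list(conc = cs, residual = r, iterations = n_iter, method = "bisection")
}

#' Speciation along a whole titration
#'
#' Convenience wrapper: solves the mass balance at every point of a titration
#' schedule and returns the species concentration matrix used by the global
#' fitting routines.
#'
#' @param schedule a [titration_schedule()]
#' @param model an [equilibrium_model()]
#' @param ... passed to [solve_speciation()]
#' @return matrix (points x species) of concentrations, columns named by
#'   species (`L`, `A`, `LA`, `A2`, ...)
#' @export
speciation_profile <- function(schedule, model, ...) {
  comps <- schedule_to_compositions(schedule)
  out <- t(vapply(seq_len(nrow(comps)), function(i) {
    solve_speciation(comps$total_L[i], comps$total_A[i], model,
                     ...)$concentrations
  }, numeric(nrow(model$species))))
  colnames(out) <- model$species$name
  out
}
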