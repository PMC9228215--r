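# Solvent-transfer thermodynamic cycles: complexation in two solvents
# (acetonitrile and methanol in the motivating study) connected by transfer
# Gibbs energies of receptor, anion, and complex. All transfer energies are
# reported for the source -> target direction (MeCN -> MeOH by default);
# literature values quoted for the reverse direction are negated on input.

#' Reaction Gibbs energy from a stability constant
#'
#' `DrG = -RT ln(10) log K` on the molar concentration scale.
#'
#' @param log_K decadic log stability constant
#' @param T temperature, K (default 298.15)
#' @return standard reaction Gibbs energy, kJ mol^-1
#' @export
gibbs_from_logK <- function(log_K, T = 298.15) {
  stopifnot(T > 0)
  -R_GAS * T * log(10) * log_K / 1000
}

#' Transfer Gibbs energy from a solubility pair
#'
#' For a neutral solute equilibrated with the same solid phase in both
#' solvents (ideal-solution assumption), `DtG = -RT ln(s_target / s_source)`.
#' A solute more soluble in the target solvent transfers favorably
#' (negative `DtG`).
#'
#' @param s_source,s_target saturation solubilities in the source and target
#'   solvents, mol dm^-3 (both > 0)
#' @param T temperature, K
#' @return transfer Gibbs energy source -> target, kJ mol^-1
#' @examples
#' transfer_from_solubility(2.72e-3, 2.81e-3)  # ~ -0.08 kJ/mol: negligible
#' @export
transfer_from_solubility <- function(s_source, s_target, T = 298.15) {
  if (!(s_source > 0) || !(s_target > 0))
    stop("solubilities must be positive")
  stopifnot(T > 0)
  -R_GAS * T * log(s_target / s_source) / 1000
}

#' Close a solvent-transfer thermodynamic cycle
#'
#' The complexation reactions `L + A- = LA-` in the source and target solvent
#' and the transfer of each participant form a closed cycle, so
#' `DtG(LA-) = DtG(A-) + DtG(L) + DrG(target) - DrG(source)`. Any single
#' unknown leg may be solved from the others by setting it to `NA`; by
#' default the complex leg is the unknown.
#'
#' @param dtG_anion anion transfer Gibbs energy (source -> target), kJ mol^-1
#' @param dtG_ligand receptor transfer Gibbs energy, kJ mol^-1
#' @param drG_source,drG_target standard complexation Gibbs energies in the
#'   two solvents, kJ mol^-1
#' @param dtG_complex complex transfer Gibbs energy; `NA` (default) to solve
#'   for it
#' @param provenance optional named character vector labelling the origin of
#'   each leg (e.g. "literature", "solubility", "titration")
#' @return object of class `"transfer_cycle"` with all five legs and a
#'   `closure` residual (zero by construction)
#' @export
complex_transfer <- function(dtG_anion, dtG_ligand, drG_source, drG_target,
                             dtG_complex = NA_real_, provenance = NULL) {
  legs <- c(dtG_anion = dtG_anion, dtG_ligand = dtG_ligand,
            drG_source = drG_source, drG_target = drG_target,
            dtG_complex = dtG_complex)
  nas <- which(is.na(legs))
  if (length(nas) > 1L)
    stop("at most one leg may be unknown; missing: ",
         paste(names(legs)[nas], collapse = ", "))
  # closure: dtG_complex - dtG_anion - dtG_ligand - drG_target + drG_source = 0
  coef <- c(dtG_anion = -1, dtG_ligand = -1, drG_source = 1,
            drG_target = -1, dtG_complex = 1)
  if (length(nas) == 1L) {
    k <- names(legs)[nas]
    legs[k] <- -sum(coef[-nas] * legs[-nas]) / coef[k]
    closure <- 0    # exact by construction
  } else {
    closure <- sum(coef * legs)
    if (abs(closure) > 1e-9)
      stop("supplied legs do not close the cycle (residual ",
           format(closure), " kJ/mol)")
    closure <- 0
  }
  structure(c(as.list(legs), list(closure = closure,
                                  provenance = provenance)),
            class = "transfer_cycle")
}

#' @export
print.transfer_cycle <- function(x, ...) {
  cat("Transfer cycle (kJ/mol, source -> target):\n")
  for (k in c("dtG_anion", "dtG_ligand", "drG_source", "drG_target",
              "dtG_complex"))
    cat(sprintf("  %-12s %8.3f%s\n", k, x[[k]],
                if (!is.null(x$provenance[k]) && !is.na(x$provenance[k]))
                  paste0("  [", x$provenance[k], "]") else ""))
  cat(sprintf("  closure      %8.3g\n", x$closure))
  invisible(x)
}

#' Reverse the transfer direction of a cycle
#'
#' Swaps source and target: every transfer leg changes sign and the two
#' reaction legs swap roles.
#'
#' @param cycle a `"transfer_cycle"`
#' @return the reversed `"transfer_cycle"`
#' @export
reverse_cycle <- function(cycle) {
  complex_transfer(dtG_anion = -cycle$dtG_anion,
                   dtG_ligand = -cycle$dtG_ligand,
                   drG_source = cycle$drG_target,
                   drG_target = cycle$drG_source,
                   dtG_complex = -cycle$dtG_complex,
                   provenance = cycle$provenance)
}

#' Build a per-anion transfer cycle from titration constants and config
#'
#' Convenience wrapper for the whole chain: stability constants in the two
#' solvents give the reaction legs via [gibbs_from_logK()]; the receptor leg
#' comes from solubilities via [transfer_from_solubility()] (or is supplied
#' directly); the anion leg is a literature value whose quoted direction is
#' recorded and normalized (values tabulated for target -> source are
#' negated).
#'
#' @param log_K_source,log_K_target stability constants in the two solvents
#' @param dtG_anion literature anion transfer energy, kJ mol^-1
#' @param anion_direction direction the literature value is quoted for:
#'   `"source->target"` (used as is) or `"target->source"` (negated)
#' @param solubility_pair optional `c(s_source, s_target)` for the receptor
#'   leg; otherwise supply `dtG_ligand`
#' @param dtG_ligand receptor transfer energy, kJ mol^-1 (default 0)
#' @param T temperature, K
#' @return a `"transfer_cycle"` with provenance labels
#' @export
cycle_from_constants <- function(log_K_source, log_K_target, dtG_anion,
                                 anion_direction = c("source->target",
                                                     "target->source"),
                                 solubility_pair = NULL, dtG_ligand = 0,
                                 T = 298.15) {
  anion_direction <- match.arg(anion_direction)
  if (anion_direction == "target->source") dtG_anion <- -dtG_anion
  lig_src <- "config"
  if (!is.null(solubility_pair)) {
    dtG_ligand <- transfer_from_solubility(solubility_pair[1L],
                                           solubility_pair[2L], T)
    lig_src <- "solubility"
  }
  complex_transfer(dtG_anion = dtG_anion, dtG_ligand = dtG_ligand,
                   drG_source = gibbs_from_logK(log_K_source, T),
                   drG_target = gibbs_from_logK(log_K_target, T),
                   provenance = c(dtG_anion = paste0("literature (",
                                                     anion_direction, ")"),
                                  dtG_ligand = lig_src,
                                  drG_source = "titration",
                                  drG_target = "titration",
                                  dtG_complex = "cycle closure"))
}
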