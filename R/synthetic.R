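# Synthetic-data generators with known ground truth for every pipeline
# stage: bilinear spectral titrations, fast-exchange NMR shift titrations,
# Wiseman-type thermograms with dilution blanks, and jittered
# cyclopeptide-anion coordinate ensembles. Each generator is deterministic
# under a fixed seed and returns its truth alongside the data.

#' Default geometric titrant ladder
#'
#' Cumulative titrant volumes reaching `max_equiv` anion equivalents over
#' `n_points` points (first point at zero addition), geometric spacing.
#'
#' @param n_points number of titration points (including the zero point)
#' @param V0 initial volume, dm^3
#' @param c_L_initial receptor concentration, mol dm^-3
#' @param c_A_titrant titrant anion concentration, mol dm^-3
#' @param max_equiv final anion:receptor equivalents (before dilution)
#' @return numeric vector of cumulative volumes, dm^3
#' @export
default_ladder <- function(n_points = 15L, V0 = 2e-3, c_L_initial = 1e-4,
                           c_A_titrant = 2e-3, max_equiv = 3) {
  v_max <- max_equiv * c_L_initial * V0 / c_A_titrant
  c(0, v_max * (2^(seq_len(n_points - 1L) / (n_points - 1L) * 5) - 1) /
      (2^5 - 1))
}

#' Titration schedule matched to the expected stability constant
#'
#' Standard titration design: the receptor concentration is chosen so the
#' saturation parameter `K * c_L` is about 10 (clipped to the practical
#' instrument range 1e-6 to 1e-2 mol dm^-3), which keeps the bound fraction
#' swinging through the informative 20--80% window along a 0--3 equivalent
#' ladder. Weak complexes are titrated concentrated, strong ones dilute --
#' the same rule an experimentalist applies at the bench.
#'
#' @param log_K the stability constant the titration is designed to probe
#' @param n_points titration points
#' @param V0 cuvette volume, dm^3
#' @param titrant_ratio titrant concentration as a multiple of `c_L`
#' @return a [titration_schedule()]
#' @export
recovery_schedule <- function(log_K, n_points = 15L, V0 = 2e-3,
                              titrant_ratio = 20) {
  c_L <- min(1e-2, max(1e-6, 10^(1 - log_K)))
  c_A <- titrant_ratio * c_L
  titration_schedule(V0 = V0, c_L_initial = c_L, c_A_titrant = c_A,
                     cumulative_added_volumes =
                       default_ladder(n_points, V0, c_L, c_A))
}

gaussian_band <- function(lambda, center, width, amplitude) {
  amplitude * exp(-0.5 * ((lambda - center) / width)^2)
}

#' Generate a synthetic spectral titration
#'
#' Bilinear model `Y = S C' + noise`: per-species emission (or absorbance)
#' spectra are sums of Gaussian bands, the concentration matrix follows from
#' the mass balance for the true constants, and homoscedastic Gaussian noise
#' is added at a signal-to-noise ratio `snr` (defined against the maximum
#' noiseless signal). The default free-receptor band sits near 283 nm, as for
#' a phenylalanine-type fluorophore excited in the far UV; `template =
#' "quench"` makes the complex dimmer than the free receptor (halide-like
#' quenching), `"enhance"` brighter.
#'
#' @param log_K true 1:1 stability constant (log10); ignored when `model` is
#'   supplied
#' @param model optional full [equilibrium_model()] to simulate (overrides
#'   `log_K`)
#' @param schedule optional [titration_schedule()]; default: 15-point
#'   geometric ladder to 3 equivalents in a 2 mL cuvette
#' @param channels emission wavelengths, nm
#' @param template `"enhance"` or `"quench"`
#' @param snr signal-to-noise ratio (Inf for noiseless)
#' @param seed RNG seed
#' @return list: `series` (a [response_series()]), `schedule`, `model`,
#'   `truth` (true constants and the molar response matrix used)
#' @export
gen_spectral_titration <- function(log_K = 4, model = NULL, schedule = NULL,
                                   channels = seq(260, 320, by = 2),
                                   template = c("enhance", "quench"),
                                   snr = 100, seed = 1L) {
  template <- match.arg(template)
  if (is.null(model))
    model <- equilibrium_model(data.frame(l = 1, a = 1, log_beta = log_K))
  if (is.null(schedule))
    schedule <- titration_schedule(V0 = 2e-3, c_L_initial = 1e-4,
                                   c_A_titrant = 2e-3,
                                   cumulative_added_volumes =
                                     default_ladder())
  C <- design_matrix(schedule, model, kind = "spectral")
  n_sp <- ncol(C)
  # species spectra: free L at 283 nm; complexes shifted and scaled
  scale_complex <- if (template == "quench") 0.35 else 1.8
  S <- vapply(seq_len(n_sp), function(s) {
    if (s == 1L) gaussian_band(channels, 283, 9, 1e6)
    else gaussian_band(channels, 283 + 3 * (s - 1L), 10,
                       1e6 * scale_complex^(s - 1L))
  }, numeric(length(channels)))
  Y <- S %*% t(C)
  set.seed(seed)
  sigma <- if (is.finite(snr)) max(abs(Y)) / snr else 0
  if (sigma > 0) Y <- Y + matrix(stats::rnorm(length(Y), 0, sigma),
                                 nrow(Y))
  list(series = response_series(channels, schedule$cumulative_added_volumes,
                                Y, kind = "fluorescence"),
       schedule = schedule, model = model,
       truth = list(log_beta = model$complexes$log_beta,
                    molar_response = S, sigma = sigma))
}

#' Generate a synthetic fast-exchange NMR shift titration
#'
#' Observed shifts are speciation-weighted averages of per-species limiting
#' shifts plus Gaussian noise, on a constant-ligand schedule (receptor in
#' both titrand and titrant) by default. The default limiting shifts move the
#' amide protons downfield on binding, the usual signature of anion
#' coordination by N-H donors.
#'
#' @param log_K true 1:1 constant (log10); ignored when `model` supplied
#' @param model optional [equilibrium_model()]
#' @param schedule optional [titration_schedule()] (default constant-ligand,
#'   15 points to 3 equivalents)
#' @param protons proton labels
#' @param delta_free free-receptor shifts, ppm (one per proton)
#' @param delta_shift complexation-induced shift changes, ppm (per proton,
#'   per complex species in column order)
#' @param noise_sd shift noise, ppm
#' @param seed RNG seed
#' @return list: `series`, `schedule`, `model`, `truth`
#' @export
gen_nmr_titration <- function(log_K = 2, model = NULL, schedule = NULL,
                              protons = c("NH", "CaH"),
                              delta_free = c(7.6, 4.4),
                              delta_shift = c(0.5, 0.12),
                              noise_sd = 0.002, seed = 1L) {
  if (is.null(model))
    model <- equilibrium_model(data.frame(l = 1, a = 1, log_beta = log_K))
  if (is.null(schedule))
    schedule <- titration_schedule(V0 = 5e-4, c_L_initial = 1e-3,
                                   c_A_titrant = 2e-2,
                                   cumulative_added_volumes =
                                     default_ladder(V0 = 5e-4,
                                                    c_L_initial = 1e-3,
                                                    c_A_titrant = 2e-2),
                                   mode = "constant-ligand")
  C <- design_matrix(schedule, model, kind = "shift")
  n_sp <- ncol(C)
  S <- matrix(delta_free, length(protons), n_sp)
  if (n_sp > 1L)
    for (s in 2:n_sp)
      S[, s] <- delta_free + delta_shift * (s - 1L)
  Y <- S %*% t(C)
  set.seed(seed)
  if (noise_sd > 0)
    Y <- Y + matrix(stats::rnorm(length(Y), 0, noise_sd), nrow(Y))
  list(series = response_series(protons, schedule$cumulative_added_volumes,
                                Y, kind = "shift"),
       schedule = schedule, model = model,
       truth = list(log_beta = model$complexes$log_beta,
                    limiting_shifts = S, noise_sd = noise_sd))
}

#' Generate a synthetic ITC thermogram with its dilution blank
#'
#' Wraps [simulate_thermogram()]: returns a noisy binding thermogram plus a
#' matching blank-only thermogram (constant dilution heat, same noise model)
#' and the ground truth, including the Wiseman parameter `c = K c_L` of the
#' configuration.
#'
#' @param log_K,dH true constants (log10 molar; kJ mol^-1)
#' @param n_inj number of injections
#' @param inj_vol per-injection volume, dm^3
#' @param V0 cell volume, dm^3 (default 1.4e-3)
#' @param c_L,c_A cell / syringe concentrations, mol dm^-3
#' @param T temperature, K
#' @param blank constant dilution heat per injection, J
#' @param noise_frac noise SD as a fraction of the largest noiseless heat
#' @param seed RNG seed
#' @return list: `thermogram`, `blank` (both [thermogram()]s), `truth`
#' @export
gen_thermogram <- function(log_K = 6.02, dH = -15, n_inj = 25L,
                           inj_vol = 1e-5, V0 = 1.4e-3, c_L = 1e-4,
                           c_A = 2e-3, T = 298.15, blank = 2e-6,
                           noise_frac = 0.01, seed = 1L) {
  inj <- rep(inj_vol, n_inj)
  q0 <- itc_model_heats(c(log_K, dH), inj, V0, c_L, c_A)
  sigma <- noise_frac * max(abs(q0))
  tg <- simulate_thermogram(log_K, dH, inj, V0, c_L, c_A, T,
                            blank = blank, noise_sd = sigma, seed = seed)
  bl <- simulate_thermogram(log_K, dH = 0, inj, V0, c_L = 0, c_A, T,
                            blank = blank, noise_sd = sigma,
                            seed = seed + 1L)
  list(thermogram = tg, blank = bl,
       truth = list(log_K = log_K, dH = dH,
                    dS = derive_entropy(log_K, dH, T),
                    blank = blank, sigma = sigma,
                    c_parameter = 10^log_K * c_L))
}

# unit vector
unitv <- function(v) v / sqrt(sum(v * v))

#' Generate a synthetic cyclopeptide-anion coordinate ensemble
#'
#' Builds a five-fold pseudo-cyclopeptide scaffold: five amide N-H units on a
#' ring (H pointing toward the endo binding site above the backbone, the
#' sidechain face), five C-alpha atoms, five carbonyl oxygens, and five
#' six-carbon phenyl dummy rings. The anion (a single heavy atom by default)
#' is placed at the endo site above the ring center or at an exo site below
#' it, frames are drawn from the two states with the given weights, and all
#' coordinates get isotropic Gaussian jitter. In the jitter-free endo
#' geometry every amide H lies 2.61 Angstrom from the anion, inside the
#' default 2.8 Angstrom coordination cutoff.
#'
#' @param n_frames number of frames
#' @param endo_weight probability of the endo state (default 0.7)
#' @param jitter_sd per-coordinate Gaussian jitter, Angstrom (default 0.05)
#' @param anion list `(name, elem)` of the anion atom (default chloride)
#' @param seed RNG seed
#' @return list: `ensemble` (an [ensemble()]), `states` (per-frame `"endo"`
#'   / `"exo"` labels), `truth` (geometry constants)
#' @export
gen_ensemble <- function(n_frames = 200L, endo_weight = 0.7,
                         jitter_sd = 0.05,
                         anion = list(name = "Cl", elem = "Cl"),
                         seed = 1L) {
  stopifnot(endo_weight >= 0, endo_weight <= 1, jitter_sd >= 0)
  endo_pos <- c(0, 0, 2); exo_pos <- c(0, 0, -4)
  atoms <- list(); coords <- list()
  for (i in 1:5) {
    phi <- 2 * pi * (i - 1) / 5
    ca <- c(4 * cos(phi), 4 * sin(phi), 0)
    nn <- c(3 * cos(phi + pi / 10), 3 * sin(phi + pi / 10), 0)
    hh <- nn + unitv(endo_pos - nn)            # N-H aimed at the endo site
    oo <- c(3.4 * cos(phi + pi / 5), 3.4 * sin(phi + pi / 5), -0.5)
    ring_center <- c(6 * cos(phi), 6 * sin(phi), 1)
    u <- unitv(c(-sin(phi), cos(phi), 0)); w <- c(0, 0, 1)
    ring <- t(vapply(0:5, function(k) {
      th <- 2 * pi * k / 6
      ring_center + 1.39 * (cos(th) * u + sin(th) * w)
    }, numeric(3)))
    atoms[[i]] <- data.frame(
      name = c("N", "H", "CA", "O", paste0("CG", 1:6)),
      resid = i,
      elem = c("N", "H", "C", "O", rep("C", 6)))
    coords[[i]] <- rbind(nn, hh, ca, oo, ring)
  }
  atoms <- do.call(rbind, atoms)
  atoms <- rbind(atoms, data.frame(name = anion$name, resid = 6L,
                                   elem = anion$elem))
  base <- do.call(rbind, coords)
  set.seed(seed)
  states <- ifelse(stats::runif(n_frames) < endo_weight, "endo", "exo")
  frames <- lapply(seq_len(n_frames), function(f) {
    xyz <- rbind(base, if (states[f] == "endo") endo_pos else exo_pos)
    xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sd), nrow(xyz))
  })
  rownames(atoms) <- NULL
  list(ensemble = ensemble(frames, atoms), states = states,
       truth = list(endo_weight = endo_weight, jitter_sd = jitter_sd,
                    endo_H_anion_distance =
                      sqrt(sum((coords[[1]][2, ] - endo_pos)^2))))
}
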