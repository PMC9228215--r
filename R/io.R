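# File formats and the pipeline driver. All text formats are plain UTF-8
# with dot decimals: titration matrices as CSV (channel column + cumulative
# volume header, mL), equilibrium models and schedules as key-value files,
# thermograms as CSV with a metadata header, trajectories as multi-model PDB
# (via bio3d) or XYZ.

fmt_num <- function(x) sprintf("%.10g", x)

#' Read a titration matrix CSV
#'
#' Dialect: an optional `# kind: <kind>` comment line, then a header row
#' whose first cell is `channel` and remaining cells are cumulative titrant
#' volumes in mL; each data row is a channel (wavelength in nm or proton
#' label) followed by the responses. Parse problems are reported with line
#' numbers.
#'
#' @param path file path
#' @param kind response kind, overriding any `# kind:` line
#' @return a [response_series()] (volumes converted to dm^3)
#' @export
read_titration_csv <- function(path, kind = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  off <- 0L
  if (grepl("^#", lines[1L])) {
    m <- regmatches(lines[1L], regexec("^#\\s*kind:\\s*(\\S+)", lines[1L]))[[1L]]
    if (length(m) == 2L && is.null(kind)) kind <- m[2L]
    lines <- lines[-1L]; off <- 1L
  }
  if (is.null(kind)) kind <- "fluorescence"
  hdr <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (tolower(hdr[1L]) != "channel")
    stop("line ", 1L + off, ": header must start with 'channel'")
  vols_ml <- suppressWarnings(as.numeric(hdr[-1L]))
  if (anyNA(vols_ml))
    stop("line ", 1L + off, ": non-numeric volume in header")
  rows <- strsplit(lines[-1L], ",", fixed = TRUE)
  nc <- length(hdr)
  channels <- character(length(rows))
  values <- matrix(NA_real_, length(rows), nc - 1L)
  for (i in seq_along(rows)) {
    ln <- i + 1L + off
    if (length(rows[[i]]) != nc)
      stop("line ", ln, ": expected ", nc, " cells, found ",
           length(rows[[i]]))
    channels[i] <- rows[[i]][1L]
    vals <- suppressWarnings(as.numeric(rows[[i]][-1L]))
    if (anyNA(vals)) stop("line ", ln, ": non-numeric response cell")
    values[i, ] <- vals
  }
  if (anyDuplicated(channels)) {
    dup <- which(duplicated(channels))[1L]
    stop("line ", dup + 1L + off, ": duplicated channel '", channels[dup],
         "'")
  }
  ch_num <- suppressWarnings(as.numeric(channels))
  if (!anyNA(ch_num)) channels <- ch_num
  response_series(channels, vols_ml * 1e-3, values, kind = kind)
}

#' Write a titration matrix CSV
#'
#' Canonical form of the dialect read by [read_titration_csv()]; writing and
#' re-reading a canonical file round-trips byte-identically.
#'
#' @param series a [response_series()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_titration_csv <- function(series, path) {
  hdr <- paste(c("channel", fmt_num(series$volumes * 1e3)), collapse = ",")
  ch <- if (is.numeric(series$channels)) fmt_num(series$channels)
        else series$channels
  rows <- vapply(seq_along(ch), function(i)
    paste(c(ch[i], fmt_num(series$values[i, ])), collapse = ","),
    character(1))
  writeLines(c(sprintf("# kind: %s", series$kind), hdr, rows), path)
  invisible(path)
}

#' Read an equilibrium model file
#'
#' Key-value text format: comment lines start with `#`; each species is a
#' line `species l:a:log_beta` with an optional `:fixed` suffix, e.g.
#' `species 0:2:2.0:fixed` for a fixed anion-dimerization constant.
#'
#' @param path file path
#' @return an [equilibrium_model()]
#' @export
read_model_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  sp <- lapply(lines, function(ln) {
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (tok[1L] != "species")
      stop("unrecognized model line: '", ln, "'")
    f <- strsplit(tok[2L], ":", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("species needs l:a:log_beta -- got '", tok[2L],
                             "'")
    data.frame(l = as.integer(f[1L]), a = as.integer(f[2L]),
               log_beta = as.numeric(f[3L]),
               fixed = length(f) >= 4L && f[4L] == "fixed")
  })
  equilibrium_model(do.call(rbind, sp))
}

#' Write an equilibrium model file
#' @param model an [equilibrium_model()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_model_file <- function(model, path) {
  cmp <- model$complexes
  writeLines(c("# equilibrium model: species l:a:log_beta[:fixed]",
               sprintf("species %d:%d:%s%s", cmp$l, cmp$a,
                       fmt_num(cmp$log_beta),
                       ifelse(cmp$fixed, ":fixed", ""))), path)
  invisible(path)
}

#' Read a titration schedule file
#'
#' Key-value lines `key = value`; keys `V0` (dm^3), `c_L_initial`,
#' `c_A_titrant` (mol dm^-3), `mode` (`dilution` or `constant-ligand`) and
#' `volumes` (comma-separated cumulative dm^3).
#'
#' @param path file path
#' @return a [titration_schedule()]
#' @export
read_schedule_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("bad schedule line: '", ln, "'")
    kv[[trimws(parts[1L])]] <- trimws(parts[2L])
  }
  need <- c("V0", "c_L_initial", "c_A_titrant", "volumes")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop("schedule file missing: ",
                         paste(miss, collapse = ", "))
  titration_schedule(
    V0 = as.numeric(kv$V0), c_L_initial = as.numeric(kv$c_L_initial),
    c_A_titrant = as.numeric(kv$c_A_titrant),
    cumulative_added_volumes =
      as.numeric(strsplit(kv$volumes, ",", fixed = TRUE)[[1L]]),
    mode = if (is.null(kv$mode)) "dilution" else kv$mode)
}

#' Write a titration schedule file
#' @param schedule a [titration_schedule()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_schedule_file <- function(schedule, path) {
  writeLines(c("# titration schedule (volumes dm^3, concentrations mol/dm^3)",
               paste0("V0 = ", fmt_num(schedule$V0)),
               paste0("c_L_initial = ", fmt_num(schedule$c_L_initial)),
               paste0("c_A_titrant = ", fmt_num(schedule$c_A_titrant)),
               paste0("mode = ", schedule$mode),
               paste0("volumes = ",
                      paste(fmt_num(schedule$cumulative_added_volumes),
                            collapse = ","))), path)
  invisible(path)
}

#' Read a thermogram CSV
#'
#' Header comment lines carry the cell metadata
#' (`# V0_mL`, `# c_L_mM`, `# c_A_mM`, `# T_K`); data columns are
#' `injection_index,volume_uL,heat_ucal`. Heats are converted at
#' 1 cal = 4.184 J.
#'
#' @param path file path
#' @return a [thermogram()]
#' @export
read_thermogram_csv <- function(path) {
  lines <- readLines(path)
  meta <- list()
  hdr_lines <- grep("^#", lines, value = TRUE)
  for (ln in hdr_lines) {
    m <- regmatches(ln, regexec("^#\\s*(\\S+)\\s*[:=]\\s*(\\S+)", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- as.numeric(m[3L])
  }
  need <- c("V0_mL", "c_L_mM", "c_A_mM", "T_K")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("thermogram header missing: ",
                         paste(miss, collapse = ", "))
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("volume_uL", "heat_ucal") %in% names(dat)))
    stop("thermogram needs columns volume_uL, heat_ucal")
  thermogram(injection_volumes = dat$volume_uL * 1e-6,
             heats = dat$heat_ucal * 1e-6 * 4.184,
             V0 = meta$V0_mL * 1e-3, c_L = meta$c_L_mM * 1e-3,
             c_A = meta$c_A_mM * 1e-3, T = meta$T_K)
}

#' Write a thermogram CSV
#' @param tg a [thermogram()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_thermogram_csv <- function(tg, path) {
  writeLines(c(sprintf("# V0_mL = %s", fmt_num(tg$V0 * 1e3)),
               sprintf("# c_L_mM = %s", fmt_num(tg$c_L * 1e3)),
               sprintf("# c_A_mM = %s", fmt_num(tg$c_A * 1e3)),
               sprintf("# T_K = %s", fmt_num(tg$T)),
               "injection_index,volume_uL,heat_ucal",
               sprintf("%d,%s,%s", seq_along(tg$heats),
                       fmt_num(tg$injection_volumes * 1e6),
                       fmt_num(tg$heats / 4.184 * 1e6))), path)
  invisible(path)
}

#' Read a coordinate ensemble (multi-model PDB or XYZ trajectory)
#'
#' PDB files are read through bio3d (models become frames); XYZ trajectories
#' are concatenated frames of `n`, comment, `n` atom lines. Atom counts must
#' be constant across frames. For XYZ input the element symbol doubles as the
#' atom name and all atoms land in residue 1 unless the comment line carries
#' `resid=` assignments.
#'
#' @param path file path (`.pdb` or `.xyz`, by extension)
#' @return an [ensemble()]
#' @export
read_ensemble <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") read_ensemble_pdb(path)
  else if (ext == "xyz") read_ensemble_xyz(path)
  else stop("unsupported trajectory format: .", ext)
}

read_ensemble_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  n_atoms <- nrow(pdb$atom)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(!nzchar(trimws(elem))))
    elem <- substr(trimws(pdb$atom$elety), 1L, 1L)
  atoms <- data.frame(name = trimws(pdb$atom$elety),
                      resid = as.integer(pdb$atom$resno),
                      elem = trimws(elem))
  ensemble(frames, atoms)
}

read_ensemble_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("line ", i, ": expected atom count")
    if (i + 1L + n > length(lines))
      stop("truncated XYZ frame starting at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(tok, length, integer(1)) < 4L)
    if (length(bad)) stop("line ", i + 1L + bad[1L], ": malformed XYZ row")
    sym <- vapply(tok, `[[`, character(1), 1L)
    xyz <- t(vapply(tok, function(t)
      as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("non-numeric coordinate in frame at line ", i)
    if (is.null(atoms)) {
      atoms <- data.frame(name = sym, resid = 1L, elem = sym)
    } else if (nrow(atoms) != n || !all(atoms$name == sym)) {
      stop("inconsistent atom count or order across XYZ frames (line ", i,
           ")")
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames in ", path)
  ensemble(frames, atoms)
}

#' Write an ensemble (or one frame) as a multi-model PDB
#'
#' @param ens an [ensemble()]
#' @param path output path
#' @param frames frame indices to write (default all)
#' @return `path`, invisibly
#' @export
write_ensemble_pdb <- function(ens, path, frames = seq_along(ens$frames)) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- ens$atoms
  for (m in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ens$frames[[frames[m]]]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), substr(at$name, 1, 4), "LIG", at$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], at$elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Run a multi-stage analysis pipeline
#'
#' Executes the requested stages in dependency order on synthetic or file
#' inputs and returns a report (also written as JSON when `out` is given).
#' Stages: `"simulate"` (spectral titration with generator truth),
#' `"fit_spectral"`, `"fit_nmr"`, `"fit_itc"`, `"cycle"`. All randomness
#' derives from the single top-level `seed`, split deterministically per
#' stage. Every numeric constant in the report carries a provenance tag
#' (`"generator truth"`, `"fitted"`, `"config"`, `"literature"`).
#'
#' @param stages character vector of stage names (possibly empty: a no-op
#'   run with a valid empty report)
#' @param seed top-level seed
#' @param config named list of stage parameters; recognized entries include
#'   `log_K`, `snr`, `itc` (list passed to [gen_thermogram()]), `cycle`
#'   (list passed to [cycle_from_constants()]), `model_file`,
#'   `schedule_file`, `input` (titration CSV path)
#' @param out optional path for the JSON report
#' @return the report, a nested list, invisibly when `out` is given
#' @export
run_pipeline <- function(stages = character(0), seed = 1L, config = list(),
                         out = NULL) {
  if (!is.null(config$model_file) && !file.exists(config$model_file))
    stop("model file not found: ", config$model_file)
  if (!is.null(config$schedule_file) && !file.exists(config$schedule_file))
    stop("schedule file not found: ", config$schedule_file)
  report <- list(seed = seed, stages = as.list(stages),
                 package_version =
                   as.character(utils::packageVersion("anionbind")),
                 results = list())
  tagged <- function(value, provenance)
    list(value = unname(value), provenance = provenance)
  sim <- NULL
  stage_seed <- function(k) as.integer(seed + 1000L * k)

  for (stage in stages) {
    if (stage == "simulate") {
      log_K <- config$log_K %||% 4
      sim <- gen_spectral_titration(log_K = log_K,
                                    snr = config$snr %||% 100,
                                    seed = stage_seed(1L))
      report$results$simulate <- list(
        log_K_true = tagged(log_K, "generator truth"),
        snr = tagged(config$snr %||% 100, "config"),
        n_points = tagged(length(sim$series$volumes), "config"))
    } else if (stage == "fit_spectral") {
      if (is.null(sim)) {
        if (is.null(config$input) || is.null(config$schedule_file) ||
            is.null(config$model_file))
          stop("fit_spectral needs a prior simulate stage or input, ",
               "schedule_file and model_file")
        series <- read_titration_csv(config$input)
        schedule <- read_schedule_file(config$schedule_file)
        model <- read_model_file(config$model_file)
      } else {
        series <- sim$series; schedule <- sim$schedule; model <- sim$model
      }
      fit <- fit_spectral(series, schedule, model)
      free <- !fit$log_beta$fixed
      report$results$fit_spectral <- list(
        log_K = tagged(fit$log_beta$log_beta[free][1L], "fitted"),
        se = tagged(fit$log_beta$se[free][1L], "fitted"),
        ss = tagged(fit$ss, "fitted"))
    } else if (stage == "fit_nmr") {
      nmr <- gen_nmr_titration(log_K = config$log_K_nmr %||% 2,
                               seed = stage_seed(2L))
      fit <- fit_nmr_shifts(nmr$series, nmr$schedule, nmr$model)
      free <- !fit$log_beta$fixed
      report$results$fit_nmr <- list(
        log_K_true = tagged(config$log_K_nmr %||% 2, "generator truth"),
        log_K = tagged(fit$log_beta$log_beta[free][1L], "fitted"))
    } else if (stage == "fit_itc") {
      itc_cfg <- config$itc %||% list()
      itc_cfg$seed <- stage_seed(3L)
      g <- do.call(gen_thermogram, itc_cfg)
      rec <- fit_thermogram(subtract_blank(g$thermogram, g$blank),
                            fit_blank = TRUE)
      report$results$fit_itc <- list(
        log_K = tagged(rec$log_K, "fitted"),
        dH_kJ_mol = tagged(rec$dH, "fitted"),
        dS_J_mol_K = tagged(rec$dS, "fitted"),
        c_parameter = tagged(attr(rec, "c_parameter"), "fitted"))
    } else if (stage == "cycle") {
      # default: chloride-like legs; anion transfer into the protic solvent
      # is favorable, so the MeCN -> MeOH leg is negative
      cyc_cfg <- config$cycle %||%
        list(log_K_source = 6.02, log_K_target = 1.5, dtG_anion = -29,
             anion_direction = "source->target",
             solubility_pair = c(2.72e-3, 2.81e-3))
      cyc <- do.call(cycle_from_constants, cyc_cfg)
      report$results$cycle <- list(
        dtG_anion = tagged(cyc$dtG_anion, "literature"),
        dtG_ligand = tagged(cyc$dtG_ligand, "solubility"),
        drG_source = tagged(cyc$drG_source, "titration"),
        drG_target = tagged(cyc$drG_target, "titration"),
        dtG_complex = tagged(cyc$dtG_complex, "cycle closure"),
        closure = tagged(cyc$closure, "identity"))
    } else {
      stop("unknown stage: '", stage, "'")
    }
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
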