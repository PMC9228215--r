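# Post-processing of receptor-anion coordinate ensembles (MD trajectory
# frames): coordination matrices over amide N-H donors and anion heavy atoms,
# intramolecular hydrogen-bond census, coordination occupancy, PCA/cluster
# representative structures, and phenyl-ring centroid distances.

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                 P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904)

#' Construct a coordinate ensemble
#'
#' @param frames list of numeric `n_atoms x 3` coordinate matrices
#'   (Angstrom), or a 3-d array `n_atoms x 3 x n_frames`
#' @param atoms data frame with one row per atom: `name` (e.g. `"N"`, `"H"`,
#'   `"CA"`), `resid` (integer residue index), `elem` (element symbol)
#' @return object of class `"ensemble"`
#' @export
ensemble <- function(frames, atoms) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3L]), function(i) frames[, , i])
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("name", "resid", "elem") %in% names(atoms)))
  n <- nrow(atoms)
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3L)
      stop("every frame must be an n_atoms x 3 matrix matching the atom table")
  structure(list(frames = frames, atoms = atoms), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d frames x %d atoms (%d residues)\n",
              length(x$frames), nrow(x$atoms), length(unique(x$atoms$resid))))
  invisible(x)
}

#' Select atoms with a small query language
#'
#' Queries are conjunctions of clauses joined by `and`; each clause is a key
#' (`name`, `resid`, `elem`) followed by one or more accepted values
#' (OR within a clause). Examples: `"resid 2 and name N"`,
#' `"name N H"`, `"elem Cl Br I"`.
#'
#' @param ens an [ensemble()] (or its atom table)
#' @param query selection string
#' @return integer vector of atom indices
#' @export
select_atoms <- function(ens, query) {
  atoms <- if (inherits(ens, "ensemble")) ens$atoms else ens
  keep <- rep(TRUE, nrow(atoms))
  for (clause in strsplit(query, "\\s+and\\s+")[[1L]]) {
    tok <- strsplit(trimws(clause), "\\s+")[[1L]]
    if (length(tok) < 2L) stop("malformed selection clause: '", clause, "'")
    key <- tok[1L]; vals <- tok[-1L]
    keep <- keep & switch(key,
      name  = atoms$name %in% vals,
      resid = atoms$resid %in% as.integer(vals),
      elem  = atoms$elem %in% vals,
      stop("unknown selection key: '", key, "'"))
  }
  which(keep)
}

# amide (N, H) index pairs, matched within each residue
amide_pairs <- function(ens, n_name = "N", h_name = "H") {
  at <- ens$atoms
  resids <- sort(unique(at$resid[at$name == n_name]))
  pairs <- lapply(resids, function(r) {
    ni <- which(at$resid == r & at$name == n_name)
    hi <- which(at$resid == r & at$name == h_name)
    if (length(ni) == 1L && length(hi) == 1L) c(N = ni, H = hi) else NULL
  })
  pairs <- Filter(Negate(is.null), pairs)
  if (!length(pairs)) stop("no amide N-H pairs found")
  do.call(rbind, pairs)
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Build the per-frame coordination matrix
#'
#' For every frame and every (amide N-H, acceptor heavy atom) pair, emits
#' three features: `d(N...X)`, `d(H...X)` (Angstrom) and the `N-H...X` angle
#' (degrees, vertex at H; 180 is a linear hydrogen bond). The acceptor group
#' is the anion's heavy atoms for a complex, or the carbonyl oxygen atoms for
#' the free receptor. Rows of the matrix are the feature vectors fed to
#' [representative_frame()].
#'
#' @param ens an [ensemble()]
#' @param acceptor_sel selection string for acceptor heavy atoms (e.g.
#'   `"elem Cl"` or `"name O"` for the free receptor)
#' @param donor_names `c(N_name, H_name)` of the amide atoms
#' @return object of class `"coordination_matrix"`: numeric matrix
#'   `frames x (3 * n_amides * n_acceptors)` with informative column names;
#'   attributes `amides`, `acceptors`
#' @export
build_coordination_matrix <- function(ens, acceptor_sel,
                                      donor_names = c("N", "H")) {
  pairs <- amide_pairs(ens, donor_names[1L], donor_names[2L])
  acc <- select_atoms(ens, acceptor_sel)
  if (!length(acc)) stop("acceptor selection is empty")
  at <- ens$atoms
  labels <- character(0)
  for (p in seq_len(nrow(pairs)))
    for (x in acc)
      labels <- c(labels,
                  sprintf("dNX_r%d_%s%d", at$resid[pairs[p, "N"]],
                          at$name[x], x),
                  sprintf("dHX_r%d_%s%d", at$resid[pairs[p, "N"]],
                          at$name[x], x),
                  sprintf("aNHX_r%d_%s%d", at$resid[pairs[p, "N"]],
                          at$name[x], x))
  M <- matrix(NA_real_, length(ens$frames), length(labels),
              dimnames = list(NULL, labels))
  for (f in seq_along(ens$frames)) {
    xyz <- ens$frames[[f]]
    col <- 1L
    for (p in seq_len(nrow(pairs))) {
      pn <- xyz[pairs[p, "N"], ]; ph <- xyz[pairs[p, "H"], ]
      for (x in acc) {
        px <- xyz[x, ]
        M[f, col] <- sqrt(sum((pn - px)^2))
        M[f, col + 1L] <- sqrt(sum((ph - px)^2))
        M[f, col + 2L] <- vec_angle(pn - ph, px - ph)
        col <- col + 3L
      }
    }
  }
  structure(M, class = c("coordination_matrix", "matrix", "array"),
            amides = at$resid[pairs[, "N"]], acceptors = acc)
}

#' Intramolecular hydrogen-bond census
#'
#' Counts, per frame, donor-acceptor pairs (amide N-H donors, carbonyl O
#' acceptors by default) satisfying a geometric criterion: heavy-atom
#' distance `d(N...O) <= d_max` and angle `N-H...O >= angle_min`. Pairs
#' within the same residue are excluded. The defaults (3.5 Angstrom, 150
#' degrees) are common MD practice and configurable.
#'
#' @param ens an [ensemble()]
#' @param acceptor_sel selection for acceptor atoms (default carbonyl O)
#' @param d_max donor-acceptor heavy-atom cutoff, Angstrom
#' @param angle_min minimum N-H...O angle, degrees
#' @param donor_names `c(N_name, H_name)`
#' @return object of class `"hbond_census"`: list with `per_frame` counts,
#'   `fractions` (time-fraction distribution over counts, sums to 1) and
#'   `mean` count
#' @export
hbond_census <- function(ens, acceptor_sel = "name O", d_max = 3.5,
                         angle_min = 150, donor_names = c("N", "H")) {
  pairs <- amide_pairs(ens, donor_names[1L], donor_names[2L])
  acc <- select_atoms(ens, acceptor_sel)
  at <- ens$atoms
  counts <- vapply(ens$frames, function(xyz) {
    k <- 0L
    for (p in seq_len(nrow(pairs))) {
      dres <- at$resid[pairs[p, "N"]]
      pn <- xyz[pairs[p, "N"], ]; ph <- xyz[pairs[p, "H"], ]
      for (x in acc) {
        if (at$resid[x] == dres) next
        if (sqrt(sum((pn - xyz[x, ])^2)) > d_max) next
        if (vec_angle(pn - ph, xyz[x, ] - ph) >= angle_min) k <- k + 1L
      }
    }
    k
  }, integer(1))
  tab <- table(factor(counts, levels = 0:max(counts)))
  fractions <- as.numeric(tab) / length(counts)
  names(fractions) <- names(tab)
  structure(list(per_frame = counts, fractions = fractions,
                 mean = mean(counts)),
            class = "hbond_census")
}

#' @export
print.hbond_census <- function(x, ...) {
  cat(sprintf("H-bond census over %d frames: mean %.2f bonds\n",
              length(x$per_frame), x$mean))
  for (k in names(x$fractions))
    if (x$fractions[k] > 0)
      cat(sprintf("  %s bond(s): %.1f%% of frames\n", k,
                  100 * x$fractions[k]))
  invisible(x)
}

#' Per-amide coordination occupancy
#'
#' For each amide, the fraction of frames in which its H atom is within
#' `cutoff` of any acceptor heavy atom (optionally gated on the N-H...X
#' angle). The default 2.8 Angstrom is a typical H...acceptor hydrogen-bond
#' range; per-anion overrides are a single argument away.
#'
#' @param cm a [build_coordination_matrix()] result
#' @param cutoff `d(H...X)` cutoff, Angstrom
#' @param angle_min optional minimum N-H...X angle gate, degrees
#' @return named numeric vector: bound fraction per amide residue
#' @export
coordination_occupancy <- function(cm, cutoff = 2.8, angle_min = NULL) {
  amides <- attr(cm, "amides")
  labs <- colnames(cm)
  out <- vapply(unique(amides), function(r) {
    dh <- cm[, grep(sprintf("^dHX_r%d_", r), labs), drop = FALSE]
    ok <- dh <= cutoff
    if (!is.null(angle_min)) {
      ang <- cm[, grep(sprintf("^aNHX_r%d_", r), labs), drop = FALSE]
      ok <- ok & ang >= angle_min
    }
    mean(apply(ok, 1L, any))
  }, numeric(1))
  names(out) <- paste0("amide_", unique(amides))
  out
}

#' Per-frame nearest coordinating acceptor atom
#'
#' Attributes each frame's coordination to the acceptor heavy atom closest to
#' any amide H, reported as a per-atom fraction of frames. Used to verify
#' statements such as an ambidentate anion binding through one specific atom
#' (e.g. thiocyanate through nitrogen) as an output statistic.
#'
#' @param cm a [build_coordination_matrix()] result
#' @param ens the [ensemble()] the matrix came from (for atom labels)
#' @return named numeric vector: fraction of frames per acceptor atom
#' @export
nearest_acceptor_fractions <- function(cm, ens) {
  acc <- attr(cm, "acceptors")
  labs <- colnames(cm)
  dh <- cm[, grep("^dHX_", labs), drop = FALSE]
  # columns cycle over acceptors within amides; fold to per-acceptor minima
  per_acc <- sapply(seq_along(acc), function(k) {
    cols <- grep(sprintf("_%s%d$", ens$atoms$name[acc[k]], acc[k]),
                 colnames(dh))
    apply(dh[, cols, drop = FALSE], 1L, min)
  })
  per_acc <- matrix(per_acc, nrow = nrow(cm))
  idx <- apply(per_acc, 1L, which.min)
  f <- tabulate(idx, nbins = length(acc)) / nrow(cm)
  names(f) <- paste0(ens$atoms$name[acc], acc)
  f
}

#' Representative frame by PCA and clustering of the coordination matrix
#'
#' Standardizes the coordination-matrix columns (so distances and angles are
#' commensurate), projects onto the leading principal components, clusters
#' the frames there by k-means (k chosen by average silhouette width over
#' 2..`k_max`, with a single-cluster fallback when even the best silhouette
#' is weak), and returns the frame closest to the centroid of the most
#' populous cluster.
#'
#' @param cm a [build_coordination_matrix()] result (or any frames x
#'   features numeric matrix)
#' @param n_components number of leading principal components (default 3;
#'   capped at the available rank)
#' @param k_max largest k considered (default 8)
#' @param seed RNG seed for k-means starts
#' @param silhouette_min below this best average silhouette width a single
#'   cluster is assumed (default 0.5, the usual "weak structure" boundary;
#'   a forced split of one homogeneous cluster scores below it)
#' @return list of class `"representative_frame"`: `frame` (index),
#'   `cluster_sizes`, `assignments`, `k`, `scores` (frames x PCs),
#'   `distance` (of the chosen frame to its centroid)
#' @export
representative_frame <- function(cm, n_components = 3L, k_max = 8L,
                                 seed = 1L, silhouette_min = 0.5) {
  M <- unclass(cm)
  if (nrow(M) < 2L) stop("need at least 2 frames")
  sds <- apply(M, 2L, stats::sd)
  if (all(sds < 1e-12)) {
    # all frames identical in feature space: any frame, distance 0
    return(structure(list(frame = 1L, cluster_sizes = nrow(M),
                          assignments = rep(1L, nrow(M)), k = 1L,
                          scores = matrix(0, nrow(M), 1L), distance = 0),
                     class = "representative_frame"))
  }
  M <- M[, sds > 1e-12, drop = FALSE]
  pc <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  ncomp <- min(n_components, ncol(pc$x))
  X <- pc$x[, seq_len(ncomp), drop = FALSE]

  set.seed(seed)
  k_max <- min(k_max, nrow(X) - 1L)
  best_k <- 1L; best_sil <- -Inf; best_fit <- NULL
  for (k in 2:max(2L, k_max)) {
    if (k > nrow(X) - 1L) break
    km <- stats::kmeans(X, centers = k, nstart = 10L, iter.max = 100L)
    sil <- mean(cluster::silhouette(km$cluster, stats::dist(X))[, 3L])
    if (sil > best_sil) { best_sil <- sil; best_k <- k; best_fit <- km }
  }
  if (!is.finite(best_sil) || best_sil < silhouette_min) {
    assignments <- rep(1L, nrow(X))
    centers <- matrix(colMeans(X), 1L)
    best_k <- 1L
  } else {
    assignments <- best_fit$cluster
    centers <- best_fit$centers
  }
  sizes <- tabulate(assignments, nbins = best_k)
  top <- which.max(sizes)
  members <- which(assignments == top)
  d <- sqrt(rowSums((X[members, , drop = FALSE] -
                       matrix(centers[top, ], length(members), ncol(X),
                              byrow = TRUE))^2))
  structure(list(frame = members[which.min(d)], cluster_sizes = sizes,
                 assignments = assignments, k = best_k, scores = X,
                 distance = min(d)),
            class = "representative_frame")
}

#' @export
print.representative_frame <- function(x, ...) {
  cat(sprintf(
    "Representative frame %d (k = %d clusters, sizes: %s; d = %.3g)\n",
    x$frame, x$k, paste(x$cluster_sizes, collapse = "/"), x$distance))
  invisible(x)
}

#' Ring-centroid to backbone-center distances
#'
#' For each frame, the Euclidean distance between the mass-weighted center of
#' mass of each aromatic ring and the unweighted geometric center of the
#' C-alpha atoms -- a measure of how closely the sidechain rings approach the
#' anion-binding site.
#'
#' @param ens an [ensemble()]
#' @param ring_sel selection matching all ring atoms, grouped by residue
#'   (default `"name CG1 CG2 CG3 CG4 CG5 CG6"`)
#' @param ca_sel selection for the C-alpha atoms (default `"name CA"`)
#' @return numeric matrix frames x rings (Angstrom), columns named by
#'   ring residue
#' @export
ring_centroid_distances <- function(ens, ring_sel =
                                      "name CG1 CG2 CG3 CG4 CG5 CG6",
                                    ca_sel = "name CA") {
  ring_atoms <- select_atoms(ens, ring_sel)
  ca <- select_atoms(ens, ca_sel)
  if (!length(ring_atoms) || !length(ca))
    stop("ring or C-alpha selection is empty")
  at <- ens$atoms
  rings <- split(ring_atoms, at$resid[ring_atoms])
  out <- matrix(NA_real_, length(ens$frames), length(rings),
                dimnames = list(NULL, paste0("ring_", names(rings))))
  for (f in seq_along(ens$frames)) {
    xyz <- ens$frames[[f]]
    cac <- colMeans(xyz[ca, , drop = FALSE])
    for (r in seq_along(rings)) {
      idx <- rings[[r]]
      w <- ATOMIC_MASS[at$elem[idx]]
      if (anyNA(w)) stop("unknown element in ring selection")
      com <- colSums(xyz[idx, , drop = FALSE] * w) / sum(w)
      out[f, r] <- sqrt(sum((com - cac)^2))
    }
  }
  out
}

#' Strided subsample-and-average of per-frame spectra
#'
#' Takes every `stride`-th row of a frames x wavelengths spectrum matrix
#' (optionally at most `count` frames) and returns the arithmetic mean
#' spectrum -- the standard way a trajectory-averaged spectrum is formed from
#' per-frame spectra supplied by an external calculator.
#'
#' @param frame_spectra numeric matrix, frames x wavelength channels; all
#'   rows must share the wavelength axis (columns)
#' @param stride keep every `stride`-th frame (default 50)
#' @param count optional cap on the number of frames kept
#' @return numeric vector: the averaged spectrum, named by the column names
#' @export
subsample_and_average <- function(frame_spectra, stride = 50L,
                                  count = NULL) {
  frame_spectra <- as.matrix(frame_spectra)
  stopifnot(stride >= 1L)
  if (stride > nrow(frame_spectra))
    stop("stride exceeds the number of frames")
  idx <- seq(from = stride, to = nrow(frame_spectra), by = stride)
  if (!is.null(count)) idx <- idx[seq_len(min(count, length(idx)))]
  colMeans(frame_spectra[idx, , drop = FALSE])
}

#' Apply a rigid transform to every frame
#'
#' Utility (used heavily in invariance testing): rotates and translates all
#' frames by a common rigid-body transform.
#'
#' @param ens an [ensemble()]
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 numeric vector
#' @return the transformed [ensemble()]
#' @export
transform_ensemble <- function(ens, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  ens$frames <- lapply(ens$frames, function(xyz)
    xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3L, byrow = TRUE))
  ens
}
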