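# Independent oracles used across the suite. These deliberately take
# different routes than the package: closed forms, 1-d bisection with the
# receptor eliminated analytically, dense normal equations, and plain loops.

# Dimer-only free anion: root of 2*beta*[A]^2 + [A] - c = 0
oracle_dimer_free_A <- function(total_A, beta02) {
  (-1 + sqrt(1 + 8 * beta02 * total_A)) / (4 * beta02)
}

# Three-species model (LA, A2, LA2): eliminate [L] analytically from the
# receptor balance, then bisect the anion balance on [A].
oracle_three_species <- function(total_L, total_A, b11, b02, b12,
                                 n_iter = 200L) {
  fA <- function(A) {
    L <- total_L / (1 + b11 * A + b12 * A^2)
    A + 2 * b02 * A^2 + L * (b11 * A + 2 * b12 * A^2) - total_A
  }
  lo <- total_A * 1e-18; hi <- total_A
  for (i in seq_len(n_iter)) {
    mid <- sqrt(lo * hi)
    if (fA(mid) > 0) hi <- mid else lo <- mid
  }
  A <- sqrt(lo * hi)
  L <- total_L / (1 + b11 * A + b12 * A^2)
  c(L = L, A = A, LA = b11 * L * A, A2 = b02 * A^2, LA2 = b12 * L * A^2)
}

# Dense normal-equations least squares for Y ~ S t(C)
oracle_molar_response <- function(Y, C) {
  t(solve(t(C) %*% C, t(C) %*% t(Y)))
}

# Plain triple-loop hydrogen-bond count for one frame
oracle_hbond_count <- function(xyz, atoms, d_max = 3.5, angle_min = 150) {
  count <- 0L
  for (r in unique(atoms$resid)) {
    ni <- which(atoms$resid == r & atoms$name == "N")
    hi <- which(atoms$resid == r & atoms$name == "H")
    if (length(ni) != 1L || length(hi) != 1L) next
    for (x in which(atoms$name == "O")) {
      if (atoms$resid[x] == r) next
      dNO <- sqrt(sum((xyz[ni, ] - xyz[x, ])^2))
      u <- xyz[ni, ] - xyz[hi, ]; v <- xyz[x, ] - xyz[hi, ]
      ang <- acos(max(-1, min(1, sum(u * v) /
                                 sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (dNO <= d_max && ang >= angle_min) count <- count + 1L
    }
  }
  count
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qrd <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qrd)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

model_1to1 <- function(log_K = 4, fixed = FALSE)
  equilibrium_model(data.frame(l = 1, a = 1, log_beta = log_K,
                               fixed = fixed))
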