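# Shared fixtures and independent oracles used across the suite.

coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

# wild-type saturating-capsaicin gating parameters used throughout:
# Po_max 0.94 and EC50 0.14 uM give L = 0.94/0.06 and K_D = EC50*(1+L)
wt_L <- 0.94 / 0.06
wt_KD <- 0.14 * (1 + wt_L)
wt_model <- function() channel_model(K_D = wt_KD, L = wt_L, g = 100, E_rev = 0)

# standard bi-ionic conditions: 140 mM NaCl outside, 70 mM CaCl2 inside
biionic_ca <- function(T = 295.15)
  ion_conditions(data.frame(name = c("Na", "Ca"), valence = c(1, 2),
                            conc_in = c(0, 70), conc_out = c(140, 0)),
                 temperature_K = T)

# hand-built alternating dwell sequence
dwells_of <- function(durations, first = "closed") {
  lv <- rep_len(if (first == "closed") c("closed", "open")
                else c("open", "closed"), length(durations))
  d <- data.frame(level = lv, duration_ms = durations,
                  stringsAsFactors = FALSE)
  attr(d, "total_duration_ms") <- sum(durations)
  class(d) <- c("dwell_sequence", "data.frame")
  d
}

# Independent rigid-superposition oracle: Horn's closed-form quaternion
# method. Returns the rotation matrix and translation mapping P onto Q.
quaternion_superpose <- function(P, Q) {
  Pc <- colMeans(P); Qc <- colMeans(Q)
  P0 <- sweep(P, 2, Pc); Q0 <- sweep(Q, 2, Qc)
  M <- crossprod(P0, Q0)  # sum p_i q_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  translation <- Qc - as.numeric(R %*% Pc)
  rmsd <- sqrt(mean(rowSums((sweep(P %*% t(R), 2, translation, "+") - Q)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

# Brute-force pore-radius oracle: largest sphere centred anywhere on a
# 0.05 A xy-grid around the axis (or exactly on the axis when
# fixed_centre) that touches no atom.
brute_force_pore_radius <- function(xyz, radii, z, xy_extent = 2,
                                    grid = 0.05, fixed_centre = FALSE) {
  if (fixed_centre) {
    d <- sqrt(xyz[, 1]^2 + xyz[, 2]^2 + (xyz[, 3] - z)^2)
    return(min(d - radii))
  }
  g <- seq(-xy_extent, xy_extent, by = grid)
  best <- -Inf
  for (cx in g) for (cy in g) {
    d <- sqrt((xyz[, 1] - cx)^2 + (xyz[, 2] - cy)^2 + (xyz[, 3] - z)^2)
    r <- min(d - radii)
    if (r > best) best <- r
  }
  best
}
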