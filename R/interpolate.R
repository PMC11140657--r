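#' Built-in 10-20 montage positions
#'
#' Approximate unit-sphere coordinates (x = right, y = anterior, z = up) for
#' the standard 10-20 electrode set plus mastoids, sufficient for
#' spherical-spline interpolation.
#'
#' @return tibble with columns label, x, y, z.
#' @export
default_montage <- function() {
  m <- matrix(c(
    0, 0, 1,          # Cz
    0, 0.7071, 0.7071,  # Fz
    0, -0.7071, 0.7071, # Pz
    -0.7071, 0, 0.7071, # C3
    0.7071, 0, 0.7071,  # C4
    -0.545, 0.673, 0.5, # F3
    0.545, 0.673, 0.5,  # F4
    -0.545, -0.673, 0.5, # P3
    0.545, -0.673, 0.5,  # P4
    -0.309, 0.951, 0,    # Fp1
    0.309, 0.951, 0,     # Fp2
    -0.309, -0.951, 0,   # O1
    0.309, -0.951, 0,    # O2
    -0.809, 0.588, 0,    # F7
    0.809, 0.588, 0,     # F8
    -1, 0, 0,            # T7
    1, 0, 0,             # T8
    -0.809, -0.588, 0,   # P7
    0.809, -0.588, 0,    # P8
    -0.92, -0.25, -0.3,  # M1
    0.92, -0.25, -0.3    # M2
  ), ncol = 3, byrow = TRUE)
  m <- m / sqrt(rowSums(m^2))
  tibble::tibble(label = c("Cz", "Fz", "Pz", "C3", "C4", "F3", "F4", "P3", "P4",
                           "Fp1", "Fp2", "O1", "O2", "F7", "F8", "T7", "T8",
                           "P7", "P8", "M1", "M2"),
                 x = m[, 1], y = m[, 2], z = m[, 3])
}

montage_positions <- function(labels, montage = default_montage()) {
  i <- match(labels, montage$label)
  tibble::tibble(label = labels,
                 x = montage$x[i], y = montage$y[i], z = montage$z[i])
}

# Legendre polynomials P_1..P_n evaluated at x (vector); rows = order.
legendre_upto <- function(n, x) {
  P <- matrix(0, n, length(x))
  P[1, ] <- x
  if (n >= 2) P[2, ] <- (3 * x^2 - 1) / 2
  if (n >= 3) for (k in 3:n) {
    P[k, ] <- ((2 * k - 1) * x * P[k - 1, ] - (k - 1) * P[k - 2, ]) / k
  }
  P
}

# Perrin-style g function: sum over n of (2n+1)/(n(n+1))^m * P_n(cos angle).
spline_g <- function(cosang, m = 4, n_terms = 50) {
  P <- legendre_upto(n_terms, pmin(pmax(cosang, -1), 1))
  n <- seq_len(n_terms)
  w <- (2 * n + 1) / (n * (n + 1))^m
  as.numeric(crossprod(w, P)) / (4 * pi)
}

#' Spherical-spline interpolation of scalp potentials
#'
#' Perrin-style spherical splines (order m = 4, 50 Legendre terms,
#' regularization 1e-5): fits spline weights on the good electrodes and
#' evaluates the potential at the target positions, per time sample.
#'
#' @param good_pos matrix (n_good x 3) of unit-sphere positions.
#' @param bad_pos matrix (n_bad x 3) of target positions.
#' @param good_data matrix (n_good x samples) of potentials.
#' @param m spline order.
#' @param n_terms Legendre series length.
#' @param reg ridge regularization added to the diagonal.
#' @return matrix (n_bad x samples) of interpolated potentials.
#' @export
spherical_spline_interp <- function(good_pos, bad_pos, good_data,
                                    m = 4, n_terms = 50, reg = 1e-5) {
  ng <- nrow(good_pos)
  if (ng < 4) abort("need at least 4 good channels with positions")
  G <- matrix(spline_g(tcrossprod(good_pos), m, n_terms), ng, ng)
  Gb <- matrix(spline_g(tcrossprod(bad_pos, good_pos), m, n_terms),
               nrow(bad_pos), ng)
  A <- rbind(cbind(G + diag(reg, ng), rep(1, ng)), c(rep(1, ng), 0))
  rhs <- rbind(good_data, 0)
  sol <- solve(A, rhs)
  C <- sol[seq_len(ng), , drop = FALSE]
  d <- sol[ng + 1, ]
  sweep(Gb %*% C, 2, d, `+`)
}

#' Interpolate bad channels of a recording
#'
#' Replaces each bad channel by its spherical-spline estimate from the
#' remaining good channels with known montage positions.
#'
#' @param rec an [eeg_recording()].
#' @param bad_labels channels to replace.
#' @param montage positions tibble (label, x, y, z).
#' @return recording with bad channels replaced.
#' @export
interpolate_channels <- function(rec, bad_labels, montage = default_montage()) {
  missing <- setdiff(bad_labels, rec$channels)
  if (length(missing)) abort(sprintf("unknown channel(s): %s", paste(missing, collapse = ", ")))
  pos <- montage_positions(rec$channels, montage)
  bad_i <- match(bad_labels, rec$channels)
  if (any(is.na(pos$x[bad_i]))) abort("bad channel has no montage position")
  good_i <- setdiff(which(!is.na(pos$x)), bad_i)
  if (length(good_i) < 4) abort("need at least 4 good channels with positions")
  data <- rec$data
  data[bad_i, ] <- spherical_spline_interp(
    as.matrix(pos[good_i, c("x", "y", "z")]),
    as.matrix(pos[bad_i, c("x", "y", "z"), drop = FALSE]),
    data[good_i, , drop = FALSE])
  eeg_recording(data, rec$fs, rec$channels, rec$reference, rec$annotations)
}
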