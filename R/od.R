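# Ocular dominance subsystem: bias-shift mapping, amplitude equations for the
# shifted dynamics, stationary branches (stripes / hexagons / constant),
# stability borders and contralateral fractions.
#
# The OD field obeys  do/dt = (r_od - (kc^2 + Lap)^2) o - o^3 + gamma.
# Shifting o = ohat + delta with delta the real root of
#   delta^3 + (kc^4 - r_od) delta = gamma
# removes the constant drive and turns it into a quadratic interaction term:
#   dohat/dt = (r_t - (kc^2 + Lap)^2) ohat + g_t ohat^2 - ohat^3
# with r_t = r_od - 3 delta^2 and g_t = -3 delta.  Near threshold the three
# active modes form a triad resonance q1 + q2 + q3 = 0 and the mode amplitudes
# B_j obey
#   dB_j/dt = r_t B_j + 2 g_t conj(B_l B_m) - 3 (|B_j|^2 + 2|B_l|^2 + 2|B_m|^2) B_j.

#' Eliminate the constant OD drive by a constant field shift
#'
#' Returns the shift \code{delta} for which the constant term of the shifted
#' dynamics vanishes, together with the transformed linear (\code{r_tilde})
#' and quadratic (\code{gamma_tilde}) coefficients.
#'
#' @param gamma OD bias (positive favours the contralateral eye).
#' @param r_od bifurcation parameter of the OD equation.
#' @param kc critical wavenumber (default \code{2*pi}, i.e. wavelength 1).
#' @return list with \code{delta}, \code{r_tilde}, \code{gamma_tilde}.
#' @export
shift_delta <- function(gamma, r_od, kc = 2 * pi) {
  p <- kc^4 - r_od
  if (p <= 0) {
    stop("no admissible real root: requires kc^4 > r_od")
  }
  # unique real root of delta^3 + p delta - gamma = 0 (monotone cubic)
  disc <- sqrt(gamma^2 / 4 + p^3 / 27)
  delta <- cbrt(gamma / 2 + disc) + cbrt(gamma / 2 - disc)
  list(delta = delta,
       r_tilde = r_od - 3 * delta^2,
       gamma_tilde = -3 * delta)
}

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Small-bias approximation of the OD shift
#'
#' Leading orders of the exact root: \code{gamma/p - gamma^3/p^4} with
#' \code{p = kc^4 - r_od}; accurate to O(gamma^5).
#' @inheritParams shift_delta
#' @export
shift_delta_approx <- function(gamma, r_od, kc = 2 * pi) {
  p <- kc^4 - r_od
  gamma / p - gamma^3 / p^4
}

#' Amplitude equations of the shifted OD dynamics
#'
#' Right-hand side for the three complex triad amplitudes, evaluated by exact
#' projection of \code{r_t ohat + g_t ohat^2 - ohat^3} onto the active modes.
#'
#' @param B complex vector of length 3.
#' @param gamma,r_od,kc model parameters.
#' @return complex vector dB/dt of length 3.
#' @export
od_amplitude_rhs <- function(B, gamma, r_od, kc = 2 * pi) {
  sh <- shift_delta(gamma, r_od, kc)
  o <- od_series(B, delta = 0)          # shifted field: no constant part
  o2 <- mode_mult(o, o)
  nl <- mode_add(mode_scale(o2, sh$gamma_tilde),
                 mode_scale(mode_mult(o2, o), -1))
  Q <- od_star()
  vapply(1:3, function(j) sh$r_tilde * B[j] + mode_coef(nl, Q[j, ]),
         complex(1))
}

#' Stationary OD branches
#'
#' Closed-form stationary amplitudes of the OD amplitude equations:
#' stripes \code{B_st = sqrt(r_t/3)}, hexagons
#' \code{B_hex = (|g_t| + sqrt(g_t^2 + 15 r_t))/15} with phase sum 0 or pi
#' (whichever is the potential minimum for the sign of \code{g_t}), and the
#' constant (monocular) branch \code{ohat = 0}, i.e. \code{o = delta}.
#'
#' @param label one of \code{"stripes"}, \code{"hexagons"}, \code{"constant"}.
#' @inheritParams od_amplitude_rhs
#' @return list with complex amplitudes \code{B}, \code{delta}, scalar
#'   amplitude \code{B_amp}, phase sum \code{phase_sum}, and \code{eta}.
#' @export
od_stationary <- function(label = c("stripes", "hexagons", "constant"),
                          gamma, r_od, kc = 2 * pi) {
  label <- match.arg(label)
  sh <- shift_delta(gamma, r_od, kc)
  rt <- sh$r_tilde; gt <- sh$gamma_tilde
  B <- switch(label,
    stripes = {
      if (rt <= 0) stop("OD stripes do not exist: r_tilde <= 0 (bias beyond the constant-onset border)")
      c(complex(real = sqrt(rt / 3)), 0i, 0i)
    },
    hexagons = {
      rad <- gt^2 + 15 * rt
      if (rad < 0) stop("OD hexagons do not exist: below the saddle-node (hexagon-loss border)")
      amp <- (abs(gt) + sqrt(rad)) / 15
      # stable phase sum: 0 for gamma_tilde > 0, pi otherwise; realized as
      # B_j = -amp (phases pi,pi,pi) so that for contralateral bias the field
      # minimum (ipsi-center) sits at the origin
      if (gt >= 0) rep(complex(real = amp), 3) else rep(complex(real = -amp), 3)
    },
    constant = c(0i, 0i, 0i))
  list(label = label, B = B, delta = sh$delta,
       B_amp = if (label == "hexagons") Mod(B[1]) else Re(B[1]),
       phase_sum = if (label == "hexagons") Arg(B[1] * B[2] * B[3]) else 0,
       eta = od_eta(gamma, r_od, kc),
       r_tilde = rt, gamma_tilde = gt)
}

#' Rescaled OD bias
#'
#' The dimensionless bias used on phase-diagram axes:
#' \code{eta = |gamma_tilde| / sqrt(r_od) = 3|delta|/sqrt(r_od)}.  All OD
#' stability borders are constants in this variable.
#' @inheritParams od_amplitude_rhs
#' @export
od_eta <- function(gamma, r_od, kc = 2 * pi) {
  3 * abs(shift_delta(gamma, r_od, kc)$delta) / sqrt(r_od)
}

#' Invert the rescaled bias to the raw bias
#' @param eta rescaled bias (non-negative).
#' @inheritParams od_amplitude_rhs
#' @export
od_gamma_from_eta <- function(eta, r_od, kc = 2 * pi) {
  delta <- eta * sqrt(r_od) / 3
  delta^3 + (kc^4 - r_od) * delta
}

#' Stability borders of the OD branches
#'
#' Closed-form borders of the three OD branches, obtained from the linear
#' stability of the amplitude equations:
#' \itemize{
#' \item stripe loss:      eta = sqrt(3/5)
#' \item hexagon onset:    eta = sqrt(3/17)
#' \item hexagon loss:     eta = sqrt(15)/2
#' \item constant onset:   eta = sqrt(3)
#' }
#' where \code{eta = 3 delta / sqrt(r_od)}.  Equivalently, in terms of the
#' shift: stripes are stable for \code{delta^2 < r_od/15}, hexagons for
#' \code{r_od/51 < delta^2 < 5 r_od/12}, the constant branch for
#' \code{delta^2 > r_od/3}.
#'
#' @param r_od bifurcation parameter (> 0).
#' @param kc critical wavenumber.
#' @return data.frame with border label, \code{eta}, \code{delta}, \code{gamma}.
#' @export
od_stability_borders <- function(r_od, kc = 2 * pi) {
  stopifnot(r_od > 0)
  eta <- c(stripe_loss = sqrt(3 / 5),
           hexagon_onset = sqrt(3 / 17),
           hexagon_loss = sqrt(15) / 2,
           constant_onset = sqrt(3))
  delta <- eta * sqrt(r_od) / 3
  data.frame(border = names(eta), eta = unname(eta), delta = unname(delta),
             gamma = unname(delta^3 + (kc^4 - r_od) * delta),
             row.names = NULL)
}

# real-coordinate Jacobian of the OD amplitude equations, with the two
# translation zero modes projected out
od_jacobian_reduced <- function(B, gamma, r_od, kc = 2 * pi, h = 1e-6) {
  f <- function(x) {
    Bx <- complex(real = x[1:3], imaginary = x[4:6])
    d <- od_amplitude_rhs(Bx, gamma, r_od, kc)
    c(Re(d), Im(d))
  }
  x0 <- c(Re(B), Im(B))
  J <- num_jacobian(f, x0, h)
  Q <- mode_k(od_star(), kc)
  gen <- lapply(1:2, function(ax) {
    v <- 1i * Q[, ax] * B            # d/deps of B_j exp(i q_j . eps e_ax)
    c(Re(v), Im(v))
  })
  project_out(J, gen)
}

num_jacobian <- function(f, x0, h = 1e-6) {
  n <- length(x0)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- h
    J[, i] <- (f(x0 + e) - f(x0 - e)) / (2 * h)
  }
  J
}

# restrict a matrix to the orthogonal complement of the span of `gens`
project_out <- function(J, gens) {
  if (length(gens) == 0) return(list(J = J, removed = 0))
  G <- do.call(cbind, gens)
  keep <- sqrt(colSums(G^2)) > 1e-12
  G <- G[, keep, drop = FALSE]
  if (ncol(G) == 0) return(list(J = J, removed = 0))
  Q <- qr.Q(qr(G))
  n <- nrow(J)
  full <- qr.Q(qr(cbind(Q, diag(n))))
  Comp <- full[, (ncol(Q) + 1):n, drop = FALSE]
  list(J = t(Comp) %*% J %*% Comp, removed = ncol(Q))
}

#' Leading non-symmetry eigenvalue of an OD branch
#'
#' Largest real part of the Jacobian spectrum of the OD amplitude equations at
#' the stationary branch, with translation zero modes removed.  Negative means
#' linearly stable.
#' @inheritParams od_stationary
#' @export
od_leading_eigenvalue <- function(label, gamma, r_od, kc = 2 * pi) {
  st <- od_stationary(label, gamma, r_od, kc)
  red <- od_jacobian_reduced(st$B, gamma, r_od, kc)
  max(Re(eigen(red$J, only.values = TRUE)$values))
}

#' Closed-form contralateral fraction of an OD branch
#'
#' Areal fraction of contralateral (o > 0) territory.  Stripes:
#' \code{1/2 + asin(delta/(2 B_st))/pi}.  Hexagons: the ipsilateral island
#' around the field minimum is approximated as a disc whose radius is the
#' first zero of the field along a symmetry axis through the minimum; the
#' fraction is one minus the disc area over the unit-cell area.  Both are
#' independent of \code{r_od} and \code{kc}.  Negative bias mirrors the
#' result (\code{f(-gamma) = 1 - f(gamma)}).
#'
#' @inheritParams od_stationary
#' @return fraction in [0, 1].
#' @export
contra_fraction <- function(label = c("stripes", "hexagons", "constant"),
                            gamma, r_od, kc = 2 * pi) {
  label <- match.arg(label)
  if (gamma < 0) return(1 - contra_fraction(label, -gamma, r_od, kc))
  st <- od_stationary(label, gamma, r_od, kc)
  delta <- st$delta
  switch(label,
    stripes = {
      t <- delta / (2 * st$B_amp)
      if (t >= 1) 1 else 1 / 2 + asin(t) / pi
    },
    hexagons = {
      Bh <- st$B_amp
      if (delta >= 6 * Bh) return(1)   # minimum no longer negative
      w <- (-1 + sqrt(3 + delta / Bh)) / 2
      x0 <- 2 * acos(w) / kc           # island radius
      1 - sqrt(3) * kc^2 * x0^2 / (8 * pi)
    },
    constant = if (delta > 0) 1 else if (delta < 0) 0 else 0.5)
}

#' Pixel-count contralateral fraction
#'
#' Brute-force oracle: fraction of strictly positive pixels of an OD map.
#' @param od an \code{od_map} (or any numeric matrix).
#' @export
pixel_contra_fraction <- function(od) {
  o <- if (is.list(od)) od$o else od
  mean(o > 0)
}
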