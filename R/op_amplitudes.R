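# Coupled OP amplitude equations in the unidirectional (no backreaction)
# limit: the OD planform is fixed at its uncoupled stationary branch and the
# six OP mode amplitudes A_1..A_3, A_1^-..A_3^- evolve under
#   dA/dt = r_op A - P[ |z|^2 z ] + coupling term,
# where P projects onto the active modes.  All nonlinear projections are
# evaluated exactly with the finite-mode algebra, so the equations contain
# every resonant contribution for the hexagonal mode configuration, including
# the delta-dependent terms of the product-type energy.

#' Model parameters for the coupled system
#'
#' @param r_op,r_od bifurcation parameters of the OP and OD equations.
#' @param gamma OD bias.
#' @param kind coupling energy: \code{"product_low"} (density c o^2 |z|^2),
#'   \code{"gradient_low"} (density c |grad o . grad z|^2), or the
#'   field-level-only higher-order variants \code{"product_high"}
#'   (c o^4 |z|^4) and \code{"gradient_high"} (c |grad o . grad z|^4).
#' @param c_coupling coupling constant (>= 0).
#' @param kc critical wavenumber; the typical wavelength is 2*pi/kc.
#' @return object of class \code{map_params}.
#' @export
model_params <- function(r_op = 0.1, r_od = 0.2, gamma = 0,
                         kind = c("product_low", "gradient_low",
                                  "product_high", "gradient_high"),
                         c_coupling = 0, kc = 2 * pi) {
  kind <- match.arg(kind)
  if (c_coupling < 0) stop("coupling constants are assumed non-negative")
  sh <- shift_delta(gamma, r_od, kc)
  structure(list(r_op = r_op, r_od = r_od, gamma = gamma, kind = kind,
                 c_coupling = c_coupling, kc = kc,
                 delta = sh$delta, r_tilde = sh$r_tilde,
                 gamma_tilde = sh$gamma_tilde),
            class = "map_params")
}

#' @export
print.map_params <- function(x, ...) {
  cat("coupled map model parameters\n")
  cat(sprintf("  r_op = %g, r_od = %g, gamma = %g (delta = %.6g, eta = %.4g)\n",
              x$r_op, x$r_od, x$gamma, x$delta, od_eta(x$gamma, x$r_od, x$kc)))
  cat(sprintf("  coupling: %s, c = %g, kc = %g\n", x$kind, x$c_coupling, x$kc))
  invisible(x)
}

# gradient-type resonant coupling term for one target mode:
# + c * sum_{q,k,q'} (q.k) (q'.K) B_q A_k B_q' delta(K - target), K = k+q+q'
grad_coupling_project <- function(target_m, zf, of, kc) {
  nz <- nrow(zf$m); no <- nrow(of$m)
  acc <- 0 + 0i
  ko <- mode_k(of$m, kc); kz <- mode_k(zf$m, kc)
  for (iq in seq_len(no)) {
    if (of$m[iq, 1] == 0 && of$m[iq, 2] == 0) next
    for (ik in seq_len(nz)) {
      qk <- sum(ko[iq, ] * kz[ik, ])
      if (qk == 0) next
      for (iq2 in seq_len(no)) {
        if (of$m[iq2, 1] == 0 && of$m[iq2, 2] == 0) next
        Km <- zf$m[ik, ] + of$m[iq, ] + of$m[iq2, ]
        if (Km[1] != target_m[1] || Km[2] != target_m[2]) next
        K <- c(Km[1] * kc / 2, Km[2] * kc * sqrt(3) / 2)
        acc <- acc + qk * sum(ko[iq2, ] * K) *
          of$coef[iq] * zf$coef[ik] * of$coef[iq2]
      }
    }
  }
  acc
}

#' Coupled OP amplitude equations
#'
#' Time derivatives of the six OP amplitudes for a fixed OD planform.
#'
#' @param A,Aopp complex vectors of length 3: amplitudes of the modes
#'   \code{+k_j} and \code{-k_j}.
#' @param params \code{model_params}.
#' @param od optional OD state as returned by \code{od_stationary}; defaults
#'   to the stable branch selected by \code{od_branch}.
#' @param od_branch OD branch label used when \code{od} is missing.
#' @return list with complex vectors \code{dA}, \code{dAopp}.
#' @export
op_amplitude_rhs <- function(A, Aopp, params,
                             od = NULL, od_branch = "hexagons") {
  if (params$kind %in% c("product_high", "gradient_high")) {
    stop("amplitude equations are implemented for the low-order energies only")
  }
  if (is.null(od)) od <- od_stationary(od_branch, params$gamma, params$r_od, params$kc)
  zf <- op_series(A, Aopp)
  of <- od_series(od$B, delta = params$delta)
  cub <- mode_mult(mode_mult(zf, zf), mode_conj(zf))
  K <- op_star()
  cc <- params$c_coupling
  d <- vapply(seq_len(6), function(i) {
    m <- if (i <= 3) K[i, ] else -K[i - 3, ]
    a <- if (i <= 3) A[i] else Aopp[i - 3]
    cpl <- if (cc == 0) 0 + 0i else if (params$kind == "product_low") {
      -cc * mode_coef(mode_mult(mode_mult(of, of), zf), m)
    } else {
      cc * grad_coupling_project(m, zf, of, params$kc)
    }
    params$r_op * a - mode_coef(cub, m) + cpl
  }, complex(1))
  list(dA = d[1:3], dAopp = d[4:6])
}

#' Amplitude-equation potential
#'
#' The amplitude equations are a gradient system, \code{dA/dt = -dV/dconj(A)}.
#' V is the energy density of the planform restricted to the active modes:
#' uncoupled OP part \code{-r_op S + <|z|^4>/2} plus the coupling density
#' average; the constant OD contribution is excluded.
#'
#' @inheritParams op_amplitude_rhs
#' @return real scalar V.
#' @export
op_potential <- function(A, Aopp, params, od = NULL, od_branch = "hexagons") {
  if (is.null(od)) od <- od_stationary(od_branch, params$gamma, params$r_od, params$kc)
  zf <- op_series(A, Aopp)
  zero <- c(0L, 0L)
  zz <- mode_mult(zf, mode_conj(zf))
  V <- -params$r_op * (sum(Mod(A)^2) + sum(Mod(Aopp)^2)) +
    0.5 * Re(mode_coef(mode_mult(zz, zz), zero))
  cc <- params$c_coupling
  if (cc > 0) {
    of <- od_series(od$B, delta = params$delta)
    V <- V + cc * switch(params$kind,
      product_low = Re(mode_coef(mode_mult(mode_mult(of, of), zz), zero)),
      gradient_low = {
        s <- grad_dot_series(of, zf, params$kc)
        Re(mode_coef(mode_mult(s, mode_conj(s)), zero))
      },
      stop("potential implemented for the low-order energies only"))
  }
  V
}

# mode series of s = grad o . grad z
grad_dot_series <- function(of, zf, kc) {
  ko <- mode_k(of$m, kc); kz <- mode_k(zf$m, kc)
  no <- nrow(of$m); nz <- nrow(zf$m)
  io <- rep(seq_len(no), times = nz)
  iz <- rep(seq_len(nz), each = no)
  coef <- -(ko[io, 1] * kz[iz, 1] + ko[io, 2] * kz[iz, 2]) *
    of$coef[io] * zf$coef[iz]
  mode_simplify(mode_series(of$m[io, , drop = FALSE] + zf$m[iz, , drop = FALSE], coef))
}

# The radial equation of every uniform planform is linear in Ahat^2:
# rhs_radial(a) = r a - C1 a^3 - c C2 a.  C1 and C2 are exact rational/
# quadratic-surd numbers; extract them from two evaluations of the projected
# rhs instead of transcribing them.
uniform_radial_coefficients <- function(params, od, psi, type) {
  radial <- function(a, p_) {
    u <- uniform_amplitudes(a, psi, type)
    d <- op_amplitude_rhs(u$A, u$Aopp, p_, od = od)
    Re(exp(-1i * Arg(u$A[1])) * d$dA[1])
  }
  p0 <- params; p0$c_coupling <- 0
  p1 <- params; p1$c_coupling <- 1
  a0 <- 1e-3; a1 <- 0.1
  C2 <- (radial(a0, p0) - radial(a0, p1)) / a0
  C1 <- (params$r_op * a1 - radial(a1, p0)) / a1^3
  list(C1 = C1, C2 = C2)
}

# Uniform (hexagonal pinwheel crystal) phase tables ---------------------------
#
# With the OD hexagons written so that the field minimum sits at the origin
# (B_j = -B_hex for contralateral bias), the uniform stationary states take
# the form
#   sin-type:  z = -2i Ahat sum_j exp(i j psi) sin(k_j . x),  psi = +-pi/3
#   cos-type:  z =  2  Ahat sum_j exp(i j psi) cos(k_j . x),  psi = +-2pi/3
# The sin-type has a simple zero (charge +-1/2 pinwheel) at the OD minimum
# (ipsi-center crystal); the cos-type has a double zero there (topological
# charge +-1, the Braitenberg crystal).
uniform_amplitudes <- function(Ahat, psi, type = c("sin", "cos")) {
  type <- match.arg(type)
  j <- 1:3
  if (type == "sin") {
    Aopp <- Ahat * exp(1i * j * psi)
    list(A = -Aopp, Aopp = Aopp)
  } else {
    A <- Ahat * exp(1i * j * psi)
    list(A = A, Aopp = A)
  }
}

#' Rescaled inter-map coupling strength
#'
#' The coupling axis of the phase diagrams: for the product-type energy
#' \code{c r_od / (3 r_op)} (the pattern-suppression border sits at 1); for
#' the gradient-type energy \code{c kc^4 B_hex^2 / r_op} (bias enters only
#' through the OD hexagon amplitude \code{B_hex}).
#' @param params \code{model_params}.
#' @param od_branch OD branch whose amplitude sets the gradient-type scale.
#' @export
rescale_coupling <- function(params, od_branch = "hexagons") {
  if (params$kind %in% c("product_low", "product_high")) {
    params$c_coupling * params$r_od / (3 * params$r_op)
  } else {
    B <- od_stationary(od_branch, params$gamma, params$r_od, params$kc)$B_amp
    params$c_coupling * params$kc^4 * B^2 / params$r_op
  }
}

#' Invert the rescaled coupling to the raw coupling constant
#' @param chat rescaled coupling.
#' @inheritParams rescale_coupling
#' @export
coupling_from_rescaled <- function(chat, params, od_branch = "hexagons") {
  if (params$kind %in% c("product_low", "product_high")) {
    chat * 3 * params$r_op / params$r_od
  } else {
    B <- od_stationary(od_branch, params$gamma, params$r_od, params$kc)$B_amp
    chat * params$r_op / (params$kc^4 * B^2)
  }
}

#' Closed-form stationary branches of the coupled OP amplitude equations
#'
#' Returns the stationary solution of the requested branch at the given
#' parameter point.  Branches whose phases depend on the coupling strength
#' (stripe-like and rhombic states interacting with OD hexagons, rhombic
#' states under the product-type energy with OD stripes) are computed by
#' Newton continuation from the uncoupled closed form; all others are closed
#' forms:
#' \describe{
#' \item{op_stripes}{uncoupled \code{A = sqrt(r_op)}; under product/OD-stripes
#'   the pair \code{(a, -a^-)} with \code{a^2 + a^-2 = r_c},
#'   \code{a a^- = c B_st^2}, \code{r_c = r_op - c (delta^2 + 2 B_st^2)};
#'   under product/OD-constant \code{sqrt(r_op - c delta^2)}.}
#' \item{op_scotoma}{product/OD-stripes symmetric pair
#'   \code{a = a^- = sqrt((r_op - c r_od/3)/3)}, representing only two
#'   orthogonal orientations; vanishes at \code{c = 3 r_op / r_od}
#'   independently of the bias.}
#' \item{op_rhombic}{four equal modes on k_2, k_3 with phase sum pi,
#'   \code{a = sqrt(r_eff/5)}.}
#' \item{hpwc_psi_a / hpwc_psi_b}{the two stationary uniform states; product:
#'   sin-type with \code{psi = -pi/3} (stable, ipsi-center) or \code{+pi/3},
#'   amplitude \code{Ahat^2 = (3 r_op - c r_od)/27}; gradient: cos-type
#'   \code{psi = 2pi/3} (stable, Braitenberg) with
#'   \code{Ahat^2 = (r_op - (3/2) c kc^4 B_hex^2)/9} or sin-type with
#'   \code{Ahat^2 = (r_op - 2 c kc^4 B_hex^2)/9}.}
#' \item{trivial}{z = 0.}
#' }
#'
#' @param label branch label.
#' @param params \code{model_params}.
#' @param od_branch OD branch the OP pattern interacts with.
#' @return object of class \code{stationary_solution} with fields \code{A},
#'   \code{Aopp}, \code{od}, \code{V}, \code{residual}, \code{exists}.
#' @export
stationary_branch <- function(label = c("op_stripes", "op_scotoma", "op_rhombic",
                                        "hpwc_psi_a", "hpwc_psi_b", "trivial"),
                              params,
                              od_branch = c("hexagons", "stripes", "constant")) {
  label <- match.arg(label)
  od_branch <- match.arg(od_branch)
  od <- od_stationary(od_branch, params$gamma, params$r_od, params$kc)
  r <- params$r_op; cc <- params$c_coupling; kc <- params$kc
  delta <- params$delta
  z0 <- c(0i, 0i, 0i)
  grad_like <- params$kind == "gradient_low"
  mk <- function(A, Aopp, exists = TRUE, note = "") {
    sol <- structure(list(label = label, A = A, Aopp = Aopp, od = od,
                          od_branch = od_branch, params = params,
                          exists = exists, note = note),
                     class = "stationary_solution")
    if (exists) {
      d <- op_amplitude_rhs(A, Aopp, params, od = od)
      sol$residual <- max(Mod(c(d$dA, d$dAopp)))
      sol$V <- op_potential(A, Aopp, params, od = od)
    } else {
      sol$residual <- NA_real_
      sol$V <- NA_real_
    }
    sol
  }
  if (label == "trivial") return(mk(z0, z0))

  if (label == "op_scotoma") {
    if (!(params$kind == "product_low" && od_branch == "stripes")) {
      stop("orientation scotoma branch is defined for the product-type energy with OD stripes")
    }
    a2 <- (r - cc * params$r_od / 3) / 3
    if (a2 <= 0) {
      return(mk(z0, z0, exists = FALSE,
                note = sprintf("beyond the pattern-existence border c = 3 r_op/r_od = %.6g", 3 * r / params$r_od)))
    }
    a <- sqrt(a2)
    return(mk(c(a, 0, 0), c(-a, 0, 0)))
  }

  if (label %in% c("hpwc_psi_a", "hpwc_psi_b")) {
    if (od_branch != "hexagons") stop("uniform hPWC branches require OD hexagons")
    if (params$gamma_tilde > 0) {
      stop("uniform hPWC branches are constructed for contralateral bias (gamma > 0); ",
           "negative bias follows by eye inversion")
    }
    if (params$kind == "product_low") {
      if (label == "hpwc_psi_a") {
        # ipsi-center crystal: z = -2i Ahat sum_j e^{-i j pi/3} sin(k_j x)
        A2 <- (3 * r - cc * params$r_od) / 27
        if (A2 <= 0) {
          return(mk(z0, z0, exists = FALSE,
                    note = sprintf("beyond the hPWC existence border c = 3 r_op/r_od = %.6g", 3 * r / params$r_od)))
        }
        u <- uniform_amplitudes(sqrt(A2), -pi / 3, "sin")
      } else {
        # the second uniform state is the cos-type planform; its linear
        # coupling coefficient depends on the bias, extract it exactly
        cf <- uniform_radial_coefficients(params, od, 2 * pi / 3, "cos")
        A2 <- (r - cc * cf$C2) / cf$C1
        if (A2 <= 0) return(mk(z0, z0, exists = FALSE, note = "uniform state suppressed"))
        u <- uniform_amplitudes(sqrt(A2), 2 * pi / 3, "cos")
      }
      return(mk(u$A, u$Aopp))
    } else if (grad_like) {
      B <- od$B_amp
      if (label == "hpwc_psi_a") {
        A2 <- (r - 1.5 * cc * kc^4 * B^2) / 9
        if (A2 <= 0) {
          return(mk(z0, z0, exists = FALSE,
                    note = sprintf("beyond the hPWC existence border c kc^4 B^2/r_op = 2/3 (c = %.6g)",
                                   2 * r / (3 * kc^4 * B^2))))
        }
        u <- uniform_amplitudes(sqrt(A2), 2 * pi / 3, "cos")
      } else {
        A2 <- (r - 2 * cc * kc^4 * B^2) / 9
        if (A2 <= 0) {
          return(mk(z0, z0, exists = FALSE,
                    note = sprintf("beyond the existence border c kc^4 B^2/r_op = 1/2 (c = %.6g)",
                                   r / (2 * kc^4 * B^2))))
        }
        u <- uniform_amplitudes(sqrt(A2), -pi / 3, "sin")
      }
      return(mk(u$A, u$Aopp))
    }
    stop("uniform hPWC branches are implemented for the low-order energies")
  }

  if (label == "op_stripes") {
    if (cc == 0 || (grad_like && od_branch == "constant")) {
      return(mk(c(complex(real = sqrt(r)), 0, 0), z0))
    }
    if (params$kind == "product_low" && od_branch == "stripes") {
      Bs <- od$B_amp
      rc <- r - cc * (delta^2 + 2 * Bs^2)
      disc <- rc^2 - 4 * cc^2 * Bs^4
      if (rc <= 0 || disc < 0) {
        return(mk(z0, z0, exists = FALSE,
                  note = sprintf("stripe pair collapses at c = r_op/(delta^2 + 4 B_st^2) = %.6g; use op_scotoma beyond",
                                 r / (delta^2 + 4 * Bs^2))))
      }
      a <- sqrt((rc + sqrt(disc)) / 2); ao <- sqrt((rc - sqrt(disc)) / 2)
      return(mk(c(a, 0, 0), c(-ao, 0, 0)))
    }
    if (params$kind == "product_low" && od_branch == "constant") {
      a2 <- r - cc * delta^2
      if (a2 <= 0) {
        return(mk(z0, z0, exists = FALSE,
                  note = sprintf("beyond the suppression border c = r_op/delta^2 = %.6g", r / delta^2)))
      }
      return(mk(c(complex(real = sqrt(a2)), 0, 0), z0))
    }
    if (grad_like && od_branch == "stripes") {
      # energetically preferred orientation is perpendicular to the OD
      # stripes, for which every coupling term vanishes identically; within
      # the hexagonal mode star the representative is the k_2 stripe with the
      # oblique-angle shift (cos^2 60 deg = 1/4)
      a2 <- r - cc * od$B_amp^2 * kc^4 / 2
      if (a2 <= 0) return(mk(z0, z0, exists = FALSE, note = "stripe suppressed"))
      return(mk(c(0i, complex(real = sqrt(a2)), 0i), z0))
    }
    # OD hexagons: coupling-dependent phases -> Newton continuation in c
    p0 <- params; p0$c_coupling <- 0
    seed <- stationary_branch("op_stripes", p0, od_branch)
    return(continue_to_c(seed, params, od))
  }

  if (label == "op_rhombic") {
    a0 <- sqrt(r / 5)
    unc <- list(A = c(0, a0, a0), Aopp = c(0, a0, -a0))
    if (cc == 0 || (grad_like && od_branch == "constant")) {
      return(mk(unc$A, unc$Aopp))
    }
    if (grad_like && od_branch == "stripes") {
      a2 <- (r - cc * od$B_amp^2 * kc^4 / 2) / 5
      if (a2 <= 0) return(mk(z0, z0, exists = FALSE, note = "rhombic suppressed"))
      a <- sqrt(a2)
      return(mk(c(0, a, a), c(0, a, -a)))
    }
    p0 <- params; p0$c_coupling <- 0
    seed <- stationary_branch("op_rhombic", p0, od_branch)
    return(continue_to_c(seed, params, od))
  }
  stop("unsupported branch")
}

#' @export
print.stationary_solution <- function(x, ...) {
  cat(sprintf("stationary OP branch '%s' on OD %s (%s, c = %g)\n",
              x$label, x$od_branch, x$params$kind, x$params$c_coupling))
  if (!x$exists) {
    cat("  does not exist:", x$note, "\n")
  } else {
    cat("  |A|    =", paste(format(Mod(x$A), digits = 5), collapse = " "), "\n")
    cat("  |Aopp| =", paste(format(Mod(x$Aopp), digits = 5), collapse = " "), "\n")
    cat(sprintf("  V = %.8g, residual = %.3g\n", x$V, x$residual))
  }
  invisible(x)
}

#' Existence borders of the OP branches
#'
#' Coupling strengths at which branches vanish or merge, in the raw constant
#' \code{c} and in rescaled units.
#' @inheritParams stationary_branch
#' @param kind coupling kind (taken from \code{params}).
#' @export
existence_borders <- function(params, od_branch = c("hexagons", "stripes", "constant")) {
  od_branch <- match.arg(od_branch)
  r <- params$r_op
  rows <- list()
  add <- function(what, cval) {
    rows[[length(rows) + 1]] <<- data.frame(border = what, c = cval)
  }
  if (params$kind == "product_low") {
    if (od_branch == "stripes") {
      od <- od_stationary("stripes", params$gamma, params$r_od, params$kc)
      add("stripe_pair_collapse (orientation scotoma onset)",
          r / (params$delta^2 + 4 * od$B_amp^2))
      add("pattern_existence (scotoma vanishes)", 3 * r / params$r_od)
    } else if (od_branch == "hexagons") {
      add("pattern_existence (hPWC vanishes)", 3 * r / params$r_od)
    } else {
      add("pattern_existence (stripe vanishes)", r / params$delta^2)
    }
  } else if (params$kind == "gradient_low") {
    if (od_branch == "hexagons") {
      od <- od_stationary("hexagons", params$gamma, params$r_od, params$kc)
      s <- params$kc^4 * od$B_amp^2
      add("pattern_existence (hPWC vanishes)", 2 * r / (3 * s))
      add("sin_uniform_existence", r / (2 * s))
    } else if (od_branch == "stripes") {
      od <- od_stationary("stripes", params$gamma, params$r_od, params$kc)
      add("oblique_stripe_suppression", 2 * r / (od$B_amp^2 * params$kc^4))
    }
  }
  out <- do.call(rbind, rows)
  out$rescaled <- vapply(out$c, function(ci) {
    p2 <- params; p2$c_coupling <- ci
    rescale_coupling(p2, od_branch)
  }, numeric(1))
  out
}

# state <-> real vector helpers
state_to_vec <- function(A, Aopp) c(Re(A), Re(Aopp), Im(A), Im(Aopp))
vec_to_state <- function(x) list(A = complex(real = x[1:3], imaginary = x[7:9]),
                                 Aopp = complex(real = x[4:6], imaginary = x[10:12]))

op_rhs_vec <- function(x, params, od, ctx = make_op_context(params, od)) {
  st <- vec_to_state(x)
  d <- op_rhs_ctx(c(st$A, st$Aopp), ctx)
  state_to_vec(d[1:3], d[4:6])
}

# pseudoinverse Newton for stationary states (gauge directions handled by the
# singular-value cutoff)
newton_polish <- function(A, Aopp, params, od, tol = 1e-12, maxit = 60) {
  x <- state_to_vec(A, Aopp)
  ctx <- make_op_context(params, od)
  f <- function(x) op_rhs_vec(x, params, od, ctx)
  for (i in seq_len(maxit)) {
    Fx <- f(x)
    if (max(abs(Fx)) < tol) break
    J <- num_jacobian(f, x, 1e-7)
    sv <- svd(J)
    inv <- sv$v %*% diag(ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)) %*% t(sv$u)
    step <- as.vector(inv %*% Fx)
    x <- x - step
  }
  st <- vec_to_state(x)
  st$residual <- max(abs(f(x)))
  st
}

# continue a closed-form seed (valid at c = 0) to params$c_coupling
continue_to_c <- function(seed, params, od) {
  path <- newton_continue(seed, params, c_path = params$c_coupling)
  n <- length(path$solutions)
  sol <- if (n > 0) path$solutions[[n]] else seed
  if (!path$converged) {
    sol$exists <- FALSE
    sol$note <- sprintf("branch terminates: Newton continuation stops at c = %.6g (last residual %.3g)",
                        path$c_reached, path$last_residual)
  }
  sol$label <- seed$label
  sol
}

#' Natural-parameter Newton continuation of a stationary branch
#'
#' Follows a stationary solution from its seed coupling strength to the end
#' of \code{c_path} with adaptive step halving; stops where Newton stops
#' converging.
#'
#' @param seed \code{stationary_solution} (stationary at \code{seed$params$c_coupling}).
#' @param params target \code{model_params}; \code{c_path} values replace its
#'   coupling constant.
#' @param c_path numeric vector of coupling strengths (or a single endpoint).
#' @param tol Newton residual tolerance.
#' @return list with \code{solutions}, \code{c_values}, \code{converged},
#'   \code{c_reached}.
#' @export
newton_continue <- function(seed, params, c_path, tol = 1e-12) {
  c_start <- seed$params$c_coupling
  d0 <- op_amplitude_rhs(seed$A, seed$Aopp, seed$params, od = seed$od)
  if (max(Mod(c(d0$dA, d0$dAopp))) > 1e-6) {
    stop("continuation seed is not stationary (residual ",
         format(max(Mod(c(d0$dA, d0$dAopp)))), ")")
  }
  targets <- sort(unique(c_path))
  if (length(targets) == 1 && targets == c_start) {
    return(list(solutions = list(seed), c_values = c_start,
                converged = TRUE, c_reached = c_start, last_residual = seed$residual))
  }
  od <- seed$od
  sols <- list(); cvals <- numeric(0)
  A <- seed$A; Aopp <- seed$Aopp
  c_cur <- c_start
  converged <- TRUE; last_res <- NA_real_
  for (ct in targets) {
    step <- ct - c_cur
    while (abs(c_cur - ct) > 1e-14) {
      attempt <- min(abs(step), abs(ct - c_cur)) * sign(ct - c_cur)
      repeat {
        p2 <- params; p2$c_coupling <- c_cur + attempt
        st <- newton_polish(A, Aopp, p2, od, tol = tol)
        jump <- sqrt(sum(Mod(c(st$A - A, st$Aopp - Aopp))^2))
        scale0 <- sqrt(sum(Mod(c(A, Aopp))^2))
        ok <- st$residual < 1e-9 && all(is.finite(c(Re(st$A), Re(st$Aopp)))) &&
          jump < 0.35 * scale0 + 1e-4   # reject branch jumps near folds
        if (ok) break
        attempt <- attempt / 2
        if (abs(attempt) < 1e-8) break
      }
      if (abs(attempt) < 1e-8) { converged <- FALSE; last_res <- st$residual; break }
      A <- st$A; Aopp <- st$Aopp; c_cur <- c_cur + attempt
      last_res <- st$residual
      step <- attempt * 2
    }
    if (!converged) break
    p2 <- params; p2$c_coupling <- c_cur
    sol <- structure(list(label = seed$label, A = A, Aopp = Aopp, od = od,
                          od_branch = seed$od_branch, params = p2,
                          exists = TRUE, note = "",
                          residual = last_res,
                          V = op_potential(A, Aopp, p2, od = od)),
                     class = "stationary_solution")
    sols[[length(sols) + 1]] <- sol
    cvals <- c(cvals, c_cur)
  }
  list(solutions = sols, c_values = cvals, converged = converged,
       c_reached = c_cur, last_residual = last_res)
}

#' Linear stability of a stationary OP solution
#'
#' Numerical Jacobian of the amplitude equations in real coordinates at the
#' solution; continuous-symmetry zero modes (orientation shift always;
#' translations whenever they commute with the coupling) are identified from
#' their constructed generators and excluded from the verdict.
#'
#' @param solution \code{stationary_solution}.
#' @param params optional \code{model_params} override.
#' @param tol eigenvalue tolerance for the stable verdict.
#' @return object of class \code{stability_report}.
#' @export
linear_stability <- function(solution, params = solution$params, tol = 1e-8) {
  if (!solution$exists) stop("solution does not exist at this parameter point")
  if (is.na(solution$residual) || solution$residual > 1e-7) {
    stop("stationary residual too large for stability analysis: ",
         format(solution$residual))
  }
  od <- solution$od
  x0 <- state_to_vec(solution$A, solution$Aopp)
  ctx <- make_op_context(params, od)
  f <- function(x) op_rhs_vec(x, params, od, ctx)
  J <- num_jacobian(f, x0, 1e-6)
  # candidate symmetry generators
  K <- mode_k(op_star(), params$kc)
  gens <- list(phase = state_to_vec(1i * solution$A, 1i * solution$Aopp))
  for (ax in 1:2) {
    gens[[c("tx", "ty")[ax]]] <-
      state_to_vec(1i * K[, ax] * solution$A, -1i * K[, ax] * solution$Aopp)
  }
  scale <- max(abs(J)) * max(abs(x0)) + 1e-12
  keep <- vapply(gens, function(v) {
    nv <- sqrt(sum(v^2))
    nv > 1e-10 && sqrt(sum((J %*% v)^2)) / nv < 1e-5 * max(1, max(abs(J)))
  }, logical(1))
  red <- project_out(J, gens[keep])
  ev <- eigen(red$J, only.values = TRUE)$values
  structure(list(eigenvalues = ev,
                 symmetry_modes = names(gens)[keep],
                 n_symmetry = red$removed,
                 stable = all(Re(ev) < tol),
                 leading = max(Re(ev)),
                 tol = tol),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("linear stability: %s (leading Re lambda = %.3e, tol %.1e)\n",
              if (x$stable) "stable" else "unstable", x$leading, x$tol))
  cat("  symmetry zero modes excluded:", paste(x$symmetry_modes, collapse = ", "), "\n")
  invisible(x)
}

#' Amplitude-equation potential of a stationary solution
#' @inheritParams linear_stability
#' @export
potential_value <- function(solution, params = solution$params) {
  if (!solution$exists) return(NA_real_)
  op_potential(solution$A, solution$Aopp, params, od = solution$od)
}

# Fast evaluation context ------------------------------------------------------
#
# For fixed OD amplitudes the coupled amplitude equations are
#   dx/dt = r x + L x - cubic(x),   x = (A_1..A_3, A_1^-..A_3^-),
# with L a constant 6x6 complex matrix (the coupling is linear in z for both
# low-order energies) and cubic(x) the fixed resonance sum of |z|^2 z.  The
# resonance table and L are precomputed once; Newton, continuation and
# Jacobian evaluations use this path.

op_cubic_env <- new.env(parent = emptyenv())

op_cubic_table <- function() {
  if (!is.null(op_cubic_env$tab)) return(op_cubic_env$tab)
  K <- op_star(); M <- rbind(K, -K)
  idx <- integer(0); ia <- integer(0); ib <- integer(0); ic <- integer(0)
  for (a in 1:6) for (b in 1:6) for (cm in 1:6) {
    tgt <- M[a, ] + M[b, ] - M[cm, ]
    hit <- which(M[, 1] == tgt[1] & M[, 2] == tgt[2])
    if (length(hit) == 1) {
      idx <- c(idx, hit); ia <- c(ia, a); ib <- c(ib, b); ic <- c(ic, cm)
    }
  }
  op_cubic_env$tab <- list(i = idx, a = ia, b = ib, c = ic)
  op_cubic_env$tab
}

#' @keywords internal
make_op_context <- function(params, od) {
  K <- op_star(); M <- rbind(K, -K)
  kc <- params$kc
  L <- matrix(0 + 0i, 6, 6)
  cc <- params$c_coupling
  if (cc > 0) {
    of <- od_series(od$B, delta = params$delta)
    if (params$kind == "product_low") {
      o2 <- mode_mult(of, of)
      for (i in 1:6) for (j in 1:6) {
        L[i, j] <- -cc * mode_coef(o2, M[i, ] - M[j, ])
      }
    } else if (params$kind == "gradient_low") {
      ko <- mode_k(of$m, kc)
      keep <- !(of$m[, 1] == 0 & of$m[, 2] == 0)
      om <- of$m[keep, , drop = FALSE]; oc <- of$coef[keep]; ko <- ko[keep, , drop = FALSE]
      Mk <- mode_k(M, kc)
      no <- nrow(om)
      for (j in 1:6) for (iq in seq_len(no)) for (iq2 in seq_len(no)) {
        tgt <- M[j, ] + om[iq, ] + om[iq2, ]
        hit <- which(M[, 1] == tgt[1] & M[, 2] == tgt[2])
        if (length(hit) == 1) {
          qk <- sum(ko[iq, ] * Mk[j, ])
          L[hit, j] <- L[hit, j] + cc * qk * sum(ko[iq2, ] * Mk[hit, ]) * oc[iq] * oc[iq2]
        }
      }
    } else {
      stop("fast context implemented for the low-order energies only")
    }
  }
  list(r = params$r_op, L = L, tab = op_cubic_table())
}

op_rhs_ctx <- function(x, ctx) {
  t <- ctx$tab
  cub <- vapply(1:6, function(i) {
    sel <- t$i == i
    sum(x[t$a[sel]] * x[t$b[sel]] * Conj(x[t$c[sel]]))
  }, complex(1))
  ctx$r * x + as.vector(ctx$L %*% x) - cub
}
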