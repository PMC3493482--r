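# Exact finite-mode (planform) arithmetic.
#
# Every active wavevector of the hexagonal planforms is an integer combination
# of the half-lattice basis e1 = (kc/2, 0), e2 = (0, kc*sqrt(3)/2), so fields
# restricted to the planform subspace are finite Fourier series with integer
# indices (m1, m2).  Products of such series are exact convolutions over a few
# dozen modes; projecting the full nonlinearities of the dynamics onto the
# active modes with this algebra yields the coupled amplitude equations
# without any transcription step.

#' @keywords internal
mode_series <- function(m, coef) {
  stopifnot(is.matrix(m), ncol(m) == 2, nrow(m) == length(coef))
  list(m = m, coef = as.complex(coef))
}

mode_key <- function(m) paste(m[, 1], m[, 2], sep = ",")

# collapse duplicate wavevectors
mode_simplify <- function(f) {
  key <- mode_key(f$m)
  agg <- rowsum(cbind(Re(f$coef), Im(f$coef)), key, reorder = FALSE)
  um <- f$m[!duplicated(key), , drop = FALSE]
  mode_series(um, complex(real = agg[, 1], imaginary = agg[, 2]))
}

mode_add <- function(a, b) {
  mode_simplify(mode_series(rbind(a$m, b$m), c(a$coef, b$coef)))
}

mode_scale <- function(a, s) mode_series(a$m, a$coef * s)

mode_conj <- function(a) mode_series(-a$m, Conj(a$coef))

# exact convolution product
mode_mult <- function(a, b) {
  na <- nrow(a$m); nb <- nrow(b$m)
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  mode_simplify(mode_series(a$m[ia, , drop = FALSE] + b$m[ib, , drop = FALSE],
                            a$coef[ia] * b$coef[ib]))
}

# coefficient at a single wavevector
mode_coef <- function(a, m) {
  hit <- a$m[, 1] == m[1] & a$m[, 2] == m[2]
  if (any(hit)) sum(a$coef[hit]) else 0 + 0i
}

# physical wavevectors for integer indices
mode_k <- function(m, kc) cbind(m[, 1] * kc / 2, m[, 2] * kc * sqrt(3) / 2)

# Hexagonal mode stars -------------------------------------------------------

#' Integer indices of the three OP wavevectors (60 degrees apart, k1 along +x)
#' @keywords internal
op_star <- function() matrix(c(2, 0, 1, 1, -1, 1), ncol = 2, byrow = TRUE)

#' Integer indices of the OD triad (120 degrees apart, q1 + q2 + q3 = 0)
#' @keywords internal
od_star <- function() matrix(c(2, 0, -1, 1, -1, -1), ncol = 2, byrow = TRUE)

# z as a mode series from the six OP amplitudes
op_series <- function(A, Aopp) {
  K <- op_star()
  mode_simplify(mode_series(rbind(K, -K), c(A, Aopp)))
}

# o as a mode series from the OD amplitudes and the constant shift
od_series <- function(B, delta = 0) {
  Q <- od_star()
  f <- mode_series(rbind(Q, -Q, c(0L, 0L)), c(B, Conj(B), complex(real = delta)))
  mode_simplify(f)
}
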