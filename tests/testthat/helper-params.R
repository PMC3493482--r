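# Shared parameter points for the test suite.
#
# Study conditions: r_op = 0.1, r_od = 0.2 (near threshold), wavelength 1
# (kc = 2 pi).  Bias values are specified through the rescaled bias eta
# (= 3 delta / sqrt(r_od)); eta = 1.2 sits in the middle of the OD-hexagon
# stability band (sqrt(3/17) ~ 0.42 to sqrt(15)/2 ~ 1.94), eta = 0.4 in the
# stripe band.

R_OP <- 0.1
R_OD <- 0.2
ETA_HEX <- 1.2
ETA_STRIPE <- 0.4
GAMMA_HEX <- od_gamma_from_eta(ETA_HEX, R_OD)
GAMMA_STRIPE <- od_gamma_from_eta(ETA_STRIPE, R_OD)

# rescaled -> raw coupling helpers
c_prod <- function(chat, r_op = R_OP, r_od = R_OD) chat * 3 * r_op / r_od
c_grad <- function(chat, gamma = GAMMA_HEX, r_op = R_OP, r_od = R_OD) {
  B <- od_stationary("hexagons", gamma, r_od)$B_amp
  chat * r_op / ((2 * pi)^4 * B^2)
}

params_prod <- function(chat, gamma = GAMMA_HEX) {
  model_params(R_OP, R_OD, gamma, "product_low", c_prod(chat))
}
params_grad <- function(chat, gamma = GAMMA_HEX) {
  model_params(R_OP, R_OD, gamma, "gradient_low", c_grad(chat, gamma))
}

max_resid <- function(sol, od = sol$od) {
  d <- op_amplitude_rhs(sol$A, sol$Aopp, sol$params, od = od)
  max(Mod(c(d$dA, d$dAopp)))
}

# connected components of a logical matrix on the periodic domain (BFS)
n_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny); cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0) {
      q <- queue[1]; queue <- queue[-1]
      i <- (q - 1L) %% nx + 1L; j <- (q - 1L) %/% nx + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- (i - 1L + d[1]) %% nx + 1L
        jj <- (j - 1L + d[2]) %% ny + 1L
        qq <- (jj - 1L) * nx + ii
        if (mask[ii, jj] && lab[qq] == 0L) { lab[qq] <- cur; queue <- c(queue, qq) }
      }
    }
  }
  cur
}
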