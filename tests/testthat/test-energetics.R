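# Field-level energies, coupling densities and their functional derivatives.

grid_e <- make_grid(64, 64, 2, 2)

rand_fields <- function(seed = 1, amp = 0.3) {
  set.seed(seed)
  # band-limited random fields (smooth enough for quadrature comparisons)
  amps <- planform_amplitudes(
    A = complex(real = rnorm(3), imaginary = rnorm(3)) * amp,
    Aopp = complex(real = rnorm(3), imaginary = rnorm(3)) * amp,
    B = complex(real = rnorm(3), imaginary = rnorm(3)) * amp,
    delta = rnorm(1) * amp)
  synthesize_planform(grid_e, amps)
}

test_that("Swift-Hohenberg energy reproduces analytic single-mode values", {
  z0 <- op_map(matrix(0i, 64, 64), grid_e)
  expect_equal(sh_energy(z0, r = 0.3), 0)
  # critical-circle mode with r > 0: E = -r |A|^2 + |A|^4/2 < 0
  a <- 0.25
  fx <- synthesize_planform(grid_e, planform_amplitudes(A = c(a, 0, 0)))
  expect_equal(sh_energy(fx$op, r = 0.1), -0.1 * a^2 + a^4 / 2, tolerance = 1e-12)
  expect_lt(sh_energy(fx$op, r = 0.1), 0)
  # off-circle mode with r < 0: damped, energy above the homogeneous state
  g2 <- grid_e
  off <- op_map(outer(exp(2i * g2$kc * g2$x), rep(1, 64)), g2)
  expect_gt(sh_energy(off, r = -0.05), 0)
})

test_that("coupling energies match a brute-force real-space quadrature", {
  fx <- rand_fields(4)
  z <- fx$op$z; o <- fx$od$o
  # independent oracle: finite-difference gradients and a plain double loop
  ddx <- (z[c(2:64, 1), ] - z[c(64, 1:63), ]) / (2 * grid_e$dx)
  ddy <- (z[, c(2:64, 1)] - z[, c(64, 1:63)]) / (2 * grid_e$dy)
  odx <- (o[c(2:64, 1), ] - o[c(64, 1:63), ]) / (2 * grid_e$dx)
  ody <- (o[, c(2:64, 1)] - o[, c(64, 1:63)]) / (2 * grid_e$dy)
  s_fd <- odx * ddx + ody * ddy
  expect_equal(coupling_energy(fx$op, fx$od, "product_low", 1.7),
               1.7 * mean(o^2 * Mod(z)^2), tolerance = 1e-12)
  expect_equal(coupling_energy(fx$op, fx$od, "product_high", 0.9),
               0.9 * mean(o^4 * Mod(z)^4), tolerance = 1e-12)
  # spectral vs central-difference gradients agree to the FD truncation error
  expect_equal(coupling_energy(fx$op, fx$od, "gradient_low", 1),
               mean(Mod(s_fd)^2), tolerance = 5e-2)
  expect_equal(coupling_energy(fx$op, fx$od, "gradient_high", 1),
               mean(Mod(s_fd)^4), tolerance = 1e-1)
})

test_that("coupling energy is zero for o = 0, positive in general, symmetric", {
  fx <- rand_fields(5)
  o0 <- od_map(matrix(0, 64, 64), grid_e)
  for (kind in c("product_low", "gradient_low", "product_high", "gradient_high")) {
    expect_equal(coupling_energy(fx$op, o0, kind, 1), 0)
    e <- coupling_energy(fx$op, fx$od, kind, 1)
    expect_gte(e, 0)
    # orientation-shift invariance
    expect_equal(coupling_energy(apply_orientation_shift(fx$op, 1.1), fx$od, kind, 1),
                 e, tolerance = 1e-10)
    # eye-inversion invariance
    inv <- od_map(-fx$od$o, grid_e)
    expect_equal(coupling_energy(fx$op, inv, kind, 1), e, tolerance = 1e-10)
  }
})

test_that("parallel OP/OD stripes maximize, orthogonal annihilate, the gradient energy", {
  g <- make_grid_square(64, 64, 4, 4)
  kc <- g$kc
  o <- outer(cos(kc * g$x), rep(1, 64))
  odm <- od_map(o, g)
  zpar <- op_map(outer(exp(1i * kc * g$x), rep(1, 64)), g)
  zort <- op_map(outer(rep(1, 64), exp(1i * kc * g$y)), g)
  e_par <- coupling_energy(zpar, odm, "gradient_low", 1)
  e_ort <- coupling_energy(zort, odm, "gradient_low", 1)
  expect_equal(e_ort, 0, tolerance = 1e-20)
  expect_gt(e_par, 1)
})

test_that("interaction terms are the functional derivatives (directional FD oracle)", {
  fx <- rand_fields(6, amp = 0.2)
  set.seed(7)
  hz <- synthesize_planform(grid_e, planform_amplitudes(
    A = complex(real = rnorm(3), imaginary = rnorm(3)),
    Aopp = complex(real = rnorm(3), imaginary = rnorm(3))))$op$z
  ho <- synthesize_planform(grid_e, planform_amplitudes(
    B = complex(real = rnorm(3), imaginary = rnorm(3)), delta = 0.3))$od$o
  for (kind in c("product_low", "gradient_low", "product_high", "gradient_high")) {
    cg <- coupling_gradients(fx$op, fx$od, kind, 1)
    U <- function(z, o) coupling_energy(op_map(z, grid_e), od_map(o, grid_e), kind, 1)
    # z-direction: dU = -2 eps Re<dz, h> + O(eps^2)
    eps <- 1e-6
    dU <- (U(fx$op$z + eps * hz, fx$od$o) - U(fx$op$z - eps * hz, fx$od$o)) / (2 * eps)
    pred <- -2 * Re(mean(Conj(cg$dz) * hz))
    expect_equal(dU, pred, tolerance = 1e-5 * max(1, abs(pred)))
    # o-direction
    dUo <- (U(fx$op$z, fx$od$o + eps * ho) - U(fx$op$z, fx$od$o - eps * ho)) / (2 * eps)
    predo <- -mean(cg$do * ho)
    expect_equal(dUo, predo, tolerance = 1e-5 * max(1, abs(predo)))
  }
})

test_that("gradient coupling with constant OD leaves both dynamics unaffected", {
  fx <- rand_fields(8)
  oc <- od_map(matrix(0.4, 64, 64), grid_e)
  cg <- coupling_gradients(fx$op, oc, "gradient_low", 1)
  expect_lt(max(Mod(cg$dz)), 1e-12)
  expect_lt(max(abs(cg$do)), 1e-12)
  # z = 0 kills the z-equation term for every kind
  z0 <- op_map(matrix(0i, 64, 64), grid_e)
  for (kind in c("product_low", "gradient_low", "product_high", "gradient_high")) {
    expect_lt(max(Mod(coupling_gradients(z0, fx$od, kind, 1)$dz)), 1e-14)
  }
})

test_that("total energy decomposes and ranks the crystals at strong coupling", {
  p0 <- params_prod(0)
  fx <- rand_fields(9)
  te <- total_energy(fx$op, fx$od, p0)
  expect_equal(te$E_total, te$E_op + te$E_od)
  expect_equal(te$E_coupling, 0)
  # product-type coupling with OD hexagons: the hPWC beats the uncoupled
  # stripe planform once coupling is strong
  g <- make_grid(64, 64, 2, 2)
  pc <- params_prod(0.5)
  hp <- fixture("hpwc_ipsi", g, pc)
  stripe_amps <- planform_amplitudes(A = c(sqrt(R_OP), 0, 0),
                                     B = hp$od$delta * 0 + od_stationary("hexagons", GAMMA_HEX, R_OD)$B,
                                     delta = hp$od$delta)
  st <- synthesize_planform(g, stripe_amps)
  expect_lt(total_energy(hp$op, hp$od, pc)$E_total,
            total_energy(st$op, st$od, pc)$E_total)
})
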