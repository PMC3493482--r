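# Coupled OP amplitude equations: closed-form branches, existence borders,
# Newton continuation, linear stability, potential.

test_that("uncoupled stationary states and potentials match the closed forms", {
  p0 <- params_prod(0, GAMMA_STRIPE)
  st <- stationary_branch("op_stripes", p0, "stripes")
  expect_equal(Mod(st$A[1]), sqrt(R_OP), tolerance = 1e-12)
  expect_equal(st$V, -R_OP^2 / 2, tolerance = 1e-12)
  rh <- stationary_branch("op_rhombic", p0, "stripes")
  expect_equal(unique(round(Mod(c(rh$A[2:3], rh$Aopp[2:3])), 12)),
               round(sqrt(R_OP / 5), 12))
  expect_equal(rh$V, -2 * R_OP^2 / 5, tolerance = 1e-12)
  expect_gt(rh$V, st$V)  # stripes always preferred without coupling
  expect_equal(stationary_branch("trivial", p0, "stripes")$V, 0)
})

test_that("gradient coupling with the constant OD branch leaves the rhs uncoupled", {
  gamma_c <- od_gamma_from_eta(2.0, R_OD)
  pg <- model_params(R_OP, R_OD, gamma_c, "gradient_low", 0.005)
  p0 <- model_params(R_OP, R_OD, gamma_c, "gradient_low", 0)
  odc <- od_stationary("constant", gamma_c, R_OD)
  set.seed(3)
  x <- complex(real = rnorm(6), imaginary = rnorm(6)) * 0.2
  d1 <- op_amplitude_rhs(x[1:3], x[4:6], pg, od = odc)
  d0 <- op_amplitude_rhs(x[1:3], x[4:6], p0, od = odc)
  expect_lt(max(Mod(c(d1$dA - d0$dA, d1$dAopp - d0$dAopp))), 1e-14)
})

test_that("every closed-form branch is stationary across a 100+ point parameter sweep", {
  worst <- 0; n_pts <- 0
  for (eta in seq(0.5, 1.85, length.out = 6)) {
    gamma <- od_gamma_from_eta(eta, R_OD)
    for (chat in seq(0.05, 0.95, length.out = 6)) {
      for (cfg in list(list("hpwc_psi_a", params_prod(chat, gamma), "hexagons"),
                       list("hpwc_psi_b", params_prod(chat, gamma), "hexagons"),
                       list("hpwc_psi_a", params_grad(chat * 0.65, gamma), "hexagons"),
                       list("hpwc_psi_b", params_grad(chat * 0.45, gamma), "hexagons"))) {
        sol <- stationary_branch(cfg[[1]], cfg[[2]], cfg[[3]])
        if (!sol$exists) next
        worst <- max(worst, sol$residual); n_pts <- n_pts + 1
      }
    }
  }
  for (eta in seq(0.1, 0.7, length.out = 5)) {
    gamma <- od_gamma_from_eta(eta, R_OD)
    for (chat in seq(0.05, 0.9, length.out = 5)) {
      for (lb in c("op_stripes", "op_scotoma")) {
        sol <- stationary_branch(lb, params_prod(chat, gamma), "stripes")
        if (!sol$exists) next
        worst <- max(worst, sol$residual); n_pts <- n_pts + 1
      }
      sol <- stationary_branch("op_rhombic", params_grad(chat, gamma), "stripes")
      if (sol$exists) { worst <- max(worst, sol$residual); n_pts <- n_pts + 1 }
    }
  }
  expect_gt(n_pts, 100)
  expect_lt(worst, 1e-10)
})

test_that("product/OD-stripes: pair collapse and bias-independent existence border", {
  ods <- od_stationary("stripes", GAMMA_STRIPE, R_OD)
  p <- params_prod(0.2, GAMMA_STRIPE)
  c_coll <- R_OP / (p$delta^2 + 4 * ods$B_amp^2)
  just_below <- model_params(R_OP, R_OD, GAMMA_STRIPE, "product_low", c_coll * (1 - 1e-4))
  sol <- stationary_branch("op_stripes", just_below, "stripes")
  expect_lt(abs(Mod(sol$A[1]) - Mod(sol$Aopp[1])), 0.05 * Mod(sol$A[1]))
  sc <- stationary_branch("op_scotoma",
                          model_params(R_OP, R_OD, GAMMA_STRIPE, "product_low", c_coll),
                          "stripes")
  expect_equal(Mod(sc$A[1]), sqrt(c_coll) * ods$B_amp, tolerance = 1e-10)
  # existence border c = 3 r_op / r_od at every bias
  for (eta in c(0.1, 0.5)) {
    b <- existence_borders(model_params(R_OP, R_OD, od_gamma_from_eta(eta, R_OD),
                                        "product_low", 0), "stripes")
    expect_equal(b$c[grepl("pattern_existence", b$border)], 3 * R_OP / R_OD)
  }
  # amplitude -> 0 continuously at the border
  eps_c <- 3 * R_OP / R_OD * (1 - 1e-4)
  tiny <- stationary_branch("op_scotoma",
                            model_params(R_OP, R_OD, GAMMA_STRIPE, "product_low", eps_c),
                            "stripes")
  expect_lt(Mod(tiny$A[1]), 0.01)
  beyond <- stationary_branch("op_scotoma",
                              model_params(R_OP, R_OD, GAMMA_STRIPE, "product_low",
                                           3 * R_OP / R_OD * 1.01), "stripes")
  expect_false(beyond$exists)
})

test_that("hPWC existence borders are independent of the bias", {
  for (cfg in list(c("product_low", 3 * R_OP / R_OD), c("gradient_low", 2 / 3))) {
    b1 <- existence_borders(model_params(R_OP, R_OD, od_gamma_from_eta(0.6, R_OD),
                                         cfg[1], 0), "hexagons")
    b2 <- existence_borders(model_params(R_OP, R_OD, od_gamma_from_eta(1.6, R_OD),
                                         cfg[1], 0), "hexagons")
    i1 <- grepl("hPWC", b1$border); i2 <- grepl("hPWC", b2$border)
    if (cfg[1] == "product_low") {
      expect_equal(b1$c[i1], b2$c[i2])
      expect_equal(b1$c[i1], as.numeric(cfg[2]))
    } else {
      # raw c differs with bias, the rescaled border is the constant 2/3
      expect_equal(b1$rescaled[i1], as.numeric(cfg[2]), tolerance = 1e-12)
      expect_equal(b2$rescaled[i2], as.numeric(cfg[2]), tolerance = 1e-12)
    }
  }
})

test_that("newton_continue returns the seed at zero path length and is tolerance-stable", {
  p0 <- params_prod(0)
  seed <- stationary_branch("op_stripes", p0, "hexagons")
  path <- newton_continue(seed, p0, c_path = 0)
  expect_true(path$converged)
  expect_equal(path$solutions[[1]]$A, seed$A)
  # halved tolerance gives the same branch point
  pt <- params_prod(0.2)
  s1 <- newton_continue(seed, pt, c_path = pt$c_coupling, tol = 1e-12)
  s2 <- newton_continue(seed, pt, c_path = pt$c_coupling, tol = 5e-13)
  expect_lt(max(Mod(s1$solutions[[1]]$A - s2$solutions[[1]]$A)), 1e-9)
  expect_error(newton_continue(structure(list(A = c(1, 0, 0) + 0i, Aopp = rep(0i, 3),
                                              od = seed$od, params = p0,
                                              residual = 1),
                                         class = "stationary_solution"),
                               pt, 0.1), "not stationary")
})

test_that("rhombic branch under product/OD hexagons loses its character before the hPWC border", {
  # the continued rhombic state is distorted by the coupling and is never
  # stable once the uniform crystal is: no rhombic/uniform bistability
  for (chat in c(0.35, 0.6)) {
    pr <- params_prod(chat)
    rh <- stationary_branch("op_rhombic", pr, "hexagons")
    hp <- stationary_branch("hpwc_psi_a", pr, "hexagons")
    expect_true(hp$exists)
    expect_true(linear_stability(hp)$stable)
    if (rh$exists) {
      expect_false(linear_stability(rh)$stable)
      # strongly transformed relative to the uncoupled rhombic amplitudes
      mods <- sort(Mod(c(rh$A, rh$Aopp)), decreasing = TRUE)[1:4]
      expect_gt(max(abs(mods - sqrt(R_OP / 5))), 0.2 * sqrt(R_OP / 5))
    }
  }
})

test_that("stability verdicts reproduce the bifurcation scenario", {
  # uncoupled: both stripes and rhombs stable, stripes lower V
  p0 <- params_prod(0, GAMMA_STRIPE)
  st <- stationary_branch("op_stripes", p0, "stripes")
  rh <- stationary_branch("op_rhombic", p0, "stripes")
  expect_true(linear_stability(st)$stable)
  expect_true(linear_stability(rh)$stable)
  expect_lt(st$V, rh$V)
  # product/OD hexagons: hPWC unstable at weak, stable at strong coupling;
  # the onset is bracketed by a sign change of the leading eigenvalue
  lead <- function(chat) linear_stability(stationary_branch("hpwc_psi_a",
                                                            params_prod(chat), "hexagons"))$leading
  expect_gt(lead(0.08), 0)
  expect_lt(lead(0.6), 0)
  onset <- uniroot(lead, c(0.08, 0.6), tol = 1e-4)$root
  expect_gt(onset, 0.08); expect_lt(onset, 0.6)
  # the second uniform branch stays unstable throughout its range
  for (chat in c(0.1, 0.4, 0.8)) {
    sb <- stationary_branch("hpwc_psi_b", params_prod(chat), "hexagons")
    if (sb$exists) expect_gt(linear_stability(sb)$leading, 0)
    sg <- stationary_branch("hpwc_psi_b", params_grad(chat * 0.45), "hexagons")
    if (sg$exists) expect_gt(linear_stability(sg)$leading, 0)
  }
  # gradient type: Braitenberg crystal stable at strong coupling
  expect_true(linear_stability(stationary_branch("hpwc_psi_a", params_grad(0.5),
                                                 "hexagons"))$stable)
})

test_that("phase gauge: global phase shifts leave residual, V and spectrum unchanged", {
  sol <- stationary_branch("hpwc_psi_a", params_prod(0.5), "hexagons")
  rep1 <- linear_stability(sol)
  sol2 <- sol
  sol2$A <- sol$A * exp(0.9i); sol2$Aopp <- sol$Aopp * exp(0.9i)
  expect_lt(max_resid(sol2), 1e-12)
  expect_equal(potential_value(sol2), potential_value(sol), tolerance = 1e-12)
  rep2 <- linear_stability(sol2)
  expect_equal(sort(Re(rep1$eigenvalues)), sort(Re(rep2$eigenvalues)), tolerance = 1e-5)
  expect_true("phase" %in% rep1$symmetry_modes)
})

test_that("potential is consistent with the rhs (gradient structure) and ranks branches", {
  pt <- params_prod(0.45)
  sol <- stationary_branch("hpwc_psi_a", pt, "hexagons")
  od <- sol$od
  # finite-difference gradient of V against -rhs at a NON-stationary point
  set.seed(11)
  A <- sol$A + 0.05 * complex(real = rnorm(3), imaginary = rnorm(3))
  Ao <- sol$Aopp + 0.05 * complex(real = rnorm(3), imaginary = rnorm(3))
  d <- op_amplitude_rhs(A, Ao, pt, od = od)
  eps <- 1e-6
  for (j in 1:3) {
    ej <- rep(0i, 3); ej[j] <- eps
    dV <- (op_potential(A + ej, Ao, pt, od = od) - op_potential(A - ej, Ao, pt, od = od)) / (2 * eps)
    # dV/dRe(A_j) = -2 Re(dA_j/dt)
    expect_equal(dV, -2 * Re(d$dA[j]), tolerance = 1e-6)
    dVi <- (op_potential(A + 1i * ej, Ao, pt, od = od) - op_potential(A - 1i * ej, Ao, pt, od = od)) / (2 * eps)
    expect_equal(dVi, -2 * Im(d$dA[j]), tolerance = 1e-6)
  }
  # stripe/hPWC potential ordering flips as the coupling grows
  Vdiff <- function(chat) {
    p <- params_prod(chat)
    stationary_branch("op_stripes", p, "hexagons")$V -
      stationary_branch("hpwc_psi_a", p, "hexagons")$V
  }
  expect_lt(Vdiff(0.05), 0)   # stripes preferred at weak coupling
  expect_gt(Vdiff(0.55), 0)   # hPWC preferred at strong coupling
})
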