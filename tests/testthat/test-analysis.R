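# Pinwheel detection and charges, OD critical points, position
# classification, intersection angles, orientation histograms.

test_that("stripes are pinwheel free; rhombic density matches the lattice count", {
  g <- make_grid(64, 64, 2, 2)
  p0 <- params_prod(0, GAMMA_STRIPE)
  expect_equal(find_pinwheels(fixture("op_stripes", g, p0)$op)$n, 0)
  pw <- find_pinwheels(fixture("op_rhombic", g, p0)$op)
  # 60-degree rhombic lattice: 4 sin(60 deg) pinwheels per Lambda^2
  expect_equal(pw$density, 4 * sin(pi / 3), tolerance = 1e-9)
  # refinement oracle: the same count on a finer grid
  g2 <- make_grid(128, 128, 2, 2)
  expect_equal(find_pinwheels(fixture("op_rhombic", g2, p0)$op)$n, pw$n)
})

test_that("pinwheel charge bookkeeping: half-integers, zero total, shift invariance", {
  g <- make_grid(96, 96, 2, 2)
  for (fx in list(fixture("hpwc_ipsi", g, params_prod(0.45)),
                  fixture("hpwc_braitenberg", g, params_grad(0.45)),
                  fixture("op_rhombic", g, params_prod(0, GAMMA_STRIPE)))) {
    pw <- find_pinwheels(fx$op)
    expect_equal(pw$total_charge, 0)
    expect_true(all(abs(pw$pinwheels$charge * 2 - round(pw$pinwheels$charge * 2)) < 1e-12))
    sh <- find_pinwheels(apply_orientation_shift(fx$op, 1.3))
    expect_equal(sh$n, pw$n)
    expect_equal(sort(sh$pinwheels$charge), sort(pw$pinwheels$charge))
  }
})

test_that("extensivity: density identical on 1x and 4x domains", {
  p <- params_prod(0.45)
  pw1 <- find_pinwheels(fixture("hpwc_ipsi", make_grid(64, 64, 2, 2), p)$op)
  pw4 <- find_pinwheels(fixture("hpwc_ipsi", make_grid(128, 128, 4, 4), p)$op)
  expect_equal(pw1$per_unit_cell, pw4$per_unit_cell, tolerance = 1e-12)
  expect_equal(pw4$n, 4L * pw1$n)
})

test_that("OD critical points have the hexagonal lattice multiplicities", {
  g <- make_grid(96, 96, 2, 2)
  cp <- od_critical_points(fixture("od_hexagons", g, params_prod(0))$od)
  counts <- table(cp$points$type)
  ncell <- g$n_cells_x * g$n_cells_y
  expect_equal(as.integer(counts["min"]), 1L * ncell)   # one ipsi peak per cell
  expect_equal(as.integer(counts["max"]), 2L * ncell)   # honeycomb of contra peaks
  expect_equal(as.integer(counts["saddle"]), 3L * ncell)
  # index theorem on the torus: extrema - saddles = 0
  expect_equal(sum(cp$points$winding), 0)
  # a single stripe mode has ridge lines, no isolated critical points
  st <- fixture("od_stripes", g, params_prod(0, GAMMA_STRIPE))$od
  expect_equal(nrow(od_critical_points(st)$points), 0L)
  expect_error(od_critical_points(od_map(matrix(1, 96, 96), g)), "constant")
})

test_that("ipsi-center crystal: pinwheels at OD extrema and saddles (2/1/3 per cell)", {
  g <- make_grid(96, 96, 2, 2)
  ncell <- g$n_cells_x * g$n_cells_y
  fx <- fixture("hpwc_ipsi", g, params_prod(0.45))
  pw <- find_pinwheels(fx$op)
  cl <- classify_pinwheel_positions(pw, fx$od)
  expect_equal(as.integer(cl$counts[c("at_max", "at_min", "at_saddle")]),
               c(2L, 1L, 3L) * ncell)
  expect_equal(sum(cl$counts), pw$n)
  # classification is bias independent within the OD-hexagon band
  for (eta in c(0.7, 1.6)) {
    fx2 <- fixture("hpwc_ipsi", g, params_prod(0.45, od_gamma_from_eta(eta, R_OD)))
    cl2 <- classify_pinwheel_positions(find_pinwheels(fx2$op), fx2$od)
    expect_equal(cl2$counts, cl$counts)
  }
})

test_that("Braitenberg crystal: 3 pinwheels per cell, charge 1 at the OD minimum", {
  g <- make_grid(96, 96, 2, 2)
  ncell <- g$n_cells_x * g$n_cells_y
  fx <- fixture("hpwc_braitenberg", g, params_grad(0.45))
  pw <- find_pinwheels(fx$op)
  expect_equal(pw$per_unit_cell, 3, tolerance = 1e-12)
  cl <- classify_pinwheel_positions(pw, fx$od)
  expect_equal(as.integer(cl$counts[c("at_max", "at_min")]), c(2L, 1L) * ncell)
  expect_equal(pw$pinwheels$charge[cl$classes == "at_min"], rep(1, ncell))
  expect_equal(pw$pinwheels$charge[cl$classes == "at_max"], rep(-0.5, 2 * ncell))
})

test_that("classification partitions arbitrary pinwheel sets", {
  g <- make_grid(64, 64, 2, 2)
  set.seed(5)
  amps <- planform_amplitudes(
    A = complex(real = rnorm(3), imaginary = rnorm(3)) * 0.2,
    Aopp = complex(real = rnorm(3), imaginary = rnorm(3)) * 0.2)
  fx <- synthesize_planform(g, amps)
  odf <- fixture("od_hexagons", g, params_prod(0))$od
  pw <- find_pinwheels(fx$op)
  cl <- classify_pinwheel_positions(pw, odf)
  expect_equal(sum(cl$counts), pw$n)
})

test_that("intersection angles: stripes give the constructed angle, crystals peak at 90 deg", {
  gsq <- make_grid_square(64, 64, 4, 4)
  kc <- gsq$kc
  odm <- od_map(outer(cos(kc * gsq$x), rep(1, 64)), gsq)
  zpar <- op_map(outer(exp(1i * kc * gsq$x), rep(1, 64)), gsq)
  zort <- op_map(outer(rep(1, 64), exp(1i * kc * gsq$y)), gsq)
  expect_lt(intersection_angles(zpar, odm)$mean_angle, 1)
  expect_gt(intersection_angles(zort, odm)$mean_angle, 89)
  expect_error(intersection_angles(zpar, od_map(matrix(1, 64, 64), gsq)), "contour")
  g <- make_grid(96, 96, 2, 2)
  for (fx in list(fixture("hpwc_ipsi", g, params_prod(0.45)),
                  fixture("hpwc_braitenberg", g, params_grad(0.45)))) {
    ia <- intersection_angles(fx$op, fx$od)
    expect_equal(ia$mode_angle, 87.5)      # all mass concentrated in the top bin
    expect_gt(ia$mean_angle, 85)
    expect_gt(max(ia$samples$angle), 89.9)
  }
})

test_that("orientation histograms: flat for stripes, 2/6/3 structure for the crystals", {
  g <- make_grid(96, 96, 2, 2)
  # a stripe is a linear theta ramp: 96 columns / 2 periods = 48 distinct
  # orientations; 24 bins hold exactly two each, so the histogram is flat
  st_op <- apply_orientation_shift(
    fixture("op_stripes", g, params_prod(0, GAMMA_STRIPE))$op, pi / 48)
  oh <- orientation_histogram(st_op, nbins = 24)
  expect_lt(max(abs(oh$density - 1 / 24)), 1e-9)
  expect_equal(oh$n_peaks, 0L)
  # orientation scotoma at the collapse point: exactly two orientations, 90 deg apart
  ods <- od_stationary("stripes", GAMMA_STRIPE, R_OD)
  sh <- shift_delta(GAMMA_STRIPE, R_OD)
  c_coll <- R_OP / (sh$delta^2 + 4 * ods$B_amp^2)
  sc <- fixture("op_scotoma", g,
                model_params(R_OP, R_OD, GAMMA_STRIPE, "product_low", c_coll))
  ohs <- orientation_histogram(sc$op, nbins = 36)
  expect_equal(ohs$n_represented, 2L)
  reps <- which(ohs$density > 0.1 / 36)
  th_rep <- (ohs$breaks[reps] + ohs$breaks[reps + 1]) / 2
  expect_equal(abs(diff(th_rep)), pi / 2, tolerance = pi / 36)
  # crystals: 6 (ipsi-center) and 3 (Braitenberg) overrepresented orientations
  oh6 <- orientation_histogram(fixture("hpwc_ipsi", g, params_prod(0.45))$op)
  expect_equal(oh6$n_peaks, 6L)
  oh3 <- orientation_histogram(fixture("hpwc_braitenberg", g, params_grad(0.45))$op)
  expect_equal(oh3$n_peaks, 3L)
})
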