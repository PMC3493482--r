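# Geometry of orientation and ocular-dominance maps: phase singularities
# (pinwheels) and their topological charges, OD critical points, pinwheel
# position classification, intersection angles between iso-orientation
# contours and OD borders, orientation histograms.

wrap_pi <- function(a) (a + pi) %% (2 * pi) - pi

# plaquette winding numbers of a complex field's phase: integer matrix, entry
# [i,j] = winding of arg(f) around the plaquette with corners (i,j)..(i+1,j+1)
plaquette_winding <- function(f) {
  ph <- Arg(f)
  nx <- nrow(f); ny <- ncol(f)
  ip <- c(2:nx, 1); jp <- c(2:ny, 1)
  d1 <- wrap_pi(ph[ip, ] - ph)           # (i,j)   -> (i+1,j)
  d2 <- wrap_pi(ph[ip, jp] - ph[ip, ])   # (i+1,j) -> (i+1,j+1)
  d3 <- wrap_pi(ph[, jp] - ph[ip, jp])   # (i+1,j+1) -> (i,j+1)
  d4 <- wrap_pi(ph - ph[, jp])           # (i,j+1) -> (i,j)
  round((d1 + d2 + d3 + d4) / (2 * pi))
}

# sub-pixel zero of a complex field inside plaquette (i,j) by Newton on the
# bilinear interpolant; returns physical coordinates
subpixel_zero <- function(f, grid, i, j) {
  ip <- if (i == grid$nx) 1L else i + 1L
  jp <- if (j == grid$ny) 1L else j + 1L
  c00 <- f[i, j]; c10 <- f[ip, j]; c01 <- f[i, jp]; c11 <- f[ip, jp]
  u <- 0.5; v <- 0.5
  for (it in 1:30) {
    val <- (1 - u) * (1 - v) * c00 + u * (1 - v) * c10 + (1 - u) * v * c01 + u * v * c11
    du <- -(1 - v) * c00 + (1 - v) * c10 - v * c01 + v * c11
    dv <- -(1 - u) * c00 - u * c10 + (1 - u) * c01 + u * c11
    J <- matrix(c(Re(du), Im(du), Re(dv), Im(dv)), 2)
    rhs <- c(Re(val), Im(val))
    if (abs(det(J)) < 1e-14) break
    step <- solve(J, rhs)
    u <- u - step[1]; v <- v - step[2]
    if (max(abs(step)) < 1e-12) break
  }
  u <- min(max(u, 0), 1); v <- min(max(v, 0), 1)
  c(grid$x[i] + u * grid$dx, grid$y[j] + v * grid$dy)
}

# A genuine point singularity has |z| bounded away from zero on a small
# circle around it; zero LINES (e.g. the orientation-scotoma planform, where
# z vanishes on stripes rather than points) cross any such circle and
# produce spurious plaquette windings, which this test rejects.
zero_is_isolated <- function(z, grid, p, ratio = 0.05) {
  rad <- 1.3 * max(grid$dx, grid$dy)
  tau <- seq(0, 2 * pi, length.out = 17)[-17]
  vals <- vapply(tau, function(t)
    Mod(bilinear_at(z, grid, p + rad * c(cos(t), sin(t)))), numeric(1))
  min(vals) > ratio * max(vals)
}

# wrapped distance on the periodic domain
torus_dist <- function(p, q, grid) {
  dx <- abs(p[1] - q[1]); dx <- min(dx, grid$Lx - dx)
  dy <- abs(p[2] - q[2]); dy <- min(dy, grid$Ly - dy)
  sqrt(dx^2 + dy^2)
}

# merge singular plaquettes within a radius into single defects (handles
# higher-charge zeros spread over adjacent plaquettes)
merge_defects <- function(pos, wind, grid, radius) {
  if (nrow(pos) == 0) {
    return(list(pos = pos, wind = integer(0)))
  }
  n <- nrow(pos)
  cluster <- seq_len(n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (torus_dist(pos[a, ], pos[b, ], grid) < radius) {
      cluster[cluster == cluster[b]] <- cluster[a]
    }
  }
  ids <- unique(cluster)
  out_pos <- matrix(0, 0, 2); out_w <- integer(0)
  for (id in ids) {
    sel <- cluster == id
    w <- sum(wind[sel])
    if (w == 0) next      # annihilating pair below merge resolution
    ref <- pos[which(sel)[1], ]
    dp <- pos[sel, , drop = FALSE]
    dp[, 1] <- ref[1] + wrap_pi(2 * pi * (dp[, 1] - ref[1]) / grid$Lx) * grid$Lx / (2 * pi)
    dp[, 2] <- ref[2] + wrap_pi(2 * pi * (dp[, 2] - ref[2]) / grid$Ly) * grid$Ly / (2 * pi)
    ctr <- colMeans(dp)
    ctr[1] <- ctr[1] %% grid$Lx; ctr[2] <- ctr[2] %% grid$Ly
    out_pos <- rbind(out_pos, ctr); out_w <- c(out_w, w)
  }
  list(pos = out_pos, wind = out_w)
}

#' Detect pinwheels of an OP map
#'
#' Zeros of z located by the plaquette winding of arg(z); the topological
#' charge is the theta-winding, i.e. the z-phase winding divided by 2.
#' Singular plaquettes closer than \code{merge_radius} are merged into one
#' defect (a charge-1 zero spreads its winding over adjacent plaquettes).
#'
#' @param op \code{op_map}.
#' @param merge_radius merge radius (default Lambda/20).
#' @return object of class \code{pinwheel_set}: data.frame \code{pinwheels}
#'   (x, y, charge), \code{n}, \code{density} (per Lambda^2 hypercolumn
#'   area), \code{per_unit_cell} (per hexagonal cell, area 2 Lambda^2/sqrt 3).
#' @export
find_pinwheels <- function(op, merge_radius = NULL) {
  grid <- op$grid
  if (all(Mod(op$z) < 1e-14)) stop("field is identically zero; no orientation map")
  if (is.null(merge_radius)) merge_radius <- grid$lambda / 20
  W <- plaquette_winding(op$z)
  sing <- which(W != 0, arr.ind = TRUE)
  if (nrow(sing) > 0 && any(abs(W[sing]) > 1)) {
    stop("plaquette with |winding| > 1: grid too coarse to separate singularities, refine the grid")
  }
  pos <- matrix(0, nrow(sing), 2)
  keep <- logical(nrow(sing))
  for (s in seq_len(nrow(sing))) {
    pos[s, ] <- subpixel_zero(op$z, grid, sing[s, 1], sing[s, 2])
    keep[s] <- zero_is_isolated(op$z, grid, pos[s, ])
  }
  mg <- merge_defects(pos[keep, , drop = FALSE], W[sing][keep], grid, merge_radius)
  area_lambda2 <- grid$Lx * grid$Ly / grid$lambda^2
  cell_area <- 2 * grid$lambda^2 / sqrt(3)
  n_cells <- grid$Lx * grid$Ly / cell_area
  df <- data.frame(x = if (nrow(mg$pos)) mg$pos[, 1] else numeric(0),
                   y = if (nrow(mg$pos)) mg$pos[, 2] else numeric(0),
                   charge = mg$wind / 2)
  structure(list(pinwheels = df, n = nrow(df),
                 total_charge = sum(df$charge),
                 density = nrow(df) / area_lambda2,
                 per_unit_cell = nrow(df) / n_cells,
                 grid = grid),
            class = "pinwheel_set")
}

#' @export
print.pinwheel_set <- function(x, ...) {
  cat(sprintf("%d pinwheels (density %.4g per Lambda^2, %.4g per unit cell, total charge %g)\n",
              x$n, x$density, x$per_unit_cell, x$total_charge))
  invisible(x)
}

#' Pinwheel density per hypercolumn area
#' @param pw \code{pinwheel_set}.
#' @export
pinwheel_density <- function(pw) pw$density

#' Critical points of an OD map
#'
#' Zeros of the spectral gradient, located by the winding of the complex
#' field dx(o) + i dy(o) (+1: extrema, -1: saddles) and classified by the
#' spectrally evaluated Hessian.
#'
#' @param od \code{od_map}.
#' @param degenerate_tol Hessian determinant tolerance (relative).
#' @return object of class \code{critical_point_set}: data.frame with
#'   x, y, type ("max", "min", "saddle", "degenerate").
#' @export
od_critical_points <- function(od, degenerate_tol = 1e-6) {
  grid <- od$grid
  D <- deriv_wavenumbers(grid)
  if (stats::sd(od$o) < 1e-12 * (abs(mean(od$o)) + 1)) {
    stop("OD field is constant: gradient vanishes everywhere (degenerate)")
  }
  gx <- Re(spec_dx(od$o, D)); gy <- Re(spec_dy(od$o, D))
  g <- gx + 1i * gy
  W <- plaquette_winding(g)
  sing <- which(W != 0, arr.ind = TRUE)
  # ridge/valley LINES of one-dimensional patterns (e.g. stripes) are not
  # isolated critical points; reject gradient zeros that are not isolated
  if (nrow(sing) > 0) {
    iso <- vapply(seq_len(nrow(sing)), function(s) {
      p <- subpixel_zero(g, grid, sing[s, 1], sing[s, 2])
      zero_is_isolated(g, grid, p)
    }, logical(1))
    sing <- sing[iso, , drop = FALSE]
  }
  oxx <- Re(spec_dx(gx, D)); oxy <- Re(spec_dy(gx, D)); oyy <- Re(spec_dy(gy, D))
  hscale <- max(abs(c(oxx, oyy, oxy)))
  rows <- list()
  for (s in seq_len(nrow(sing))) {
    i <- sing[s, 1]; j <- sing[s, 2]
    p <- subpixel_zero(g, grid, i, j)
    hxx <- bilinear_at(oxx, grid, p); hyy <- bilinear_at(oyy, grid, p)
    hxy <- bilinear_at(oxy, grid, p)
    det_h <- hxx * hyy - hxy^2
    type <- if (abs(det_h) < degenerate_tol * hscale^2) "degenerate"
      else if (det_h < 0) "saddle"
      else if (hxx + hyy < 0) "max" else "min"
    rows[[s]] <- data.frame(x = p[1], y = p[2], type = type,
                            winding = W[i, j])
  }
  pts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), type = character(0),
               winding = integer(0))
  structure(list(points = pts, grid = grid), class = "critical_point_set")
}

#' @export
print.critical_point_set <- function(x, ...) {
  cat("OD critical points:\n")
  print(table(x$points$type))
  invisible(x)
}

# bilinear interpolation of a periodic field at a physical point
bilinear_at <- function(f, grid, p) {
  u <- (p[1] %% grid$Lx) / grid$dx; v <- (p[2] %% grid$Ly) / grid$dy
  i <- floor(u); j <- floor(v)
  fu <- u - i; fv <- v - j
  i0 <- (i %% grid$nx) + 1; j0 <- (j %% grid$ny) + 1
  i1 <- (i0 %% grid$nx) + 1; j1 <- (j0 %% grid$ny) + 1
  (1 - fu) * (1 - fv) * f[i0, j0] + fu * (1 - fv) * f[i1, j0] +
    (1 - fu) * fv * f[i0, j1] + fu * fv * f[i1, j1]
}

#' Classify pinwheel positions relative to the OD map
#'
#' Each pinwheel is matched to the nearest OD critical point within
#' \code{tol}; unmatched pinwheels closer than \code{tol} to the OD zero
#' contour (estimated as |o| / |grad o|) are "near_border", the rest
#' "other".
#'
#' @param pw \code{pinwheel_set}.
#' @param od \code{od_map}.
#' @param tol matching tolerance in length units (default Lambda/20).
#' @return list with \code{counts} (at_max, at_min, at_saddle, near_border,
#'   other) and the per-pinwheel \code{classes}.
#' @export
classify_pinwheel_positions <- function(pw, od, tol = NULL) {
  grid <- od$grid
  if (is.null(tol)) tol <- grid$lambda / 20
  cp <- od_critical_points(od)
  D <- deriv_wavenumbers(grid)
  gx <- Re(spec_dx(od$o, D)); gy <- Re(spec_dy(od$o, D))
  gmod <- sqrt(gx^2 + gy^2)
  classes <- character(pw$n)
  for (i in seq_len(pw$n)) {
    p <- c(pw$pinwheels$x[i], pw$pinwheels$y[i])
    if (nrow(cp$points) > 0) {
      dists <- vapply(seq_len(nrow(cp$points)), function(s)
        torus_dist(p, c(cp$points$x[s], cp$points$y[s]), grid), numeric(1))
      s <- which.min(dists)
    } else dists <- Inf
    if (nrow(cp$points) > 0 && dists[s] < tol) {
      classes[i] <- paste0("at_", cp$points$type[s])
    } else {
      dist_border <- abs(bilinear_at(od$o, grid, p)) /
        max(bilinear_at(gmod, grid, p), 1e-12)
      classes[i] <- if (dist_border < tol) "near_border" else "other"
    }
  }
  counts <- c(at_max = sum(classes == "at_max"),
              at_min = sum(classes == "at_min"),
              at_saddle = sum(classes == "at_saddle"),
              near_border = sum(classes == "near_border"),
              other = sum(classes == "other" | classes == "at_degenerate"))
  list(counts = counts, classes = classes)
}

# OP gradient of the orientation angle: grad theta = Im(conj(z) grad z)/(2|z|^2)
theta_gradient <- function(op, D) {
  zx <- spec_dx(op$z, D); zy <- spec_dy(op$z, D)
  denom <- 2 * pmax(Mod(op$z)^2, 1e-300)
  list(tx = Im(Conj(op$z) * zx) / denom, ty = Im(Conj(op$z) * zy) / denom)
}

#' Intersection angles between iso-orientation contours and OD borders
#'
#' Extracts the o = 0 contour (marching squares), samples it at segment
#' midpoints, and measures the angle between the OD border tangent and the
#' iso-orientation contour (perpendicular to grad theta), folded into
#' [0, 90] degrees.  Each sample is weighted by the magnitude of the OP
#' gradient |grad theta| (times the segment length), emphasizing the
#' regions carrying intersection-angle information.
#'
#' @param op,od the two maps.
#' @param nbins number of histogram bins over [0, 90] degrees.
#' @return object of class \code{angle_histogram}: \code{breaks},
#'   \code{density} (normalized to sum 1), \code{mean_angle},
#'   \code{mode_angle}, \code{samples} data.frame.
#' @export
intersection_angles <- function(op, od, nbins = 18) {
  grid <- od$grid
  if (max(od$o) <= 0 || min(od$o) >= 0) {
    stop("OD zero contour is empty: field does not change sign")
  }
  cl <- grDevices::contourLines(grid$x, grid$y, od$o, levels = 0)
  if (length(cl) == 0) stop("OD zero contour is empty")
  D <- deriv_wavenumbers(grid)
  tg <- theta_gradient(op, D)
  ogx <- Re(spec_dx(od$o, D)); ogy <- Re(spec_dy(od$o, D))
  ang <- numeric(0); wt <- numeric(0)
  # the marching-squares polyline supplies sample points and arc-length
  # weights; both tangents are taken from the spectrally evaluated gradients
  # (iso-orientation line perpendicular to grad theta, OD border
  # perpendicular to grad o), which is far more accurate than the polyline
  # segment direction
  for (seg in cl) {
    n <- length(seg$x)
    if (n < 2) next
    mx <- (seg$x[-1] + seg$x[-n]) / 2
    my <- (seg$y[-1] + seg$y[-n]) / 2
    dx <- diff(seg$x); dy <- diff(seg$y)
    len <- sqrt(dx^2 + dy^2)
    keep <- len > 1e-12
    for (s in which(keep)) {
      p <- c(mx[s], my[s])
      gtx <- bilinear_at(tg$tx, grid, p); gty <- bilinear_at(tg$ty, grid, p)
      gmod <- sqrt(gtx^2 + gty^2)
      box <- bilinear_at(ogx, grid, p); boy <- bilinear_at(ogy, grid, p)
      bmod <- sqrt(box^2 + boy^2)
      if (gmod < 1e-12 || bmod < 1e-12) next
      # angle between the two contours = angle between their normals
      a <- acos(min(1, abs((gtx * box + gty * boy) / (gmod * bmod)))) * 180 / pi
      ang <- c(ang, a); wt <- c(wt, gmod * len[s])
    }
  }
  if (length(ang) == 0) stop("no usable contour samples")
  breaks <- seq(0, 90, length.out = nbins + 1)
  bins <- cut(ang, breaks, include.lowest = TRUE)
  dens <- tapply(wt, bins, sum, default = 0)
  dens <- dens / sum(dens)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  structure(list(breaks = breaks, density = as.numeric(dens),
                 mean_angle = sum(ang * wt) / sum(wt),
                 mode_angle = mids[which.max(dens)],
                 samples = data.frame(angle = ang, weight = wt)),
            class = "angle_histogram")
}

#' @export
print.angle_histogram <- function(x, ...) {
  cat(sprintf("intersection angles: weighted mean %.2f deg, mode %.1f deg (%d samples)\n",
              x$mean_angle, x$mode_angle, nrow(x$samples)))
  invisible(x)
}

#' Distribution of preferred orientations
#'
#' Area-weighted histogram of theta over [0, pi) with peak detection
#' (cyclic local maxima exceeding the uniform level).
#'
#' @param op \code{op_map}.
#' @param nbins number of bins.
#' @param min_selectivity pixels with |z| below this fraction of the mean
#'   selectivity are excluded (unselective).
#' @param peak_rel a bin is a peak if it is a cyclic local maximum and
#'   exceeds the uniform density by this relative factor.
#' @return list with \code{breaks}, \code{density} (sums to 1),
#'   \code{peaks} (theta values), \code{n_peaks},
#'   \code{n_represented} (bins with non-negligible mass).
#' @export
orientation_histogram <- function(op, nbins = 72, min_selectivity = 1e-3,
                                  peak_rel = 1.1) {
  th <- op_theta(op)
  sel <- Mod(op$z)
  keep <- sel > min_selectivity * mean(sel)
  breaks <- seq(0, pi, length.out = nbins + 1)
  h <- tabulate(findInterval(th[keep], breaks, rightmost.closed = TRUE),
                nbins)
  dens <- h / sum(h)
  uni <- 1 / nbins
  # cyclic triangular smoothing suppresses pixelation noise before peak
  # detection
  sm <- (c(dens[nbins], dens[-nbins]) + 2 * dens + c(dens[-1], dens[1])) / 4
  prev <- c(sm[nbins], sm[-nbins]); nxt <- c(sm[-1], sm[1])
  is_peak <- sm > peak_rel * uni & sm > prev & sm >= nxt
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(breaks = breaks, density = dens, peaks = mids[is_peak],
       n_peaks = sum(is_peak),
       n_represented = sum(dens > 0.1 * uni))
}
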