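# Periodic grids and the two order-parameter fields.
#
# The domain is a rectangle Lx = n_cells_x * Lambda, Ly = n_cells_y *
# (2 Lambda / sqrt(3)) with periodic boundaries, chosen so that the
# hexagonal triad wavevectors (60 degrees apart, k_1 along +x) fall exactly
# on grid Fourier modes.  Commensurability requires n_cells_x to be even:
# the oblique wavevectors k_2, k_3 have x-index n_cells_x / 2.  One
# hexagonal primitive cell has area 2 Lambda^2 / sqrt(3), so the domain
# covers n_cells_x * n_cells_y primitive cells.

#' Construct a commensurate periodic grid
#'
#' @param nx,ny pixel counts (>= 32).
#' @param n_cells_x,n_cells_y domain extent; the domain covers
#'   \code{n_cells_x * n_cells_y} hexagonal unit cells.  \code{n_cells_x}
#'   must be even for the oblique triad wavevectors to be exact grid modes.
#' @param lambda typical wavelength (default 1, so kc = 2 pi).
#' @return object of class \code{grid_spec}.
#' @export
make_grid <- function(nx = 128, ny = 128, n_cells_x = 4, n_cells_y = 4,
                      lambda = 1) {
  stopifnot(nx >= 32, ny >= 32, n_cells_x >= 1, n_cells_y >= 1)
  if (n_cells_x %% 2 != 0) {
    stop("n_cells_x must be even: the oblique triad wavevectors (x-index ",
         "n_cells_x/2) are not exact grid modes otherwise")
  }
  kc <- 2 * pi / lambda
  Lx <- n_cells_x * lambda
  Ly <- n_cells_y * 2 * lambda / sqrt(3)
  g <- structure(list(nx = nx, ny = ny,
                      n_cells_x = n_cells_x, n_cells_y = n_cells_y,
                      lambda = lambda, kc = kc, Lx = Lx, Ly = Ly,
                      x = seq(0, Lx, length.out = nx + 1)[1:nx],
                      y = seq(0, Ly, length.out = ny + 1)[1:ny],
                      dx = Lx / nx, dy = Ly / ny),
                 class = "grid_spec")
  # every triad mode must land on an exact grid mode below Nyquist
  idx <- grid_mode_index(g, mode_k(rbind(op_star(), od_star()), kc))
  if (any(abs(idx$ix) > nx / 2 - 1) || any(abs(idx$iy) > ny / 2 - 1)) {
    stop("grid too coarse: triad wavevectors beyond the Nyquist mode")
  }
  g
}

#' Rectangular periodic grid without the hexagonal aspect ratio
#'
#' A square-cell variant (Ly = n_cells_y * lambda) used for stripe
#' configurations in which orthogonal wavevector pairs must be grid modes;
#' hexagonal planforms are not commensurate on it.
#' @inheritParams make_grid
#' @export
make_grid_square <- function(nx = 128, ny = 128, n_cells_x = 4, n_cells_y = 4,
                             lambda = 1) {
  stopifnot(nx >= 32, ny >= 32)
  kc <- 2 * pi / lambda
  Lx <- n_cells_x * lambda; Ly <- n_cells_y * lambda
  structure(list(nx = nx, ny = ny,
                 n_cells_x = n_cells_x, n_cells_y = n_cells_y,
                 lambda = lambda, kc = kc, Lx = Lx, Ly = Ly,
                 x = seq(0, Lx, length.out = nx + 1)[1:nx],
                 y = seq(0, Ly, length.out = ny + 1)[1:ny],
                 dx = Lx / nx, dy = Ly / ny),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("periodic grid %d x %d, Lx = %.4g, Ly = %.4g (lambda = %g, kc = %.4g)\n",
              x$nx, x$ny, x$Lx, x$Ly, x$lambda, x$kc))
  invisible(x)
}

# fractional Fourier indices of physical wavevectors
grid_mode_index <- function(grid, k) {
  list(ix = k[, 1] * grid$Lx / (2 * pi), iy = k[, 2] * grid$Ly / (2 * pi))
}

# signed FFT wavenumbers
fft_freqs <- function(n, L) {
  j <- c(0:(floor(n / 2)), (-(ceiling(n / 2) - 1)):-1)
  2 * pi * j / L
}

#' Fourier wavenumber matrices of a grid
#' @param grid \code{grid_spec}.
#' @return list with matrices \code{KX}, \code{KY}, \code{K2} (nx x ny).
#' @export
grid_wavenumbers <- function(grid) {
  kx <- fft_freqs(grid$nx, grid$Lx)
  ky <- fft_freqs(grid$ny, grid$Ly)
  KX <- matrix(kx, grid$nx, grid$ny)
  KY <- matrix(ky, grid$nx, grid$ny, byrow = TRUE)
  list(KX = KX, KY = KY, K2 = KX^2 + KY^2)
}

#' Orientation-preference map
#'
#' Complex order parameter z on a grid; the preferred orientation is
#' \code{arg(z)/2} (cyclic with period pi) and the selectivity \code{|z|}.
#' @param z complex matrix (nx x ny).
#' @param grid \code{grid_spec}.
#' @export
op_map <- function(z, grid) {
  stopifnot(is.matrix(z), nrow(z) == grid$nx, ncol(z) == grid$ny)
  structure(list(z = z, grid = grid), class = "op_map")
}

#' Preferred-orientation angle of an OP map, in [0, pi)
#' @param op \code{op_map}.
#' @export
op_theta <- function(op) (Arg(op$z) / 2) %% pi

#' Orientation selectivity |z|
#' @param op \code{op_map}.
#' @export
op_selectivity <- function(op) Mod(op$z)

#' Ocular-dominance map
#'
#' Real field o on a grid; positive values mean contralateral, negative
#' ipsilateral eye dominance.
#' @param o numeric matrix.
#' @param grid \code{grid_spec}.
#' @param gamma OD bias used to generate the map (bookkeeping).
#' @param delta constant shift of the quadratic-term mapping (bookkeeping).
#' @export
od_map <- function(o, grid, gamma = 0, delta = 0) {
  stopifnot(is.matrix(o), nrow(o) == grid$nx, ncol(o) == grid$ny)
  structure(list(o = o, grid = grid, gamma = gamma, delta = delta),
            class = "od_map")
}

#' @export
print.op_map <- function(x, ...) {
  cat(sprintf("OP map on %dx%d grid; mean selectivity %.4g\n",
              x$grid$nx, x$grid$ny, mean(Mod(x$z))))
  invisible(x)
}

#' @export
print.od_map <- function(x, ...) {
  cat(sprintf("OD map on %dx%d grid; contra fraction %.3f (gamma = %g)\n",
              x$grid$nx, x$grid$ny, mean(x$o > 0), x$gamma))
  invisible(x)
}

#' Apply a global orientation shift
#'
#' z -> exp(i phi) z; the preferred orientation shifts by phi/2 (mod pi).
#' @param op \code{op_map}.
#' @param phi shift of the z-phase.
#' @export
apply_orientation_shift <- function(op, phi) {
  op_map(op$z * exp(1i * phi), op$grid)
}

#' Planform amplitudes
#'
#' Active-mode description of a hexagonal planform: three OP amplitudes
#' \code{A} on the wavevectors \code{k_j} (60 degrees apart, k_1 along +x),
#' their opposite-mode amplitudes \code{Aopp}, three OD amplitudes \code{B}
#' on the triad \code{q_1 + q_2 + q_3 = 0}, and the OD shift \code{delta}.
#' @param A,Aopp complex length-3 vectors.
#' @param B complex length-3 vector.
#' @param delta OD constant shift.
#' @param lambda wavelength of all modes.
#' @export
planform_amplitudes <- function(A = rep(0i, 3), Aopp = rep(0i, 3),
                                B = rep(0i, 3), delta = 0, lambda = 1) {
  kc <- 2 * pi / lambda
  structure(list(A = as.complex(A), Aopp = as.complex(Aopp),
                 B = as.complex(B), delta = delta, lambda = lambda, kc = kc,
                 k_op = mode_k(op_star(), kc), k_od = mode_k(od_star(), kc)),
            class = "planform_amplitudes")
}

# evaluate a sum of plane waves on the grid; errors if not commensurate
eval_modes <- function(grid, k, coef) {
  acc <- matrix(0 + 0i, grid$nx, grid$ny)
  idx <- grid_mode_index(grid, k)
  for (m in seq_len(nrow(k))) {
    if (coef[m] == 0) next
    if (max(abs(idx$ix[m] - round(idx$ix[m])),
            abs(idx$iy[m] - round(idx$iy[m]))) > 1e-9) {
      stop(sprintf("wavevector (%.4g, %.4g) is not commensurate with the grid",
                   k[m, 1], k[m, 2]))
    }
    acc <- acc + coef[m] * outer(exp(1i * k[m, 1] * grid$x),
                                 exp(1i * k[m, 2] * grid$y))
  }
  acc
}

#' Synthesize OP and OD fields from planform amplitudes
#'
#' z(x) = sum_j A_j e^{i k_j x} + Aopp_j e^{-i k_j x};
#' o(x) = delta + sum_j B_j e^{i q_j x} + c.c.
#' @param grid \code{grid_spec}.
#' @param amps \code{planform_amplitudes}.
#' @param gamma bias bookkeeping value stored on the OD map.
#' @return list with \code{op} and \code{od}.
#' @export
synthesize_planform <- function(grid, amps, gamma = 0) {
  stopifnot(inherits(amps, "planform_amplitudes"))
  if (abs(grid$kc - amps$kc) > 1e-12) {
    stop("planform wavelength does not match the grid")
  }
  z <- eval_modes(grid, rbind(amps$k_op, -amps$k_op), c(amps$A, amps$Aopp))
  o <- Re(eval_modes(grid, rbind(amps$k_od, -amps$k_od),
                     c(amps$B, Conj(amps$B)))) + amps$delta
  list(op = op_map(z, grid), od = od_map(o, grid, gamma = gamma, delta = amps$delta))
}

#' Project fields onto the active planform modes
#'
#' Exact inverse of \code{synthesize_planform} for commensurate fields:
#' \code{A_j = <z e^{-i k_j x}>} etc.
#' @param op \code{op_map}; \code{od} an \code{od_map} (optional).
#' @param od optional \code{od_map}.
#' @param lambda wavelength of the mode star.
#' @export
project_planform <- function(op, od = NULL, lambda = 1) {
  grid <- op$grid
  kc <- 2 * pi / lambda
  Kop <- mode_k(op_star(), kc)
  proj <- function(f, k) {
    ph <- eval_modes(grid, matrix(-k, ncol = 2), complex(real = 1))
    mean(f * ph)
  }
  A <- vapply(1:3, function(j) proj(op$z, Kop[j, ]), complex(1))
  Aopp <- vapply(1:3, function(j) proj(op$z, -Kop[j, ]), complex(1))
  B <- rep(0i, 3); delta <- 0
  if (!is.null(od)) {
    Kod <- mode_k(od_star(), kc)
    B <- vapply(1:3, function(j) proj(od$o + 0i, Kod[j, ]), complex(1))
    delta <- mean(od$o)
  }
  planform_amplitudes(A, Aopp, B, delta, lambda)
}

#' Closed-form solution fixtures
#'
#' Synthesizes any named stationary solution of the model on a grid, using
#' the stationary formulas of the OD and OP amplitude modules.  Errors (with
#' the violated border in the message) when the requested label does not
#' exist at the parameter point.
#'
#' @param label one of \code{op_stripes}, \code{op_rhombic},
#'   \code{op_scotoma}, \code{hpwc_ipsi}, \code{hpwc_braitenberg},
#'   \code{od_stripes}, \code{od_hexagons}, \code{od_constant}.
#' @param grid \code{grid_spec}.
#' @param params \code{model_params}.
#' @return list with \code{op} (NULL for pure OD labels) and \code{od}.
#' @export
fixture <- function(label = c("op_stripes", "op_rhombic", "op_scotoma",
                              "hpwc_ipsi", "hpwc_braitenberg",
                              "od_stripes", "od_hexagons", "od_constant"),
                    grid, params = model_params()) {
  label <- match.arg(label)
  lambda <- 2 * pi / params$kc
  od_label <- switch(label,
    od_stripes = "stripes", od_hexagons = "hexagons", od_constant = "constant",
    op_scotoma = "stripes",
    hpwc_ipsi = "hexagons", hpwc_braitenberg = "hexagons",
    op_stripes = , op_rhombic = if (params$c_coupling == 0) "stripes" else "stripes")
  odst <- od_stationary(od_label, params$gamma, params$r_od, params$kc)
  if (label %in% c("od_stripes", "od_hexagons", "od_constant")) {
    amps <- planform_amplitudes(B = odst$B, delta = odst$delta, lambda = lambda)
    return(list(op = NULL, od = synthesize_planform(grid, amps, gamma = params$gamma)$od))
  }
  branch <- switch(label,
    op_stripes = "op_stripes", op_rhombic = "op_rhombic",
    op_scotoma = "op_scotoma",
    hpwc_ipsi = "hpwc_psi_a", hpwc_braitenberg = "hpwc_psi_a")
  if (label == "hpwc_ipsi" && params$kind != "product_low") {
    stop("hpwc_ipsi is the stable uniform solution of the product-type energy")
  }
  if (label == "hpwc_braitenberg" && params$kind != "gradient_low") {
    stop("hpwc_braitenberg is the stable uniform solution of the gradient-type energy")
  }
  sol <- stationary_branch(branch, params, od_branch = od_label)
  if (!sol$exists) stop("fixture '", label, "' does not exist here: ", sol$note)
  amps <- planform_amplitudes(sol$A, sol$Aopp, odst$B, odst$delta, lambda)
  synthesize_planform(grid, amps, gamma = params$gamma)
}
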