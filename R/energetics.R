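# Field-level energies: single-field Swift-Hohenberg functionals, the four
# positive-definite coupling energies and their functional derivatives
# (interaction terms of the dynamics).  All derivatives are spectral; the
# gradient-descent identity dE = -2 eps Re<term, h> is exact on the grid
# because products are pointwise and the spectral derivative is
# skew-adjoint (Nyquist derivative set to zero).

fft2 <- function(f) stats::fft(f)
ifft2 <- function(F) stats::fft(F, inverse = TRUE) / length(F)

# spectral derivative matrices with zeroed Nyquist mode
deriv_wavenumbers <- function(grid) {
  w <- grid_wavenumbers(grid)
  kx <- fft_freqs(grid$nx, grid$Lx); ky <- fft_freqs(grid$ny, grid$Ly)
  if (grid$nx %% 2 == 0) kx[grid$nx / 2 + 1] <- 0
  if (grid$ny %% 2 == 0) ky[grid$ny / 2 + 1] <- 0
  list(KX = matrix(kx, grid$nx, grid$ny),
       KY = matrix(ky, grid$nx, grid$ny, byrow = TRUE),
       K2 = w$K2)
}

spec_dx <- function(f, D) ifft2(1i * D$KX * fft2(f))
spec_dy <- function(f, D) ifft2(1i * D$KY * fft2(f))

#' Swift-Hohenberg growth spectrum
#'
#' lambda(k) = r - (kc^2 - k^2)^2; maximal (= r) on the critical circle
#' k = kc.  For r < 0 all modes are damped.
#' @param k wavenumber (vector ok).
#' @param r control parameter.
#' @param kc critical wavenumber.
#' @export
sh_spectrum <- function(k, r, kc = 2 * pi) r - (kc^2 - k^2)^2

#' Single-field Swift-Hohenberg energy (per unit area)
#'
#' Complex field z: \code{E = -<conj(z) L z> + <|z|^4>/2}; real field o:
#' \code{E = -<o L o>/2 + <o^4>/4 - gamma <o>}, with L evaluated spectrally.
#' @param field \code{op_map}, \code{od_map}, or a matrix.
#' @param r control parameter.
#' @param kc critical wavenumber.
#' @param gamma bias (real field only).
#' @param grid required when \code{field} is a bare matrix.
#' @export
sh_energy <- function(field, r, kc = 2 * pi, gamma = 0, grid = NULL) {
  if (inherits(field, "op_map")) { f <- field$z; grid <- field$grid; cplx <- TRUE }
  else if (inherits(field, "od_map")) { f <- field$o; grid <- field$grid; cplx <- FALSE }
  else { f <- field; cplx <- is.complex(field) }
  stopifnot(!is.null(grid))
  w <- grid_wavenumbers(grid)
  lam <- sh_spectrum(sqrt(w$K2), r, kc)
  fh <- fft2(f) / length(f)
  quad <- sum(lam * Mod(fh)^2)
  if (cplx) {
    -quad + 0.5 * mean(Mod(f)^4)
  } else {
    -quad / 2 + 0.25 * mean(Re(f)^4) - gamma * mean(Re(f))
  }
}

# pointwise density of each coupling energy (without the constant c)
coupling_density <- function(z, o, kind, D) {
  switch(kind,
    product_low = o^2 * Mod(z)^2,
    product_high = o^4 * Mod(z)^4,
    gradient_low = ,
    gradient_high = {
      s <- spec_dx(o, D) * spec_dx(z, D) + spec_dy(o, D) * spec_dy(z, D)
      if (kind == "gradient_low") Mod(s)^2 else Mod(s)^4
    },
    stop("unknown coupling kind: ", kind))
}

#' Inter-map coupling energy (per unit area)
#'
#' product_low: \code{c <o^2 |z|^2>}; gradient_low:
#' \code{c <|grad o . grad z|^2>}; product_high: \code{c <o^4 |z|^4>};
#' gradient_high: \code{c <|grad o . grad z|^4>}.  Always >= 0.
#' @param op \code{op_map}; \code{od} \code{od_map}.
#' @param od \code{od_map}.
#' @param kind coupling kind.
#' @param c_coupling coupling constant.
#' @export
coupling_energy <- function(op, od, kind = "product_low", c_coupling = 1) {
  grid <- op$grid
  D <- deriv_wavenumbers(grid)
  o <- od$o
  dens <- coupling_density(op$z, o, kind, D)
  c_coupling * Re(mean(dens))
}

#' Interaction terms of the coupled dynamics
#'
#' Functional derivatives of the selected coupling energy: returns
#' \code{dz = -dU/dconj(z)} (enters the z-equation) and
#' \code{do = -dU/do} (enters the o-equation).
#' @inheritParams coupling_energy
#' @return list with complex matrix \code{dz} and real matrix \code{do}.
#' @export
coupling_gradients <- function(op, od, kind = "product_low", c_coupling = 1) {
  grid <- op$grid
  D <- deriv_wavenumbers(grid)
  z <- op$z; o <- od$o
  cc <- c_coupling
  div <- function(fx, fy) spec_dx(fx, D) + spec_dy(fy, D)
  if (kind == "product_low") {
    list(dz = -cc * o^2 * z, do = -2 * cc * o * Mod(z)^2)
  } else if (kind == "product_high") {
    list(dz = -2 * cc * o^4 * Mod(z)^2 * z, do = -4 * cc * o^3 * Mod(z)^4)
  } else if (kind %in% c("gradient_low", "gradient_high")) {
    ox <- Re(spec_dx(o, D)); oy <- Re(spec_dy(o, D))
    zx <- spec_dx(z, D); zy <- spec_dy(z, D)
    s <- ox * zx + oy * zy
    if (kind == "gradient_low") {
      dz <- cc * div(s * ox, s * oy)
      do_ <- 2 * cc * Re(div(Conj(s) * zx, Conj(s) * zy))
    } else {
      w <- Mod(s)^2
      dz <- 2 * cc * div(w * s * ox, w * s * oy)
      do_ <- 4 * cc * Re(div(w * Conj(s) * zx, w * Conj(s) * zy))
    }
    list(dz = dz, do = do_)
  } else stop("unknown coupling kind: ", kind)
}

#' Energy decomposition of a coupled state
#'
#' @param op,od the two maps.
#' @param params \code{model_params}.
#' @return list with \code{E_op}, \code{E_od}, \code{E_coupling},
#'   \code{E_total}.
#' @export
total_energy <- function(op, od, params) {
  E_op <- Re(sh_energy(op, params$r_op, params$kc))
  E_od <- Re(sh_energy(od, params$r_od, params$kc, gamma = params$gamma))
  E_c <- if (params$c_coupling > 0) {
    coupling_energy(op, od, params$kind, params$c_coupling)
  } else 0
  list(E_op = E_op, E_od = E_od, E_coupling = E_c,
       E_total = E_op + E_od + E_c)
}
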