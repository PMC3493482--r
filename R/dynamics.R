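# Spectral time integration of the coupled gradient-descent dynamics
#   dz/dt = (r_op - (kc^2 + Lap)^2) z - |z|^2 z + coupling term
#   do/dt = (r_od - (kc^2 + Lap)^2) o - o^3 + gamma + coupling term
# by first-order exponential time differencing: the diagonal linear operator
# is integrated exactly in Fourier space, the nonlinear terms explicitly.
# Products are evaluated pointwise and the result is dealiased by a 2/3-rule
# spectral mask (near-threshold fields concentrate at |k| ~ kc, far below
# the mask for all practical grids; the mask guards the strong-coupling
# higher-order densities).

dealias_mask <- function(grid) {
  w <- grid_wavenumbers(grid)
  kx_max <- pi * grid$nx / grid$Lx
  ky_max <- pi * grid$ny / grid$Ly
  (abs(w$KX) <= 2 / 3 * kx_max) & (abs(w$KY) <= 2 / 3 * ky_max)
}

#' Integrate the coupled field dynamics
#'
#' @param op,od initial maps (shared grid).
#' @param params \code{model_params}.
#' @param T total integration time.
#' @param dt time step.
#' @param freeze_od if TRUE the OD field is held fixed (no backreaction;
#'   unidirectional coupling limit).
#' @param snapshot_every record a snapshot every this many time units
#'   (default: only the final state).
#' @param energy_every record the energy decomposition every this many steps.
#' @param energy_tol tolerated energy increase per unit time before a
#'   warning is raised (gradient descent must be monotone up to integrator
#'   error).
#' @return object of class \code{map_trajectory}: final \code{op}, \code{od},
#'   \code{times}, \code{snapshots}, \code{energies} (data.frame),
#'   \code{residual} (relative field change per unit time at the end).
#' @export
integrate_maps <- function(op, od, params, T, dt = 0.5, freeze_od = FALSE,
                           snapshot_every = NULL, energy_every = 20,
                           energy_tol = 1e-6) {
  grid <- op$grid
  stopifnot(identical(dim(op$z), dim(od$o)), dt > 0)
  w <- grid_wavenumbers(grid)
  lam <- sh_spectrum(sqrt(w$K2), 0, params$kc)   # r added per field below
  lam_z <- lam + params$r_op
  lam_o <- lam + params$r_od
  Ez <- exp(lam_z * dt); Eo <- exp(lam_o * dt)
  phi1 <- function(l) ifelse(abs(l * dt) > 1e-8, (exp(l * dt) - 1) / l, dt * (1 + l * dt / 2))
  Pz <- phi1(lam_z); Po <- phi1(lam_o)
  mask <- dealias_mask(grid)
  nsteps <- max(1L, round(T / dt))
  z <- op$z; o <- od$o
  zh <- fft2(z); oh <- fft2(o)
  cc <- params$c_coupling
  times <- numeric(0); snaps <- list()
  erows <- list()
  snap_steps <- if (!is.null(snapshot_every)) {
    unique(pmax(1L, round(seq(snapshot_every, T, by = snapshot_every) / dt)))
  } else integer(0)
  last_E <- NULL; warned <- FALSE
  zprev <- z
  for (n in seq_len(nsteps)) {
    z <- ifft2(zh); o <- Re(ifft2(oh))
    if (any(!is.finite(Re(z))) || any(!is.finite(o))) {
      stop(sprintf("field blow-up (NaN/Inf) at t = %.4g; reduce dt", (n - 1) * dt))
    }
    zprev <- z
    Nz <- -Mod(z)^2 * z
    No <- -o^3 + params$gamma
    if (cc > 0) {
      cg <- coupling_gradients(op_map(z, grid), od_map(o, grid), params$kind, cc)
      Nz <- Nz + cg$dz
      if (!freeze_od) No <- No + Re(cg$do)
    }
    Nzh <- fft2(Nz) * mask
    zh <- Ez * zh + Pz * Nzh
    if (!freeze_od) {
      Noh <- fft2(No) * mask
      oh <- Eo * oh + Po * Noh
    }
    if (n %% energy_every == 0 || n == nsteps) {
      zc <- ifft2(zh); oc <- Re(ifft2(oh))
      E <- total_energy(op_map(zc, grid), od_map(oc, grid, gamma = params$gamma), params)
      erows[[length(erows) + 1]] <- data.frame(t = n * dt, E_op = E$E_op,
                                               E_od = E$E_od,
                                               E_coupling = E$E_coupling,
                                               E_total = E$E_total)
      if (!is.null(last_E) && !warned &&
          E$E_total > last_E$E + energy_tol * (n * dt - last_E$t)) {
        warning(sprintf("energy increased by %.3g between t = %.4g and %.4g: dt too large",
                        E$E_total - last_E$E, last_E$t, n * dt))
        warned <- TRUE
      }
      last_E <- list(E = E$E_total, t = n * dt)
    }
    if (n %in% snap_steps) {
      times <- c(times, n * dt)
      snaps[[length(snaps) + 1]] <-
        list(op = op_map(ifft2(zh), grid),
             od = od_map(Re(ifft2(oh)), grid, gamma = params$gamma))
    }
  }
  zfin <- ifft2(zh); ofin <- Re(ifft2(oh))
  nz <- sqrt(mean(Mod(zfin)^2))
  res <- sqrt(mean(Mod(zfin - zprev)^2)) / (dt * max(nz, 1e-12))
  structure(list(op = op_map(zfin, grid),
                 od = od_map(ofin, grid, gamma = params$gamma,
                             delta = params$delta),
                 times = times, snapshots = snaps,
                 energies = do.call(rbind, erows),
                 residual = res, dt = dt, T = T),
            class = "map_trajectory")
}

#' @export
print.map_trajectory <- function(x, ...) {
  cat(sprintf("trajectory to T = %g (dt = %g); final residual %.3g\n",
              x$T, x$dt, x$residual))
  if (!is.null(x$energies)) {
    n <- nrow(x$energies)
    cat(sprintf("  E_total: %.6g -> %.6g\n", x$energies$E_total[1],
                x$energies$E_total[n]))
  }
  invisible(x)
}

#' Relax the coupled dynamics to an attractor
#'
#' Integrates in chunks until the relative field change per unit time drops
#' below \code{tol} or \code{max_T} is reached.  Non-convergence is reported
#' in the returned object, not raised.
#'
#' @inheritParams integrate_maps
#' @param tol stopping threshold on the relative L2 change per unit time.
#' @param chunk_T chunk length between convergence checks.
#' @param max_T maximum total integration time.
#' @return list with final \code{op}, \code{od}, \code{converged},
#'   \code{residual}, \code{T_used}, \code{energies}.
#' @export
relax_to_attractor <- function(op, od, params, tol = 1e-7, dt = 0.5,
                               chunk_T = 50, max_T = 5000,
                               freeze_od = FALSE) {
  t_used <- 0; conv <- FALSE; res <- NA_real_
  energies <- NULL
  while (t_used < max_T) {
    tr <- integrate_maps(op, od, params, T = chunk_T, dt = dt,
                         freeze_od = freeze_od)
    op <- tr$op; od <- tr$od
    t_used <- t_used + chunk_T
    res <- tr$residual
    energies <- rbind(energies, within(tr$energies, t <- t + t_used - chunk_T))
    if (is.finite(res) && res < tol) { conv <- TRUE; break }
  }
  list(op = op, od = od, converged = conv, residual = res,
       T_used = t_used, energies = energies)
}

#' White-noise initial condition
#'
#' Zero-mean complex (or real) white noise of the given RMS amplitude.
#' @param grid \code{grid_spec}.
#' @param amplitude RMS amplitude (default 1e-3).
#' @param complex_field complex or real field.
#' @param seed optional RNG seed.
#' @export
noise_field <- function(grid, amplitude = 1e-3, complex_field = TRUE,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- grid$nx * grid$ny
  f <- if (complex_field) {
    matrix(complex(real = rnorm(n), imaginary = rnorm(n)), grid$nx) * amplitude / sqrt(2)
  } else {
    matrix(rnorm(n), grid$nx) * amplitude
  }
  f - mean(f)
}
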