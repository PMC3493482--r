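# Snapshot and report I/O.  Field snapshots are stored as RDS files with a
# flat, documented structure (op real/imag, od values, grid attributes);
# analysis reports are plain CSV.

#' Write an OP/OD field snapshot
#'
#' @param op \code{op_map} (or NULL).
#' @param od \code{od_map} (or NULL).
#' @param file output path (.rds).
#' @param params optional \code{model_params} stored alongside.
#' @export
write_fields <- function(op, od, file, params = NULL) {
  grid <- if (!is.null(op)) op$grid else od$grid
  obj <- list(op_real = if (!is.null(op)) Re(op$z),
              op_imag = if (!is.null(op)) Im(op$z),
              od_values = if (!is.null(od)) od$o,
              nx = grid$nx, ny = grid$ny, Lx = grid$Lx, Ly = grid$Ly,
              lambda = grid$lambda, kc = grid$kc,
              n_cells_x = grid$n_cells_x, n_cells_y = grid$n_cells_y,
              gamma = if (!is.null(od)) od$gamma else NA_real_,
              delta = if (!is.null(od)) od$delta else NA_real_,
              params = params)
  saveRDS(obj, file)
  invisible(file)
}

#' Read an OP/OD field snapshot written by \code{write_fields}
#' @param file path.
#' @return list with \code{op}, \code{od}, \code{params}.
#' @export
read_fields <- function(file) {
  obj <- readRDS(file)
  grid <- if (!is.null(obj$n_cells_x) && obj$n_cells_x %% 2 == 0 &&
              abs(obj$Ly - obj$n_cells_y * 2 * obj$lambda / sqrt(3)) < 1e-9) {
    make_grid(obj$nx, obj$ny, obj$n_cells_x, obj$n_cells_y, obj$lambda)
  } else {
    make_grid_square(obj$nx, obj$ny, obj$n_cells_x, obj$n_cells_y, obj$lambda)
  }
  op <- if (!is.null(obj$op_real)) {
    op_map(matrix(complex(real = obj$op_real, imaginary = obj$op_imag),
                  obj$nx, obj$ny), grid)
  }
  od <- if (!is.null(obj$od_values)) {
    od_map(obj$od_values, grid, gamma = obj$gamma, delta = obj$delta)
  }
  list(op = op, od = od, params = obj$params)
}

#' Write the analysis report of a coupled state
#'
#' Emits the pinwheel table (x, y, charge, class), summary statistics, and
#' the two histograms as CSV files sharing a path prefix.
#' @param op,od the maps.
#' @param prefix output path prefix.
#' @return named vector of written files.
#' @export
write_analysis_report <- function(op, od, prefix) {
  pw <- find_pinwheels(op)
  cls <- classify_pinwheel_positions(pw, od)
  tab <- pw$pinwheels
  tab$class <- cls$classes
  f1 <- paste0(prefix, "_pinwheels.csv")
  utils::write.csv(tab, f1, row.names = FALSE)
  oh <- orientation_histogram(op)
  f2 <- paste0(prefix, "_orientation_histogram.csv")
  utils::write.csv(data.frame(theta_lo = oh$breaks[-length(oh$breaks)],
                              theta_hi = oh$breaks[-1],
                              density = oh$density), f2, row.names = FALSE)
  files <- c(pinwheels = f1, orientation = f2)
  ia <- tryCatch(intersection_angles(op, od), error = function(e) NULL)
  if (!is.null(ia)) {
    f3 <- paste0(prefix, "_intersection_angles.csv")
    utils::write.csv(data.frame(angle_lo = ia$breaks[-length(ia$breaks)],
                                angle_hi = ia$breaks[-1],
                                density = ia$density), f3, row.names = FALSE)
    files <- c(files, angles = f3)
  }
  f4 <- paste0(prefix, "_summary.csv")
  utils::write.csv(data.frame(
    n_pinwheels = pw$n, density_per_lambda2 = pw$density,
    per_unit_cell = pw$per_unit_cell, total_charge = pw$total_charge,
    contra_fraction = pixel_contra_fraction(od)), f4, row.names = FALSE)
  c(files, summary = f4)
}

#' Energy log of a trajectory as CSV
#' @param traj \code{map_trajectory}.
#' @param file path.
#' @export
write_energy_log <- function(traj, file) {
  utils::write.csv(traj$energies, file, row.names = FALSE)
  invisible(file)
}
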