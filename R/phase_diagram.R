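# Phase diagrams: stability regions of the OD subsystem over the rescaled
# bias, and of the coupled OP system over the (bias, rescaled coupling)
# plane.  Cell labels are painted from border curves (the OD borders are
# closed forms; the OP borders are located by bisection on the linear
# stability / existence of the branches), which is also how the borders are
# reported.

#' OD phase diagram (1-D sweep over the rescaled bias)
#'
#' @param r_od bifurcation parameter.
#' @param eta_range range of the rescaled bias.
#' @param n number of sample points.
#' @param kc critical wavenumber.
#' @return object of class \code{od_phase_diagram}: \code{cells} data.frame
#'   (eta, gamma, labels), \code{borders}.
#' @export
od_phase_diagram <- function(r_od, eta_range = c(0, 2.2), n = 221,
                             kc = 2 * pi) {
  b <- od_stability_borders(r_od, kc)
  eta <- seq(eta_range[1], eta_range[2], length.out = n)
  bv <- stats::setNames(b$eta, b$border)
  lab <- vapply(eta, function(e) {
    stable <- c(
      if (e < bv["stripe_loss"]) "stripes",
      if (e > bv["hexagon_onset"] && e < bv["hexagon_loss"]) "hexagons",
      if (e > bv["constant_onset"]) "constant")
    paste(stable, collapse = "+")
  }, character(1))
  structure(list(cells = data.frame(eta = eta,
                                    gamma = od_gamma_from_eta(eta, r_od, kc),
                                    labels = lab),
                 borders = b, r_od = r_od),
            class = "od_phase_diagram")
}

#' @export
print.od_phase_diagram <- function(x, ...) {
  cat("OD phase diagram, r_od =", x$r_od, "\n")
  r <- rle(x$cells$labels)
  lo <- cumsum(c(1, r$lengths))
  for (i in seq_along(r$values)) {
    cat(sprintf("  eta in [%.3f, %.3f]: %s\n", x$cells$eta[lo[i]],
                x$cells$eta[min(lo[i + 1] - 1, nrow(x$cells))], r$values[i]))
  }
  invisible(x)
}

# stable OP labels at one parameter point, given an OD branch
op_stable_labels <- function(params, od_branch) {
  labs <- switch(od_branch,
    stripes = if (params$kind == "product_low")
      c("op_stripes", "op_scotoma") else c("op_stripes", "op_rhombic"),
    hexagons = c("op_stripes", "op_rhombic", "hpwc_psi_a"),
    constant = c("op_stripes", "op_rhombic"))
  out <- character(0)
  any_exists <- FALSE
  for (lb in labs) {
    sol <- tryCatch(stationary_branch(lb, params, od_branch),
                    error = function(e) NULL)
    if (is.null(sol) || !sol$exists) next
    any_exists <- TRUE
    st <- tryCatch(linear_stability(sol), error = function(e) NULL)
    if (!is.null(st) && st$stable) out <- c(out, lb)
  }
  if (length(out) == 0 && !any_exists) out <- "trivial"
  out
}

# bisect the rescaled coupling at which `pred` flips (pred: chat -> logical)
bisect_chat <- function(pred, lo, hi, tol = 1e-3) {
  plo <- pred(lo); phi <- pred(hi)
  if (is.na(plo) || is.na(phi) || plo == phi) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    pm <- pred(mid)
    if (is.na(pm)) return((lo + hi) / 2)
    if (pm == plo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# OP border curves in the OD-hexagon band at one bias value
op_borders_at_eta <- function(kind, eta, params0, tol = 1e-3) {
  gamma <- od_gamma_from_eta(eta, params0$r_od, params0$kc)
  mkp <- function(chat) {
    p <- model_params(params0$r_op, params0$r_od, gamma, kind,
                      c_coupling = 0, kc = params0$kc)
    p$c_coupling <- coupling_from_rescaled(chat, p, "hexagons")
    p
  }
  stable_of <- function(label, chat) {
    p <- mkp(chat)
    sol <- tryCatch(stationary_branch(label, p, "hexagons"),
                    error = function(e) NULL)
    if (is.null(sol) || !sol$exists) return(NA)
    st <- tryCatch(linear_stability(sol), error = function(e) NULL)
    if (is.null(st)) NA else st$stable
  }
  exist_of <- function(label, chat) {
    p <- mkp(chat)
    sol <- tryCatch(stationary_branch(label, p, "hexagons"),
                    error = function(e) NULL)
    !is.null(sol) && sol$exists
  }
  cmax <- if (kind == "product_low") 0.999 else 0.66
  c(hpwc_onset = bisect_chat(function(ch) isTRUE(stable_of("hpwc_psi_a", ch)),
                             1e-3, cmax, tol),
    stripe_loss = bisect_chat(function(ch) isTRUE(stable_of("op_stripes", ch)),
                              1e-3, cmax, tol),
    rhombic_end = bisect_chat(function(ch) exist_of("op_rhombic", ch),
                              1e-3, cmax, tol),
    existence = if (kind == "product_low") 1 else 2 / 3)
}

#' Phase diagram of the coupled OP system
#'
#' Sweeps the (rescaled bias, rescaled coupling) plane.  Within the
#' OD-hexagon band the OP borders (hPWC onset, stripe-like loss, rhombic
#' termination, pattern existence) are located by bisection at each bias
#' value and the cell labels painted from them; in the OD stripe and
#' constant bands the closed-form borders are used.  In rescaled units the
#' diagram is independent of \code{r_op}.
#'
#' @param kind \code{"product_low"} or \code{"gradient_low"}.
#' @param eta_range,chat_range axis ranges (rescaled bias, rescaled coupling).
#' @param resolution cells per axis, length 2.
#' @param params0 base parameters (r_op, r_od, kc).
#' @param border_tol bisection tolerance in the rescaled coupling.
#' @return object of class \code{op_phase_diagram} with \code{cells}
#'   (eta, chat, od_branch, labels), \code{borders} (per-eta border curves),
#'   \code{od_borders}.
#' @export
op_phase_diagram <- function(kind = c("product_low", "gradient_low"),
                             eta_range = c(0.05, 2.1), chat_range = c(0.02, 1.1),
                             resolution = c(21, 21),
                             params0 = model_params(kind = kind),
                             border_tol = 1e-3) {
  kind <- match.arg(kind)
  odb <- od_stability_borders(params0$r_od, params0$kc)
  bv <- stats::setNames(odb$eta, odb$border)
  eta <- seq(eta_range[1], eta_range[2], length.out = resolution[1])
  chat <- seq(chat_range[1], chat_range[2], length.out = resolution[2])
  hex_eta <- eta[eta > bv["hexagon_onset"] & eta < bv["hexagon_loss"]]
  # gradient-type borders are bias independent: compute once
  bl <- list()
  if (length(hex_eta) > 0) {
    if (kind == "gradient_low") {
      b1 <- op_borders_at_eta(kind, stats::median(hex_eta), params0, border_tol)
      for (e in hex_eta) bl[[as.character(e)]] <- b1
    } else {
      for (e in hex_eta) bl[[as.character(e)]] <- op_borders_at_eta(kind, e, params0, border_tol)
    }
  }
  cells <- list()
  for (e in eta) {
    od_stable <- c(if (e < bv["stripe_loss"]) "stripes",
                   if (e > bv["hexagon_onset"] && e < bv["hexagon_loss"]) "hexagons",
                   if (e > bv["constant_onset"]) "constant")
    for (ch in chat) {
      labs <- character(0)
      for (ob in od_stable) {
        labs <- c(labs, paste0(ob, ":", op_labels_from_borders(
          kind, ob, e, ch, bl, params0)))
      }
      cells[[length(cells) + 1]] <- data.frame(
        eta = e, chat = ch,
        labels = paste(unique(labs), collapse = " | "))
    }
  }
  structure(list(kind = kind, cells = do.call(rbind, cells),
                 borders = bl, od_borders = odb, params0 = params0),
            class = "op_phase_diagram")
}

# label logic per OD branch from precomputed borders
op_labels_from_borders <- function(kind, od_branch, eta, chat, bl, params0) {
  gamma <- od_gamma_from_eta(eta, params0$r_od, params0$kc)
  p <- model_params(params0$r_op, params0$r_od, gamma, kind, 0, params0$kc)
  if (od_branch == "stripes") {
    if (kind == "product_low") {
      ods <- od_stationary("stripes", gamma, params0$r_od, params0$kc)
      # rescaled positions of the closed-form borders
      ch_coll <- rescale_coupling({
        p2 <- p; p2$c_coupling <- p$r_op / (p$delta^2 + 4 * ods$B_amp^2); p2
      }, "stripes")
      if (chat < ch_coll) return("op_stripes")
      if (chat < 1) return("op_scotoma")
      return("trivial")
    }
    return("op_stripes_orthogonal")
  }
  if (od_branch == "constant") {
    if (kind == "product_low") {
      ch_sup <- p$r_op / p$delta^2 * p$r_od / (3 * p$r_op)
      return(if (chat < ch_sup) "op_stripes" else "trivial")
    }
    return("op_stripes")
  }
  # hexagons
  b <- bl[[as.character(eta)]]
  if (is.null(b)) return("trivial")
  labs <- character(0)
  if (!is.na(b["stripe_loss"]) && chat < b["stripe_loss"]) labs <- c(labs, "op_stripes")
  if (!is.na(b["rhombic_end"]) && chat < b["rhombic_end"]) labs <- c(labs, "op_rhombic")
  if (!is.na(b["hpwc_onset"]) && chat > b["hpwc_onset"] && chat < b["existence"]) {
    labs <- c(labs, "hpwc")
  }
  if (length(labs) == 0) labs <- if (chat >= b["existence"]) "trivial" else "none"
  paste(labs, collapse = "+")
}

#' @export
print.op_phase_diagram <- function(x, ...) {
  cat(sprintf("OP phase diagram (%s), %d cells\n", x$kind, nrow(x$cells)))
  if (length(x$borders) > 0) {
    b <- x$borders[[1]]
    cat(sprintf("  OD-hexagon band borders (rescaled coupling%s):\n",
                if (x$kind == "gradient_low") ", bias independent" else ", first bias value"))
    for (nm in names(b)) cat(sprintf("    %-12s %.4g\n", nm, b[nm]))
  }
  invisible(x)
}
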