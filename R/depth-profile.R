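# Depth-dependent average Young's modulus estimation from a single curve.
#
# For a heterogeneous sample the modulus fitted over a truncated window
# [0, h_j] is the depth-averaged modulus E(h_j) = (1/h_j) int_0^h_j E(y) dy.
# Repeating the truncated fit over a grid of depths yields the per-pixel
# profile E = f(h), which for cells is well described by E(h) = a h^b + c
# (a, c > 0, b < 0).

#' Average Young's modulus from a truncated window fit
#'
#' Least-squares fit of `F = E * g(h)` over the window `0 <= h <= depth`,
#' where `g` is the geometry shape function ([shape_function()]). Since the
#' modulus is the single linear parameter, the solution is closed form:
#' `E = sum(F_i g_i) / sum(g_i^2)`. Sphere geometry uses the exact Sneddon
#' bracket as `g` (also linear in the half-space modulus). A negative
#' estimate (possible near contact under noise) is clipped to 0 with a
#' warning, never silently.
#'
#' @param curve a [force_curve()].
#' @param geometry an [indenter_geometry()].
#' @param v Poisson's ratio (default 0.5, incompressible).
#' @param depth upper window edge in metres; must not exceed the curve's
#'   maximum depth.
#' @param min_points minimum in-window samples (default 5).
#' @return Estimated average Young's modulus in pascals, with attributes
#'   `n_points` (window size) and `residual_norm`.
#' @export
fit_average_modulus <- function(curve, geometry, v = 0.5, depth,
                                min_points = 5L) {
  stopifnot(inherits(curve, "force_curve"))
  if (depth > max(curve$h) * (1 + 1e-12))
    .stopf("fit_average_modulus: depth %.4g nm exceeds curve maximum %.4g nm",
           m_to_nm(depth), m_to_nm(max(curve$h)))
  sel <- curve$h <= depth * (1 + 1e-12)
  if (sum(sel) < min_points)
    .stopf("fit_average_modulus: only %d samples in window [0, %.4g nm] (need %d)",
           sum(sel), m_to_nm(depth), min_points)
  hs <- curve$h[sel]; Fs <- curve$F[sel]
  g <- shape_function(geometry, v, hs, sphere_exact = TRUE)
  denom <- sum(g^2)
  E <- if (denom > 0) sum(Fs * g) / denom else 0
  if (E < 0) {
    .warnf("fit_average_modulus: negative estimate %.4g kPa clipped to 0",
           pa_to_kpa(E))
    E <- 0
  }
  structure(E, n_points = sum(sel),
            residual_norm = sqrt(sum((Fs - E * g)^2)))
}

#' Pointwise average Young's modulus
#'
#' Reads the average modulus directly at one depth as `E(h) = F(h) / g(h)`,
#' interpolating the force linearly between samples. Unlike the windowed
#' fit this uses only the local force value, so on depth-varying samples it
#' tracks the profile exactly at sampled depths.
#'
#' @inheritParams fit_average_modulus
#' @return Estimated average Young's modulus in pascals.
#' @export
pointwise_average_modulus <- function(curve, geometry, v = 0.5, depth) {
  stopifnot(inherits(curve, "force_curve"))
  pos <- curve$h[curve$h > 0]
  if (!length(pos) || depth < min(pos) * (1 - 1e-12))
    .stopf("pointwise_average_modulus: depth below first positive sample")
  if (depth > max(curve$h) * (1 + 1e-12))
    .stopf("pointwise_average_modulus: depth beyond curve range")
  g <- shape_function(geometry, v, depth, sphere_exact = TRUE)
  if (g <= 0) .stopf("pointwise_average_modulus: g(depth) must be > 0")
  # clamp depths that equal the range edges up to floating-point slack
  xq <- min(max(depth, min(curve$h)), max(curve$h))
  Fd <- stats::approx(curve$h, curve$F, xout = xq, rule = 1)$y
  E <- Fd / g
  if (E < 0) {
    .warnf("pointwise_average_modulus: negative estimate clipped to 0")
    E <- 0
  }
  E
}

#' Modulus-depth profile for one curve
#'
#' Applies the configured estimator at every depth of a grid, producing the
#' per-pixel profile E = f(h). Depths that fail (outside the curve range,
#' too few window points) are masked with a warning rather than aborting
#' the profile.
#'
#' @inheritParams fit_average_modulus
#' @param depth_grid strictly increasing depths in metres.
#' @param estimator `"windowed_ls"` (default; best constant-modulus fit over
#'   `[0, h]`) or `"pointwise"` (`F(h)/g(h)`).
#' @return An object of class `modulus_profile`: depths `h` (m), values
#'   `E_avg` (Pa, NA where masked), `estimator`, and per-depth diagnostics.
#' @export
modulus_depth_profile <- function(curve, geometry, v = 0.5, depth_grid,
                                  estimator = c("windowed_ls", "pointwise"),
                                  min_points = 5L) {
  estimator <- match.arg(estimator)
  if (any(diff(depth_grid) <= 0))
    .stopf("modulus_depth_profile: depth grid must be strictly increasing")
  n <- length(depth_grid)
  E <- rep(NA_real_, n)
  npts <- rep(NA_integer_, n)
  rnorm_ <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    res <- tryCatch({
      if (estimator == "windowed_ls") {
        e <- fit_average_modulus(curve, geometry, v, depth_grid[j],
                                 min_points = min_points)
        npts[j] <- attr(e, "n_points")
        rnorm_[j] <- attr(e, "residual_norm")
        as.numeric(e)
      } else {
        pointwise_average_modulus(curve, geometry, v, depth_grid[j])
      }
    }, error = function(e) {
      .warnf("modulus_depth_profile: depth %.4g nm masked: %s",
             m_to_nm(depth_grid[j]), conditionMessage(e))
      NA_real_
    })
    E[j] <- res
  }
  structure(list(h = depth_grid, E_avg = E, estimator = estimator,
                 n_points = npts, residual_norm = rnorm_,
                 pixel_index = curve$pixel_index),
            class = "modulus_profile")
}

#' @export
print.modulus_profile <- function(x, ...) {
  cat(sprintf("<modulus_profile> %d depths (%.4g-%.4g nm), estimator %s\n",
              length(x$h), m_to_nm(min(x$h)), m_to_nm(max(x$h)), x$estimator))
  print(data.frame(depth_nm = m_to_nm(x$h), E_avg_kPa = pa_to_kpa(x$E_avg)))
  invisible(x)
}

# Inner constrained linear solve for fixed exponent b:
# E = a t + c with t = h^b, subject to a >= 0, c >= 0.
.powerlaw_inner <- function(t, E, b) {
  X <- cbind(t, 1)
  beta <- tryCatch(qr.solve(X, E), error = function(e) c(0, mean(E)))
  a <- beta[1]; c <- beta[2]
  if (a < 0 || c < 0) {
    # active-set for the 2-parameter problem: try each boundary
    cand <- list(
      c(0, mean(E)),
      c(max(0, sum(E * t) / sum(t^2)), 0)
    )
    sse <- vapply(cand, function(p) sum((E - p[1] * t - p[2])^2), numeric(1))
    best <- cand[[which.min(sse)]]
    a <- best[1]; c <- best[2]
  }
  list(a = a, c = c, sse = sum((E - a * t - c)^2))
}

#' Fit the power-law depth profile E(h) = a h^b + c
#'
#' Constrained least squares with `a > 0`, `c > 0`, `b < 0` — the form that
#' describes depth-dependent cell mechanics (stiff superficial layer over a
#' softer interior). The exponent is found by an outer 1-D search: a
#' log-spaced grid over `b` in `[-3, -1e-3]` followed by golden-section
#' refinement; for each candidate `b` the inner problem in `(a, c)` is a
#' non-negative linear solve. Deterministic. Fitting is carried out with
#' depths in nm and moduli in kPa, so `a` is reported in kPa nm^(-b).
#'
#' @param profile a [modulus_profile()] with >= 4 unmasked points.
#' @param b_range exponent search interval (default `c(-3, -1e-3)`).
#' @param n_grid size of the initial exponent grid (default 60).
#' @return An object of class `power_law_fit`: `a_kpa_nm` (kPa nm^(-b)),
#'   `b`, `c_kpa` (kPa), `sse`, `r_squared`, `degenerate` (TRUE when the
#'   profile is flat and only `c` is identified).
#' @export
fit_power_law_profile <- function(profile, b_range = c(-3, -1e-3),
                                  n_grid = 60L) {
  stopifnot(inherits(profile, "modulus_profile"))
  ok <- is.finite(profile$E_avg)
  if (sum(ok) < 4L)
    .stopf("fit_power_law_profile: need >= 4 unmasked profile points, have %d",
           sum(ok))
  h_nm <- m_to_nm(profile$h[ok])
  E_kpa <- pa_to_kpa(profile$E_avg[ok])
  tss <- sum((E_kpa - mean(E_kpa))^2)
  if (tss <= .Machine$double.eps * max(1, mean(E_kpa)^2) * length(E_kpa)) {
    return(structure(list(a_kpa_nm = 0, b = NA_real_, c_kpa = mean(E_kpa),
                          sse = 0, r_squared = NA_real_, degenerate = TRUE),
                     class = "power_law_fit"))
  }
  obj <- function(b) .powerlaw_inner(h_nm^b, E_kpa, b)$sse
  bs <- -exp(seq(log(-b_range[1]), log(-b_range[2]), length.out = n_grid))
  sses <- vapply(bs, obj, numeric(1))
  i <- which.min(sses)
  lo <- bs[max(1L, i - 1L)]; hi <- bs[min(length(bs), i + 1L)]
  opt <- stats::optimize(obj, lower = min(lo, hi), upper = max(lo, hi),
                         tol = 1e-12)
  b <- opt$minimum
  inner <- .powerlaw_inner(h_nm^b, E_kpa, b)
  structure(list(a_kpa_nm = inner$a, b = b, c_kpa = inner$c,
                 sse = inner$sse, r_squared = 1 - inner$sse / tss,
                 degenerate = FALSE),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<power_law_fit> degenerate (flat profile): c = %.4g kPa\n", x$c_kpa))
  } else {
    cat(sprintf("<power_law_fit> E(h) = %.4g h^(%.4g) + %.4g  [kPa, h in nm], R^2 = %.4f\n",
                x$a_kpa_nm, x$b, x$c_kpa, x$r_squared))
  }
  invisible(x)
}

#' Default depth grid for a force-volume grid
#'
#' M equally spaced depths between 10% of the deepest common indentation
#' and the largest depth reached by every non-empty pixel, so every map
#' slice is computable at every pixel.
#'
#' @param grid an [fv_grid()].
#' @param M number of depths (default 8).
#' @return Strictly increasing depths in metres, length `M`.
#' @export
default_depth_grid <- function(grid, M = 8L) {
  stopifnot(inherits(grid, "fv_grid"))
  maxima <- vapply(grid$curves, function(cu)
    if (is.null(cu)) NA_real_ else max(cu$h), numeric(1))
  common <- min(maxima, na.rm = TRUE)
  if (!is.finite(common) || common <= 0)
    .stopf("default_depth_grid: no usable pixels")
  seq(0.1 * common, common, length.out = M)
}
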