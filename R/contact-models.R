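# Forward force-indentation laws for the supported indenter geometries.
# Cylinder / cone / paraboloid are the classical Hertzian laws, linear in
# the (average) Young's modulus; the sphere uses the exact Sneddon solution
# with the contact radius defined implicitly.

#' Indenter geometry
#'
#' Describes the AFM tip used for indentation. Supported shapes are the flat
#' cylindrical punch, the cone, the paraboloid (the small-depth limit of a
#' sphere) and the sphere (exact Sneddon treatment).
#'
#' @param kind one of `"cylinder"`, `"cone"`, `"paraboloid"`, `"sphere"`.
#' @param radius tip radius in metres; required for cylinder, paraboloid and
#'   sphere kinds.
#' @param half_angle cone half-angle in radians, in (0, pi/2); required for
#'   the cone kind.
#' @return An object of class `indenter_geometry`.
#' @examples
#' indenter_geometry("sphere", radius = 1e-6)
#' indenter_geometry("cone", half_angle = 25 * pi / 180)
#' @export
indenter_geometry <- function(kind = c("cylinder", "cone", "paraboloid", "sphere"),
                              radius = NULL, half_angle = NULL) {
  kind <- match.arg(kind)
  if (kind == "cone") {
    if (is.null(half_angle)) .stopf("cone geometry requires 'half_angle'")
    if (!is.null(radius)) .stopf("cone geometry must not set 'radius'")
    if (!is.finite(half_angle) || half_angle <= 0 || half_angle >= pi / 2)
      .stopf("'half_angle' must lie in (0, pi/2) radians")
  } else {
    if (is.null(radius)) .stopf("%s geometry requires 'radius'", kind)
    if (!is.null(half_angle)) .stopf("%s geometry must not set 'half_angle'", kind)
    if (!is.finite(radius) || radius <= 0) .stopf("'radius' must be positive")
  }
  structure(list(kind = kind, radius = radius, half_angle = half_angle),
            class = "indenter_geometry")
}

#' @export
print.indenter_geometry <- function(x, ...) {
  if (x$kind == "cone") {
    cat(sprintf("<indenter_geometry> cone, half angle %.3g deg\n",
                x$half_angle * 180 / pi))
  } else {
    cat(sprintf("<indenter_geometry> %s, radius %.3g nm\n",
                x$kind, m_to_nm(x$radius)))
  }
  invisible(x)
}

#' Elastic parameters of the indented medium
#'
#' @param modulus Young's modulus in pascals. For the Hertzian laws this is
#'   interpreted as the depth-averaged modulus of the probed volume; for the
#'   exact Sneddon sphere it is the modulus of the elastic half-space.
#' @param poisson_ratio Poisson's ratio, in (-1, 0.5]; defaults to 0.5
#'   (incompressible), the convention for highly hydrated biological samples.
#' @return An object of class `elastic_params`.
#' @export
elastic_params <- function(modulus, poisson_ratio = 0.5) {
  if (!is.finite(modulus) || modulus < 0) .stopf("'modulus' must be >= 0")
  if (!is.finite(poisson_ratio) || poisson_ratio <= -1 || poisson_ratio > 0.5)
    .stopf("'poisson_ratio' must lie in (-1, 0.5]")
  structure(list(modulus = modulus, poisson_ratio = poisson_ratio),
            class = "elastic_params")
}

.check_geometry <- function(geometry, expected, op) {
  if (!inherits(geometry, "indenter_geometry"))
    .stopf("%s: 'geometry' must be an indenter_geometry object", op)
  if (!geometry$kind %in% expected)
    .stopf("%s: geometry kind '%s' not supported (expected %s)",
           op, geometry$kind, paste(expected, collapse = "/"))
  invisible(TRUE)
}

.check_depth <- function(h, op) {
  if (any(!is.finite(h)) || any(h < 0))
    .stopf("%s: indentation depth must be finite and >= 0", op)
  invisible(TRUE)
}

#' Force on a flat cylindrical punch
#'
#' F = 2 E R h / (1 - v^2): linear in both the modulus and the depth.
#'
#' @param params an [elastic_params()] object.
#' @param geometry an [indenter_geometry()] of kind `"cylinder"`.
#' @param h indentation depth(s) in metres, >= 0. Vectorized.
#' @return Force in newtons.
#' @export
force_cylindrical <- function(params, geometry, h) {
  .check_geometry(geometry, "cylinder", "force_cylindrical")
  .check_depth(h, "force_cylindrical")
  params$modulus * shape_function(geometry, params$poisson_ratio, h)
}

#' Force on a conical indenter
#'
#' F = (2 tan(theta) / (pi (1 - v^2))) E h^2: quadratic in depth.
#'
#' @inheritParams force_cylindrical
#' @param geometry an [indenter_geometry()] of kind `"cone"`.
#' @return Force in newtons.
#' @export
force_conical <- function(params, geometry, h) {
  .check_geometry(geometry, "cone", "force_conical")
  .check_depth(h, "force_conical")
  params$modulus * shape_function(geometry, params$poisson_ratio, h)
}

#' Force on a paraboloidal indenter
#'
#' F = (4 sqrt(R) E / (3 (1 - v^2))) h^(3/2). Also the small-depth (Hertz)
#' limit of a spherical tip of the same radius.
#'
#' @inheritParams force_cylindrical
#' @param geometry an [indenter_geometry()] of kind `"paraboloid"`.
#' @return Force in newtons.
#' @export
force_paraboloid <- function(params, geometry, h) {
  .check_geometry(geometry, c("paraboloid", "sphere"), "force_paraboloid")
  .check_depth(h, "force_paraboloid")
  g <- .shape_paraboloid(geometry$radius, params$poisson_ratio, h)
  params$modulus * g
}

.shape_paraboloid <- function(R, v, h) 4 * sqrt(R) / (3 * (1 - v^2)) * h^1.5

#' Sneddon contact radius for a spherical indenter
#'
#' Solves ln((R + r_c) / (R - r_c)) = 2 h / r_c for the contact radius
#' r_c in (0, R), by bracketed (Brent) root finding. The left side is
#' increasing and the right side decreasing in r_c, so the root is unique
#' and bracketing is globally safe. Returns 0 at h = 0.
#'
#' @param geometry an [indenter_geometry()] of kind `"sphere"`.
#' @param h indentation depth(s) in metres. Vectorized.
#' @param tol relative convergence tolerance (default 1e-12).
#' @return Contact radius r_c in metres, same length as `h`.
#' @export
sneddon_contact_radius <- function(geometry, h, tol = 1e-12) {
  .check_geometry(geometry, "sphere", "sneddon_contact_radius")
  .check_depth(h, "sneddon_contact_radius")
  R <- geometry$radius
  vapply(h, function(hi) {
    if (hi == 0) return(0)
    eps <- 1e-15 * R
    f <- function(rc) log((R + rc) / (R - rc)) - 2 * hi / rc
    lo <- eps
    hi_b <- R * (1 - 1e-15)
    if (f(lo) > 0 || f(hi_b) < 0)
      .stopf("sneddon_contact_radius: root not bracketed for h = %g m (h/R = %g)",
             hi, hi / R)
    out <- stats::uniroot(f, c(lo, hi_b), tol = tol * R, maxiter = 2000L)
    rc <- out$root
    # Newton polish: f'(rc) = 2R/(R^2-rc^2) + 2h/rc^2
    for (i in 1:3) {
      fr <- f(rc)
      dfr <- 2 * R / (R^2 - rc^2) + 2 * hi / rc^2
      step <- fr / dfr
      rc2 <- rc - step
      if (rc2 <= 0 || rc2 >= R) break
      rc <- rc2
      if (abs(step) < tol * rc) break
    }
    if (abs(f(rc)) > 1e-9)
      .stopf("sneddon_contact_radius: residual %.3g > 1e-9 at h = %g m", f(rc), hi)
    rc
  }, numeric(1))
}

#' Exact Sneddon force for a spherical indenter
#'
#' F = E / (2 (1 - v^2)) * ((r_c^2 + R^2) ln((R + r_c)/(R - r_c)) - 2 r_c R),
#' with the contact radius r_c obtained from [sneddon_contact_radius()].
#' Valid at any h/R (unlike the paraboloidal small-depth approximation).
#'
#' @inheritParams force_cylindrical
#' @param geometry an [indenter_geometry()] of kind `"sphere"`.
#' @return Force in newtons.
#' @export
force_sneddon_sphere <- function(params, geometry, h) {
  .check_geometry(geometry, "sphere", "force_sneddon_sphere")
  .check_depth(h, "force_sneddon_sphere")
  params$modulus * .shape_sneddon(geometry, params$poisson_ratio, h)
}

# Sneddon bracket per unit modulus: F = E * .shape_sneddon(...)
.shape_sneddon <- function(geometry, v, h) {
  R <- geometry$radius
  rc <- sneddon_contact_radius(geometry, h)
  out <- numeric(length(h))
  pos <- rc > 0
  out[pos] <- ((rc[pos]^2 + R^2) * log((R + rc[pos]) / (R - rc[pos])) -
                 2 * rc[pos] * R) / (2 * (1 - v^2))
  out
}

#' Series correction for spherical indentation
#'
#' A power-series alternative to the implicit Sneddon solution writes the
#' sphere force as the paraboloidal law times a correction factor
#' Z = c_1 + sum_{M>=2} (3/(2M)) c_M R^(3/2 - M) h^(M - 3/2), with Z <= 1.
#' The coefficients are not fixed here and must be supplied by the caller.
#'
#' @param coefficients numeric vector c_1, c_2, ... (dimensionless), nonempty.
#' @return An object of class `sneddon_series_correction`.
#' @export
sneddon_series_correction <- function(coefficients) {
  if (length(coefficients) < 1L || any(!is.finite(coefficients)))
    .stopf("series correction requires a nonempty finite coefficient vector")
  structure(list(coefficients = as.numeric(coefficients)),
            class = "sneddon_series_correction")
}

# Correction factor Z(h) for one depth vector.
.series_Z <- function(corr, R, h) {
  cs <- corr$coefficients
  Z <- rep(cs[1], length(h))
  if (length(cs) >= 2L) {
    for (M in 2:length(cs)) {
      Z <- Z + 3 / (2 * M) * cs[M] * R^(3 / 2 - M) * h^(M - 3 / 2)
    }
  }
  Z
}

#' Series-corrected spherical force
#'
#' F = (4 E sqrt(R) / (3 (1 - v^2))) h^(3/2) * Z, with Z from
#' [sneddon_series_correction()]. With `coefficients = 1` this reduces
#' exactly to [force_paraboloid()]. A computed Z exceeding 1 (beyond
#' numerical slack) violates the stated bound and triggers a warning.
#'
#' @inheritParams force_cylindrical
#' @param geometry an [indenter_geometry()] of kind `"sphere"` or
#'   `"paraboloid"` (radius is what matters).
#' @param corr a [sneddon_series_correction()].
#' @return Force in newtons.
#' @export
force_sphere_series <- function(params, geometry, h, corr) {
  .check_geometry(geometry, c("sphere", "paraboloid"), "force_sphere_series")
  .check_depth(h, "force_sphere_series")
  if (!inherits(corr, "sneddon_series_correction"))
    .stopf("force_sphere_series: 'corr' must be a sneddon_series_correction")
  Z <- .series_Z(corr, geometry$radius, h)
  if (any(Z > 1 + 1e-9))
    .warnf("force_sphere_series: correction factor Z = %.6g exceeds 1 (bound Z <= 1 violated)",
           max(Z))
  params$modulus * .shape_paraboloid(geometry$radius, params$poisson_ratio, h) * Z
}

#' Geometry shape function g(h) with F = E * g(h)
#'
#' Factors each force law as force = modulus x g(h), which makes the
#' windowed least-squares modulus estimate a closed-form single-parameter
#' solve. Supported for cylinder, cone and paraboloid; the sphere kind uses
#' the exact Sneddon bracket (also linear in E) via `sphere_exact = TRUE`.
#'
#' @param geometry an [indenter_geometry()].
#' @param v Poisson's ratio.
#' @param h indentation depth(s) in metres. Vectorized.
#' @param sphere_exact if TRUE, sphere geometry yields the exact Sneddon
#'   bracket per unit modulus; if FALSE (default) sphere kind errors.
#' @return g(h), in units such that E * g(h) is a force in newtons.
#' @export
shape_function <- function(geometry, v, h, sphere_exact = FALSE) {
  .check_depth(h, "shape_function")
  if (!inherits(geometry, "indenter_geometry"))
    .stopf("shape_function: 'geometry' must be an indenter_geometry object")
  switch(geometry$kind,
    cylinder   = 2 * geometry$radius * h / (1 - v^2),
    cone       = 2 * tan(geometry$half_angle) / (pi * (1 - v^2)) * h^2,
    paraboloid = .shape_paraboloid(geometry$radius, v, h),
    sphere     = {
      if (!sphere_exact)
        .stopf("shape_function: sphere geometry unsupported unless sphere_exact = TRUE")
      .shape_sneddon(geometry, v, h)
    }
  )
}
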