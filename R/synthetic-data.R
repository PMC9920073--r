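# Synthetic force curves and force-volume grids generated from prescribed
# depth-dependent modulus structure, with ground truth retained. The
# generator inverts the analysis model: a sample is a stack of narrow
# homogeneous slices (or a continuous modulus-depth function), whose
# depth-averaged modulus drives the Hertzian force law, plus seeded force
# noise.

#' Layered (or continuous) sample description
#'
#' Either a discrete stack of N homogeneous slices of equal thickness
#' `dh` with moduli `E_slices`, or a continuous depth-dependent modulus
#' function `E_fun(y)` defined on `[0, depth_max]`.
#'
#' @param E_slices slice moduli in Pa (discrete form), all >= 0.
#' @param dh slice thickness in metres (discrete form), > 0.
#' @param E_fun function of depth y (metres) returning modulus in Pa
#'   (continuous form); must be finite on `[0, depth_max]`.
#' @param depth_max domain limit for the continuous form, metres.
#' @return An object of class `layered_sample`.
#' @examples
#' layered_sample(E_slices = c(10e3, 5e3), dh = 100e-9)
#' layered_sample(E_fun = function(y) 20e3 * exp(-y / 1e-6), depth_max = 1e-6)
#' @export
layered_sample <- function(E_slices = NULL, dh = NULL, E_fun = NULL,
                           depth_max = NULL) {
  if (!is.null(E_slices)) {
    if (is.null(dh) || !is.finite(dh) || dh <= 0)
      .stopf("layered_sample: discrete form requires slice thickness dh > 0")
    if (length(E_slices) < 1L || any(!is.finite(E_slices)) || any(E_slices < 0))
      .stopf("layered_sample: slice moduli must be finite and >= 0")
    structure(list(type = "discrete", E_slices = as.numeric(E_slices),
                   dh = dh, depth_max = dh * length(E_slices)),
              class = "layered_sample")
  } else if (!is.null(E_fun)) {
    if (is.null(depth_max) || !is.finite(depth_max) || depth_max <= 0)
      .stopf("layered_sample: continuous form requires depth_max > 0")
    probe <- E_fun(seq(0, depth_max, length.out = 17))
    if (any(!is.finite(probe)))
      .stopf("layered_sample: E_fun must be finite on [0, depth_max]")
    structure(list(type = "continuous", E_fun = E_fun, depth_max = depth_max),
              class = "layered_sample")
  } else {
    .stopf("layered_sample: supply either (E_slices, dh) or (E_fun, depth_max)")
  }
}

#' Depth-averaged modulus of a layered sample
#'
#' The average Young's modulus probed down to depth h:
#' discrete form — thickness-weighted mean of the slices intersected by
#' `[0, h]` (the final slice counted by its covered fraction); continuous
#' form — (1/h) times the adaptive-quadrature integral of the modulus
#' function over `[0, h]` (relative tolerance 1e-10).
#'
#' @param sample a [layered_sample()].
#' @param h depth(s) in metres, 0 < h <= sample depth. Vectorized.
#' @return Average modulus in Pa.
#' @export
average_modulus_of_sample <- function(sample, h) {
  stopifnot(inherits(sample, "layered_sample"))
  if (any(!is.finite(h)) || any(h <= 0))
    .stopf("average_modulus_of_sample: h must be > 0")
  if (any(h > sample$depth_max * (1 + 1e-12)))
    .stopf("average_modulus_of_sample: h beyond sample depth %.4g nm",
           m_to_nm(sample$depth_max))
  if (sample$type == "discrete") {
    cum <- cumsum(sample$E_slices) * sample$dh   # integral to each slice edge
    edges <- seq_along(sample$E_slices) * sample$dh
    vapply(h, function(hi) {
      k <- findInterval(hi, edges, left.open = TRUE) # full slices below hi
      full <- if (k > 0) cum[k] else 0
      part <- if (k < length(sample$E_slices))
        sample$E_slices[k + 1L] * (hi - k * sample$dh) else 0
      (full + part) / hi
    }, numeric(1))
  } else {
    vapply(h, function(hi) {
      stats::integrate(sample$E_fun, 0, hi, rel.tol = 1e-10,
                       subdivisions = 500L)$value / hi
    }, numeric(1))
  }
}

#' Power-law average-modulus profile
#'
#' Convenience constructor for the depth profile E(h) = a h^b + c in the
#' field's reporting convention (a in kPa nm^(-b), c in kPa, h in nm), with
#' a, c > 0, b < 0. Returns a function of depth in metres yielding Pa,
#' suitable as the `profile` argument of [simulate_curve()].
#'
#' @param a_kpa_nm coefficient a, kPa nm^(-b), > 0.
#' @param b exponent, < 0.
#' @param c_kpa offset c, kPa, > 0.
#' @return Function h (m) -> average modulus (Pa), with the parameters
#'   attached as attributes.
#' @export
power_law_profile <- function(a_kpa_nm, b, c_kpa) {
  if (a_kpa_nm <= 0 || c_kpa <= 0 || b >= 0)
    .stopf("power_law_profile: requires a > 0, c > 0, b < 0")
  f <- function(h) kpa_to_pa(a_kpa_nm * m_to_nm(h)^b + c_kpa)
  attr(f, "params") <- c(a_kpa_nm = a_kpa_nm, b = b, c_kpa = c_kpa)
  f
}

# Derive a pixel's RNG seed from the master seed by a fixed counter scheme
# (Knuth multiplicative hash of the pixel counter), kept below 2^31.
.substream_seed <- function(seed, counter) {
  # doubles stay exact here: |values| < 2^53
  as.integer(((seed %% 2147483647) * 48271 + counter * 2654435761) %% 2147483647)
}

#' Simulate one force-indentation curve
#'
#' Builds F(h_j) = g(h_j) * Ebar(h_j) on the given depth samples, where
#' `Ebar` is the depth-averaged modulus of a [layered_sample()], a profile
#' function (e.g. [power_law_profile()]), or a constant (Pa), and `g` is
#' the geometry shape function. For sphere geometry with a constant
#' modulus, `sphere_exact = TRUE` uses the exact Sneddon law instead of the
#' paraboloidal approximation (depth-varying profiles always use the
#' Hertzian forms, which is the averaging theory's domain). Noise is then
#' applied to force only: `F <- F * (1 + eps_m) + eps_a` with seeded
#' Gaussian draws, `eps_a` scaled by the maximum noiseless force.
#'
#' @param profile a [layered_sample()], a function h (m) -> Pa, or a single
#'   non-negative number (constant modulus, Pa).
#' @param geometry an [indenter_geometry()].
#' @param v Poisson's ratio (default 0.5).
#' @param depth_grid sample depths in metres, strictly increasing; a
#'   leading 0 is allowed and yields F = 0 there.
#' @param noise list with `multiplicative` and `additive` relative noise
#'   levels (standard deviations; additive is relative to max force).
#' @param seed integer RNG seed; required when noise is nonzero.
#' @param sphere_exact use the exact Sneddon sphere law (constant modulus
#'   only).
#' @return A [force_curve()] with the ground truth stored in
#'   `metadata$ground_truth` (list: `depths`, `E_avg` in Pa).
#' @export
simulate_curve <- function(profile, geometry, v = 0.5, depth_grid,
                           noise = list(multiplicative = 0, additive = 0),
                           seed = NULL, sphere_exact = FALSE) {
  if (any(diff(depth_grid) <= 0) || any(depth_grid < 0))
    .stopf("simulate_curve: depth_grid must be non-negative, strictly increasing")
  mult <- noise$multiplicative %||% 0
  addv <- noise$additive %||% 0
  if (mult < 0 || addv < 0) .stopf("simulate_curve: noise levels must be >= 0")

  const_E <- is.numeric(profile) && length(profile) == 1L
  ebar_fun <- if (inherits(profile, "layered_sample")) {
    function(h) average_modulus_of_sample(profile, h)
  } else if (is.function(profile)) {
    profile
  } else if (const_E) {
    if (profile < 0) .stopf("simulate_curve: constant modulus must be >= 0")
    function(h) rep(as.numeric(profile), length(h))
  } else {
    .stopf("simulate_curve: unsupported profile type")
  }
  if (sphere_exact && !const_E)
    .stopf("simulate_curve: sphere_exact requires a constant modulus")

  pos <- depth_grid > 0
  E_avg <- numeric(length(depth_grid))
  E_avg[pos] <- ebar_fun(depth_grid[pos])
  if (!all(pos)) E_avg[!pos] <- if (const_E) as.numeric(profile) else
    ebar_fun(min(depth_grid[pos]))  # limit value recorded at h = 0
  F <- numeric(length(depth_grid))
  if (sphere_exact) {
    F[pos] <- force_sneddon_sphere(elastic_params(as.numeric(profile), v),
                                   geometry, depth_grid[pos])
  } else {
    # sphere kind without sphere_exact deliberately uses the paraboloidal
    # Hertz form: that is the averaging theory's stated domain; the exact
    # Sneddon law is reserved for constant-modulus validation.
    g <- if (geometry$kind == "sphere")
      .shape_paraboloid(geometry$radius, v, depth_grid[pos])
    else shape_function(geometry, v, depth_grid[pos])
    F[pos] <- g * E_avg[pos]
  }
  if (mult > 0 || addv > 0) {
    if (is.null(seed)) .stopf("simulate_curve: noisy simulation requires a seed")
    Fmax <- max(abs(F))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    F <- F * (1 + stats::rnorm(length(F), 0, mult)) +
      stats::rnorm(length(F), 0, addv * Fmax)
  }
  force_curve(depth_grid, F,
              metadata = list(
                ground_truth = list(depths = depth_grid, E_avg = E_avg),
                noise_multiplicative = mult, noise_additive = addv,
                seed = seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Specification of a synthetic force-volume field
#'
#' Describes a full synthetic acquisition: grid dimensions, the spatial
#' assignment of modulus structure, tip geometry, depth sampling, noise and
#' seed. Field types:
#' * `uniform` — one constant modulus `E` (Pa) everywhere.
#' * `inclusion` — background `E` with a stiffer rectangular inclusion
#'   (`E_inclusion`, 0-based `rows`/`cols` ranges).
#' * `normal` — per-pixel constant moduli drawn once from
#'   N(`mu`, `sd`^2) (Pa), truncated at 0; emulates lateral heterogeneity.
#' * `power_law` — every pixel follows E(h) = a h^b + c
#'   ([power_law_profile()] convention), emulating depth-dependent
#'   (softening) samples.
#'
#' @param ny,nx grid dimensions, >= 1.
#' @param field named list with `type` and type-specific parameters above.
#' @param geometry an [indenter_geometry()].
#' @param v Poisson's ratio.
#' @param h_max maximum indentation depth, metres.
#' @param n_samples samples per curve (default 200).
#' @param noise list(`multiplicative`, `additive`) relative noise levels.
#' @param seed master seed (integer); per-pixel substreams are derived by a
#'   fixed counter hash so regeneration is stable under partial evaluation.
#' @param pixel_size pixel pitch, metres (default 78.125 nm: a 5 x 5 um
#'   scan at 64 x 64 pixels).
#' @return An object of class `synthetic_field_spec`.
#' @export
synthetic_field_spec <- function(ny, nx, field, geometry, v = 0.5,
                                 h_max = 800e-9, n_samples = 200L,
                                 noise = list(multiplicative = 0, additive = 0),
                                 seed = 1L, pixel_size = 78.125e-9) {
  ny <- as.integer(ny); nx <- as.integer(nx)
  if (ny < 1L || nx < 1L) .stopf("synthetic_field_spec: dims must be >= 1")
  if (is.null(field$type) ||
      !field$type %in% c("uniform", "inclusion", "normal", "power_law"))
    .stopf("synthetic_field_spec: unknown field type '%s'", field$type %||% "NULL")
  if ((noise$multiplicative %||% 0) < 0 || (noise$additive %||% 0) < 0)
    .stopf("synthetic_field_spec: noise levels must be >= 0")
  structure(list(ny = ny, nx = nx, field = field, geometry = geometry, v = v,
                 h_max = h_max, n_samples = as.integer(n_samples),
                 noise = noise, seed = as.integer(seed),
                 pixel_size = pixel_size),
            class = "synthetic_field_spec")
}

# Per-pixel profile (function or constant in Pa) for a field spec.
.field_profiles <- function(spec) {
  ny <- spec$ny; nx <- spec$nx; fld <- spec$field
  idx <- seq_len(ny * nx)
  switch(fld$type,
    uniform = lapply(idx, function(i) fld$E),
    inclusion = lapply(idx, function(i) {
      r <- (i - 1L) %/% nx; c <- (i - 1L) %% nx
      inside <- r >= fld$rows[1] && r <= fld$rows[2] &&
                c >= fld$cols[1] && c <= fld$cols[2]
      if (inside) fld$E_inclusion else fld$E
    }),
    normal = {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(.substream_seed(spec$seed, 0L))
      Es <- pmax(0, stats::rnorm(ny * nx, fld$mu, fld$sd))
      as.list(Es)
    },
    power_law = {
      prof <- power_law_profile(fld$a_kpa_nm, fld$b, fld$c_kpa)
      lapply(idx, function(i) prof)
    }
  )
}

#' Simulate a force-volume grid with ground truth
#'
#' Generates one curve per pixel via [simulate_curve()] with an independent
#' seeded substream each, and also evaluates the noiseless ground-truth
#' average modulus on a depth grid to form the reference [map_stack()].
#'
#' @param spec a [synthetic_field_spec()].
#' @param truth_depths depths (m) at which the ground-truth stack is
#'   evaluated; default 8 equally spaced depths from `h_max / 8` to `h_max`.
#' @return list with `grid` (an [fv_grid()]), `truth` (a [map_stack()] of
#'   noiseless ground-truth average moduli), and `spec`.
#' @export
simulate_force_volume <- function(spec, truth_depths = NULL) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  if (is.null(truth_depths))
    truth_depths <- seq(spec$h_max / 8, spec$h_max, length.out = 8)
  profiles <- .field_profiles(spec)
  depth_grid <- seq(0, spec$h_max, length.out = spec$n_samples + 1L)
  curves <- vector("list", spec$ny * spec$nx)
  truth <- array(NA_real_, dim = c(spec$ny, spec$nx, length(truth_depths)))
  for (i in seq_along(profiles)) {
    r <- (i - 1L) %/% spec$nx; c <- (i - 1L) %% spec$nx
    cu <- simulate_curve(profiles[[i]], spec$geometry, spec$v, depth_grid,
                         noise = spec$noise,
                         seed = .substream_seed(spec$seed, i))
    cu$pixel_index <- c(r, c)
    curves[[i]] <- cu
    prof <- profiles[[i]]
    truth[r + 1L, c + 1L, ] <- if (is.function(prof)) prof(truth_depths)
      else rep(as.numeric(prof), length(truth_depths))
  }
  meta <- list(synthetic = TRUE, seed = spec$seed,
               field_type = spec$field$type)
  truth_maps <- lapply(seq_along(truth_depths), function(j)
    depth_map(truth_depths[j], truth[, , j, drop = TRUE], metadata = meta))
  list(grid = fv_grid(curves, ny = spec$ny, nx = spec$nx,
                      pixel_size = spec$pixel_size, metadata = meta),
       truth = map_stack(truth_maps, metadata = meta),
       spec = spec)
}
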