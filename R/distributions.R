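# Per-depth Gaussian summaries of modulus maps, the indicator-weighted
# mixture representation across depths, (mu, sigma, h) vectors, and
# classification of depth behavior (softening / stiffening, homogenizing /
# heterogenizing).

#' Gaussian summary of one depth slice
#'
#' @param mu mean modulus, Pa.
#' @param sigma standard deviation, Pa, >= 0.
#' @param depth indentation depth, metres, > 0.
#' @param n number of values summarized (>= 2 for sigma to be defined).
#' @param method fitting method tag.
#' @return An object of class `gaussian_summary`.
#' @export
gaussian_summary <- function(mu, sigma, depth, n, method = "moments") {
  if (!is.finite(sigma) || sigma < 0) .stopf("gaussian_summary: sigma must be >= 0")
  if (!is.finite(depth) || depth <= 0) .stopf("gaussian_summary: depth must be > 0")
  structure(list(mu = mu, sigma = sigma, depth = depth, n = as.integer(n),
                 method = method),
            class = "gaussian_summary")
}

#' @export
print.gaussian_summary <- function(x, ...) {
  cat(sprintf("<gaussian_summary> h = %g nm: mu = %.4g kPa, sigma = %.4g kPa (n = %d, %s)\n",
              m_to_nm(x$depth), pa_to_kpa(x$mu), pa_to_kpa(x$sigma), x$n, x$method))
  invisible(x)
}

#' Fit a Gaussian to modulus values
#'
#' Two fitting routes for the per-depth modulus distribution:
#' * `moments` (default): mu = sample mean, sigma = sample standard
#'   deviation with the n-1 denominator. Exact and deterministic.
#' * `histogram_ls`: nonlinear least squares of the normal density against
#'   a density-normalized histogram with Freedman-Diaconis bins, started at
#'   the moment estimates — mirrors the curve-fitting workflow used when
#'   distributions are read off histograms. Falls back to moments (with a
#'   warning) when fewer than 5 bins are populated.
#'
#' @param values numeric vector of moduli (Pa); non-finite entries dropped.
#' @param depth indentation depth in metres the values belong to.
#' @param method `"moments"` or `"histogram_ls"`.
#' @return A [gaussian_summary()].
#' @export
fit_gaussian <- function(values, depth, method = c("moments", "histogram_ls")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    .stopf("fit_gaussian: need >= 2 finite values, have %d", length(values))
  mu0 <- mean(values)
  sd0 <- stats::sd(values)
  if (method == "moments" || sd0 == 0)
    return(gaussian_summary(mu0, sd0, depth, length(values), "moments"))

  brk <- tryCatch(graphics::hist(values, breaks = "FD", plot = FALSE),
                  error = function(e) NULL)
  if (is.null(brk) || sum(brk$density > 0) < 5L) {
    .warnf("fit_gaussian: histogram has < 5 populated bins; falling back to moments")
    return(gaussian_summary(mu0, sd0, depth, length(values), "moments"))
  }
  x <- brk$mids; y <- brk$density
  obj <- function(p) {
    if (p[2] <= 0) return(Inf)
    sum((y - stats::dnorm(x, p[1], p[2]))^2)
  }
  opt <- stats::optim(c(mu0, sd0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000L))
  gaussian_summary(opt$par[1], opt$par[2], depth, length(values), "histogram_ls")
}

#' Summarize every slice of a map stack
#'
#' Applies [fit_gaussian()] to the unmasked values of each depth slice.
#'
#' @param stack a [map_stack()].
#' @param method passed to [fit_gaussian()].
#' @return List of [gaussian_summary()], ordered by depth.
#' @export
summarize_stack <- function(stack, method = "moments") {
  stopifnot(inherits(stack, "map_stack"))
  lapply(stack$maps, function(m)
    fit_gaussian(m$values[!m$mask], m$depth, method = method))
}

#' Normal density for a fitted summary
#'
#' f(E) = 1 / (sigma sqrt(2 pi)) exp(-((E - mu) / sigma)^2 / 2), in Pa^-1.
#'
#' @param E modulus value(s), Pa.
#' @param summary a [gaussian_summary()] with sigma > 0.
#' @return Density value(s), Pa^-1.
#' @export
gaussian_density <- function(E, summary) {
  stopifnot(inherits(summary, "gaussian_summary"))
  if (summary$sigma <= 0)
    .stopf("gaussian_density: degenerate distribution (sigma = 0)")
  stats::dnorm(E, mean = summary$mu, sd = summary$sigma)
}

#' Indicator-weighted Gaussian mixture across depths
#'
#' Collects the per-depth Gaussian components into one expression
#' f(E) = sum_i c_i N(E; mu_i, sigma_i) where, for any selected depth h_i,
#' the indicator weights are c_i = 1 and all others 0 — i.e. at each fixed
#' depth exactly one component is active, and the mixture is a compact
#' bookkeeping device for plotting the per-depth distributions together.
#'
#' @param summaries list of [gaussian_summary()], distinct depths.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(summaries) {
  ok <- vapply(summaries, inherits, logical(1), what = "gaussian_summary")
  if (!all(ok)) .stopf("mixture_spec: entries must be gaussian_summary objects")
  depths <- vapply(summaries, `[[`, numeric(1), "depth")
  if (anyDuplicated(depths)) .stopf("mixture_spec: depths must be distinct")
  summaries <- summaries[order(depths)]
  structure(list(components = summaries, depths = sort(depths)),
            class = "mixture_spec")
}

#' Evaluate the mixture at a given depth
#'
#' Selects the component whose depth matches (the indicator weight for that
#' depth is 1, all others 0) and evaluates its normal density.
#'
#' @param E modulus value(s), Pa.
#' @param spec a [mixture_spec()].
#' @param depth one of the component depths, metres.
#' @return Density value(s), Pa^-1.
#' @export
mixture_density <- function(E, spec, depth) {
  stopifnot(inherits(spec, "mixture_spec"))
  i <- which(abs(spec$depths - depth) <= 1e-9 * max(depth, 1e-12))
  if (length(i) != 1L)
    .stopf("mixture_density: depth %.4g nm not among component depths (%s nm)",
           m_to_nm(depth), paste(signif(m_to_nm(spec$depths), 4), collapse = ", "))
  gaussian_density(E, spec$components[[i]])
}

#' The (mu, sigma, h) vector of a depth slice
#'
#' Maps a Gaussian summary to the dimensionless 3-vector
#' (x, y, z) = (A mu, B sigma, C h) with A = B = 1 kPa^-1 and C = 1 nm^-1:
#' the per-depth fingerprint used to track softening/stiffening and
#' homogenizing trends. E.g. mu = 20 kPa, sigma = 5 kPa, h = 300 nm gives
#' (20, 5, 300); a homogeneous sample has y = 0.
#'
#' @param summary a [gaussian_summary()].
#' @return An object of class `musigmah_vector` with fields `x`, `y`, `z`.
#' @export
musigmah_vector <- function(summary) {
  stopifnot(inherits(summary, "gaussian_summary"))
  structure(list(x = pa_to_kpa(summary$mu),
                 y = pa_to_kpa(summary$sigma),
                 z = m_to_nm(summary$depth)),
            class = "musigmah_vector")
}

#' @export
print.musigmah_vector <- function(x, ...) {
  cat(sprintf("<musigmah_vector> r = %g i + %g j + %g k  (mu kPa, sigma kPa, h nm)\n",
              x$x, x$y, x$z))
  invisible(x)
}

# Classify one consecutive-change sequence: -1 down, +1 up, 0 flat.
.trend_steps <- function(vals, rel_tol) {
  rel <- diff(vals) / pmax(abs(vals[-length(vals)]), .Machine$double.xmin)
  ifelse(rel < -rel_tol, -1L, ifelse(rel > rel_tol, 1L, 0L))
}

#' Classify depth behavior from (mu, sigma, h) vectors
#'
#' Labels the mean trend as `softening` (mu decreases with depth beyond
#' `rel_tol`), `stiffening` (increases), or `depth-independent` (all
#' consecutive changes within tolerance, or mixed up/down trends — flagged
#' in the note). The spread trend is labelled analogously as
#' `homogenizing`, `heterogenizing` or `stable-sigma`.
#'
#' @param vectors list of [musigmah_vector()] (or a list of
#'   [gaussian_summary()], converted automatically), >= 2, increasing depth.
#' @param rel_tol relative change regarded as meaningful (default 0.05).
#' @return list with `mu_trend`, `sigma_trend`, `note`.
#' @export
classify_depth_behavior <- function(vectors, rel_tol = 0.05) {
  vectors <- lapply(vectors, function(v)
    if (inherits(v, "gaussian_summary")) musigmah_vector(v) else v)
  ok <- vapply(vectors, inherits, logical(1), what = "musigmah_vector")
  if (!all(ok)) .stopf("classify_depth_behavior: entries must be musigmah_vector")
  if (length(vectors) < 2L)
    .stopf("classify_depth_behavior: need >= 2 vectors")
  z <- vapply(vectors, `[[`, numeric(1), "z")
  if (any(diff(z) <= 0))
    .stopf("classify_depth_behavior: vectors must be ordered by increasing depth")
  x <- vapply(vectors, `[[`, numeric(1), "x")
  y <- vapply(vectors, `[[`, numeric(1), "y")

  label <- function(steps, down, up, flat) {
    has_dn <- any(steps < 0L); has_up <- any(steps > 0L)
    if (has_dn && !has_up) list(lab = down, note = NULL)
    else if (has_up && !has_dn) list(lab = up, note = NULL)
    else if (!has_up && !has_dn) list(lab = flat, note = NULL)
    else list(lab = flat, note = "mixed trend (non-monotone beyond tolerance)")
  }
  mu_cl <- label(.trend_steps(x, rel_tol), "softening", "stiffening",
                 "depth-independent")
  sg_cl <- label(.trend_steps(y, rel_tol), "homogenizing", "heterogenizing",
                 "stable-sigma")
  note <- paste(stats::na.omit(c(
    if (!is.null(mu_cl$note)) paste("mu:", mu_cl$note),
    if (!is.null(sg_cl$note)) paste("sigma:", sg_cl$note))), collapse = "; ")
  list(mu_trend = mu_cl$lab, sigma_trend = sg_cl$lab,
       note = if (nzchar(note)) note else NA_character_)
}

#' Export summaries and vectors as CSV
#'
#' Columns: depth_nm, mu_kPa, sigma_kPa, n, x, y, z.
#'
#' @param summaries list of [gaussian_summary()].
#' @param path output CSV path.
#' @return The data frame written, invisibly.
#' @export
export_summaries <- function(summaries, path) {
  vecs <- lapply(summaries, musigmah_vector)
  df <- data.frame(
    depth_nm = vapply(summaries, function(s) m_to_nm(s$depth), numeric(1)),
    mu_kPa = vapply(summaries, function(s) pa_to_kpa(s$mu), numeric(1)),
    sigma_kPa = vapply(summaries, function(s) pa_to_kpa(s$sigma), numeric(1)),
    n = vapply(summaries, `[[`, integer(1), "n"),
    x = vapply(vecs, `[[`, numeric(1), "x"),
    y = vapply(vecs, `[[`, numeric(1), "y"),
    z = vapply(vecs, `[[`, numeric(1), "z"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
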