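# Assembling per-pixel profiles into depth-sliced average-modulus maps —
# the 3D characterization — plus substrate-region masking and text export.

#' Depth-sliced modulus map
#'
#' One 2D map of average Young's modulus values, valid at a single
#' indentation depth.
#'
#' @param depth indentation depth in metres, > 0.
#' @param values `(ny, nx)` numeric matrix of moduli in pascals (NA where a
#'   pixel failed or is empty).
#' @param mask `(ny, nx)` logical matrix, TRUE = excluded from downstream
#'   statistics. Defaults to masking the non-finite values.
#' @param metadata named list (estimator, provenance).
#' @return An object of class `depth_map`.
#' @export
depth_map <- function(depth, values, mask = NULL, metadata = list()) {
  if (!is.matrix(values)) .stopf("depth_map: 'values' must be a matrix")
  if (!is.finite(depth) || depth <= 0) .stopf("depth_map: depth must be > 0")
  if (is.null(mask)) mask <- !is.finite(values)
  if (!identical(dim(mask), dim(values)))
    .stopf("depth_map: mask and values dimensions differ")
  mask <- mask | !is.finite(values)
  if (any(values[!mask] < 0)) .stopf("depth_map: unmasked values must be >= 0")
  structure(list(depth = depth, values = values, mask = mask,
                 metadata = metadata),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> h = %.4g nm, %d x %d pixels, %d masked\n",
              m_to_nm(x$depth), nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' Stack of depth-sliced modulus maps
#'
#' An ordered set of M [depth_map()]s sharing one pixel grid, with strictly
#' increasing depths: the full 3D mechanical characterization of an area.
#'
#' @param maps list of [depth_map()], any order; sorted by depth on
#'   construction.
#' @param metadata named list.
#' @return An object of class `map_stack`.
#' @export
map_stack <- function(maps, metadata = list()) {
  if (length(maps) < 1L) .stopf("map_stack: need at least one map")
  ok <- vapply(maps, inherits, logical(1), what = "depth_map")
  if (!all(ok)) .stopf("map_stack: all entries must be depth_map objects")
  depths <- vapply(maps, `[[`, numeric(1), "depth")
  maps <- maps[order(depths)]
  depths <- sort(depths)
  if (any(diff(depths) <= 0)) .stopf("map_stack: depths must be distinct")
  dims <- lapply(maps, function(m) dim(m$values))
  if (length(unique(dims)) != 1L) .stopf("map_stack: maps differ in shape")
  structure(list(maps = maps, depths = depths, M = length(maps),
                 metadata = metadata),
            class = "map_stack")
}

#' @export
print.map_stack <- function(x, ...) {
  d <- dim(x$maps[[1]]$values)
  cat(sprintf("<map_stack> M = %d depth slices (%s nm), %d x %d pixels\n",
              x$M, paste(signif(m_to_nm(x$depths), 4), collapse = ", "),
              d[1], d[2]))
  invisible(x)
}

#' Build depth-sliced modulus maps from a force-volume grid
#'
#' Runs the per-pixel truncated-window (or pointwise) modulus estimate at
#' every depth of the grid and assembles one [depth_map()] per depth.
#' Pixels that are empty or fail at a depth are masked there. Processing is
#' pixel-independent: the result does not depend on evaluation order.
#'
#' @param grid an [fv_grid()].
#' @param geometry an [indenter_geometry()].
#' @param v Poisson's ratio (default 0.5).
#' @param depth_grid strictly increasing depths in metres; default
#'   [default_depth_grid()] with `M = 8`.
#' @param estimator `"windowed_ls"` or `"pointwise"`.
#' @param min_points minimum in-window samples for the windowed estimator.
#' @return A [map_stack()] with M = `length(depth_grid)` slices.
#' @export
build_depth_maps <- function(grid, geometry, v = 0.5, depth_grid = NULL,
                             estimator = c("windowed_ls", "pointwise"),
                             min_points = 5L) {
  stopifnot(inherits(grid, "fv_grid"))
  estimator <- match.arg(estimator)
  if (is.null(depth_grid)) depth_grid <- default_depth_grid(grid)
  maxima <- vapply(grid$curves, function(cu)
    if (is.null(cu)) NA_real_ else max(cu$h), numeric(1))
  n_live <- sum(is.finite(maxima))
  reach <- vapply(depth_grid, function(d)
    sum(maxima >= d * (1 - 1e-12), na.rm = TRUE), numeric(1))
  if (any(reach < n_live / 2)) {
    bad <- depth_grid[which(reach < n_live / 2)[1]]
    .stopf(paste0("build_depth_maps: depth %.4g nm reachable by only %d/%d pixels ",
                  "(< 50%%); per-pixel max depths range %.4g-%.4g nm"),
           m_to_nm(bad), min(reach), n_live,
           m_to_nm(min(maxima, na.rm = TRUE)), m_to_nm(max(maxima, na.rm = TRUE)))
  }
  M <- length(depth_grid)
  vals <- array(NA_real_, dim = c(grid$ny, grid$nx, M))
  for (r in seq_len(grid$ny) - 1L) {
    for (c in seq_len(grid$nx) - 1L) {
      curve <- fv_pixel(grid, r, c)
      if (is.null(curve)) next
      prof <- suppressWarnings(
        modulus_depth_profile(curve, geometry, v, depth_grid,
                              estimator = estimator, min_points = min_points))
      vals[r + 1L, c + 1L, ] <- prof$E_avg
    }
  }
  meta <- list(estimator = estimator, poisson_ratio = v,
               geometry_kind = geometry$kind)
  maps <- lapply(seq_len(M), function(j)
    depth_map(depth_grid[j], vals[, , j, drop = TRUE], metadata = meta))
  map_stack(maps, metadata = meta)
}

.apply_mask_rule <- function(map, rule) {
  if (!is.list(rule) || is.null(names(rule)) || length(rule) < 1L)
    .stopf("mask rule must be a named list with elements among min/max/quantile")
  bad <- setdiff(names(rule), c("min", "max", "quantile"))
  if (length(bad)) .stopf("unknown mask rule element '%s'", bad[1])
  v <- map$values
  add <- matrix(FALSE, nrow(v), ncol(v))
  if (!is.null(rule$min)) {
    if (!is.finite(rule$min)) .stopf("mask rule 'min' must be finite")
    add <- add | (is.finite(v) & v < rule$min)
  }
  if (!is.null(rule$max)) {
    if (!is.finite(rule$max)) .stopf("mask rule 'max' must be finite")
    add <- add | (is.finite(v) & v > rule$max)
  }
  if (!is.null(rule$quantile)) {
    q <- rule$quantile
    if (!is.finite(q) || q <= 0 || q >= 1)
      .stopf("mask rule 'quantile' must lie in (0, 1)")
    live <- v[!map$mask]
    k <- length(live) - floor(q * length(live))   # mask the top (1-q) share
    if (k > 0L) {
      ord <- order(live, seq_along(live), decreasing = TRUE)  # value, then index
      cut_idx <- which(!map$mask)[ord[seq_len(k)]]
      sel <- matrix(FALSE, nrow(v), ncol(v))
      sel[cut_idx] <- TRUE
      add <- add | sel
    }
  }
  new_mask <- map$mask | add
  if (all(new_mask)) .warnf("mask rule excludes every pixel at depth %.4g nm",
                            m_to_nm(map$depth))
  depth_map(map$depth, map$values, new_mask, map$metadata)
}

#' Mask map pixels by a value threshold rule
#'
#' Marks pixels as excluded where a rule triggers; values are untouched.
#' This is how substrate-affected regions (anomalously stiff pixels over a
#' rigid support) are removed before distribution fitting. The rule is an
#' explicit user choice — there is no default cut. Applied to a stack, the
#' rule acts per slice. Masking only ever grows the mask.
#'
#' @param x a [depth_map()] or [map_stack()].
#' @param rule named list with any of `min` (Pa; mask below), `max` (Pa;
#'   mask above), `quantile` (in (0,1); mask the top `1 - q` fraction of
#'   unmasked values, ties broken by value then index).
#' @return Same class as `x`, with updated masks.
#' @export
mask_by_threshold <- function(x, rule) {
  if (inherits(x, "depth_map")) return(.apply_mask_rule(x, rule))
  if (inherits(x, "map_stack")) {
    maps <- lapply(x$maps, .apply_mask_rule, rule = rule)
    return(map_stack(maps, x$metadata))
  }
  .stopf("mask_by_threshold: 'x' must be a depth_map or map_stack")
}

#' Export a map stack as text files
#'
#' Writes, under `out_dir`:
#' * one TSV matrix per depth slice (`map_h<depth>nm.tsv`, masked cells as
#'   literal `NA`),
#' * `stack_long.csv` — long format with columns
#'   `row, col, depth_nm, E_avg_kPa` (masked pixels omitted),
#' * `stack_sidecar.json` — depths, units, estimator, per-slice mask counts.
#'
#' @param stack a [map_stack()].
#' @param out_dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
export_stack <- function(stack, out_dir) {
  stopifnot(inherits(stack, "map_stack"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  long <- list()
  for (j in seq_len(stack$M)) {
    m <- stack$maps[[j]]
    d_nm <- m_to_nm(m$depth)
    vals <- pa_to_kpa(m$values)
    vals[m$mask] <- NA_real_
    tsv <- file.path(out_dir, sprintf("map_h%gnm.tsv", d_nm))
    utils::write.table(format(vals, digits = 12, trim = TRUE, scientific = NA),
                       tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "NA")
    written <- c(written, tsv)
    live <- which(!m$mask, arr.ind = TRUE)
    if (nrow(live)) {
      long[[j]] <- data.frame(row = live[, 1] - 1L, col = live[, 2] - 1L,
                              depth_nm = d_nm,
                              E_avg_kPa = vals[live])
    }
  }
  long_df <- do.call(rbind, long)
  csv <- file.path(out_dir, "stack_long.csv")
  utils::write.csv(format(long_df, digits = 12, trim = TRUE, scientific = NA),
                   csv, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    depths_nm = m_to_nm(stack$depths),
    units = list(depth = "nm", modulus = "kPa"),
    estimator = stack$metadata$estimator %||% NA,
    geometry_kind = stack$metadata$geometry_kind %||% NA,
    poisson_ratio = stack$metadata$poisson_ratio %||% NA,
    shape = dim(stack$maps[[1]]$values),
    mask_counts = vapply(stack$maps, function(m) sum(m$mask), numeric(1))
  )
  side <- file.path(out_dir, "stack_sidecar.json")
  jsonlite::write_json(sidecar, side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(written, csv, side))
}

#' Re-import a stack exported by [export_stack()]
#'
#' Reads the long CSV plus sidecar back into a [map_stack()]; pixels absent
#' from the CSV come back masked. Used for round-trip validation and by the
#' reporting command.
#'
#' @param out_dir directory previously written by [export_stack()].
#' @return A [map_stack()].
#' @export
import_stack <- function(out_dir) {
  side <- jsonlite::read_json(file.path(out_dir, "stack_sidecar.json"),
                              simplifyVector = TRUE)
  long <- utils::read.csv(file.path(out_dir, "stack_long.csv"))
  ny <- side$shape[1]; nx <- side$shape[2]
  maps <- lapply(side$depths_nm, function(d_nm) {
    vals <- matrix(NA_real_, ny, nx)
    sel <- abs(long$depth_nm - d_nm) < 1e-9 * max(1, d_nm)
    sub <- long[sel, ]
    vals[cbind(sub$row + 1L, sub$col + 1L)] <- kpa_to_pa(sub$E_avg_kPa)
    depth_map(nm_to_m(d_nm), vals)
  })
  map_stack(maps, metadata = list(estimator = side$estimator,
                                  poisson_ratio = side$poisson_ratio,
                                  geometry_kind = side$geometry_kind))
}
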