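# Reading, validating and writing force curves and force-volume grids.
# On-disk dialect: UTF-8 delimited text, '#'-prefixed "key: value" header
# lines with a mandatory "units:" line, then whitespace-separated columns,
# either (h, F) or raw (z, d). Grids are described by a JSON manifest.

#' Force-indentation curve
#'
#' Container for one force-indentation record: depths `h` (metres, from the
#' contact point) and forces `F` (newtons). Construction validates the
#' invariants: equal lengths, `h >= 0` strictly increasing, finite forces.
#' Use [repair_force_curve()] for raw data that may need sorting or
#' duplicate-depth averaging first.
#'
#' @param h indentation depths in metres, non-negative, strictly increasing.
#' @param F forces in newtons, finite, same length as `h`.
#' @param pixel_index optional integer `c(row, col)`, 0-based, row-major,
#'   top-left origin.
#' @param metadata named list (spring constant `k_N_per_m`, `probe_id`,
#'   `source_file`, ...).
#' @param min_samples minimum accepted number of samples (default 2 for
#'   programmatic construction; file readers default to 8).
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(h, F, pixel_index = NULL, metadata = list(),
                        min_samples = 2L) {
  h <- as.numeric(h); F <- as.numeric(F)
  if (length(h) != length(F)) .stopf("force_curve: h and F lengths differ")
  if (length(h) < min_samples)
    .stopf("force_curve: %d samples < required minimum %d", length(h), min_samples)
  if (any(!is.finite(h)) || any(h < 0))
    .stopf("force_curve: depths must be finite and >= 0")
  if (any(diff(h) <= 0)) .stopf("force_curve: depths must be strictly increasing")
  if (any(!is.finite(F))) .stopf("force_curve: forces must be finite")
  if (!is.null(pixel_index)) {
    pixel_index <- as.integer(pixel_index)
    if (length(pixel_index) != 2L || any(pixel_index < 0L))
      .stopf("force_curve: pixel_index must be 0-based c(row, col)")
  }
  structure(list(h = h, F = F, pixel_index = pixel_index, metadata = metadata),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d samples, depth %.4g-%.4g nm, max force %.4g nN\n",
              length(x$h), m_to_nm(min(x$h)), m_to_nm(max(x$h)),
              n_to_nn(max(abs(x$F)))))
  invisible(x)
}

#' Repair raw (h, F) samples into valid curve order
#'
#' Stable-sorts by depth and averages forces at duplicated depths, reporting
#' how many rows were reordered or merged. Negative depths are an error
#' (they indicate an unsubtracted contact point, not noise to repair).
#'
#' @inheritParams force_curve
#' @return list with `h`, `F`, `n_reordered`, `n_merged`.
#' @export
repair_force_curve <- function(h, F) {
  ord <- order(h)                    # radix sort, stable
  n_reordered <- sum(ord != seq_along(h))
  h <- h[ord]; F <- F[ord]
  dup <- duplicated(h)
  n_merged <- sum(dup)
  if (n_merged > 0L) {
    F <- as.numeric(tapply(F, match(h, unique(h)), mean))
    h <- unique(h)
  }
  list(h = h, F = F, n_reordered = n_reordered, n_merged = n_merged)
}

# Parse '#'-header key: value lines. Returns list(header=named list, data=matrix).
.read_dialect <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  is_head <- grepl("^\\s*#", lines)
  header <- list()
  for (ln in lines[is_head]) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (!nzchar(body)) next
    if (grepl(":", body, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", body))
      val <- trimws(sub("^[^:]*:", "", body))
      header[[key]] <- val
    }
  }
  data_lines <- lines[!is_head & nzchar(trimws(lines))]
  if (length(data_lines) == 0L) .stopf("%s: no data rows", path)
  fields <- strsplit(trimws(data_lines), "[,\t ]+")
  ncol <- lengths(fields)
  if (any(ncol != 2L))
    .stopf("%s: expected 2 columns, line %d has %d",
           path, which(ncol != 2L)[1], ncol[which(ncol != 2L)[1]])
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (any(is.na(vals))) .stopf("%s: non-numeric data value", path)
  list(header = header,
       data = matrix(vals, ncol = 2L, byrow = TRUE))
}

.parse_units <- function(header, path) {
  if (is.null(header[["units"]]))
    .stopf("%s: mandatory '# units:' header line missing", path)
  u <- strsplit(trimws(header[["units"]]), "\\s+")[[1]]
  if (length(u) != 2L)
    .stopf("%s: 'units:' line must name two units, got '%s'",
           path, header[["units"]])
  u
}

#' Read a force curve from a delimited text file
#'
#' Accepts the documented dialect: '#' header lines with `key: value` pairs,
#' a mandatory `units:` line naming the two column units, then two columns,
#' either `(h, F)` (default) or raw `(z, d)` piezo-displacement/deflection
#' pairs declared via `# columns: z d` plus a `# k_N_per_m:` spring
#' constant (converted through [deflection_to_force_indentation()]).
#' Values are converted to SI on read. Non-monotone or duplicated depths
#' are repaired by stable sorting and duplicate averaging, with a message
#' reporting the repair count.
#'
#' @param path file path.
#' @param min_samples minimum number of samples (default 8).
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path, min_samples = 8L) {
  if (!file.exists(path)) .stopf("read_force_curve: no such file '%s'", path)
  parsed <- .read_dialect(path)
  units <- .parse_units(parsed$header, path)
  columns <- tolower(parsed$header[["columns"]] %||% "h F")
  cols <- strsplit(trimws(columns), "\\s+")[[1]]
  meta <- parsed$header
  meta$units <- NULL; meta$columns <- NULL
  meta$source_file <- path
  x1 <- parsed$data[, 1] * .unit_factor(units[1])
  x2 <- parsed$data[, 2] * .unit_factor(units[2])
  if (identical(cols, c("z", "d"))) {
    k <- as.numeric(parsed$header[["k_N_per_m"]])
    if (!length(k) || is.na(k))
      .stopf("%s: '# columns: z d' requires a '# k_N_per_m:' header", path)
    curve <- deflection_to_force_indentation(x1, x2, k,
                                             min_samples = min_samples)
    curve$metadata <- utils::modifyList(meta, curve$metadata)
    return(curve)
  }
  if (!identical(cols, c("h", "f")))
    .stopf("%s: unsupported 'columns:' declaration '%s'", path, columns)
  rep <- repair_force_curve(x1, x2)
  if (rep$n_reordered + rep$n_merged > 0L)
    message(sprintf("read_force_curve: %s: repaired %d reordered and merged %d duplicate-depth rows",
                    basename(path), rep$n_reordered, rep$n_merged))
  force_curve(rep$h, rep$F, metadata = meta, min_samples = min_samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a force curve to the delimited text dialect
#'
#' Emits full-precision (h, F) columns in nm / nN with a '#' header that
#' round-trips metadata, so `read_force_curve(write_force_curve(x))` is the
#' identity to better than 1e-12 relative.
#'
#' @param curve a [force_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# afm3d force curve", con)
  writeLines("# units: nm nN", con)
  writeLines("# columns: h F", con)
  meta <- curve$metadata
  meta$source_file <- NULL
  for (key in names(meta)) {
    val <- meta[[key]]
    if (is.null(val) || length(val) == 0L) next
    writeLines(sprintf("# %s: %s", key, paste(format(val, digits = 17), collapse = " ")), con)
  }
  if (!is.null(curve$pixel_index))
    writeLines(sprintf("# pixel: %d %d", curve$pixel_index[1], curve$pixel_index[2]), con)
  writeLines(sprintf("%.17g %.17g", m_to_nm(curve$h), n_to_nn(curve$F)), con)
  invisible(path)
}

#' Convert raw piezo-displacement / deflection data to a force curve
#'
#' Standard AFM kinematics for a calibrated cantilever: force `F = k d` and
#' indentation `h = z - d`, where `z` is the piezo displacement past the
#' contact point and `d` the cantilever deflection (both metres). Samples
#' with `h < 0` (pre-contact) are clipped. Assumes the contact point is at
#' the z-origin; pass `z - z0` otherwise.
#'
#' @param z piezo displacement past contact, metres.
#' @param d cantilever deflection, metres, same length.
#' @param k cantilever spring constant, N/m, > 0.
#' @param min_samples minimum samples for the resulting curve.
#' @return A [force_curve()] with `k_N_per_m` recorded in metadata.
#' @export
deflection_to_force_indentation <- function(z, d, k, min_samples = 2L) {
  if (length(z) != length(d)) .stopf("z and d lengths differ")
  if (!is.finite(k) || k <= 0) .stopf("spring constant k must be > 0")
  F <- k * d
  h <- z - d
  keep <- h >= 0
  rep <- repair_force_curve(h[keep], F[keep])
  force_curve(rep$h, rep$F, metadata = list(k_N_per_m = k),
              min_samples = min_samples)
}

#' Force-volume grid
#'
#' A row-major `(ny, nx)` grid of [force_curve()] objects with top-left
#' origin and 0-based pixel coordinates. Missing pixels are held as explicit
#' `NULL` entries, never dropped.
#'
#' @param curves list of length `ny * nx`, row-major: entry
#'   `r * nx + c + 1` is pixel `(r, c)`; `NULL` marks an empty pixel.
#' @param ny,nx grid dimensions, >= 1.
#' @param pixel_size pixel pitch in metres, or NULL if unknown.
#' @param metadata named list.
#' @return An object of class `fv_grid`.
#' @export
fv_grid <- function(curves, ny, nx, pixel_size = NULL, metadata = list()) {
  ny <- as.integer(ny); nx <- as.integer(nx)
  if (ny < 1L || nx < 1L) .stopf("fv_grid: dimensions must be >= 1")
  if (length(curves) != ny * nx)
    .stopf("fv_grid: %d curves but ny*nx = %d", length(curves), ny * nx)
  ok <- vapply(curves, function(x) is.null(x) || inherits(x, "force_curve"),
               logical(1))
  if (!all(ok)) .stopf("fv_grid: entries must be force_curve or NULL")
  structure(list(curves = curves, ny = ny, nx = nx,
                 pixel_size = pixel_size, metadata = metadata),
            class = "fv_grid")
}

#' @export
print.fv_grid <- function(x, ...) {
  n_empty <- sum(vapply(x$curves, is.null, logical(1)))
  cat(sprintf("<fv_grid> %d x %d pixels (%d empty)%s\n", x$ny, x$nx, n_empty,
              if (!is.null(x$pixel_size))
                sprintf(", pitch %.3g nm", m_to_nm(x$pixel_size)) else ""))
  invisible(x)
}

#' Retrieve the curve at pixel (row, col)
#'
#' @param grid an [fv_grid()].
#' @param row,col 0-based pixel coordinates, top-left origin.
#' @return The [force_curve()] at that pixel, or NULL if empty.
#' @export
fv_pixel <- function(grid, row, col) {
  stopifnot(inherits(grid, "fv_grid"))
  if (row < 0 || row >= grid$ny || col < 0 || col >= grid$nx)
    .stopf("fv_pixel: (%d, %d) outside %d x %d grid", row, col, grid$ny, grid$nx)
  grid$curves[[row * grid$nx + col + 1L]]
}

#' Read a force-volume grid from a JSON manifest
#'
#' The manifest declares `nx`, `ny`, optional `pixel_size_nm`, and either
#' `paths` — an array of objects `{row, col, path}` with per-pixel curve
#' files (paths relative to the manifest) — or `packed_table` — one
#' delimited file with columns `row, col, h, F` (header line naming the
#' columns; units declared by manifest fields `units_length` / `units_force`,
#' default nm / nN). Pixels absent from either source load as explicit empty
#' pixels with a warning.
#'
#' @param manifest_path path to the JSON manifest.
#' @param min_samples minimum samples per curve (default 8).
#' @return An [fv_grid()].
#' @export
read_force_volume <- function(manifest_path, min_samples = 8L) {
  if (!file.exists(manifest_path))
    .stopf("read_force_volume: no such manifest '%s'", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (fld in c("nx", "ny"))
    if (is.null(man[[fld]])) .stopf("manifest missing field '%s'", fld)
  nx <- as.integer(man$nx); ny <- as.integer(man$ny)
  base <- dirname(manifest_path)
  pixel_size <- if (!is.null(man$pixel_size_nm)) nm_to_m(man$pixel_size_nm) else NULL
  curves <- vector("list", ny * nx)

  if (!is.null(man$packed_table)) {
    tab_path <- file.path(base, man$packed_table)
    if (!file.exists(tab_path)) .stopf("packed table '%s' not found", tab_path)
    tab <- utils::read.csv(tab_path, comment.char = "#")
    need <- c("row", "col", "h", "F")
    if (!all(need %in% names(tab)))
      .stopf("packed table must have columns %s", paste(need, collapse = ", "))
    fl <- .unit_factor(man$units_length %||% "nm")
    ff <- .unit_factor(man$units_force %||% "nN")
    if (any(tab$row < 0 | tab$row >= ny | tab$col < 0 | tab$col >= nx))
      .stopf("packed table pixel index outside %d x %d grid", ny, nx)
    key <- tab$row * nx + tab$col + 1L
    for (idx in unique(key)) {
      sel <- key == idx
      rep <- repair_force_curve(tab$h[sel] * fl, tab$F[sel] * ff)
      rc <- c((idx - 1L) %/% nx, (idx - 1L) %% nx)
      curves[[idx]] <- force_curve(rep$h, rep$F, pixel_index = rc,
                                   min_samples = min_samples)
    }
  } else if (!is.null(man$paths)) {
    p <- man$paths
    if (is.null(dim(p))) p <- as.data.frame(p)
    if (any(p$row < 0 | p$row >= ny | p$col < 0 | p$col >= nx))
      .stopf("manifest pixel index outside %d x %d grid", ny, nx)
    for (i in seq_len(nrow(p))) {
      idx <- p$row[i] * nx + p$col[i] + 1L
      fpath <- file.path(base, p$path[i])
      if (!file.exists(fpath)) {
        .warnf("read_force_volume: pixel (%d, %d) file '%s' missing; loaded as empty pixel",
               p$row[i], p$col[i], p$path[i])
        next
      }
      curve <- read_force_curve(fpath, min_samples = min_samples)
      curve$pixel_index <- c(p$row[i], p$col[i])
      curves[[idx]] <- curve
    }
  } else {
    .stopf("manifest must provide either 'paths' or 'packed_table'")
  }

  n_empty <- sum(vapply(curves, is.null, logical(1)))
  if (n_empty > 0L && is.null(man$packed_table) &&
      nrow(as.data.frame(man$paths)) == ny * nx) {
    # already warned per pixel above
  } else if (n_empty > 0L) {
    .warnf("read_force_volume: %d of %d pixels empty", n_empty, ny * nx)
  }
  fv_grid(curves, ny = ny, nx = nx, pixel_size = pixel_size,
          metadata = list(manifest = manifest_path))
}

#' Write a force-volume grid (per-pixel files + manifest)
#'
#' @param grid an [fv_grid()].
#' @param out_dir output directory (created if needed).
#' @return Path to the written manifest, invisibly.
#' @export
write_force_volume <- function(grid, out_dir) {
  stopifnot(inherits(grid, "fv_grid"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (r in seq_len(grid$ny) - 1L) {
    for (c in seq_len(grid$nx) - 1L) {
      curve <- fv_pixel(grid, r, c)
      if (is.null(curve)) next
      fname <- sprintf("pixel_r%03d_c%03d.txt", r, c)
      write_force_curve(curve, file.path(out_dir, fname))
      paths[[length(paths) + 1L]] <- list(row = r, col = c, path = fname)
    }
  }
  man <- list(nx = grid$nx, ny = grid$ny, paths = paths)
  if (!is.null(grid$pixel_size)) man$pixel_size_nm <- m_to_nm(grid$pixel_size)
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man_path)
}

#' Detect the contact point in a raw signal
#'
#' Ratio-of-variances scan: for each candidate split index the signal
#' variance in a window just after the split is compared with the variance
#' in a window just before it, and the split maximizing the after/before
#' ratio is the estimated contact point. Before contact the deflection is
#' flat noise (low variance); after contact it rises steeply (high
#' variance), so the ratio peaks where the windows straddle the kink. The
#' score is invariant to constant signal offsets; deterministic for a fixed
#' input. If no candidate clearly improves on the null (ratio near 1
#' everywhere, as for pure noise), a low-confidence flag is set and offset
#' 0 returned.
#'
#' @param z piezo position or depth axis, metres, length >= 32.
#' @param signal deflection or force signal, same length.
#' @param window window width in samples (default `max(8, n %/% 10)`).
#' @param min_ratio score threshold below which the result is flagged
#'   low-confidence (default 10; genuine contacts score orders of magnitude
#'   higher at typical signal-to-noise).
#' @return list with `index` (1-based sample index of the detected contact),
#'   `offset` (the `z` value there), `score`, `low_confidence`.
#' @export
detect_contact_point <- function(z, signal, window = NULL, min_ratio = 10) {
  n <- length(z)
  if (n != length(signal)) .stopf("detect_contact_point: length mismatch")
  if (n < 32L) .stopf("detect_contact_point: need >= 32 samples, got %d", n)
  w <- if (is.null(window)) max(8L, n %/% 10L) else as.integer(window)
  cand <- seq(w + 1L, n - w)
  eps <- 1e-12 * stats::var(signal) + 1e-300
  scores <- vapply(cand, function(i) {
    (stats::var(signal[i:(i + w)]) + eps) /
      (stats::var(signal[(i - w):i]) + eps)
  }, numeric(1))
  best <- which.max(scores)
  low <- scores[best] < min_ratio
  list(index = if (low) 1L else cand[best],
       offset = if (low) 0 else z[cand[best]],
       score = scores[best],
       low_confidence = low)
}
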