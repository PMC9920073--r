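# Internal unit handling. All computation is in strict SI (m, N, Pa);
# report/interface layers use the field's conventional nm / nN / kPa.

#' Unit conversion helpers
#'
#' All internal computation in afm3d is carried out in SI units (metres,
#' newtons, pascals). These helpers convert between SI and the reporting
#' units conventional in AFM nanomechanics: nanometres for depth,
#' nanonewtons for force and kilopascals for moduli.
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @examples
#' nm_to_m(100)      # 1e-7 m
#' pa_to_kpa(154e3)  # 154 kPa
#' @name units
NULL

#' @rdname units
#' @export
nm_to_m <- function(x) x * 1e-9

#' @rdname units
#' @export
m_to_nm <- function(x) x * 1e9

#' @rdname units
#' @export
nn_to_n <- function(x) x * 1e-9

#' @rdname units
#' @export
n_to_nn <- function(x) x * 1e9

#' @rdname units
#' @export
kpa_to_pa <- function(x) x * 1e3

#' @rdname units
#' @export
pa_to_kpa <- function(x) x * 1e-3

# Multiplicative factor taking a value in `unit` to SI. Supports the
# length/force units admitted in curve file headers.
.unit_factor <- function(unit) {
  switch(unit,
    "m"  = 1, "mm" = 1e-3, "um" = 1e-6, "nm" = 1e-9, "pm" = 1e-12,
    "N"  = 1, "mN" = 1e-3, "uN" = 1e-6, "nN" = 1e-9, "pN" = 1e-12,
    stop("unknown unit '", unit, "'", call. = FALSE)
  )
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
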