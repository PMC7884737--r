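#' Convert between the physical units used in hemodynamic analysis
#'
#' All conversions go through a single base unit per physical dimension so
#' that any path between two units of the same dimension yields the same
#' factor.  Supported dimensions and units:
#' \itemize{
#'   \item pressure: \code{"mmHg"}, \code{"dyn/cm2"}, \code{"Pa"}
#'     (1 mmHg = 1333.22 dyn/cm2 = 133.322 Pa)
#'   \item flow: \code{"mL/s"}, \code{"cm3/s"}, \code{"L/min"}
#'   \item velocity: \code{"m/s"}, \code{"cm/s"}
#'   \item length: \code{"mm"}, \code{"cm"}, \code{"m"}
#' }
#'
#' @param value numeric vector to convert.
#' @param from,to unit strings (see above).
#' @return `value` expressed in `to` units.
#' @examples
#' convert_units(1, "mmHg", "dyn/cm2")   # 1333.22
#' convert_units(4.7, "L/min", "mL/s")   # 78.33...
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value), length(from) == 1L, length(to) == 1L)
  dim_from <- .unit_dimension(from)
  dim_to <- .unit_dimension(to)
  if (is.na(dim_from)) {
    stop("unsupported unit: '", from, "'", call. = FALSE)
  }
  if (is.na(dim_to)) {
    stop("unsupported unit: '", to, "'", call. = FALSE)
  }
  if (dim_from != dim_to) {
    stop("unsupported unit pair: '", from, "' -> '", to,
         "' (different physical dimensions)", call. = FALSE)
  }
  value * .unit_factors[[dim_from]][[from]] / .unit_factors[[dim_to]][[to]]
}

# factor = how many base units one of this unit is
# base units: dyn/cm2 (pressure), mL/s (flow), m/s (velocity), m (length)
.unit_factors <- list(
  pressure = c("dyn/cm2" = 1, "mmHg" = 1333.22, "Pa" = 10),
  flow     = c("mL/s" = 1, "cm3/s" = 1, "L/min" = 1000 / 60),
  velocity = c("m/s" = 1, "cm/s" = 0.01),
  length   = c("m" = 1, "cm" = 0.01, "mm" = 0.001)
)

.unit_dimension <- function(unit) {
  for (d in names(.unit_factors)) {
    if (unit %in% names(.unit_factors[[d]])) return(d)
  }
  NA_character_
}

# single source of truth for the mmHg <-> CGS pressure factor
.mmhg_to_dyn_cm2 <- 1333.22
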