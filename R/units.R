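# Energy-rate units. Canonical internal unit is kcal/s: ground truth is
# per-second, and every estimator is converted to kcal/s before comparison.

.energy_units <- c("kcal/min", "kJ/min", "kcal/s", "kcal/day")

# kcal per unit of energy, seconds per unit of time
.kcal_per <- c(kcal = 1, kJ = 1 / 4.184)
.sec_per <- c(min = 60, s = 1, day = 86400)

.split_unit <- function(unit) {
  if (length(unit) != 1L || !unit %in% .energy_units) {
    stop("unknown energy-rate unit: ", paste(unit, collapse = ", "),
         " (known: ", paste(.energy_units, collapse = ", "), ")",
         call. = FALSE)
  }
  strsplit(unit, "/", fixed = TRUE)[[1L]]
}

#' Convert an energy rate between units
#'
#' Converts between the units used across the package: `kcal/min` (indirect
#' calorimetry, MET formula), `kJ/min` (Keytel), `kcal/day` (Mifflin-St Jeor
#' RMR) and the canonical `kcal/s`.  The kilojoule is the thermochemical one
#' (1 kcal = 4.184 kJ); conversions compose and round-trip to machine
#' precision.
#'
#' @param x numeric vector of rate values.
#' @param from,to unit strings, one of `"kcal/min"`, `"kJ/min"`, `"kcal/s"`,
#'   `"kcal/day"`.
#' @return numeric vector of `x` expressed in `to`.
#' @examples
#' convert_energy(4.184, "kJ/min", "kcal/min")  # 1
#' convert_energy(12.25, "kcal/min", "kcal/s")  # 0.2041667
#' @export
convert_energy <- function(x, from, to) {
  f <- .split_unit(from)
  t <- .split_unit(to)
  x * (.kcal_per[[f[1L]]] / .kcal_per[[t[1L]]]) *
    (.sec_per[[t[2L]]] / .sec_per[[f[2L]]])
}

#' Tag a numeric vector as an energy rate
#'
#' A light S3 wrapper carrying the unit, so mixed-unit arithmetic mistakes
#' (e.g. dividing a kcal/min EE by a kcal/day RMR) can be caught.  Most
#' package functions accept and return bare numerics with units documented;
#' use this wrapper where the unit should travel with the value.
#'
#' @param value numeric vector, must be finite.
#' @param unit unit string (see [convert_energy()]).
#' @return numeric vector of class `energy_rate` with a `unit` attribute.
#' @export
energy_rate <- function(value, unit) {
  .split_unit(unit)
  stopifnot(is.numeric(value), all(is.finite(value)))
  structure(as.numeric(value), unit = unit, class = "energy_rate")
}

#' @export
print.energy_rate <- function(x, ...) {
  cat("<energy_rate> [", attr(x, "unit"), "]\n", sep = "")
  print(as.numeric(x), ...)
  invisible(x)
}

#' @rdname energy_rate
#' @param x an `energy_rate` object.
#' @export
rate_unit <- function(x) {
  stopifnot(inherits(x, "energy_rate"))
  attr(x, "unit")
}

#' @rdname convert_energy
#' @export
convert <- function(x, to) {
  stopifnot(inherits(x, "energy_rate"))
  energy_rate(convert_energy(as.numeric(x), attr(x, "unit"), to), to)
}
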