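# Closed-form energy-expenditure equations. All functions are pure,
# deterministic and vectorized over their time-varying argument.

#' Indirect calorimetry: energy expenditure from oxygen consumption
#'
#' The caloric equivalent of oxygen: `EE (kcal/min) = VO2 * weight * 5 / 1000`,
#' with VO2 in mL/kg/min.  This is the ground-truth generator for the whole
#' package.
#'
#' @param vo2 oxygen consumption in mL/kg/min, >= 0 (vectorized).
#' @param weight_kg body mass in kg, > 0.
#' @return energy expenditure in kcal/min.
#' @examples
#' ee_from_vo2(35, 70)  # 12.25 kcal/min
#' @export
ee_from_vo2 <- function(vo2, weight_kg) {
  stopifnot(is.numeric(vo2), is.numeric(weight_kg))
  if (any(weight_kg <= 0)) stop("weight_kg must be > 0", call. = FALSE)
  if (any(vo2 < 0)) stop("vo2 must be >= 0", call. = FALSE)
  vo2 * weight_kg * 5 / 1000
}

#' Per-second ground-truth energy expenditure
#'
#' [ee_from_vo2()] divided by 60: the per-second ground truth used for
#' training and evaluation.
#'
#' @inheritParams ee_from_vo2
#' @return energy expenditure in kcal/s.
#' @export
gt_ee_per_second <- function(vo2, weight_kg) {
  ee_from_vo2(vo2, weight_kg) / 60
}

#' MET-based energy expenditure
#'
#' `EE (kcal/min) = MET * weight * 3.5 / 200`.  Requires the activity's MET
#' index to be known in advance.
#'
#' @param met activity intensity in METs, >= 0 (vectorized).
#' @param weight_kg body mass in kg, > 0.
#' @return energy expenditure in kcal/min.
#' @examples
#' ee_met(8, 70)  # 9.8 kcal/min
#' @export
ee_met <- function(met, weight_kg) {
  stopifnot(is.numeric(met), is.numeric(weight_kg))
  if (any(weight_kg <= 0)) stop("weight_kg must be > 0", call. = FALSE)
  if (any(met < 0)) stop("met must be >= 0", call. = FALSE)
  met * weight_kg * 3.5 / 200
}

#' MET index from energy expenditure and resting metabolic rate
#'
#' `MET = EE / RMR`.  Both arguments must be on the same unit; pass
#' [energy_rate()] objects to have the units checked.
#'
#' @param ee energy expenditure (numeric or `energy_rate`).
#' @param rmr resting metabolic rate in the same unit, > 0.
#' @return dimensionless MET value.
#' @export
met_from_ee <- function(ee, rmr) {
  if (inherits(ee, "energy_rate") || inherits(rmr, "energy_rate")) {
    if (!(inherits(ee, "energy_rate") && inherits(rmr, "energy_rate")) ||
        !identical(attr(ee, "unit"), attr(rmr, "unit"))) {
      stop("ee and rmr must carry the same unit", call. = FALSE)
    }
  }
  ee <- as.numeric(ee)
  rmr <- as.numeric(rmr)
  if (any(rmr <= 0)) stop("rmr must be > 0", call. = FALSE)
  ee / rmr
}

# Keytel et al. heart-rate regression coefficients (kJ/min)
.keytel_male <- c(intercept = -55.0969, hr = 0.6309, weight = 0.1988,
                  age = 0.2017)
.keytel_female <- c(intercept = -20.4022, hr = 0.4472, weight = -0.1263,
                    age = 0.074)

#' Keytel heart-rate-based energy expenditure
#'
#' The Keytel linear regression of energy expenditure on heart rate, weight
#' and age, with separate male/female coefficient sets selected by the
#' profile's gender flag.  Output is in kJ/min and is returned *unclamped*:
#' the regression is negative at very low heart rates, and whether to clamp
#' is an evaluation-level decision (see [keytel_series()]).
#'
#' @param profile a [participant_profile()].
#' @param hr heart rate in bpm, > 0 (vectorized).
#' @return energy expenditure in kJ/min (possibly negative).
#' @examples
#' p <- participant_profile(70, 175, 30, 1)
#' ee_keytel(p, 120)  # 40.5781 kJ/min
#' @export
ee_keytel <- function(profile, hr) {
  assert_profile(profile)
  stopifnot(is.numeric(hr))
  if (any(hr <= 0, na.rm = TRUE)) stop("hr must be > 0", call. = FALSE)
  k <- if (profile$gender_flag == 1L) .keytel_male else .keytel_female
  k[["intercept"]] + k[["hr"]] * hr + k[["weight"]] * profile$weight +
    k[["age"]] * profile$age
}

#' Mifflin-St Jeor resting metabolic rate
#'
#' Daily resting metabolic rate from weight, height, age and gender:
#' males `10 W + 6.25 H - 5 A + 5`, females `10 W + 6.25 H - 5 A - 161`
#' (kcal/day).
#'
#' @param profile a [participant_profile()].
#' @return RMR in kcal/day.
#' @examples
#' rmr_day_mifflin(participant_profile(70, 175, 30, 1))  # 1648.75
#' @export
rmr_day_mifflin <- function(profile) {
  assert_profile(profile)
  base <- 10 * profile$weight + 6.25 * profile$height - 5 * profile$age
  base + if (profile$gender_flag == 1L) 5 else -161
}

#' Resting metabolic rate per second
#'
#' [rmr_day_mifflin()] divided by exactly 86,400 s/day: the per-second
#' baseline that the activity-intensity coefficient scales.
#'
#' @param profile a [participant_profile()].
#' @return RMR in kcal/s.
#' @export
rmr_per_second <- function(profile) {
  rmr_day_mifflin(profile) / 86400
}

#' Predicted energy expenditure from an activity-intensity coefficient
#'
#' The model's output equation: `pred_EE (kcal/s) = RMR_sec * (1 + a)`, where
#' `a` is the learned activity-intensity coefficient (MET minus the resting
#' 1) on the discrete grid 0, 0.1, ..., 20.  Strictly increasing in `a`;
#' `a = 0` returns the resting rate itself.
#'
#' @param rmr_sec resting metabolic rate in kcal/s, > 0.
#' @param a activity-intensity coefficient in `[0, 20]` (vectorized).
#' @return predicted energy expenditure in kcal/s.
#' @examples
#' pred_ee(0.02, 9)  # 0.2 kcal/s
#' @export
pred_ee <- function(rmr_sec, a) {
  stopifnot(is.numeric(rmr_sec), is.numeric(a))
  if (any(rmr_sec <= 0)) stop("rmr_sec must be > 0", call. = FALSE)
  if (any(a < 0 | a > 20)) {
    stop("a must lie within the action grid range [0, 20]", call. = FALSE)
  }
  rmr_sec * (1 + a)
}
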