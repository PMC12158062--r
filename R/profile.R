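#' Participant profile
#'
#' Demographics consumed by the Mifflin-St Jeor and Keytel formulas and by
#' the reinforcement-learning state vector.
#'
#' @param weight_kg body mass in kilograms, > 0.
#' @param height_cm stature in centimetres, > 0.
#' @param age_y age in years, > 0.
#' @param gender_flag 1 for male, 0 for female (the Keytel and Mifflin
#'   conventions); `"male"`/`"female"` are also accepted.
#' @param id optional participant identifier.
#' @return an object of class `participant_profile`.
#' @examples
#' participant_profile(70, 175, 30, 1)
#' @export
participant_profile <- function(weight_kg, height_cm, age_y, gender_flag,
                                id = NULL) {
  if (is.character(gender_flag)) {
    gender_flag <- switch(tolower(gender_flag),
      male = 1L, m = 1L, female = 0L, f = 0L,
      stop("gender_flag string must be 'male' or 'female'", call. = FALSE)
    )
  }
  stopifnot(
    is.numeric(weight_kg), length(weight_kg) == 1L, is.finite(weight_kg),
    is.numeric(height_cm), length(height_cm) == 1L, is.finite(height_cm),
    is.numeric(age_y), length(age_y) == 1L, is.finite(age_y)
  )
  if (weight_kg <= 0) stop("weight_kg must be > 0", call. = FALSE)
  if (height_cm <= 0) stop("height_cm must be > 0", call. = FALSE)
  if (age_y <= 0) stop("age_y must be > 0", call. = FALSE)
  if (!(is.numeric(gender_flag) && length(gender_flag) == 1L &&
        gender_flag %in% c(0, 1))) {
    stop("gender_flag must be 0 (female) or 1 (male)", call. = FALSE)
  }
  structure(
    list(weight = as.numeric(weight_kg), height = as.numeric(height_cm),
         age = as.numeric(age_y), gender_flag = as.integer(gender_flag),
         id = id),
    class = "participant_profile"
  )
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf(
    "<participant_profile%s> %.1f kg, %.1f cm, %.0f y, %s\n",
    if (is.null(x$id)) "" else paste0(" ", x$id),
    x$weight, x$height, x$age,
    if (x$gender_flag == 1L) "male" else "female"
  ))
  invisible(x)
}

is_profile <- function(x) inherits(x, "participant_profile")

assert_profile <- function(x) {
  if (!is_profile(x)) {
    stop("expected a participant_profile; see ?participant_profile",
         call. = FALSE)
  }
  invisible(x)
}
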