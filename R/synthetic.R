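# Synthetic per-second wearable sessions emulating the 30-min
# sit/stand/cycle/run protocol: piecewise-constant target MET, first-order
# VO2 lag for cardiorespiratory transitions, linear HR-on-MET with AR(1)
# noise, and ground-truth EE via indirect calorimetry.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL draws from the current stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Activity protocol
#'
#' An ordered sequence of activity segments, each with a duration and a
#' target MET level.  The default protocol ([default_protocol()]) is six
#' 5-minute segments (Sitting, Standing, Cycle1, Cycle2, Run1, Run2)
#' totalling 30 minutes.
#'
#' @param segments a data.frame with columns `label` (segment name, see
#'   [normalize_segment_labels()]), `duration_s` (> 0) and `met_level`
#'   (>= 1).
#' @return an object of class `activity_protocol`.
#' @export
activity_protocol <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("label", "duration_s", "met_level") %in% names(segments)))
  segments$label <- normalize_segment_labels(segments$label)
  if (any(segments$duration_s <= 0)) {
    stop("segment durations must be > 0", call. = FALSE)
  }
  if (any(segments$met_level < 1)) {
    stop("met_level must be >= 1 (1 MET is the resting floor)",
         call. = FALSE)
  }
  segments$duration_s <- as.integer(segments$duration_s)
  structure(list(segments = segments), class = "activity_protocol")
}

#' @rdname activity_protocol
#' @param met_levels optional named numeric vector of MET levels per segment
#'   (names among `Sitting, Standing, Cycle1, Cycle2, Run1, Run2`); missing
#'   exercise segments are sampled uniformly within the observed ranges of
#'   [segment_met_ranges()].  Sitting (1.0) and Standing (1.2) are fixed.
#' @param segment_duration_s duration of each of the six segments (default
#'   300 s).
#' @param seed optional integer seed for the sampled MET levels; `NULL`
#'   draws from the current RNG stream.
#' @export
default_protocol <- function(met_levels = NULL, segment_duration_s = 300L,
                             seed = NULL) {
  ranges <- .segment_met_ranges
  local_seed(seed, {
    levels <- vapply(.segment_levels, function(seg) {
      if (!is.null(met_levels) && seg %in% names(met_levels)) {
        as.numeric(met_levels[[seg]])
      } else {
        r <- ranges[[seg]]
        if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
      }
    }, numeric(1))
    activity_protocol(data.frame(
      label = .segment_levels,
      duration_s = as.integer(segment_duration_s),
      met_level = unname(levels)
    ))
  })
}

#' @export
print.activity_protocol <- function(x, ...) {
  cat("<activity_protocol>", sum(x$segments$duration_s), "s total\n")
  print(x$segments)
  invisible(x)
}

protocol_duration <- function(protocol) sum(protocol$segments$duration_s)

#' Draw a random participant profile
#'
#' Demographics are sampled uniformly within the observed brackets of the
#' reference cohort: age 23-41 y, height 160-186 cm, weight 53-99 kg,
#' gender Bernoulli(0.5).
#'
#' @param seed optional integer seed; `NULL` draws from the current stream.
#' @param id optional participant identifier.
#' @return a [participant_profile()].
#' @export
generate_profile <- function(seed = NULL, id = NULL) {
  local_seed(seed, {
    participant_profile(
      weight_kg = stats::runif(1, 53, 99),
      height_cm = stats::runif(1, 160, 186),
      age_y = stats::runif(1, 23, 41),
      gender_flag = stats::rbinom(1, 1, 0.5),
      id = id
    )
  })
}

#' Per-second target MET trajectory of a protocol
#'
#' Expands the protocol into a piecewise-constant per-second series: the
#' target MET is the segment's level for every second of the segment, and
#' changes exactly at segment boundaries.
#'
#' @param protocol an [activity_protocol()].
#' @return a data.frame with columns `time_s` (0-based), `activity` and
#'   `met` (target MET).
#' @export
generate_met_trajectory <- function(protocol) {
  stopifnot(inherits(protocol, "activity_protocol"))
  seg <- protocol$segments
  n <- sum(seg$duration_s)
  data.frame(
    time_s = seq_len(n) - 1L,
    activity = factor(rep(as.character(seg$label), seg$duration_s),
                      levels = .segment_levels),
    met = rep(seg$met_level, seg$duration_s)
  )
}

#' Generate a synthetic per-second session
#'
#' Simulates one participant performing a protocol at 1 Hz:
#' \enumerate{
#'   \item target VO2 is `3.5 * MET_target` mL/kg/min (the MET definition);
#'   \item effective VO2 follows the target through a first-order lag with
#'     time constant `tau_s` (default 30 s), modelling the delay in reaching
#'     a steady physiological state at segment transitions;
#'   \item heart rate is linear in effective MET,
#'     `HR_t = hr_rest + hr_slope * (MET_eff - 1) + e_t`, with AR(1) noise
#'     `e_t = ar * e_(t-1) + N(0, noise_sd^2)` (innovation sd);
#'   \item ground-truth EE is indirect calorimetry on the effective VO2,
#'     per second ([gt_ee_per_second()]).
#' }
#' All draws flow from `seed`; identical inputs give identical sessions.
#'
#' @param profile a [participant_profile()].
#' @param protocol an [activity_protocol()]; `NULL` samples
#'   [default_protocol()] from the same stream.
#' @param hr_rest resting heart rate, bpm (default 65).
#' @param hr_slope heart-rate rise per MET, bpm/MET (default 9).
#' @param noise_sd sd of the AR(1) innovation on HR, bpm (default 2;
#'   0 gives a noise-free session).
#' @param ar AR(1) coefficient of the HR noise (default 0.9).
#' @param tau_s VO2 lag time constant in seconds (default 30; <= 0 disables
#'   the lag).
#' @param seed optional integer seed.
#' @return an object of class `session_record`: a list with `profile`,
#'   a per-second `data` frame (`time_s, hr_bpm, vo2_ml_kg_min, activity,
#'   met_true`) and the generator `params`.  Ground truth is available via
#'   [session_gt_ee()].
#' @export
generate_session <- function(profile, protocol = NULL, hr_rest = 65,
                             hr_slope = 9, noise_sd = 2, ar = 0.9,
                             tau_s = 30, seed = NULL) {
  assert_profile(profile)
  local_seed(seed, {
    if (is.null(protocol)) protocol <- default_protocol()
    traj <- generate_met_trajectory(protocol)
    n <- nrow(traj)
    target <- traj$met

    # first-order lag toward the target MET (equivalently toward target VO2)
    if (tau_s > 0) {
      alpha <- 1 - exp(-1 / tau_s)
      met_eff <- numeric(n)
      met_eff[1] <- target[1]
      for (t in seq_len(n - 1L)) {
        met_eff[t + 1L] <- met_eff[t] + alpha * (target[t + 1L] - met_eff[t])
      }
    } else {
      met_eff <- target
    }

    noise <- numeric(n)
    if (noise_sd > 0) {
      e <- stats::rnorm(n, 0, noise_sd)
      noise[1] <- e[1]
      for (t in seq_len(n - 1L)) noise[t + 1L] <- ar * noise[t] + e[t + 1L]
    }
    hr <- pmax(hr_rest + hr_slope * (met_eff - 1) + noise, 1)
    vo2 <- 3.5 * met_eff

    structure(
      list(
        profile = profile,
        data = data.frame(
          time_s = traj$time_s,
          hr_bpm = hr,
          vo2_ml_kg_min = vo2,
          activity = traj$activity,
          met_true = target
        ),
        params = list(
          hr_rest = hr_rest, hr_slope = hr_slope, noise_sd = noise_sd,
          ar = ar, tau_s = tau_s, seed = seed,
          protocol = protocol$segments
        )
      ),
      class = "session_record"
    )
  })
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record%s> %d s, %d segments\n",
              if (is.null(x$profile$id)) "" else paste0(" ", x$profile$id),
              nrow(x$data), length(unique(x$data$activity))))
  print(x$profile)
  invisible(x)
}

#' Session accessors
#'
#' `session_length()` is the duration in seconds; `session_gt_ee()` is the
#' per-second ground-truth EE (kcal/s), computed from the stored VO2 by
#' indirect calorimetry; `session_rmr_sec()` is the participant's
#' Mifflin-St Jeor RMR in kcal/s.
#'
#' @param session a `session_record`.
#' @return numeric scalar or per-second numeric vector.
#' @export
session_length <- function(session) {
  stopifnot(inherits(session, "session_record"))
  nrow(session$data)
}

#' @rdname session_length
#' @export
session_gt_ee <- function(session) {
  stopifnot(inherits(session, "session_record"))
  if (is.null(session$data$vo2_ml_kg_min) ||
      anyNA(session$data$vo2_ml_kg_min)) {
    stop("session has no complete VO2 series; ground truth unavailable",
         call. = FALSE)
  }
  gt_ee_per_second(session$data$vo2_ml_kg_min, session$profile$weight)
}

#' @rdname session_length
#' @export
session_rmr_sec <- function(session) {
  stopifnot(inherits(session, "session_record"))
  rmr_per_second(session$profile)
}
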