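# Episodic sliding-window environment: a window of L consecutive seconds of
# one session is an episode; the state at each second is
# [weight, height, age, gender, HR_t]; the action is an index into the
# discrete activity-intensity grid a = 0, 0.1, ..., 20; the reward is the
# normalized absolute prediction error -|GT - Pred| / (1 + GT).

#' The discrete activity-intensity action grid
#'
#' 201 coefficients `a = 0, 0.1, ..., 19.9, 20`; `action_to_coefficient()`
#' maps a 0-based action index onto the grid.
#'
#' @return `action_grid()`: the 201 coefficients in index order.
#' @export
action_grid <- function() {
  (0:200) / 10
}

#' @rdname action_grid
#' @param index integer action index (0-based, 0..200; vectorized).
#' @export
action_to_coefficient <- function(index) {
  if (any(index != round(index)) || any(index < 0L | index > 200L)) {
    stop("action index must be an integer in [0, 200]", call. = FALSE)
  }
  round(index) / 10
}

#' Normalized absolute-error reward
#'
#' `reward = -|gt - pred| / (1 + gt)`, in kcal/s on both sides.  Always
#' non-positive; zero exactly when the prediction equals the ground truth;
#' for a fixed absolute error the magnitude shrinks as the ground truth
#' grows (the normalization that stabilizes learning across intensities).
#'
#' @param gt_ee ground-truth EE, kcal/s, >= 0 (vectorized).
#' @param pred_ee predicted EE, kcal/s (vectorized).
#' @return reward values, <= 0.
#' @export
ee_reward <- function(gt_ee, pred_ee) {
  stopifnot(is.numeric(gt_ee), is.numeric(pred_ee))
  if (any(gt_ee < 0)) stop("gt_ee must be >= 0", call. = FALSE)
  -abs(gt_ee - pred_ee) / (1 + gt_ee)
}

#' Best grid action for a known ground truth
#'
#' Brute-force oracle: evaluates [ee_reward()] for all 201 grid actions
#' against `pred = rmr_sec * (1 + a)` and returns the argmax index, ties
#' broken toward the lowest index.  Used as the training diagnostic
#' ("what the policy should converge to") and by the oracle agent.
#'
#' @param gt_ee ground-truth EE, kcal/s (vectorized).
#' @param rmr_sec resting metabolic rate, kcal/s, > 0.
#' @return integer action indices (0-based).
#' @export
optimal_action <- function(gt_ee, rmr_sec) {
  stopifnot(is.numeric(gt_ee), length(rmr_sec) == 1L, rmr_sec > 0)
  preds <- pred_ee(rmr_sec, action_grid())           # 201 candidates
  # |gt - pred| minimal <=> reward maximal (denominator fixed per gt)
  vapply(gt_ee, function(g) which.min(abs(g - preds)) - 1L, integer(1))
}

#' Sliding windows over a session
#'
#' Window starts at `0, stride, 2*stride, ...` (0-based, half-open
#' `[t, t + length)`), so the count is
#' `floor((T - length) / stride) + 1`.
#'
#' @param session a `session_record`.
#' @param length_s window length in seconds (default 300).
#' @param stride_s shift between consecutive windows (default 1).
#' @return integer vector of 0-based window start times; empty (with a
#'   warning) if the session is shorter than `length_s`.
#' @export
make_windows <- function(session, length_s = 300L, stride_s = 1L) {
  stopifnot(inherits(session, "session_record"),
            length_s >= 1L, stride_s >= 1L)
  T_ <- session_length(session)
  if (T_ < length_s) {
    warning("session (", T_, " s) shorter than window length (", length_s,
            " s); no windows")
    return(integer(0))
  }
  seq.int(0L, T_ - length_s, by = stride_s)
}

#' Episodic environment over one session window
#'
#' Binds a window of a session into the conventional episodic-control
#' contract: [env_reset()] returns the first state, [env_step()] applies an
#' action index, computes the predicted EE via [pred_ee()] and the reward
#' via [ee_reward()] against the ground truth at the current second, then
#' advances.  `done` becomes `TRUE` exactly at the last second of the
#' window; stepping a finished window is an error.
#'
#' @param session a `session_record` with VO2 ground truth.
#' @param start 0-based window start within the session.
#' @param length_s window length in seconds.
#' @return an object of class `ee_env` (a mutable environment).
#' @export
ee_env <- function(session, start = 0L, length_s = 300L) {
  stopifnot(inherits(session, "session_record"))
  T_ <- session_length(session)
  start <- as.integer(start)
  length_s <- as.integer(length_s)
  if (start < 0L || start + length_s > T_) {
    stop("window [", start, ", ", start + length_s,
         ") lies outside the session of length ", T_, call. = FALSE)
  }
  e <- new.env(parent = emptyenv())
  e$profile <- session$profile
  e$hr <- session$data$hr_bpm[(start + 1L):(start + length_s)]
  e$gt <- session_gt_ee(session)[(start + 1L):(start + length_s)]
  e$rmr_sec <- rmr_per_second(session$profile)
  e$length <- length_s
  e$start <- start
  e$cursor <- 0L
  e$done <- FALSE
  class(e) <- "ee_env"
  e
}

#' @export
print.ee_env <- function(x, ...) {
  cat(sprintf("<ee_env> window [%d, %d), cursor %d, %s\n",
              x$start, x$start + x$length, x$cursor,
              if (x$done) "done" else "running"))
  invisible(x)
}

#' State vector at a window position
#'
#' Assembles `[weight, height, age, gender_flag, HR_t]` (raw scales; the
#' agent owns any standardization).
#'
#' @param env an [ee_env()].
#' @param t 0-based position within the window (default: the cursor).
#' @return named numeric vector of length 5.
#' @export
state_at <- function(env, t = env$cursor) {
  stopifnot(inherits(env, "ee_env"))
  if (t < 0L || t >= env$length) {
    stop("t = ", t, " outside window of length ", env$length, call. = FALSE)
  }
  c(weight = env$profile$weight, height = env$profile$height,
    age = env$profile$age, gender = as.numeric(env$profile$gender_flag),
    hr = env$hr[t + 1L])
}

#' @rdname ee_env
#' @param env an `ee_env`.
#' @return `env_reset()`: the first state vector.
#' @export
env_reset <- function(env) {
  stopifnot(inherits(env, "ee_env"))
  env$cursor <- 0L
  env$done <- FALSE
  state_at(env, 0L)
}

#' @rdname ee_env
#' @param action_index integer in 0..200.
#' @return `env_step()`: a list with `state` (the next state, `NULL` when
#'   done), `reward`, `done`, and the diagnostic `pred_ee`, `gt_ee`, `a`.
#' @export
env_step <- function(env, action_index) {
  stopifnot(inherits(env, "ee_env"))
  if (env$done) stop("environment is done; reset before stepping",
                     call. = FALSE)
  a <- action_to_coefficient(action_index)
  t <- env$cursor
  pred <- pred_ee(env$rmr_sec, a)
  r <- ee_reward(env$gt[t + 1L], pred)
  env$cursor <- t + 1L
  env$done <- env$cursor >= env$length
  list(
    state = if (env$done) NULL else state_at(env, env$cursor),
    reward = r,
    done = env$done,
    pred_ee = pred,
    gt_ee = env$gt[t + 1L],
    a = a
  )
}
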