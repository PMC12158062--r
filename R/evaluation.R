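# Evaluation protocol: per-second EE series for the learned estimator and
# the two formula baselines (Keytel, MET), overall and per-activity-segment
# MAE in kcal/s, and the scenario-length ablation.

#' Keytel baseline series for a session
#'
#' Per-second Keytel EE converted kJ/min -> kcal/s.  Negative values (the
#' regression crosses zero at low heart rates) are clamped to 0 by default;
#' the number of clamped seconds is attached as attribute `n_clamped`.
#' Missing heart-rate seconds are forward-filled (leading gap back-filled)
#' under `fill = "locf"`, with the count in attribute `n_filled`;
#' `fill = "none"` leaves them `NA`.
#'
#' @param session a `session_record` with heart rate.
#' @param clamp clamp negative outputs to 0 (default `TRUE`).
#' @param fill `"locf"` (default) or `"none"`.
#' @return numeric vector of kcal/s, one per second, with attributes
#'   `n_clamped` and `n_filled`.
#' @export
keytel_series <- function(session, clamp = TRUE, fill = c("locf", "none")) {
  stopifnot(inherits(session, "session_record"))
  fill <- match.arg(fill)
  hr <- session$data$hr_bpm
  n_filled <- sum(is.na(hr))
  if (n_filled > 0 && fill == "locf") {
    if (all(is.na(hr))) stop("session has no heart-rate data", call. = FALSE)
    idx <- seq_along(hr)
    known <- which(!is.na(hr))
    # last observation carried forward; leading gap backfilled
    hr <- hr[known][pmax(findInterval(idx, known), 1L)]
  }
  ee <- convert_energy(ee_keytel(session$profile, hr), "kJ/min", "kcal/s")
  n_clamped <- 0L
  if (clamp) {
    n_clamped <- sum(ee < 0, na.rm = TRUE)
    ee <- pmax(ee, 0)
  }
  structure(ee, n_clamped = n_clamped,
            n_filled = if (fill == "locf") n_filled else 0L)
}

#' MET baseline series for a session
#'
#' Per-second MET-based EE, `MET_segment * weight * 3.5 / 200 / 60` kcal/s,
#' piecewise constant over the activity segments.  Segment MET levels come
#' from the session's `met_true` column unless `met_per_segment` supplies
#' them (named by canonical segment label); `met_offset` shifts every
#' segment level, which is how a deliberately mis-specified MET table is
#' constructed in the evaluation.
#'
#' @param session a `session_record` with activity labels.
#' @param met_per_segment optional named numeric vector (names among the
#'   canonical segment labels).
#' @param met_offset additive offset applied to all segment levels
#'   (default 0).
#' @return numeric vector of kcal/s, one per second.
#' @export
met_series <- function(session, met_per_segment = NULL, met_offset = 0) {
  stopifnot(inherits(session, "session_record"))
  if (is.null(met_per_segment)) {
    met <- session$data$met_true
    if (is.null(met) || anyNA(met)) {
      stop("session lacks per-second MET labels (met_true); supply ",
           "met_per_segment", call. = FALSE)
    }
  } else {
    lab <- as.character(normalize_segment_labels(session$data$activity))
    if (!all(lab %in% names(met_per_segment))) {
      stop("met_per_segment misses segment(s): ",
           paste(setdiff(unique(lab), names(met_per_segment)),
                 collapse = ", "), call. = FALSE)
    }
    met <- as.numeric(met_per_segment[lab])
  }
  ee_met(met + met_offset, session$profile$weight) / 60
}

#' Mean absolute error, overall and per segment
#'
#' @param pred,gt numeric series of equal length (kcal/s).
#' @param na.rm drop seconds where either series is `NA`.
#' @return `mae()`: scalar MAE.
#' @export
mae <- function(pred, gt, na.rm = FALSE) {
  if (length(pred) != length(gt)) {
    stop("pred (", length(pred), ") and gt (", length(gt),
         ") differ in length", call. = FALSE)
  }
  mean(abs(pred - gt), na.rm = na.rm)
}

#' @rdname mae
#' @param labels activity labels, same length as the series.
#' @return `segment_mae()`: named numeric vector of per-segment MAE, in
#'   canonical segment order (only segments present).
#' @export
segment_mae <- function(pred, gt, labels, na.rm = FALSE) {
  if (length(labels) != length(pred)) {
    stop("labels and series differ in length", call. = FALSE)
  }
  lab <- normalize_segment_labels(labels)
  err <- abs(pred - gt)
  out <- tapply(err, lab, mean, na.rm = na.rm)
  out[!is.na(out)]
}

#' Three-estimator evaluation report
#'
#' Runs the learned estimator (`ours`), the Keytel baseline and the MET
#' baseline over the given sessions, pooling per-second absolute errors
#' across sessions, and reports overall (`Total`) and per-segment MAE in
#' kcal/s.  The `Total` column is by construction the duration-weighted
#' mean of the segment MAEs.
#'
#' @param agent a `dqn_agent` or [oracle_agent()].
#' @param sessions a `session_record` or list of them, with ground truth.
#' @param met_offset additive MET mis-specification passed to
#'   [met_series()] (default 0, i.e. the true segment levels).
#' @param clamp_keytel,fill Keytel options, see [keytel_series()].
#' @return an object of class `ee_eval_report`: `table` (3 estimators x
#'   Total + segments), `traces` (per-session per-second data.frames) and
#'   `notes` (clamp/fill counts, options).
#' @export
compare_methods <- function(agent, sessions, met_offset = 0,
                            clamp_keytel = TRUE, fill = "locf") {
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1)

  n_clamped <- 0L
  n_filled <- 0L
  traces <- lapply(sessions, function(s) {
    ky <- keytel_series(s, clamp = clamp_keytel, fill = fill)
    n_clamped <<- n_clamped + attr(ky, "n_clamped")
    n_filled <<- n_filled + attr(ky, "n_filled")
    data.frame(
      id = if (is.null(s$profile$id)) NA_character_ else s$profile$id,
      time_s = s$data$time_s,
      activity = normalize_segment_labels(s$data$activity),
      gt = session_gt_ee(s),
      ours = predict_ee_series(agent, s),
      keytel = as.numeric(ky),
      met = met_series(s, met_offset = met_offset)
    )
  })
  pooled <- do.call(rbind, traces)

  estimators <- c("ours", "keytel", "met")
  segs <- levels(droplevels(pooled$activity))
  table <- data.frame(
    method = estimators,
    Total = vapply(estimators,
                   function(m) mae(pooled[[m]], pooled$gt), numeric(1)),
    stringsAsFactors = FALSE
  )
  for (sg in segs) {
    sel <- pooled$activity == sg
    table[[sg]] <- vapply(estimators, function(m) {
      mae(pooled[[m]][sel], pooled$gt[sel])
    }, numeric(1))
  }
  rownames(table) <- NULL

  structure(
    list(table = table, traces = traces,
         notes = list(n_keytel_clamped = n_clamped,
                      n_hr_filled = n_filled,
                      met_offset = met_offset,
                      clamp_keytel = clamp_keytel, fill = fill,
                      n_sessions = length(sessions),
                      n_seconds = nrow(pooled))),
    class = "ee_eval_report"
  )
}

#' @export
print.ee_eval_report <- function(x, ...) {
  cat("<ee_eval_report>", x$notes$n_sessions, "session(s),",
      x$notes$n_seconds, "s; MAE in kcal/s\n")
  print(x$table, digits = 4)
  if (x$notes$n_keytel_clamped > 0 || x$notes$n_hr_filled > 0) {
    cat(sprintf("keytel: %d s clamped at 0, %d HR s filled\n",
                x$notes$n_keytel_clamped, x$notes$n_hr_filled))
  }
  invisible(x)
}

#' Write / read an evaluation report
#'
#' `write_report()` writes the MAE table as CSV, the full report (table +
#' notes) as JSON, and per-session per-second error traces as CSV.
#' `read_report()` restores the report (without traces unless present).
#'
#' @param report an `ee_eval_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ee_eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, "report.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(table = report$table, notes = report$notes),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  traces <- do.call(rbind, report$traces)
  traces$activity <- as.character(traces$activity)
  utils::write.csv(traces, file.path(dir, "traces.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  obj <- jsonlite::read_json(file.path(dir, "report.json"),
                             simplifyVector = TRUE)
  traces_path <- file.path(dir, "traces.csv")
  traces <- NULL
  if (file.exists(traces_path)) {
    tr <- utils::read.csv(traces_path, stringsAsFactors = FALSE)
    traces <- split(tr, tr$id)
  }
  structure(list(table = as.data.frame(obj$table), traces = traces,
                 notes = obj$notes),
            class = "ee_eval_report")
}

#' Leave-participants-out train/test split
#'
#' Holds out the first male and the first female session (in list order)
#' for testing, mirroring the one-male + one-female test-set policy.  If
#' only one gender is present, the first two sessions are held out with a
#' warning.
#'
#' @param sessions list of `session_record`s (>= 3).
#' @return list with `train`, `test` and a `manifest` data.frame.
#' @export
split_sessions <- function(sessions) {
  stopifnot(length(sessions) >= 3)
  genders <- vapply(sessions, function(s) s$profile$gender_flag, integer(1))
  male <- which(genders == 1L)[1]
  female <- which(genders == 0L)[1]
  if (is.na(male) || is.na(female)) {
    warning("only one gender among sessions; holding out the first two")
    test_idx <- c(1L, 2L)
  } else {
    test_idx <- c(male, female)
  }
  ids <- vapply(seq_along(sessions), function(i) {
    id <- sessions[[i]]$profile$id
    if (is.null(id)) sprintf("session_%02d", i) else id
  }, character(1))
  list(
    train = sessions[-test_idx],
    test = sessions[test_idx],
    manifest = data.frame(
      id = ids,
      gender = ifelse(genders == 1L, "male", "female"),
      role = ifelse(seq_along(sessions) %in% test_idx, "test", "train"),
      stringsAsFactors = FALSE
    )
  )
}

#' Scenario-length ablation
#'
#' Trains two agents identical except for the episode (scenario) length --
#' by default 300 s ("5Min") and 60 s ("1Min") -- on the training split
#' and reports each agent's overall MAE on the held-out sessions.  The
#' direction of the comparison is reported, not asserted: which length
#' wins depends on the data.
#'
#' @param sessions list of `session_record`s (split internally via
#'   [split_sessions()]).
#' @param config a [dqn_config()]; its `window_length_s` is overridden.
#' @param lengths integer vector of scenario lengths in seconds.
#' @return a data.frame with one row per scenario length: `scenario`,
#'   `window_length_s`, `mae`.
#' @export
scenario_length_ablation <- function(sessions, config = dqn_config(),
                                     lengths = c(300L, 60L)) {
  split <- split_sessions(sessions)
  rows <- lapply(lengths, function(len) {
    cfg <- config
    cfg$window_length_s <- as.integer(len)
    agent <- train_dqn(split$train, cfg)
    rep_ <- compare_methods(agent, split$test)
    data.frame(
      scenario = if (len %% 60L == 0L) sprintf("%dMin", len %/% 60L)
                 else sprintf("%ds", len),
      window_length_s = as.integer(len),
      mae = rep_$table$Total[rep_$table$method == "ours"],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
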