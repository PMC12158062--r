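# Session file I/O: one CSV of per-second samples plus a JSON sidecar with
# the profile and generator parameters.  The CSV schema
# (time_s, hr_bpm, vo2_ml_kg_min, activity, met_true) doubles as the import
# target for external per-second HR/VO2 exports.

.session_columns <- c("time_s", "hr_bpm", "vo2_ml_kg_min", "activity",
                      "met_true")

sidecar_path <- function(csv_path) sub("\\.csv$", ".json", csv_path)

#' Write a session to CSV (+ JSON sidecar)
#'
#' Writes the per-second samples as CSV and the profile / generator
#' parameters / seed as a JSON sidecar next to it (same name, `.json`).
#'
#' @param session a `session_record`.
#' @param csv_path output CSV path (the sidecar replaces `.csv` with
#'   `.json`).
#' @return `csv_path`, invisibly.
#' @export
write_session <- function(session, csv_path) {
  stopifnot(inherits(session, "session_record"))
  df <- session$data
  df$activity <- as.character(df$activity)
  utils::write.csv(df[, .session_columns], csv_path, row.names = FALSE,
                   quote = FALSE)
  params <- session$params
  params$protocol <- if (!is.null(params$protocol)) {
    p <- params$protocol
    p$label <- as.character(p$label)
    p
  }
  meta <- list(
    profile = list(
      weight_kg = session$profile$weight,
      height_cm = session$profile$height,
      age_y = session$profile$age,
      gender_flag = session$profile$gender_flag,
      id = session$profile$id
    ),
    params = params
  )
  jsonlite::write_json(meta, sidecar_path(csv_path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(csv_path)
}

#' Read a session from CSV (+ JSON sidecar)
#'
#' @param csv_path path to a session CSV written by [write_session()] or any
#'   per-second export with columns `time_s, hr_bpm, vo2_ml_kg_min,
#'   activity, met_true` (the last three may be empty).
#' @param profile a [participant_profile()]; if `NULL` it is read from the
#'   JSON sidecar, which must then exist.
#' @return a `session_record`.
#' @export
read_session <- function(csv_path, profile = NULL) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.session_columns[1:2], names(df))
  if (length(missing_cols) > 0) {
    stop("session CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  params <- list()
  if (is.null(profile)) {
    sp <- sidecar_path(csv_path)
    if (!file.exists(sp)) {
      stop("no profile given and sidecar not found: ", sp, call. = FALSE)
    }
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    profile <- participant_profile(meta$profile$weight_kg,
                                   meta$profile$height_cm,
                                   meta$profile$age_y,
                                   meta$profile$gender_flag,
                                   id = meta$profile$id)
    if (!is.null(meta$params)) params <- meta$params
  }
  for (col in setdiff(.session_columns, names(df))) df[[col]] <- NA
  if (!all(is.na(df$activity))) {
    df$activity <- normalize_segment_labels(df$activity)
  }
  if (is.unsorted(df$time_s, strictly = TRUE) ||
      !all(diff(df$time_s) == 1)) {
    stop("time_s must be consecutive at 1 s spacing", call. = FALSE)
  }
  structure(list(profile = profile,
                 data = df[, .session_columns],
                 params = params),
            class = "session_record")
}
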