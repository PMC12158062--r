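#' Representative MET index by activity type
#'
#' The standard compendium-style lookup mapping an activity description to
#' its MET index.  The resting entry is 1.0 by definition.
#'
#' @return a data.frame with columns `activity` and `met`.
#' @examples
#' met_reference()
#' @export
met_reference <- function() {
  data.frame(
    activity = c(
      "Resting (sitting quietly)",
      "Office work",
      "Cycling 10 mph",
      "Food serving",
      "Firefighting",
      "Cycling over 20 mph"
    ),
    met = c(1.0, 1.5, 4.0, 8.0, 13.0, 16.0),
    stringsAsFactors = FALSE
  )
}

# Canonical activity-segment labels (report column order) and the aliases
# the generator / external data may use.
.segment_levels <- c("Sitting", "Standing", "Cycle1", "Cycle2", "Run1", "Run2")

.segment_aliases <- c(
  Sitting = "Sitting", Sit = "Sitting",
  Standing = "Standing", Stand = "Standing",
  Cycle1 = "Cycle1", Cycling1 = "Cycle1",
  Cycle2 = "Cycle2", Cycling2 = "Cycle2",
  Run1 = "Run1", Running1 = "Run1",
  Run2 = "Run2", Running2 = "Run2"
)

#' Normalize activity-segment labels
#'
#' Maps label variants (`Cycling1`, `Running2`, ...) onto the six canonical
#' report columns `Sitting, Standing, Cycle1, Cycle2, Run1, Run2`.
#'
#' @param labels character vector of segment labels.
#' @return factor with the canonical levels.
#' @export
normalize_segment_labels <- function(labels) {
  out <- .segment_aliases[as.character(labels)]
  if (anyNA(out)) {
    bad <- unique(as.character(labels)[is.na(out)])
    stop("unknown activity segment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(unname(out), levels = .segment_levels)
}

# Observed per-segment MET ranges across the 17-participant protocol;
# sitting and standing are fixed for everyone.
.segment_met_ranges <- list(
  Sitting = c(1, 1),
  Standing = c(1.2, 1.2),
  Cycle1 = c(4, 16),
  Cycle2 = c(12, 16),
  Run1 = c(4.5, 15),
  Run2 = c(10, 20)
)

#' Observed MET ranges per protocol segment
#'
#' Minimum and maximum MET levels recorded per activity segment across the
#' reference 17-participant sit/stand/cycle/run protocol.  The synthetic
#' generator samples segment intensities inside these brackets.
#'
#' @return a data.frame with columns `segment`, `met_min`, `met_max`.
#' @export
segment_met_ranges <- function() {
  data.frame(
    segment = names(.segment_met_ranges),
    met_min = vapply(.segment_met_ranges, `[`, numeric(1), 1L),
    met_max = vapply(.segment_met_ranges, `[`, numeric(1), 2L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
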