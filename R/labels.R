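#' Read per-cycle ground-truth labels from CSV
#'
#' The label schema has one row per breathing cycle:
#' `start_s`, `end_s` (cycle interval in seconds), `state` in
#' `{"normal", "abnormal"}`, `snore` in `{0, 1}` and `event` in
#' `{"none", "hypopnea", "apnea"}` (the breathing-stop event attached to the
#' pause that follows the cycle). Intervals must be positive-length, sorted
#' and non-overlapping.
#'
#' @param path Path to a label CSV.
#' @return A `data.frame` with the validated columns above.
#' @seealso [write_labels()]
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_labels(df)
}

#' Write per-cycle labels to CSV
#'
#' @param records A `data.frame` in the [read_labels()] schema.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(records, path) {
  records <- validate_labels(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_labels <- function(df) {
  required <- c("start_s", "end_s", "state", "snore", "event")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("label table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[required]
  df$start_s <- as.numeric(df$start_s)
  df$end_s <- as.numeric(df$end_s)
  df$snore <- as.integer(df$snore)
  if (anyNA(df$start_s) || anyNA(df$end_s)) {
    stop("label table has non-numeric start_s/end_s", call. = FALSE)
  }
  bad <- which(df$end_s <= df$start_s)
  if (length(bad) > 0L) {
    stop("label row ", bad[1], ": end_s <= start_s", call. = FALSE)
  }
  bad <- which(!df$state %in% c("normal", "abnormal"))
  if (length(bad) > 0L) {
    stop("label row ", bad[1], ": unknown state '", df$state[bad[1]], "'",
         call. = FALSE)
  }
  bad <- which(!df$snore %in% c(0L, 1L))
  if (length(bad) > 0L) {
    stop("label row ", bad[1], ": snore must be 0 or 1", call. = FALSE)
  }
  bad <- which(!df$event %in% c("none", "hypopnea", "apnea"))
  if (length(bad) > 0L) {
    stop("label row ", bad[1], ": unknown event '", df$event[bad[1]], "'",
         call. = FALSE)
  }
  if (nrow(df) > 1L) {
    if (is.unsorted(df$start_s, strictly = TRUE)) {
      stop("label intervals must be sorted by start_s", call. = FALSE)
    }
    overlap <- which(df$start_s[-1] < df$end_s[-nrow(df)])
    if (length(overlap) > 0L) {
      stop("label rows ", overlap[1], " and ", overlap[1] + 1L,
           " overlap", call. = FALSE)
    }
  }
  df
}
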