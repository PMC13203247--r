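#' Read a two-channel force recording from delimited text
#'
#' Canonical layout: a header row naming the columns `time_s`,
#' `force_left_N`, `force_right_N`; period decimal separator; comma or tab
#' delimiter (auto-detected from the header line); lines starting with `#`
#' are treated as comments. Malformed content is reported with the
#' offending line number.
#'
#' @param path Path to the file.
#' @param target_total Summed target force (N) to attach.
#' @param metadata Optional named list of labels.
#' @return A [force_recording()].
#' @export
read_force_recording <- function(path, target_total, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  n_comment_before_header <- which(keep)[1] - 1L
  if (is.na(n_comment_before_header))
    stop("file is empty: ", path, call. = FALSE)
  header <- lines[which(keep)[1]]
  sep <- detect_delimiter(header)
  df <- utils::read.table(text = lines[keep], header = TRUE, sep = sep,
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("time_s", "force_left_N", "force_right_N")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (cl in need) {
    if (!is.numeric(df[[cl]]))
      stop("column '", cl, "' is not numeric", call. = FALSE)
    if (anyNA(df[[cl]])) {
      row <- which(is.na(df[[cl]]))[1]
      stop(sprintf("missing/NaN value in column '%s' at data line %d", cl,
                   row), call. = FALSE)
    }
  }
  dtv <- diff(df$time_s)
  if (any(dtv <= 0)) {
    row <- which(dtv <= 0)[1] + 1L
    stop(sprintf("time_s is not strictly increasing at data line %d", row),
         call. = FALSE)
  }
  force_recording(df$time_s, df$force_left_N, df$force_right_N,
                  target_total = target_total, metadata = metadata)
}

detect_delimiter <- function(header) {
  if (grepl("\t", header)) "\t"
  else if (grepl(",", header)) ","
  else stop("could not detect delimiter (expect comma or tab)",
            call. = FALSE)
}

provenance_header <- function(fields) {
  vapply(names(fields), function(nm) {
    sprintf("# %s: %s", nm, paste(format(fields[[nm]], digits = 15),
                                  collapse = " "))
  }, character(1))
}

#' Write a force recording to delimited text
#'
#' Writes the canonical comma-separated layout of
#' [read_force_recording()], preceded by `#` comment lines recording the
#' target force and any metadata (e.g. seed and parameters for simulated
#' trials), so outputs carry their provenance.
#'
#' @param recording A [force_recording()] (or a [simulate_trial()] result,
#'   which is converted first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_recording <- function(recording, path) {
  if (inherits(recording, "simulated_trial"))
    recording <- as_force_recording(recording)
  stopifnot(inherits(recording, "force_recording"))
  hdr <- provenance_header(c(
    list(target_total_N = recording$target_total,
         sampling_rate_Hz = recording$sampling_rate),
    recording$metadata
  ))
  body <- sprintf("%.6f,%.10f,%.10f", recording$time,
                  recording$force_left, recording$force_right)
  writeLines(c(hdr, "time_s,force_left_N,force_right_N", body), path)
  invisible(path)
}

#' Write a metric or summary table to delimited text
#'
#' Comma-separated with `#` provenance comment lines (parameters, seeds)
#' before the header.
#'
#' @param table Data frame.
#' @param path Output path.
#' @param provenance Named list written as comment lines.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(table, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(provenance_header(provenance), con)
  utils::write.table(table, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a long-format study table from delimited text
#'
#' Expects columns `id`, `group`, `metric`, `pre`, `post` (see
#' [build_report()]); `#` lines are comments; comma or tab delimited.
#'
#' @param path Path to the table.
#' @return Data frame.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  sep <- detect_delimiter(lines[which(keep)[1]])
  df <- utils::read.table(text = lines[keep], header = TRUE, sep = sep,
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("id", "group", "metric", "pre", "post")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df
}
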