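#' Load one session's ROI time-series matrix
#'
#' Reads a delimited numeric text file (comma, tab, or whitespace separated;
#' the delimiter is auto-detected) holding one fMRI session after ROI
#' extraction: one row per volume, one column per ROI.
#'
#' @param path Path to the delimited text file.
#' @param participant_id,session_id Identity of the session within the study.
#' @param t_r Optional repetition time in seconds (metadata only).
#' @return An object of class `roi_time_series`: a list with elements
#'   `data` (T x N numeric matrix), `participant_id`, `session_id`, `t_r`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("1,2", "3,4", "5,6"), f)
#' ts <- load_session(f, "sub01", "ses01")
#' dim(ts$data)
#' @export
load_session <- function(path, participant_id, session_id, t_r = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("session file ", path, " has fewer than 2 volumes (rows)")
  sep <- detect_delimiter(lines[[1L]])
  toks <- if (identical(sep, "whitespace")) {
    lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1L]])
  } else {
    lapply(lines, function(l) trimws(strsplit(l, sep, fixed = TRUE)[[1L]]))
  }
  ncol1 <- length(toks[[1L]])
  lens <- lengths(toks)
  if (any(lens != ncol1)) {
    bad <- which(lens != ncol1)[1L]
    stop("ragged row in ", path, ": row ", bad, " has ", lens[bad],
         " fields, expected ", ncol1)
  }
  if (ncol1 < 2L) stop("session file ", path, " has fewer than 2 ROIs (columns)")
  vals <- suppressWarnings(vapply(toks, as.numeric, numeric(ncol1)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]  # vals is ncol x nrow
    stop("non-numeric cell in ", path, " at row ", idx[["col"]],
         ", column ", idx[["row"]], ": '", toks[[idx[["col"]]]][idx[["row"]]], "'")
  }
  X <- t(vals)
  dimnames(X) <- NULL
  roi_time_series(X, participant_id, session_id, t_r = t_r)
}

detect_delimiter <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  "whitespace"
}

#' Construct an ROI time-series object
#'
#' @param data T x N numeric matrix (rows = volumes, columns = ROIs).
#' @inheritParams load_session
#' @return An object of class `roi_time_series`.
#' @export
roi_time_series <- function(data, participant_id, session_id, t_r = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("time series must have T >= 2 volumes and N >= 2 ROIs")
  if (anyNA(data) || any(!is.finite(data)))
    stop("time series contains missing or non-finite values")
  structure(
    list(data = data,
         participant_id = as.character(participant_id),
         session_id = as.character(session_id),
         t_r = t_r),
    class = "roi_time_series"
  )
}

#' @export
print.roi_time_series <- function(x, ...) {
  cat(sprintf("<roi_time_series> participant=%s session=%s T=%d N=%d\n",
              x$participant_id, x$session_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Load a study manifest
#'
#' The manifest is a CSV with header `participant,session,file` mapping each
#' session file to its (participant, session) cell. The design must be
#' rectangular: every participant has the same number of sessions. This is a
#' hard requirement of the ND statistic, whose normalizing prefactors assume
#' N_p participants times N_s sessions each.
#'
#' @param path Path to the manifest CSV.
#' @return An object of class `study_manifest`: list with `entries`
#'   (data.frame participant/session/file), `n_participants`, `n_sessions`.
#' @export
load_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  study_manifest(df)
}

#' Construct and validate a study manifest
#'
#' @param entries data.frame with columns `participant`, `session`, `file`.
#' @return An object of class `study_manifest`.
#' @export
study_manifest <- function(entries) {
  req <- c("participant", "session", "file")
  if (!all(req %in% names(entries)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  entries <- as.data.frame(entries)[, req]
  key <- paste(entries$participant, entries$session, sep = "\r")
  if (anyDuplicated(key)) {
    d <- entries[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicated (participant, session) pair in manifest: (",
         d$participant, ", ", d$session, ")")
  }
  counts <- table(entries$participant)
  if (length(unique(as.integer(counts))) != 1L)
    stop("non-rectangular design: participants have unequal session counts (",
         paste(sprintf("%s=%d", names(counts), as.integer(counts)), collapse = ", "),
         "); the ND statistic requires every participant to have the same ",
         "number of sessions")
  structure(
    list(entries = entries,
         n_participants = length(counts),
         n_sessions = as.integer(counts[[1L]])),
    class = "study_manifest"
  )
}

#' @export
print.study_manifest <- function(x, ...) {
  cat(sprintf("<study_manifest> %d participants x %d sessions (%d files)\n",
              x$n_participants, x$n_sessions, nrow(x$entries)))
  invisible(x)
}

#' Write a reliability results table
#'
#' Serializes permutation-test results as a CSV with columns
#' `method,K,observable,nd,p_value,sig_05,sig_001,sig_bonf`, one row per
#' (method, K, observable) cell. Round-trips losslessly through
#' [read_results()].
#'
#' @param table data.frame of result records (e.g. from [run_study()]).
#' @param path Output path.
#' @export
write_results <- function(table, path) {
  cols <- c("method", "K", "observable", "nd", "p_value",
            "sig_05", "sig_001", "sig_bonf")
  if (nrow(table) > 0L && !all(cols %in% names(table)))
    stop("results table must have columns: ", paste(cols, collapse = ", "))
  if (nrow(table) == 0L) {
    table <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    table <- table[, cols]
  }
  utils::write.csv(format_results_numeric(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# full-precision text so the round-trip is lossless
format_results_numeric <- function(table) {
  for (nm in c("nd", "p_value")) {
    if (nm %in% names(table) && is.numeric(table[[nm]]))
      table[[nm]] <- sprintf("%.17g", table[[nm]])
  }
  table
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the results CSV.
#' @return data.frame with the standard result columns.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    df$K <- as.integer(df$K)
    df$nd <- as.numeric(df$nd)
    df$p_value <- as.numeric(df$p_value)
    for (nm in c("sig_05", "sig_001", "sig_bonf")) df[[nm]] <- as.logical(df[[nm]])
  }
  df
}
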