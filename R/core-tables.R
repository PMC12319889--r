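paradigm_conditions <- c("AM_construction", "AM_elaboration", "math", "rest",
                         "transition", "active", "fixation")

#' Task paradigm event table
#'
#' @param onset event onsets, seconds, nonnegative and nondecreasing.
#' @param duration event durations, seconds.
#' @param condition condition labels; one of `AM_construction`,
#'   `AM_elaboration`, `math`, `rest`, `transition`, `active`, `fixation`.
#' @param tr_vol volume repeat time, seconds.
#' @param n_volumes number of volumes in the run.
#' @return a `data.frame` of class `paradigm_events` with attributes `tr_vol`
#'   and `n_volumes`.
#' @export
paradigm_events <- function(onset, duration, condition, tr_vol, n_volumes) {
  onset <- as.numeric(onset); duration <- as.numeric(duration)
  condition <- as.character(condition)
  if (any(onset < 0)) stop("onsets must be nonnegative")
  if (is.unsorted(onset)) stop("onsets must be nondecreasing")
  bad <- setdiff(unique(condition), paradigm_conditions)
  if (length(bad) > 0L) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  run_len <- tr_vol * n_volumes
  if (any(onset + duration > run_len + 1e-9))
    stop("event extends past the run end (", run_len, " s)")
  structure(data.frame(onset = onset, duration = duration,
                       condition = condition),
            tr_vol = tr_vol, n_volumes = as.integer(n_volumes),
            class = c("paradigm_events", "data.frame"))
}

#' Read/write a paradigm event table (TSV: onset, duration, condition)
#'
#' @param path TSV path.
#' @param tr_vol,n_volumes run metadata (seconds; count).
#' @return a [paradigm_events] table.
#' @export
read_events <- function(path, tr_vol, n_volumes) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  paradigm_events(df$onset, df$duration, df$condition, tr_vol, n_volumes)
}

#' @param events a [paradigm_events] table.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Motion-parameter table
#'
#' Per-volume rigid-body parameters: 3 translations (mm) then 3 rotations
#' (rad), columns `trans_x..rot_z`.
#'
#' @param x n_volumes x 6 matrix or data frame.
#' @return a `data.frame` of class `motion_table`.
#' @export
motion_table <- function(x) {
  x <- as.data.frame(x)
  if (ncol(x) != 6L) stop("motion table must have 6 columns, got ", ncol(x))
  names(x) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  structure(x, class = c("motion_table", "data.frame"))
}

#' Read/write a motion table (TSV)
#'
#' @param path TSV path.
#' @return a [motion_table].
#' @export
read_motion <- function(path) {
  motion_table(utils::read.delim(path, sep = "\t"))
}

#' @param motion a [motion_table].
#' @rdname read_motion
#' @export
write_motion <- function(motion, path) {
  utils::write.table(as.data.frame(motion), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
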