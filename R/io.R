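# Readers for the pipeline's plain-text interchange formats.

#' Read per-frame eye landmarks from CSV
#'
#' Expects a header row and columns
#' `frame, lx1, ly1, ..., lx6, ly6, rx1, ry1, ..., rx6, ry6` with 0-based
#' frame indices; rows must cover frames consecutively.
#'
#' @param path CSV file path.
#' @param fps frames per second of the recording (default 30).
#' @param eps degenerate-aperture threshold, see [compute_ear()].
#' @return An [ear_series()].
#' @export
read_landmark_csv <- function(path, fps = 30, eps = 1e-6) {
  df <- utils::read.csv(path)
  lcols <- as.vector(rbind(paste0("lx", 1:6), paste0("ly", 1:6)))
  rcols <- as.vector(rbind(paste0("rx", 1:6), paste0("ry", 1:6)))
  need <- c("frame", lcols, rcols)
  if (!all(need %in% names(df))) {
    stop("landmark CSV must contain columns frame, lx1..ly6, rx1..ry6",
      call. = FALSE
    )
  }
  df <- df[order(df$frame), , drop = FALSE]
  to_mat <- function(row, cols) {
    matrix(as.numeric(row[cols]), ncol = 2L, byrow = TRUE)
  }
  left <- lapply(seq_len(nrow(df)), function(i) to_mat(df[i, ], lcols))
  right <- lapply(seq_len(nrow(df)), function(i) to_mat(df[i, ], rcols))
  series_from_landmarks(left, right, fps = fps, eps = eps)
}

#' Read a precomputed EAR series from CSV
#'
#' Accepts either per-eye columns `frame, ear_left, ear_right` or a single
#' `frame, mear` column; empty cells mark missing values.
#'
#' @param path CSV file path.
#' @param fps frames per second (default 30).
#' @return An [ear_series()].
#' @export
read_ear_csv <- function(path, fps = 30) {
  df <- utils::read.csv(path)
  if (all(c("ear_left", "ear_right") %in% names(df))) {
    df <- df[order(df$frame), , drop = FALSE]
    values <- mapply(mean_ear, df$ear_left, df$ear_right)
    single <- xor(is.na(df$ear_left), is.na(df$ear_right))
    ear_series(values, fps = fps, single_eye = single)
  } else if ("mear" %in% names(df)) {
    df <- df[order(df$frame), , drop = FALSE]
    ear_series(df$mear, fps = fps)
  } else {
    stop("EAR CSV must contain either ear_left/ear_right or mear columns",
      call. = FALSE
    )
  }
}

#' Read questionnaire item responses from CSV
#'
#' Expects columns `participant_id`, `bfi_1..bfi_60`, `pss_1..pss_14` and
#' optionally `subjective_blink`; see [score_questionnaires()].
#'
#' @param path CSV file path.
#' @return A data frame of raw item responses.
#' @export
read_items_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"participant_id" %in% names(df)) {
    stop("items CSV must contain a participant_id column", call. = FALSE)
  }
  df
}

#' Read manual blink counts for calibration windows
#'
#' Expects columns `participant_id, manual_count, window_start_s,
#' window_end_s`; the conventional calibration window is the first two
#' minutes (`0`--`120` s).
#'
#' @param path CSV file path.
#' @return A data frame, one row per participant.
#' @export
read_manual_counts_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("participant_id", "manual_count", "window_start_s", "window_end_s")
  if (!all(need %in% names(df))) {
    stop("manual-count CSV must contain columns ",
      paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(df$manual_count < 0)) stop("manual counts must be non-negative", call. = FALSE)
  df
}

#' Read a correlation-input JSON
#'
#' Expects keys `r_xm, r_xy, r_my, n` describing the three pairwise
#' correlations among predictor, mediator and outcome.
#'
#' @param path JSON file path.
#' @return A [correlation_input()].
#' @export
read_correlation_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("r_xm", "r_xy", "r_my", "n")
  if (!all(need %in% names(obj))) {
    stop("correlation JSON must contain keys r_xm, r_xy, r_my, n", call. = FALSE)
  }
  correlation_input(obj$r_xm, obj$r_xy, obj$r_my, obj$n)
}

#' Read scale keying configuration from JSON
#'
#' Each top-level key names a scale and maps to an object with
#' `item_count`, `response_min`, `response_max`, `reverse_items` and
#' `aggregation` (`"mean"` or `"sum"`).
#'
#' @param path JSON file path.
#' @return A named list of [scale_definition()]s.
#' @export
read_keying_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(obj), function(nm) {
    s <- obj[[nm]]
    def <- scale_definition(
      name = nm, item_count = s$item_count,
      response_min = s$response_min, response_max = s$response_max,
      reverse_items = s$reverse_items, aggregation = s$aggregation
    )
    if (!is.null(s$items)) attr(def, "items") <- as.integer(s$items)
    def
  })
  names(out) <- names(obj)
  out
}
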