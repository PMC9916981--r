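# Trial-table dialect: CSV, UTF-8, header row; required columns
# participant_id, culture, stimulus_key, face_id, response; AU amplitude
# columns named as in au_columns(). Unknown columns are preserved but
# ignored; a missing AU column means amplitude 0 (logged once).

trial_required_cols <- c("participant_id", "culture", "stimulus_key",
                         "face_id", "response")

#' Read a trial table
#'
#' Reads and validates the canonical CSV dialect: one row per categorization
#' trial with participant id, culture, stimulus key, face id, per-AU peak
#' amplitudes in `[0, 1]` and a categorical response. Trials categorized as
#' `"other"` carry no category hypothesis and are excluded (the count is kept
#' in the `excluded_other` attribute).
#'
#' @param path CSV file path.
#' @param task Task whose category vocabulary validates the responses.
#' @param drop_other Exclude `"other"` responses (default `TRUE`).
#' @return Trial table (data frame) with attributes `task` and
#'   `excluded_other`.
#' @export
read_trials <- function(path, task = c("basic6", "conversational4"),
                        drop_other = TRUE) {
  task <- match.arg(task)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        encoding = "UTF-8")
  miss <- setdiff(trial_required_cols, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  miss_au <- setdiff(au_columns(), names(df))
  if (length(miss_au)) {
    message("AU columns absent, assumed amplitude 0: ",
            paste(miss_au, collapse = ", "))
    for (cn in miss_au) df[[cn]] <- 0
  }
  for (cn in au_columns()) {
    v <- df[[cn]]
    if (!is.numeric(v)) stop("AU column ", cn, " is not numeric")
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad))
      stop("amplitude outside [0, 1] at row ", bad[1], ", column ", cn)
  }
  cats <- hk_categories(task)
  unknown <- setdiff(unique(df$response), c(cats, "other"))
  if (length(unknown))
    stop("unknown response categories for task '", task, "': ",
         paste(unknown, collapse = ", "))
  df$participant_id <- as.character(df$participant_id)
  as_trial_table(df, task, drop_other = drop_other)
}

as_trial_table <- function(df, task, drop_other = TRUE) {
  n_other <- sum(df$response == "other")
  if (drop_other) df <- df[df$response != "other", , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "task") <- task
  attr(df, "excluded_other") <- if (drop_other) n_other else 0L
  df
}

#' Exclude "other" responses from a trial table
#'
#' @param trials Trial table.
#' @return Trial table without `"other"` rows; the number removed is added to
#'   its `excluded_other` attribute.
#' @export
drop_other <- function(trials) {
  n <- sum(trials$response == "other")
  if (n == 0) return(trials)
  prev <- attr(trials, "excluded_other")
  out <- trials[trials$response != "other", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "task") <- attr(trials, "task")
  attr(out, "excluded_other") <- (if (is.null(prev)) 0L else prev) + n
  out
}

#' Write a trial table in the canonical CSV dialect
#'
#' @param trials Trial table.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c(trial_required_cols, au_columns(),
            setdiff(names(trials), c(trial_required_cols, au_columns())))
  utils::write.csv(trials[, cols[cols %in% names(trials)], drop = FALSE],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize an AUROC table as tidy CSV
#'
#' @param x An `hka` fit or its `$auroc` data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_auroc <- function(x, path) {
  tab <- if (inherits(x, "hka")) x$auroc else x
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
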