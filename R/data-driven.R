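# Data-driven model estimation: per-participant point-biserial correlation
# screening, proportion-weighted (or majority) aggregation, and
# leave-one-participant-out evaluation.

#' Fit a per-participant binary model matrix
#'
#' For each (category, AU): the point-biserial Pearson correlation between
#' the AU amplitude column and the binary response indicator (1 if the
#' category was selected), with a two-sided p-value from the t transform with
#' n - 2 degrees of freedom. The cell is 1 iff `p < alpha` (uncorrected) and
#' the correlation satisfies `sign_rule`. Categories missing a response class
#' give an all-zero row; constant amplitude columns give 0 cells (both
#' recorded in attributes).
#'
#' @param trials Trial table of a single participant (>= 3 trials).
#' @param alpha Significance level (default 0.05, uncorrected).
#' @param sign_rule `"positive"` (default: require r > 0, so a significant
#'   negative correlation never adds an AU to a category's template) or
#'   `"any"`.
#' @return Binary matrix, categories x 33 canonical AUs, with attributes
#'   `flagged_categories` and `constant_aus`.
#' @export
fit_participant_model <- function(trials, alpha = 0.05,
                                  sign_rule = c("positive", "any")) {
  sign_rule <- match.arg(sign_rule)
  trials <- drop_other(trials)
  if (length(unique(trials$participant_id)) > 1)
    stop("expected trials of a single participant")
  n <- nrow(trials)
  if (n < 3) stop("need >= 3 trials to fit a participant model")
  task <- attr(trials, "task")
  cats <- if (!is.null(task)) hk_categories(task) else sort(unique(trials$response))
  A <- as_stimulus_matrix(trials)
  colnames(A) <- au_labels()
  L <- outer(trials$response, cats, "==") + 0
  sdA <- apply(A, 2, stats::sd)
  sdL <- apply(L, 2, stats::sd)
  constant <- sdA == 0
  flagged <- cats[sdL == 0]
  # Pearson r for all pairs at once; undefined columns handled below
  r <- suppressWarnings(stats::cor(A, L))           # 33 x Q
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  sig <- !is.na(p) & p < alpha
  if (sign_rule == "positive") sig <- sig & !is.na(r) & r > 0
  sig[constant, ] <- FALSE
  sig[, sdL == 0] <- FALSE
  out <- t(sig) + 0
  dimnames(out) <- list(cats, au_labels())
  attr(out, "flagged_categories") <- flagged
  attr(out, "constant_aus") <- au_labels()[constant]
  out
}

#' Aggregate per-participant model matrices
#'
#' `mode = "weighted"`: each cell's weight is the proportion of participants
#' for whom the AU was significant; AUs significant in no participant are
#' excluded (weight 0). `mode = "majority"`: binary at a strict threshold
#' (default: included iff significant in more than 50% of participants).
#'
#' @param matrices List of binary matrices from [fit_participant_model()]
#'   (homogeneous dimensions).
#' @param mode `"weighted"` or `"majority"`.
#' @param threshold Majority threshold (strict `>`; default 0.5).
#' @return Numeric matrix, categories x 33: proportions in `[0, 1]`
#'   (weighted) or 0/1 (majority).
#' @export
#' @examples
#' # an AU significant in 9 of 10 participants aggregates to weight 0.9
aggregate_participant_models <- function(matrices, mode = c("weighted", "majority"),
                                         threshold = 0.5) {
  mode <- match.arg(mode)
  if (!length(matrices)) stop("empty list of participant matrices")
  dims <- lapply(matrices, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("participant matrices have heterogeneous dimensions")
  prop <- Reduce(`+`, matrices) / length(matrices)
  if (mode == "majority") (prop > threshold) + 0 else prop
}

#' Wrap an aggregated matrix as a hypothesis model
#'
#' Each category with at least one nonzero weight becomes a
#' single-configuration category whose configuration vector is the weighted
#' row; all-zero categories are dropped (recorded in the
#' `dropped_categories` attribute).
#'
#' @param m Aggregated matrix (categories x 33).
#' @param name Model name.
#' @param task Task label.
#' @return An `au_model`.
#' @export
as_au_model <- function(m, name = "data-driven",
                        task = c("basic6", "conversational4")) {
  task <- match.arg(task)
  nonzero <- rownames(m)[rowSums(m != 0) > 0]
  if (!length(nonzero)) stop("aggregated model has no nonzero category")
  configs <- lapply(nonzero, function(cat)
    matrix(m[cat, ], nrow = 1, dimnames = list(NULL, au_labels())))
  names(configs) <- nonzero
  mod <- au_model(name, task, configs)
  dropped <- setdiff(rownames(m), nonzero)
  if (length(dropped)) attr(mod, "dropped_categories") <- dropped
  mod
}

#' Fit an aggregated data-driven model
#'
#' Fits every participant's binary matrix and aggregates (weighted by
#' default). The result carries the per-participant matrices for inspection.
#'
#' @param trials Trial table covering several participants.
#' @inheritParams fit_participant_model
#' @inheritParams aggregate_participant_models
#' @param name Name of the resulting model.
#' @return Object of class `datadriven_fit`: `$model` (`au_model` with the
#'   weighted configuration vectors), `$weights` (aggregated matrix),
#'   `$participant_matrices`.
#' @export
hk_fit_datadriven <- function(trials, alpha = 0.05,
                              sign_rule = c("positive", "any"),
                              mode = c("weighted", "majority"), threshold = 0.5,
                              name = "data-driven") {
  sign_rule <- match.arg(sign_rule); mode <- match.arg(mode)
  trials <- drop_other(trials)
  task <- attr(trials, "task")
  mats <- lapply(split(seq_len(nrow(trials)), trials$participant_id, drop = TRUE),
                 function(i) {
                   tr <- trials[i, , drop = FALSE]
                   attr(tr, "task") <- task
                   fit_participant_model(tr, alpha, sign_rule)
                 })
  w <- aggregate_participant_models(mats, mode, threshold)
  structure(list(model = as_au_model(w, name, task),
                 weights = w, participant_matrices = mats,
                 alpha = alpha, sign_rule = sign_rule, mode = mode),
            class = "datadriven_fit")
}

#' @export
print.datadriven_fit <- function(x, ...) {
  cat("Data-driven model fit (", length(x$participant_matrices),
      " participants, alpha = ", x$alpha, ", ", x$mode, " aggregation)\n", sep = "")
  print(x$model)
  invisible(x)
}

#' @export
coef.datadriven_fit <- function(object, ...) object$weights

#' Leave-one-participant-out evaluation of the data-driven model
#'
#' For each fold: per-participant matrices are fitted on the remaining N - 1
#' participants, aggregated with proportion weighting into a
#' single-configuration-per-category model, and evaluated on the left-out
#' participant's trials. Deterministic; per-participant fits are computed
#' once and reused across folds.
#'
#' @param trials Trial table of the training participants (>= 3).
#' @inheritParams fit_participant_model
#' @param beta Softmax inverse temperature passed to [hka()].
#' @param kernel Kernel name or function.
#' @return An `hka`-style object whose `$auroc` table has one record per
#'   (left-out participant, category); fold models are in `$fold_models`.
#' @export
lopo_evaluate <- function(trials, alpha = 0.05, beta = 1, kernel = "cosine",
                          sign_rule = c("positive", "any")) {
  sign_rule <- match.arg(sign_rule)
  trials <- drop_other(trials)
  task <- attr(trials, "task")
  ids <- unique(trials$participant_id)
  if (length(ids) < 3) stop("need >= 3 participants for leave-one-participant-out")
  mats <- lapply(split(seq_len(nrow(trials)), trials$participant_id, drop = TRUE),
                 function(i) {
                   tr <- trials[i, , drop = FALSE]
                   attr(tr, "task") <- task
                   fit_participant_model(tr, alpha, sign_rule)
                 })
  rows <- list(); skips <- list(); fold_models <- list()
  for (id in ids) {
    w <- aggregate_participant_models(mats[setdiff(names(mats), id)], "weighted")
    model <- as_au_model(w, paste0("data-driven (LOPO, held out ", id, ")"), task)
    fold_models[[id]] <- model
    held <- trials[trials$participant_id == id, , drop = FALSE]
    attr(held, "task") <- task
    fit <- hka(model, held, beta = beta, kernel = kernel)
    fit$auroc$model <- "data-driven (LOPO)"
    rows[[id]] <- fit$auroc
    if (!is.null(fit$skipped)) {
      fit$skipped$model <- "data-driven (LOPO)"
      skips[[id]] <- fit$skipped
    }
  }
  structure(list(
    auroc = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    skipped = if (length(skips)) do.call(rbind, c(skips, list(make.row.names = FALSE))) else NULL,
    models = fold_models, beta = beta,
    kernel = if (is.function(kernel)) "custom" else kernel,
    ranking = "margin", n_trials = nrow(trials), data = NULL,
    call = match.call()),
    class = "hka")
}
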