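# Kernel engine: similarity of stimuli to hypothesis configurations, softmax
# normalization into category probabilities, one-vs-rest AUROC scoring, and
# the hka() fit object tying them together.

#' Similarity kernels
#'
#' Returns the kernel function used to score stimuli against configurations.
#' `"cosine"` (default) is scale-invariant in [0, 1] for nonnegative vectors;
#' `"dot"` and `"neg_euclidean"` (a monotone `1 / (1 + d)` transform of
#' Euclidean distance) are available as alternatives.
#'
#' @param name Kernel name.
#' @return Function `(S, C) -> N x M` similarity matrix for a stimulus matrix
#'   `S` (N x 33) and configuration matrix `C` (M x 33).
#' @export
hk_kernel <- function(name = c("cosine", "dot", "neg_euclidean")) {
  name <- match.arg(name)
  switch(name,
    cosine = function(S, C) {
      sn <- sqrt(rowSums(S^2)); cn <- sqrt(rowSums(C^2))
      sn[sn == 0] <- Inf; cn[cn == 0] <- Inf  # zero-norm vectors score 0
      (S / sn) %*% t(C / cn)
    },
    dot = function(S, C) S %*% t(C),
    neg_euclidean = function(S, C) {
      d2 <- outer(rowSums(S^2), rowSums(C^2), "+") - 2 * S %*% t(C)
      1 / (1 + sqrt(pmax(d2, 0)))
    })
}

#' Cosine similarity of two AU vectors
#'
#' `dot(u, v) / (|u| |v|)`, defined as 0 when either norm is 0.
#'
#' @param u,v Numeric vectors of equal length with nonnegative entries.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' cosine_similarity(au_config_vector(12), au_config_vector(c(6, 12)))  # 1/sqrt(2)
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

# Per-category similarity scores: max over the category's configurations
# (a multi-configuration category is scored by its most similar set).
hk_scores <- function(model, S, kernel = "cosine") {
  k <- if (is.function(kernel)) kernel else hk_kernel(kernel)
  cats <- covered_categories(model)
  out <- matrix(0, nrow(S), length(cats), dimnames = list(NULL, cats))
  for (cat in cats) {
    sim <- k(S, model$configs[[cat]])
    out[, cat] <- if (ncol(sim) == 1) sim[, 1] else do.call(pmax, asplit(sim, 2))
  }
  out
}

# One-vs-rest margin: score_c minus the best other category's score. For a
# single covered category the score itself is returned.
hk_margins <- function(scores) {
  q <- ncol(scores)
  if (q == 1) return(scores)
  out <- scores
  for (j in seq_len(q)) {
    other <- scores[, -j, drop = FALSE]
    best <- if (ncol(other) == 1) other[, 1] else do.call(pmax, asplit(other, 2))
    out[, j] <- scores[, j] - best
  }
  out
}

softmax_rows <- function(x, beta = 1) {
  z <- exp(beta * (x - apply(x, 1, max)))
  z / rowSums(z)
}

#' Predict category probabilities (or scores) for stimuli
#'
#' Embeds stimuli in the canonical AU space, scores each covered category by
#' the kernel similarity of its best-matching configuration, and normalizes
#' scores into probabilities with a softmax of inverse temperature `beta`.
#'
#' @param model An `au_model`.
#' @param stimuli A trial table / data frame containing [au_columns()], a
#'   numeric matrix with 33 columns, or a single named amplitude map.
#' @param beta Softmax inverse temperature (> 0). Affects probabilities only;
#'   rank-based evaluation uses margins and is invariant to it.
#' @param type `"prob"` (softmax probabilities, rows sum to 1), `"score"`
#'   (raw similarities), `"margin"` (one-vs-rest margins, the default ranking
#'   column of [hka()]), or `"category"` (argmax label).
#' @param kernel Kernel name or function, see [hk_kernel()].
#' @return Matrix with one row per stimulus and one column per covered
#'   category (`"category"`: a character vector).
#' @export
#' @examples
#' m <- au_model_from_spec("toy", "basic6",
#'                         list(happy = "6 + 12", sadness = "1 + 15"))
#' hk_predict(m, c("6" = 1, "12" = 1))
hk_predict <- function(model, stimuli, beta = 1,
                       type = c("prob", "score", "margin", "category"),
                       kernel = "cosine") {
  type <- match.arg(type)
  if (beta <= 0) stop("beta must be > 0")
  S <- as_stimulus_matrix(stimuli)
  scores <- hk_scores(model, S, kernel)
  switch(type,
    score = scores,
    margin = hk_margins(scores),
    prob = softmax_rows(scores, beta),
    category = colnames(scores)[max.col(scores, ties.method = "first")])
}

as_stimulus_matrix <- function(stimuli) {
  if (is.data.frame(stimuli)) {
    miss <- setdiff(au_columns(), names(stimuli))
    if (length(miss)) stop("missing AU columns: ", paste(miss, collapse = ", "))
    return(as.matrix(stimuli[, au_columns()]))
  }
  if (is.matrix(stimuli)) {
    if (ncol(stimuli) != 33) stop("stimulus matrix needs 33 columns")
    return(stimuli)
  }
  matrix(au_embed(au_recode(stimuli)), nrow = 1)
}

#' One-vs-rest AUROC with tie-halving
#'
#' The probability that a random positive outranks a random negative, ties
#' counted 1/2 (the Mann-Whitney convention); computed from average ranks.
#'
#' @param scores Numeric vector.
#' @param labels Logical (or 0/1) vector; `TRUE` marks positives.
#' @return AUROC in `[0, 1]`, or `NA` when either class is absent (an
#'   undefined cell, never silently 0.5).
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must not contain NA")
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate hypothesis models against categorization behavior
#'
#' The central fitting/evaluation routine. For each model, trials are
#' restricted to responses within the model's covered categories ("other"
#' responses are always excluded), per-category ranking scores are computed
#' from the kernel similarities, and a one-vs-rest AUROC is recorded per
#' participant and category. Cells with a single response class are skipped
#' and recorded, never imputed.
#'
#' @param models An `au_model` or a (named) list of them.
#' @param data A trial table: data frame with columns `participant_id`,
#'   `culture`, `response` and the AU amplitude columns [au_columns()] (see
#'   [read_trials()] / [simulate_experiment()]).
#' @param beta Softmax inverse temperature (probability calibration only).
#' @param kernel Kernel name or function, see [hk_kernel()].
#' @param ranking Ranking column for the AUROC: `"margin"` (default;
#'   one-vs-rest margin, invariant to `beta` and to any monotone transform of
#'   scores) or `"prob"` (full multiclass softmax probability column).
#' @param keep_data Store the evaluated trials in the object (needed by
#'   [residuals.hka()]).
#' @return Object of class `hka` with the per-(participant, model, category)
#'   AUROC table in `$auroc`.
#' @export
#' @examples
#' trials <- simulate_experiment(n_participants = 4, n_trials = 80, seed = 1)
#' fit <- hka(hk_models("basic6")[["Darwin (1872)"]], trials)
#' summary(fit)
hka <- function(models, data, beta = 1, kernel = "cosine",
                ranking = c("margin", "prob"), keep_data = FALSE) {
  ranking <- match.arg(ranking)
  if (beta <= 0) stop("beta must be > 0")
  if (inherits(models, "au_model")) {
    models <- stats::setNames(list(models), models$name)
  }
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$name, character(1))
  data <- drop_other(data)
  rows <- list(); skips <- list()
  for (mn in names(models)) {
    model <- models[[mn]]
    if (!length(covered_categories(model))) stop("model covers no category")
    keep <- data$response %in% covered_categories(model)
    trials <- data[keep, , drop = FALSE]
    if (!nrow(trials))
      stop("no trials left for model '", mn, "' after restricting to covered categories")
    S <- as_stimulus_matrix(trials)
    scores <- hk_scores(model, S, kernel)
    rk <- if (ranking == "margin") hk_margins(scores) else softmax_rows(scores, beta)
    idx <- split(seq_len(nrow(trials)), trials$participant_id, drop = TRUE)
    cats <- covered_categories(model)
    for (pid in names(idx)) {
      i <- idx[[pid]]
      resp <- trials$response[i]
      cult <- trials$culture[i][1]
      np <- vapply(cats, function(cat) sum(resp == cat), integer(1))
      nn <- length(i) - np
      ok <- np > 0 & nn > 0
      if (any(ok)) {
        aucs <- vapply(cats[ok], function(cat)
          auroc(rk[i, cat], resp == cat), numeric(1))
        rows[[length(rows) + 1L]] <- list(
          participant = rep(pid, sum(ok)), culture = rep(cult, sum(ok)),
          model = rep(mn, sum(ok)), category = cats[ok],
          auroc = unname(aucs), n_pos = unname(np[ok]), n_neg = unname(nn[ok]))
      }
      if (any(!ok)) {
        skips[[length(skips) + 1L]] <- list(
          participant = rep(pid, sum(!ok)), culture = rep(cult, sum(!ok)),
          model = rep(mn, sum(!ok)), category = cats[!ok],
          n_pos = unname(np[!ok]), n_neg = unname(nn[!ok]))
      }
    }
  }
  structure(list(
    auroc = bind_chunks(rows),
    skipped = if (length(skips)) bind_chunks(skips) else NULL,
    models = models, beta = beta,
    kernel = if (is.function(kernel)) "custom" else kernel,
    ranking = ranking,
    n_trials = nrow(data),
    data = if (keep_data) data else NULL,
    call = match.call()),
    class = "hka")
}

bind_chunks <- function(chunks) {
  if (!length(chunks)) return(NULL)
  cols <- names(chunks[[1]])
  out <- lapply(cols, function(cn)
    unlist(lapply(chunks, `[[`, cn), use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @export
print.hka <- function(x, ...) {
  cat("Hypothesis kernel evaluation (", x$kernel, " kernel, ranking = ",
      x$ranking, ")\n", sep = "")
  cat("  models:      ", paste(names(x$models), collapse = ", "), "\n")
  cat("  participants:", length(unique(x$auroc$participant)),
      "  trials:", x$n_trials, "\n")
  cat("  mean AUROC:  ", round(mean(x$auroc$auroc), 3), "\n")
  if (!is.null(x$skipped))
    cat("  skipped cells (single response class):", nrow(x$skipped), "\n")
  invisible(x)
}

#' @export
summary.hka <- function(object, ...) {
  tab <- object$auroc
  agg <- stats::aggregate(auroc ~ model + category, tab, mean)
  wide <- stats::reshape(agg, idvar = "model", timevar = "category",
                         direction = "wide")
  names(wide) <- sub("^auroc\\.", "", names(wide))
  rownames(wide) <- wide$model
  wide$model <- NULL
  out <- list(by_model_category = as.matrix(wide),
              by_culture = stats::aggregate(auroc ~ culture + category, tab, mean),
              overall = mean(tab$auroc),
              n_participants = length(unique(tab$participant)),
              n_skipped = if (is.null(object$skipped)) 0L else nrow(object$skipped))
  class(out) <- "summary.hka"
  out
}

#' @export
print.summary.hka <- function(x, digits = 3, ...) {
  cat("Mean one-vs-rest AUROC by model and category\n")
  print(round(x$by_model_category, digits))
  cat("\nOverall mean AUROC:", round(x$overall, digits),
      " (chance 0.5, ceiling <= noise ceiling)\n")
  cat("Participants:", x$n_participants,
      "  skipped single-class cells:", x$n_skipped, "\n")
  invisible(x)
}

#' @export
coef.hka <- function(object, ...) {
  agg <- stats::aggregate(auroc ~ model + category, object$auroc, mean)
  cats <- sort(unique(agg$category))
  mods <- unique(agg$model)
  out <- matrix(NA_real_, length(mods), length(cats),
                dimnames = list(mods, cats))
  out[cbind(agg$model, agg$category)] <- agg$auroc
  out
}

#' Predict from an evaluated model set
#'
#' @param object An `hka` fit.
#' @param newdata Trial table or stimulus matrix.
#' @param type See [hk_predict()].
#' @param ... Unused.
#' @return A matrix for a single-model fit, otherwise a named list of
#'   matrices.
#' @export
predict.hka <- function(object, newdata,
                        type = c("prob", "score", "margin", "category"), ...) {
  type <- match.arg(type)
  out <- lapply(object$models, hk_predict, stimuli = newdata,
                beta = object$beta, type = type, kernel = object$kernel)
  if (length(out) == 1) out[[1]] else out
}

#' One-vs-rest prediction residuals
#'
#' Per trial and category: the binary response indicator minus the predicted
#' softmax probability. Requires the fit to have been created with
#' `keep_data = TRUE` (or pass `data`).
#'
#' @param object An `hka` fit.
#' @param data Trial table; defaults to the data stored in the fit.
#' @param ... Unused.
#' @return Matrix (or named list of matrices for multi-model fits).
#' @export
residuals.hka <- function(object, data = object$data, ...) {
  if (is.null(data))
    stop("no stored data; refit with keep_data = TRUE or supply 'data'")
  data <- drop_other(data)
  res <- lapply(object$models, function(model) {
    keep <- data$response %in% covered_categories(model)
    trials <- data[keep, , drop = FALSE]
    p <- hk_predict(model, trials, beta = object$beta, type = "prob",
                    kernel = object$kernel)
    y <- outer(trials$response, colnames(p), "==") + 0
    y - p
  })
  if (length(res) == 1) res[[1]] else res
}

#' Plot mean AUROC by category and model
#'
#' Grouped bar plot of the per-category mean AUROC of each evaluated model,
#' with the chance line at 0.5 and, optionally, the per-category noise
#' ceiling as dashed segments.
#'
#' @param x An `hka` fit.
#' @param ceiling Optional `noise_ceiling` object (or named numeric vector of
#'   per-category ceilings).
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the matrix of plotted means.
#' @export
plot.hka <- function(x, ceiling = NULL, ...) {
  m <- coef.hka(x)
  bp <- graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                          ylab = "one-vs-rest AUROC", legend.text = rownames(m),
                          args.legend = list(x = "topright", cex = 0.7, bty = "n"),
                          ...)
  graphics::abline(h = 0.5, lty = 1)
  if (!is.null(ceiling)) {
    cv <- if (inherits(ceiling, "noise_ceiling"))
      stats::setNames(ceiling$per_category$ceiling, ceiling$per_category$category)
    else ceiling
    for (j in seq_len(ncol(m))) {
      cat <- colnames(m)[j]
      if (cat %in% names(cv))
        graphics::segments(min(bp[, j]) - 0.5, cv[[cat]],
                           max(bp[, j]) + 0.5, cv[[cat]], lty = 2)
    }
  }
  invisible(m)
}
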