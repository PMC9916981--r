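# Categorical noise ceiling: the maximum one-vs-rest AUROC achievable by any
# fixed stimulus-based model, estimated from between-participant label
# inconsistency on repeated presentations of identical stimuli.

#' Optimal stimulus-conditional predictions
#'
#' For each trial, the empirical distribution of responses over all
#' observations sharing its stimulus key (the plug-in conditional label
#' distribution). This is the AUROC-maximizing stimulus-measurable score for
#' every one-vs-rest problem, hence the basis of the noise ceiling.
#'
#' @param trials Trial table (`"other"` responses are excluded first).
#' @param grouping `"pooled"` (one distribution per stimulus across cultures)
#'   or `"per_culture"` (distributions conditioned on culture as well).
#' @return Matrix, one row per trial (rows sum to 1), one column per observed
#'   category.
#' @export
optimal_predictions <- function(trials, grouping = c("pooled", "per_culture")) {
  grouping <- match.arg(grouping)
  trials <- drop_other(trials)
  if (!nrow(trials)) stop("empty trial table")
  key <- trial_keys(trials)
  if (grouping == "per_culture") key <- paste(trials$culture, key, sep = "\r")
  cats <- sort(unique(trials$response))
  ind <- outer(trials$response, cats, "==") + 0
  counts <- rowsum(ind, key)
  prob <- counts / rowSums(counts)
  out <- prob[key, , drop = FALSE]
  dimnames(out) <- list(NULL, cats)
  out
}

trial_keys <- function(trials) {
  if ("stimulus_key" %in% names(trials) && !anyNA(trials$stimulus_key) &&
      all(nzchar(trials$stimulus_key)))
    as.character(trials$stimulus_key)
  else stimulus_key(trials)
}

#' Estimate the categorical noise ceiling
#'
#' Per category, the one-vs-rest AUROC of the optimal stimulus-conditional
#' prediction column against the observed labels, with a bootstrap SD from
#' resampling observations with replacement within each repeated-stimulus
#' group.
#'
#' `mode = "plug_in"` (default) scores each trial by the empirical label
#' distribution of the observations sharing its stimulus key, with two bias
#' controls: the trial's own response is left out of its distribution
#' (self-inclusion would spuriously lift the ceiling of even stimulus-
#' independent labels above chance), and positive-negative pairs within the
#' same stimulus key count as ties (no stimulus-based score can rank trials
#' of an identical stimulus, so a half-win is the ceiling there too).
#' Singleton keys fall back to the trial's own label, which is optimistic;
#' their fraction is reported and warned about above 50%.
#'
#' `mode = "leave_one_participant_out"` predicts each participant's trials
#' from the other participants' observations only (a conservative variant;
#' trials whose stimulus no other participant saw are dropped and counted).
#'
#' @param trials Trial table.
#' @param n_boot Number of bootstrap resamples for the SD (>= 1).
#' @param seed Optional integer seed making the bootstrap deterministic.
#' @param mode `"plug_in"` or `"leave_one_participant_out"`.
#' @param grouping See [optimal_predictions()]; named in the output.
#' @return Object of class `noise_ceiling`: `$per_category` data frame with
#'   `ceiling`, `sd`, `n_pos`, `n_neg`; plus `n_unique_stimuli`,
#'   `n_observations`, `singleton_fraction`, `mode`, `grouping`, `n_boot`,
#'   `degenerate` and (for the leave-one-out mode) `n_dropped`.
#' @export
noise_ceiling <- function(trials, n_boot = 1000, seed = NULL,
                          mode = c("plug_in", "leave_one_participant_out"),
                          grouping = c("pooled", "per_culture")) {
  mode <- match.arg(mode)
  grouping <- match.arg(grouping)
  stopifnot(n_boot >= 1)
  trials <- drop_other(trials)
  if (!nrow(trials)) stop("empty trial table")
  key <- trial_keys(trials)
  if (grouping == "per_culture") key <- paste(trials$culture, key, sep = "\r")
  cats <- sort(unique(trials$response))
  ind <- outer(trials$response, cats, "==") + 0
  colnames(ind) <- cats

  group_sizes <- table(key)
  singleton_fraction <- mean(group_sizes == 1)
  degenerate <- all(group_sizes == 1)
  if (degenerate)
    warning("all stimulus keys are singletons; the ceiling is degenerate (1.0 by construction)")
  else if (singleton_fraction > 0.5)
    warning(sprintf("%.0f%% of stimulus keys are singletons; the plug-in ceiling will be optimistic",
                    100 * singleton_fraction))

  n_dropped <- 0L
  point <- if (mode == "plug_in") {
    ceiling_from(ind, key, cats)
  } else {
    counts <- rowsum(ind, key)
    pk <- paste(key, trials$participant_id, sep = "\r")
    own <- rowsum(ind, pk)[pk, , drop = FALSE]
    loo <- counts[key, , drop = FALSE] - own
    tot <- rowSums(loo)
    keep <- tot > 0
    n_dropped <- sum(!keep)
    if (!any(keep))
      stop("no trial has observations from other participants; cannot compute leave-one-participant-out ceiling")
    prob <- loo[keep, , drop = FALSE] / tot[keep]
    indk <- ind[keep, , drop = FALSE]
    keyk <- key[keep]
    stats::setNames(vapply(cats, function(cat)
      auroc_key_tied(prob[, cat], indk[, cat] == 1, keyk), numeric(1)), cats)
  }

  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  groups <- split(seq_along(key), key)
  boot <- matrix(NA_real_, n_boot, length(cats), dimnames = list(NULL, cats))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), replace = TRUE)]), use.names = FALSE)
    boot[b, ] <- ceiling_from(ind[idx, , drop = FALSE], key[idx], cats)
  }

  structure(list(
    per_category = data.frame(
      category = cats,
      ceiling = unname(point[cats]),
      sd = apply(boot, 2, stats::sd, na.rm = TRUE),
      n_pos = colSums(ind), n_neg = nrow(ind) - colSums(ind),
      row.names = NULL),
    n_unique_stimuli = length(group_sizes),
    n_observations = nrow(ind),
    singleton_fraction = singleton_fraction,
    degenerate = degenerate,
    mode = mode, grouping = grouping, n_boot = n_boot,
    n_dropped = n_dropped),
    class = "noise_ceiling")
}

# Point estimate for the plug_in mode: leave-one-response-out conditional
# distributions, stimulus-identity ties for within-key pairs.
ceiling_from <- function(ind, key, cats) {
  counts <- rowsum(ind, key)
  tot <- rowSums(counts)
  loo <- counts[key, , drop = FALSE] - ind
  denom <- tot[key] - 1
  single <- denom == 0
  prob <- loo / ifelse(single, 1, denom)
  # singleton keys: no other observation; fall back to the trial's own label
  prob[single, ] <- ind[single, , drop = FALSE]
  stats::setNames(vapply(cats, function(cat)
    auroc_key_tied(prob[, cat], ind[, cat] == 1, key), numeric(1)), cats)
}

# Mann-Whitney AUROC in which positive-negative pairs sharing a stimulus key
# count 1/2 regardless of score: a stimulus-based score is constant on a key,
# so within-key pairs are irreducible ties for any fixed model.
auroc_key_tied <- function(scores, labels, key) {
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  u <- sum(r[labels]) - npos * (npos + 1) / 2
  mixed <- unique(key[labels])[unique(key[labels]) %in% unique(key[!labels])]
  for (k in mixed) {
    i <- key == k
    y <- labels[i]
    rk <- rank(scores[i])
    np <- sum(y)
    u_within <- sum(rk[y]) - np * (np + 1) / 2
    u <- u - u_within + 0.5 * np * sum(!y)
  }
  u / (npos * nneg)
}

#' @export
print.noise_ceiling <- function(x, digits = 3, ...) {
  cat("Categorical noise ceiling (", x$mode, ", ", x$grouping, " grouping, ",
      x$n_boot, " bootstrap resamples)\n", sep = "")
  df <- x$per_category
  df$ceiling <- round(df$ceiling, digits)
  df$sd <- round(df$sd, digits)
  print(df, row.names = FALSE)
  cat(sprintf("Unique stimuli: %d of %d observations (singleton fraction %.2f)\n",
              x$n_unique_stimuli, x$n_observations, x$singleton_fraction))
  if (x$n_dropped > 0)
    cat("Trials without other-participant observations dropped:", x$n_dropped, "\n")
  if (x$degenerate) cat("NOTE: degenerate estimate (all keys singleton)\n")
  invisible(x)
}

#' Write a noise-ceiling report as JSON
#'
#' @param x A `noise_ceiling` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_noise_ceiling <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
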