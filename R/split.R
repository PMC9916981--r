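# Cross-validation splits (participants, faces, stimulus keys) and culture
# comparisons of per-participant AUROC scores.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Participant / face / stimulus train-test split
#'
#' Per culture: participants are randomly partitioned at
#' `participant_fraction` (default 2/3, i.e. 40 train / 20 test of 60), face
#' identities 50/50 and stimulus keys 50/50. Train trials are those of train
#' participants showing a train face and a train stimulus key; test trials
#' likewise on the test side. Off-diagonal trials (e.g. a train participant
#' seeing a test stimulus) are dropped and counted, so test stimuli contain
#' AU combinations and face identities never seen in training.
#'
#' @param trials Trial table.
#' @param participant_fraction Fraction of participants assigned to training.
#' @param seed Optional integer seed; the plan is deterministic given it.
#' @return Object of class `split_plan`: `$cultures` (per-culture id sets and
#'   drop counts), `$train_idx`, `$test_idx` (row indices into `trials`),
#'   `$n_dropped`, `$dropped_fraction`.
#' @export
split_train_test <- function(trials, participant_fraction = 2/3, seed = NULL) {
  stopifnot(participant_fraction > 0, participant_fraction < 1)
  key <- trial_keys(trials)
  with_seed(seed, {
    cultures <- unique(trials$culture)
    plan <- list()
    assign_vec <- rep(NA_character_, nrow(trials))
    for (cu in cultures) {
      rows <- which(trials$culture == cu)
      parts <- unique(trials$participant_id[rows])
      faces <- unique(trials$face_id[rows])
      keys <- unique(key[rows])
      if (length(parts) < 2 || length(faces) < 2 || length(keys) < 2)
        stop("culture '", cu, "' needs at least 2 participants, faces and stimulus keys")
      n_train <- round(length(parts) * participant_fraction)
      n_train <- min(max(n_train, 1L), length(parts) - 1L)
      p_train <- sample(parts, n_train)
      f_train <- sample(faces, floor(length(faces) / 2))
      k_train <- sample(keys, floor(length(keys) / 2))
      in_p <- trials$participant_id[rows] %in% p_train
      in_f <- trials$face_id[rows] %in% f_train
      in_k <- key[rows] %in% k_train
      grp <- ifelse(in_p & in_f & in_k, "train",
                    ifelse(!in_p & !in_f & !in_k, "test", NA))
      assign_vec[rows] <- grp
      plan[[cu]] <- list(
        participants_train = sort(p_train),
        participants_test = sort(setdiff(parts, p_train)),
        faces_train = sort(f_train), faces_test = sort(setdiff(faces, f_train)),
        keys_train = sort(k_train), keys_test = sort(setdiff(keys, k_train)),
        n_dropped = sum(is.na(grp)))
    }
    structure(list(
      cultures = plan,
      participant_fraction = participant_fraction,
      seed = seed,
      train_idx = which(assign_vec == "train"),
      test_idx = which(assign_vec == "test"),
      n_dropped = sum(is.na(assign_vec)),
      dropped_fraction = mean(is.na(assign_vec))),
      class = "split_plan")
  })
}

# Internal guard: asserts the disjointness invariants of a plan before the
# exploration pipeline evaluates anything on the test side.
assert_split_disjoint <- function(plan) {
  for (cu in names(plan$cultures)) {
    p <- plan$cultures[[cu]]
    stopifnot(
      length(intersect(p$participants_train, p$participants_test)) == 0,
      length(intersect(p$faces_train, p$faces_test)) == 0,
      length(intersect(p$keys_train, p$keys_test)) == 0)
  }
  stopifnot(length(intersect(plan$train_idx, plan$test_idx)) == 0)
  invisible(TRUE)
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Train/test split (participant fraction ",
      round(x$participant_fraction, 3), ")\n", sep = "")
  for (cu in names(x$cultures)) {
    p <- x$cultures[[cu]]
    cat(sprintf("  %s: %d train / %d test participants, %d/%d faces, %d/%d keys, %d trials dropped\n",
                cu, length(p$participants_train), length(p$participants_test),
                length(p$faces_train), length(p$faces_test),
                length(p$keys_train), length(p$keys_test), p$n_dropped))
  }
  cat(sprintf("  trials: %d train, %d test, %d dropped (%.1f%%)\n",
              length(x$train_idx), length(x$test_idx), x$n_dropped,
              100 * x$dropped_fraction))
  invisible(x)
}

#' Write a split plan as JSON
#' @param x A `split_plan`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_split_plan <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compare per-participant AUROC scores across cultures
#'
#' Per category: participant scores are averaged across models, then the two
#' cultures are compared with a two-sided independent-samples t test (pooled
#' variance) and a pooled-SD Cohen's d signed as first culture minus second
#' (WE - EA by default). No multiple-testing correction is applied, as
#' flagged in the output attribute `correction`.
#'
#' @param x An `hka` fit or an AUROC table data frame.
#' @param cultures Length-2 character: the two groups, in sign order.
#' @return Data frame with one row per category: group means, `t`, `df`, `p`,
#'   `cohens_d`, flagged undefined (NA) when both groups have zero variance.
#' @export
compare_cultures <- function(x, cultures = c("WE", "EA")) {
  tab <- if (inherits(x, "hka")) x$auroc else x
  stopifnot(length(cultures) == 2)
  tab <- tab[tab$culture %in% cultures, , drop = FALSE]
  per <- stats::aggregate(auroc ~ participant + culture + category, tab, mean)
  out <- lapply(sort(unique(per$category)), function(cat) {
    d1 <- per$auroc[per$category == cat & per$culture == cultures[1]]
    d2 <- per$auroc[per$category == cat & per$culture == cultures[2]]
    if (length(d1) < 2 || length(d2) < 2)
      stop("need >= 2 participants per culture with defined scores for '", cat, "'")
    if (stats::sd(d1) == 0 && stats::sd(d2) == 0) {
      return(data.frame(category = cat, n_1 = length(d1), n_2 = length(d2),
                        mean_1 = mean(d1), mean_2 = mean(d2),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        cohens_d = NA_real_))
    }
    tt <- stats::t.test(d1, d2, var.equal = TRUE)
    sp <- sqrt(((length(d1) - 1) * stats::var(d1) + (length(d2) - 1) * stats::var(d2)) /
                 (length(d1) + length(d2) - 2))
    data.frame(category = cat, n_1 = length(d1), n_2 = length(d2),
               mean_1 = mean(d1), mean_2 = mean(d2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               cohens_d = if (sp == 0) NA_real_ else (mean(d1) - mean(d2)) / sp)
  })
  out <- do.call(rbind, out)
  attr(out, "cultures") <- cultures
  attr(out, "correction") <- "none (uncorrected two-sided t tests)"
  out
}

#' One-sample comparison of AUROC scores against chance
#'
#' Per model and category (or per category, averaged over models): two-sided
#' one-sample t test of the per-participant AUROCs against `mu` (chance 0.5).
#'
#' @param x An `hka` fit or AUROC table.
#' @param mu Null value (default 0.5).
#' @param by `"model_category"` or `"category"`.
#' @return Data frame of test records; zero-variance cells are NA-flagged.
#' @export
compare_to_chance <- function(x, mu = 0.5, by = c("model_category", "category")) {
  by <- match.arg(by)
  tab <- if (inherits(x, "hka")) x$auroc else x
  per <- if (by == "model_category")
    stats::aggregate(auroc ~ participant + model + category, tab, mean)
  else stats::aggregate(auroc ~ participant + category, tab, mean)
  grp <- if (by == "model_category") interaction(per$model, per$category, sep = "\r")
         else per$category
  out <- lapply(split(per, grp, drop = TRUE), function(g) {
    v <- g$auroc
    base <- data.frame(category = g$category[1], n = length(v), mean = mean(v))
    if (by == "model_category") base <- cbind(model = g$model[1], base)
    if (length(v) < 2 || stats::sd(v) == 0) {
      cbind(base, t = NA_real_, df = NA_real_, p = NA_real_)
    } else {
      tt <- stats::t.test(v, mu = mu)
      cbind(base, t = unname(tt$statistic), df = unname(tt$parameter),
            p = tt$p.value)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "mu") <- mu
  out
}
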