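# Synthetic-behavior simulator: random-AU stimuli matching the study's
# generative statistics (AU count ~ Binomial(5, 0.6), amplitudes ~ U(0, 1),
# 8 base faces per culture, 42-label generative vocabulary) and softmax
# responders with lapse, "other" threshold, culture accents and per-
# participant idiosyncrasy. Every stage of the analysis runs on its output.

#' Simulate random-AU facial expression stimuli
#'
#' Each stimulus activates a random subset of generative AU labels (count
#' drawn from Binomial(`size`, `prob`), zero draws resampled: an
#' expressionless face cannot be categorized) with peak amplitudes uniform on
#' (0, 1), then is recoded into the canonical 33-AU space with [au_recode()].
#' Six temporal parameters per active AU are generated for structural
#' fidelity but ignored by all analyses (stored only with `keep_raw = TRUE`).
#'
#' @param n_stimuli Number of stimuli.
#' @param n_faces Base-face identities to sample from (default 8).
#' @param culture Culture tag used in face ids.
#' @param size,prob Binomial parameters of the active-AU count (defaults 5
#'   and 0.6).
#' @param vocabulary Generative label vocabulary (default [hk_vocabulary()]).
#' @param seed Optional seed; the table is deterministic given it.
#' @param keep_raw Also store the raw generative AU maps and temporal
#'   parameters as attributes `raw` and `temporal`.
#' @return Data frame: `stimulus_key`, `face_id` and the canonical AU
#'   amplitude columns [au_columns()].
#' @export
simulate_stimuli <- function(n_stimuli, n_faces = 8, culture = "WE",
                             size = 5, prob = 0.6,
                             vocabulary = hk_vocabulary(), seed = NULL,
                             keep_raw = FALSE) {
  stopifnot(n_stimuli >= 1, n_faces >= 1)
  with_seed(seed, {
    cols_per_label <- lapply(vocabulary, function(lab)
      match(resolve_au_label(lab), au_labels()))
    if (any(vapply(cols_per_label, function(x) anyNA(x) || !length(x), logical(1))))
      stop("vocabulary contains labels outside the recoding scheme")
    k <- stats::rbinom(n_stimuli, size, prob)
    while (any(k == 0)) k[k == 0] <- stats::rbinom(sum(k == 0), size, prob)
    M <- matrix(0, n_stimuli, 33, dimnames = list(NULL, au_columns()))
    raw <- if (keep_raw) vector("list", n_stimuli)
    temporal <- if (keep_raw) vector("list", n_stimuli)
    nv <- length(vocabulary)
    for (i in seq_len(n_stimuli)) {
      lab <- sample.int(nv, k[i])
      amp <- stats::runif(k[i])
      tp <- matrix(stats::runif(6 * k[i]), ncol = 6)
      for (j in seq_len(k[i])) {
        cc <- cols_per_label[[lab[j]]]
        M[i, cc] <- pmax(M[i, cc], amp[j])
      }
      if (keep_raw) {
        raw[[i]] <- stats::setNames(amp, vocabulary[lab])
        temporal[[i]] <- tp
      }
    }
    out <- data.frame(
      stimulus_key = stimulus_key(M),
      face_id = paste0(culture, "_face", sample.int(n_faces, n_stimuli, replace = TRUE)),
      M, check.names = FALSE)
    if (keep_raw) { attr(out, "raw") <- raw; attr(out, "temporal") <- temporal }
    out
  })
}

#' Specify a simulated responder population
#'
#' The generative perceiver: a responder carries a personal hypothesis model
#' (the culture's base model, optionally accent-edited and idiosyncratically
#' perturbed), scores each stimulus by kernel similarity, answers `"other"`
#' when no category resembles the stimulus enough, occasionally lapses, and
#' otherwise samples a category from a softmax over the scores.
#'
#' @param model Base `au_model` of the population.
#' @param accents Optional accent edits: named list
#'   `category -> list(add = AU numbers, remove = AU numbers)` applied to
#'   every configuration of that category.
#' @param idiosyncrasy Probability, per (category, model AU number), that a
#'   responder's personal model toggles that AU (present AUs dropped, absent
#'   model-pool AUs added to all configurations).
#' @param beta Softmax inverse temperature of the choice rule (> 0; large
#'   values approach deterministic argmax).
#' @param lapse Probability of answering uniformly at random.
#' @param other_threshold Respond `"other"` when the maximum category score
#'   falls below this value (in `[0, 1)`).
#' @return Object of class `responder_spec`.
#' @export
responder_spec <- function(model, accents = NULL, idiosyncrasy = 0,
                           beta = 10, lapse = 0.1, other_threshold = 0.2) {
  stopifnot(inherits(model, "au_model"), beta > 0,
            lapse >= 0, lapse <= 1, idiosyncrasy >= 0, idiosyncrasy <= 1,
            other_threshold >= 0, other_threshold < 1)
  base <- if (is.null(accents)) model else edit_model(model, accents)
  structure(list(model = base, idiosyncrasy = idiosyncrasy, beta = beta,
                 lapse = lapse, other_threshold = other_threshold),
            class = "responder_spec")
}

# Apply add/remove AU edits per category.
edit_model <- function(model, edits) {
  for (cat in names(edits)) {
    if (!cat %in% covered_categories(model))
      stop("edit for category '", cat, "' not covered by model")
    m <- model$configs[[cat]]
    e <- edits[[cat]]
    if (length(e$remove)) m[, labels_of(e$remove)] <- 0
    if (length(e$add)) m[, labels_of(e$add)] <- 1
    m <- clean_config_matrix(m)
    if (is.null(m)) stop("edits empty every configuration of '", cat, "'")
    model$configs[[cat]] <- m
  }
  model
}

# A responder's personal model: idiosyncratic toggles over the model's AU pool.
personal_model <- function(spec) {
  model <- spec$model
  pi <- spec$idiosyncrasy
  if (pi <= 0) return(model)
  pool <- unique(unlist(lapply(model$configs, function(m)
    unique(sub("[LR]$", "", au_labels()[colSums(m != 0) > 0])))))
  for (cat in covered_categories(model)) {
    m <- model$configs[[cat]]
    for (num in pool) {
      if (stats::runif(1) >= pi) next
      labs <- labels_of(num)
      if (any(m[, labs] != 0)) m[, labs] <- 0 else m[, labs] <- 1
    }
    m2 <- clean_config_matrix(m)
    if (!is.null(m2)) model$configs[[cat]] <- m2  # keep original if emptied
  }
  model
}

#' Simulate categorization responses
#'
#' Per trial: with probability `lapse` a uniformly random category; otherwise
#' category scores are computed under the responder's personal model,
#' `"other"` is returned when the maximum score is below `other_threshold`,
#' and otherwise a category is sampled from softmax(`beta` x scores) (via the
#' Gumbel-max trick, so `beta = Inf` reduces to the argmax).
#'
#' @param stimuli Stimulus table from [simulate_stimuli()] (or any table with
#'   [au_columns()]).
#' @param responder A `responder_spec`.
#' @param seed Optional seed.
#' @return Character vector of responses (task categories or `"other"`).
#' @export
simulate_responses <- function(stimuli, responder, seed = NULL) {
  stopifnot(inherits(responder, "responder_spec"))
  with_seed(seed, {
    model <- personal_model(responder)
    cats <- covered_categories(model)
    S <- as_stimulus_matrix(stimuli)
    scores <- hk_scores(model, S)
    n <- nrow(S)
    resp <- character(n)
    top <- apply(scores, 1, max)
    if (is.finite(responder$beta)) {
      g <- matrix(-log(-log(stats::runif(n * length(cats)))), n)
      pick <- max.col(responder$beta * scores + g, ties.method = "first")
    } else {
      pick <- max.col(scores, ties.method = "first")
    }
    resp <- cats[pick]
    resp[top < responder$other_threshold] <- "other"
    lapse <- stats::runif(n) < responder$lapse
    resp[lapse] <- cats[sample.int(length(cats), sum(lapse), replace = TRUE)]
    resp
  })
}

#' Simulate a full categorization experiment
#'
#' Emulates the study's structure: per culture, `n_participants` responders
#' each categorize `n_trials` stimuli — `n_trials - n_repeated` unique to the
#' participant plus a block of `n_repeated` stimuli shared by every
#' participant of the culture (the repeated observations that noise-ceiling
#' estimation needs). Trials answered `"other"` are retained in the output
#' and excluded by the preprocessing filter downstream.
#'
#' @param n_participants Participants per culture (default 60).
#' @param n_trials Trials per participant (default 1200).
#' @param cultures Culture labels (any grouping labels are accepted).
#' @param responders A single `responder_spec` for all cultures, or a named
#'   list (culture -> spec). Default: every culture responds according to the
#'   bundled Jack et al. (2014) model with the default responder parameters.
#' @param n_repeated Size of the shared repeated-stimulus block (default 40).
#' @param n_faces Base faces per culture (default 8).
#' @param size,prob Binomial parameters of the stimulus AU count.
#' @param task Task whose categories are simulated.
#' @param seed Optional seed; all randomness flows through it.
#' @return Trial table (see [read_trials()] for the dialect) with `task`
#'   attribute set; `"other"` rows are retained.
#' @export
#' @examples
#' trials <- simulate_experiment(n_participants = 3, n_trials = 50, seed = 1)
simulate_experiment <- function(n_participants = 60, n_trials = 1200,
                                cultures = c("WE", "EA"), responders = NULL,
                                n_repeated = 40, n_faces = 8,
                                size = 5, prob = 0.6,
                                task = c("basic6", "conversational4"),
                                seed = NULL) {
  task <- match.arg(task)
  stopifnot(n_repeated >= 0, n_repeated < n_trials)
  if (is.null(responders)) {
    base <- hk_models(task)[["Jack et al. (2014)"]]
    if (is.null(base)) stop("no default responder model for task '", task, "'")
    responders <- responder_spec(base)
  }
  if (inherits(responders, "responder_spec"))
    responders <- stats::setNames(rep(list(responders), length(cultures)), cultures)
  missing_cult <- setdiff(cultures, names(responders))
  if (length(missing_cult))
    stop("no responder spec for culture(s): ", paste(missing_cult, collapse = ", "))
  for (cu in cultures) {
    cover <- covered_categories(responders[[cu]]$model)
    if (!setequal(cover, hk_categories(task)))
      stop("responder model for '", cu, "' must cover all task categories")
  }
  with_seed(seed, {
    out <- vector("list", length(cultures))
    for (ci in seq_along(cultures)) {
      cu <- cultures[ci]
      shared <- if (n_repeated > 0)
        simulate_stimuli(n_repeated, n_faces, cu, size, prob)
      parts <- vector("list", n_participants)
      for (p in seq_len(n_participants)) {
        own <- simulate_stimuli(n_trials - n_repeated, n_faces, cu, size, prob)
        stim <- if (n_repeated > 0) rbind(own, shared) else own
        resp <- simulate_responses(stim, responders[[cu]])
        parts[[p]] <- data.frame(
          participant_id = sprintf("%s_p%02d", cu, p),
          culture = cu, stimulus_key = stim$stimulus_key,
          face_id = stim$face_id, response = resp,
          stim[, au_columns()], check.names = FALSE)
      }
      out[[ci]] <- do.call(rbind, parts)
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    as_trial_table(df, task, drop_other = FALSE)
  })
}

#' Simulate behavior from a hypothesis model
#'
#' Convenience wrapper: a population of responders whose base model is
#' `object` categorizes random-AU stimuli (see [simulate_experiment()]).
#'
#' @param object An `au_model` covering all task categories.
#' @param nsim Number of experiments to simulate.
#' @param seed Optional seed.
#' @param n_participants,n_trials,cultures,... Passed to
#'   [simulate_experiment()]; responder parameters (`beta`, `lapse`,
#'   `other_threshold`, `idiosyncrasy`) are passed to [responder_spec()].
#' @param beta,lapse,other_threshold,idiosyncrasy Responder parameters.
#' @return A trial table, or a list of `nsim` trial tables.
#' @export
simulate.au_model <- function(object, nsim = 1, seed = NULL,
                              n_participants = 60, n_trials = 1200,
                              cultures = c("WE", "EA"),
                              beta = 10, lapse = 0.1, other_threshold = 0.2,
                              idiosyncrasy = 0, ...) {
  spec <- responder_spec(object, beta = beta, lapse = lapse,
                         other_threshold = other_threshold,
                         idiosyncrasy = idiosyncrasy)
  task <- object$task
  with_seed(seed, {
    sims <- lapply(seq_len(nsim), function(i)
      simulate_experiment(n_participants, n_trials, cultures,
                          responders = spec, task = task, ...))
    if (nsim == 1) sims[[1]] else sims
  })
}
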