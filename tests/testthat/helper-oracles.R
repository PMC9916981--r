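# Independent oracles and small fixture builders shared across tests.

# Brute-force pairwise AUROC: count positive-negative pairs, ties worth 1/2.
auroc_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Trial table from a stimulus matrix (rows x 33, canonical order) and labels.
make_trials <- function(S, response, participant_id = "p1", culture = "WE",
                        task = "basic6", face_id = "f1") {
  colnames(S) <- au_columns()
  df <- data.frame(
    participant_id = rep_len(participant_id, nrow(S)),
    culture = rep_len(culture, nrow(S)),
    stimulus_key = stimulus_key(S),
    face_id = rep_len(face_id, nrow(S)),
    response = response,
    S, check.names = FALSE)
  attr(df, "task") <- task
  attr(df, "excluded_other") <- 0L
  df
}

# Stimulus matrix whose rows are exactly a model's configuration patterns.
config_stimuli <- function(model) {
  rows <- lapply(covered_categories(model), function(cat) model$configs[[cat]])
  S <- do.call(rbind, rows)
  labels <- rep(covered_categories(model),
                vapply(rows, nrow, integer(1)))
  list(S = S, labels = labels)
}

# Independent expander for random configuration expressions: nested loops over
# alternation choices and optional-inclusion masks (no sharing with the
# package parser).
expand_oracle <- function(required, optionals) {
  # required/optionals: lists of integer vectors (each vector = alternation)
  pick <- function(term_list) {
    if (!length(term_list)) return(list(integer(0)))
    grid <- do.call(expand.grid, lapply(term_list, seq_along))
    lapply(seq_len(nrow(grid)), function(r)
      unlist(lapply(seq_along(term_list), function(j)
        term_list[[j]][grid[r, j]])))
  }
  out <- list()
  n_opt <- length(optionals)
  masks <- if (n_opt) expand.grid(rep(list(c(FALSE, TRUE)), n_opt)) else
    data.frame(row.names = 1)
  for (mi in seq_len(nrow(masks))) {
    inc <- if (n_opt) unlist(masks[mi, ]) else logical(0)
    terms <- c(required, optionals[inc])
    out <- c(out, pick(terms))
  }
  sets <- lapply(out, function(s) sort(unique(as.integer(s))))
  sets[!duplicated(vapply(sets, paste, character(1), collapse = ","))]
}

set_signature <- function(sets)
  sort(vapply(sets, paste, character(1), collapse = ","))
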