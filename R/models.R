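# Hypothesis models: per category, one or more configuration vectors over the
# canonical AU space. Theory models are binary; data-driven models carry
# weights in (0, 1]. A registry bundles the published basic-emotion models.

#' Task category vocabularies
#'
#' @param task `"basic6"` (anger, disgust, fear, happy, sadness, surprise) or
#'   `"conversational4"` (bored, confused, interested, thinking).
#' @return Character vector of category labels.
#' @export
hk_categories <- function(task = c("basic6", "conversational4")) {
  task <- match.arg(task)
  switch(task,
    basic6 = c("anger", "disgust", "fear", "happy", "sadness", "surprise"),
    conversational4 = c("bored", "confused", "interested", "thinking"))
}

#' Construct a hypothesis model
#'
#' @param name Model name.
#' @param task Task whose categories the model may cover.
#' @param configs Named list, one element per covered category: a numeric
#'   matrix with 33 columns (one row per configuration, canonical AU order) or
#'   anything coercible to one (a single configuration vector, or a list of
#'   AU-number sets).
#' @return Object of class `au_model`.
#' @export
au_model <- function(name, task = c("basic6", "conversational4"), configs) {
  task <- match.arg(task)
  cats <- hk_categories(task)
  if (!length(configs) || is.null(names(configs)))
    stop("'configs' must be a named list with at least one category")
  bad <- setdiff(names(configs), cats)
  if (length(bad))
    stop("categories not in task '", task, "': ", paste(bad, collapse = ", "))
  configs <- lapply(configs, as_config_matrix)
  for (cat in names(configs)) {
    m <- configs[[cat]]
    if (nrow(m) < 1 || all(m == 0))
      stop("category '", cat, "' has no nonempty configuration")
    if (any(m < 0 | m > 1))
      stop("configuration weights must lie in [0, 1]")
    if (anyDuplicated(config_keys(m)))
      stop("duplicate configuration vectors in category '", cat, "'")
  }
  configs <- configs[cats[cats %in% names(configs)]]  # canonical category order
  structure(list(name = name, task = task, configs = configs),
            class = "au_model")
}

as_config_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 33) stop("configuration matrices need 33 columns")
    colnames(x) <- au_labels()
    return(x)
  }
  if (is.numeric(x)) return(matrix(x, nrow = 1, dimnames = list(NULL, au_labels())))
  if (is.list(x)) {
    rows <- lapply(x, function(s)
      if (is.numeric(s) && length(s) == 33) s else au_config_vector(s))
    return(do.call(rbind, rows))
  }
  stop("cannot interpret configuration specification")
}

config_keys <- function(m) apply(round(m, 9), 1, paste, collapse = ",")

# Drop all-zero rows and duplicates; NULL if nothing remains.
clean_config_matrix <- function(m) {
  keep <- rowSums(m != 0) > 0
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  m[!duplicated(config_keys(m)), , drop = FALSE]
}

#' Build a hypothesis model from notation strings
#'
#' Parses each category's configuration expressions with [parse_au_spec()] and
#' lateralizes the resulting AU sets into the canonical space.
#'
#' @inheritParams au_model
#' @param specs Named list: category -> character vector of configuration
#'   expressions, or explicit AU-number lists (which bypass the parser).
#' @param drop_unknown Drop AU numbers with no canonical counterpart (recorded
#'   in the model's `dropped_aus` attribute) instead of erroring.
#' @return Object of class `au_model`.
#' @export
#' @examples
#' au_model_from_spec("toy", "basic6", list(happy = "6 + 12", disgust = "9 + 25"))
au_model_from_spec <- function(name, task = c("basic6", "conversational4"),
                               specs, drop_unknown = FALSE) {
  task <- match.arg(task)
  dropped <- character(0)
  configs <- lapply(specs, function(sp) {
    sets <- if (is.character(sp)) parse_au_spec(sp) else lapply(sp, as.integer)
    rows <- lapply(sets, au_config_vector, drop_unknown = drop_unknown)
    for (r in rows) dropped <<- c(dropped, attr(r, "dropped"))
    m <- do.call(rbind, lapply(rows, as.numeric))
    colnames(m) <- au_labels()
    m <- clean_config_matrix(m)
    if (is.null(m)) stop("category expansion produced no nonempty configuration")
    m
  })
  mod <- au_model(name, task, configs)
  if (length(dropped)) attr(mod, "dropped_aus") <- unique(dropped)
  mod
}

#' Categories covered by a model
#' @param model An `au_model`.
#' @return Character vector.
#' @export
covered_categories <- function(model) names(model$configs)

#' Load the bundled or a user-supplied model registry
#'
#' The `basic6` registry bundles the seven published basic-emotion models with
#' all configuration expansions. The `conversational4` registry ships the five
#' study slots without configurations (supply your own specs); entries without
#' configurations are skipped with a message. A user JSON file with the same
#' layout (`models: [{name, categories: {label: [spec strings or AU lists]}}]`)
#' may be given as `source`.
#'
#' @param task `"basic6"` or `"conversational4"`.
#' @param source Optional path to a model registry JSON file.
#' @return Named list of `au_model` objects.
#' @export
#' @examples
#' length(hk_models("basic6"))  # 7
hk_models <- function(task = c("basic6", "conversational4"), source = NULL) {
  task <- match.arg(task)
  path <- if (is.null(source))
    system.file("extdata", paste0("models_", task, ".json"), package = "hka")
  else source
  reg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(reg$task) && !identical(reg$task, task))
    stop("registry file is for task '", reg$task, "', not '", task, "'")
  models <- list()
  skipped <- character(0)
  for (entry in reg$models) {
    cats <- entry$categories
    if (!length(cats)) { skipped <- c(skipped, entry$name); next }
    specs <- lapply(cats, function(sp) {
      if (all(vapply(sp, is.character, logical(1)))) unlist(sp) else sp
    })
    models[[entry$name]] <-
      au_model_from_spec(entry$name, task, specs, drop_unknown = TRUE)
  }
  if (length(skipped))
    message("registry slots without configurations (skipped): ",
            paste(skipped, collapse = "; "))
  models
}

#' Write / read a model in the package's JSON format
#'
#' Models are stored with explicit weighted AU lists per configuration, so
#' both binary theory models and weighted data-driven models round-trip.
#'
#' @param model An `au_model`.
#' @param path File path.
#' @return `hk_read_model()` returns an `au_model`; `hk_write_model()` the
#'   path, invisibly.
#' @export
hk_write_model <- function(model, path) {
  cats <- lapply(model$configs, function(m)
    lapply(seq_len(nrow(m)), function(i) {
      on <- m[i, ] != 0
      list(labels = au_labels()[on], weights = unname(m[i, on]))
    }))
  jsonlite::write_json(
    list(name = model$name, task = model$task, categories = cats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname hk_write_model
#' @export
hk_read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  configs <- lapply(x$categories, function(cfgs) {
    rows <- lapply(cfgs, function(cfg) {
      v <- stats::setNames(numeric(33), au_labels())
      v[unlist(cfg$labels)] <- unlist(cfg$weights)
      v
    })
    m <- do.call(rbind, rows)
    colnames(m) <- au_labels()
    m
  })
  au_model(x$name, x$task, configs)
}

#' @export
print.au_model <- function(x, ...) {
  cat("Hypothesis model:", x$name, " [task:", x$task, "]\n")
  for (cat_name in covered_categories(x)) {
    m <- x$configs[[cat_name]]
    cat(sprintf("  %-10s %s\n", cat_name,
                paste(apply(m, 1, format_config), collapse = " | ")))
  }
  d <- attr(x, "dropped_aus")
  if (length(d)) cat("  (AUs with no canonical counterpart dropped:",
                     paste(d, collapse = ", "), ")\n")
  invisible(x)
}

# Compact rendering of one configuration vector, collapsing L/R pairs with
# equal weight back to the bare number.
format_config <- function(v) {
  on <- which(v != 0)
  if (!length(on)) return("(empty)")
  labs <- au_labels()[on]
  w <- unname(v[on])
  nums <- sub("[LR]$", "", labs)
  parts <- character(0)
  done <- logical(length(labs))
  for (i in seq_along(labs)) {
    if (done[i]) next
    pair <- which(nums == nums[i])
    if (length(pair) == 2 && isTRUE(all.equal(w[pair[1]], w[pair[2]])) &&
        grepl("[LR]$", labs[i])) {
      done[pair] <- TRUE
      parts <- c(parts, fmt_au(nums[i], w[pair[1]]))
    } else {
      done[i] <- TRUE
      parts <- c(parts, fmt_au(labs[i], w[i]))
    }
  }
  paste(parts, collapse = " + ")
}

fmt_au <- function(lab, w) {
  if (isTRUE(all.equal(w, 1))) lab else sprintf("%s(%.2g)", lab, w)
}

#' @export
coef.au_model <- function(object, ...) {
  out <- do.call(rbind, lapply(object$configs, function(m) apply(m, 2, max)))
  rownames(out) <- covered_categories(object)
  out
}
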