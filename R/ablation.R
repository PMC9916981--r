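# Explanation stage: single-AU ablation of hypothesis models, Delta-AUROC
# maps averaged over participants and models, classification of AUs as
# performance-critical / performance-detrimental, and construction of
# optimized (accented) models.

labels_of <- function(x) {
  out <- unlist(lapply(x, function(a) {
    a <- normalize_au_label(as.character(a))
    if (a %in% au_labels()) return(a)
    labs <- resolve_au_number(suppressWarnings(as.integer(a)))
    if (is.null(labs)) stop("AU", x, " has no canonical counterpart")
    labs
  }), use.names = FALSE)
  unique(out)
}

#' Ablate an AU from one category of a model
#'
#' Removes the AU (both laterals, if a bare bilateral number is given) from
#' every configuration of the target category only; emptied configurations
#' are dropped and duplicates arising from the removal are deduplicated.
#' Other categories are untouched.
#'
#' @param model An `au_model`.
#' @param category Covered category to ablate from.
#' @param au AU number or canonical label; must occur in at least one of the
#'   category's configurations (so that "cannot ablate" is distinguishable
#'   from a zero effect).
#' @return The ablated `au_model`.
#' @export
#' @examples
#' m <- au_model_from_spec("toy", "basic6", list(disgust = "9 + 25"))
#' au_ablate(m, "disgust", 9)  # disgust becomes {25}
au_ablate <- function(model, category, au) {
  if (!category %in% covered_categories(model))
    stop("category '", category, "' not covered by model '", model$name, "'")
  labs <- labels_of(au)
  m <- model$configs[[category]]
  if (all(m[, labs] == 0))
    stop("AU ", paste(au, collapse = "/"), " occurs in no configuration of '",
         category, "' in model '", model$name, "'")
  m[, labs] <- 0
  m <- clean_config_matrix(m)
  if (is.null(m))
    stop("ablating AU ", paste(au, collapse = "/"), " empties every configuration of '",
         category, "'; the category is non-evaluable")
  model$configs[[category]] <- m
  model
}

#' Delta-AUROC ablation map
#'
#' For every model, category, and canonical AU present in that category's
#' configurations: ablate the AU, re-evaluate, and record the mean over
#' participants of AUROC(ablated) - AUROC(original). The map cell for a
#' (category, AU) is the mean of these deltas over the models containing the
#' AU; AUs in no model's category are undefined (`NA`). Negative cells mark
#' performance-critical AUs, positive cells performance-detrimental ones.
#'
#' Evaluation matches [hka()] with margin ranking; because ablation changes
#' only the target category's configurations, only that category's scores are
#' recomputed. Cells whose ablation empties a category are recorded in
#' `$non_evaluable` and skipped rather than aborting the map.
#'
#' @param models An `au_model` or list of them.
#' @param trials Trial table (train-split trials, in the cross-validated
#'   pipeline).
#' @param kernel Kernel name or function.
#' @return Object of class `ablation_map`: `$delta` (categories x 33 matrix,
#'   `NA` = undefined), `$per_model` (long data frame), `$non_evaluable`.
#' @export
ablation_map <- function(models, trials, kernel = "cosine") {
  if (inherits(models, "au_model"))
    models <- stats::setNames(list(models), models$name)
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$name, character(1))
  trials <- drop_other(trials)
  task <- attr(trials, "task")
  cats <- if (!is.null(task)) hk_categories(task) else
    sort(unique(unlist(lapply(models, covered_categories))))
  rows <- list(); bad <- list()
  for (mn in names(models)) {
    model <- models[[mn]]
    keep <- trials$response %in% covered_categories(model)
    tr <- trials[keep, , drop = FALSE]
    if (!nrow(tr)) next
    S <- as_stimulus_matrix(tr)
    scores <- hk_scores(model, S, kernel)
    idx <- split(seq_len(nrow(tr)), tr$participant_id, drop = TRUE)
    for (cat in covered_categories(model)) {
      cfg <- model$configs[[cat]]
      best_other <- other_max(scores, cat)
      base_margin <- scores[, cat] - best_other
      y_all <- tr$response == cat
      base_auc <- vapply(idx, function(i) auroc(base_margin[i], y_all[i]), numeric(1))
      present <- au_labels()[colSums(cfg != 0) > 0]
      for (lab in present) {
        m2 <- cfg
        m2[, lab] <- 0
        m2 <- clean_config_matrix(m2)
        if (is.null(m2)) {
          bad[[length(bad) + 1L]] <- data.frame(model = mn, category = cat, au = lab)
          next
        }
        k <- if (is.function(kernel)) kernel else hk_kernel(kernel)
        sim <- k(S, m2)
        s2 <- if (ncol(sim) == 1) sim[, 1] else do.call(pmax, asplit(sim, 2))
        abl_margin <- s2 - best_other
        d <- vapply(seq_along(idx), function(j) {
          i <- idx[[j]]
          a <- auroc(abl_margin[i], y_all[i])
          if (is.na(a) || is.na(base_auc[j])) NA_real_ else a - base_auc[j]
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          model = mn, category = cat, au = lab,
          delta = mean(d, na.rm = TRUE), n_participants = sum(!is.na(d)))
      }
    }
  }
  per_model <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = character(0), category = character(0),
               au = character(0), delta = numeric(0), n_participants = integer(0))
  delta <- matrix(NA_real_, length(cats), 33,
                  dimnames = list(cats, au_labels()))
  if (nrow(per_model)) {
    agg <- stats::aggregate(delta ~ category + au, per_model, mean)
    delta[cbind(agg$category, agg$au)] <- agg$delta
  }
  structure(list(delta = delta, per_model = per_model,
                 non_evaluable = if (length(bad)) do.call(rbind, bad) else NULL,
                 categories = cats),
            class = "ablation_map")
}

other_max <- function(scores, cat) {
  other <- scores[, setdiff(colnames(scores), cat), drop = FALSE]
  if (!ncol(other)) return(rep(0, nrow(scores)))
  if (ncol(other) == 1) other[, 1] else do.call(pmax, asplit(other, 2))
}

#' @export
print.ablation_map <- function(x, digits = 3, ...) {
  cat("Ablation map: mean Delta AUROC (ablated - original), ",
      nrow(x$per_model), " model x category x AU cells\n", sep = "")
  def <- !is.na(x$delta)
  cat("Defined cells:", sum(def), "of", length(x$delta), "\n")
  if (sum(def)) {
    v <- x$delta[def]
    cat("Delta range:", round(min(v), digits), "..", round(max(v), digits), "\n")
  }
  invisible(x)
}

#' Write an ablation map as CSV (categories x 33 AUs; empty = undefined)
#' @param x An `ablation_map`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ablation_map <- function(x, path) {
  df <- data.frame(category = rownames(x$delta), x$delta, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Classify AUs as performance-critical or performance-detrimental
#'
#' Applies the sign rule with a dead-zone `epsilon` to per-culture ablation
#' maps: an AU whose ablation decreases mean performance (`delta < -epsilon`)
#' is critical for that category; one whose ablation increases it
#' (`delta > +epsilon`) is detrimental. Undefined cells are ignored.
#'
#' @param maps Named list (culture -> `ablation_map`), or a single
#'   `ablation_map` (treated as one grouping named `"all"`).
#' @param epsilon Dead-zone half-width (default 0: strict sign rule).
#' @return Object of class `accent_sets`:
#'   `$sets[[culture]][[category]]$critical` / `$detrimental` (canonical
#'   labels).
#' @export
derive_accents <- function(maps, epsilon = 0) {
  if (inherits(maps, "ablation_map")) maps <- list(all = maps)
  if (is.null(names(maps))) stop("'maps' must be named by culture")
  stopifnot(epsilon >= 0)
  sets <- lapply(maps, function(m) {
    out <- lapply(rownames(m$delta), function(cat) {
      v <- m$delta[cat, ]
      def <- !is.na(v)
      list(critical = names(v)[def & v < -epsilon],
           detrimental = names(v)[def & v > epsilon])
    })
    stats::setNames(out, rownames(m$delta))
  })
  structure(list(sets = sets, epsilon = epsilon), class = "accent_sets")
}

#' @export
print.accent_sets <- function(x, ...) {
  cat("Accent sets (epsilon =", x$epsilon, ")\n")
  for (cu in names(x$sets)) {
    cat(" ", cu, "\n")
    for (cat_name in names(x$sets[[cu]])) {
      s <- x$sets[[cu]][[cat_name]]
      if (!length(s$critical) && !length(s$detrimental)) next
      cat(sprintf("    %-10s critical: %-28s detrimental: %s\n", cat_name,
                  paste(s$critical, collapse = ","),
                  paste(s$detrimental, collapse = ",")))
    }
  }
  invisible(x)
}

#' Write accent sets as JSON
#' @param x An `accent_sets` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_accents <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct an optimized, accented model
#'
#' Per covered category: every performance-critical AU (for the given
#' culture) is added to every configuration at weight 1 and every
#' performance-detrimental AU is removed from every configuration; emptied
#' configurations are dropped and duplicates deduplicated. A category that
#' would lose all configurations keeps its original configuration with the
#' fewest detrimental AUs and is flagged in the `kept_original` attribute.
#'
#' @param model An `au_model`.
#' @param accents An `accent_sets` object.
#' @param culture Which culture's accent sets to apply (default the single
#'   grouping present).
#' @return The optimized `au_model` (name suffixed with the culture accent).
#' @export
#' @examples
#' # disgust {10, 25} with critical {9} and detrimental {25} becomes {9, 10}
optimize_model <- function(model, accents, culture = NULL) {
  stopifnot(inherits(accents, "accent_sets"))
  if (is.null(culture)) {
    if (length(accents$sets) != 1)
      stop("multiple cultures in 'accents'; specify 'culture'")
    culture <- names(accents$sets)[1]
  }
  if (!culture %in% names(accents$sets))
    stop("no accent sets for culture '", culture, "'")
  sets <- accents$sets[[culture]]
  kept <- character(0)
  for (cat in covered_categories(model)) {
    s <- sets[[cat]]
    if (is.null(s)) next
    m <- model$configs[[cat]]
    if (length(s$detrimental)) m[, s$detrimental] <- 0
    if (length(s$critical)) m[, s$critical] <- 1
    m2 <- clean_config_matrix(m)
    if (is.null(m2)) {
      orig <- model$configs[[cat]]
      ndet <- rowSums(orig[, s$detrimental, drop = FALSE] != 0)
      m2 <- orig[which.min(ndet), , drop = FALSE]
      kept <- c(kept, cat)
    }
    model$configs[[cat]] <- m2
  }
  model$name <- paste0(model$name, " [", culture, "-accented]")
  if (length(kept)) attr(model, "kept_original") <- kept
  model
}
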