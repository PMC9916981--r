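# End-to-end prediction -> explanation -> exploration cycle with the
# cross-validated split: ablation maps and accents are derived on train
# trials of train participants only, optimized culture-accented models are
# evaluated on test trials of test participants.

subset_trials <- function(trials, idx) {
  out <- trials[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "task") <- attr(trials, "task")
  out
}

#' Run the prediction-explanation-exploration cycle
#'
#' 1. Splits trials by participant, face and stimulus key ([split_train_test()];
#'    disjointness is asserted inside the pipeline, not only in tests).
#' 2. Evaluates the original models on the train split (prediction stage).
#' 3. Computes per-culture ablation maps on the train split and derives
#'    performance-critical / performance-detrimental AUs (explanation stage).
#' 4. Builds optimized culture-accented models and evaluates them on the test
#'    split of their own culture; the original models are evaluated on the
#'    same test split for comparison (exploration stage).
#' 5. Compares cultures before (original models) and after (accented models)
#'    optimization.
#'
#' @param trials Trial table covering at least two cultures.
#' @param models An `au_model` or list of them.
#' @param epsilon Dead-zone for accent classification (default 0).
#' @param participant_fraction Train fraction of participants (default 2/3).
#' @param seed Seed for the split.
#' @param beta,kernel Passed to [hka()].
#' @param cultures Length-2 culture ordering for the comparisons (default:
#'   order of appearance in `trials`).
#' @return Object of class `hk_exploration`: `$plan`, `$maps`, `$accents`,
#'   `$optimized` (per-culture model lists), `$fit_train`,
#'   `$fit_test_original`, `$fit_test_optimized`, `$comparison_pre`
#'   (original models, train split), `$comparison_pre_test`,
#'   `$comparison_post` (accented models, test split).
#' @export
hk_explore <- function(trials, models, epsilon = 0, participant_fraction = 2/3,
                       seed = NULL, beta = 1, kernel = "cosine",
                       cultures = NULL) {
  if (inherits(models, "au_model"))
    models <- stats::setNames(list(models), models$name)
  trials <- drop_other(trials)
  if (is.null(cultures)) cultures <- unique(trials$culture)
  if (length(cultures) != 2)
    stop("exploration with culture comparison needs exactly 2 cultures")
  plan <- split_train_test(trials, participant_fraction, seed)
  assert_split_disjoint(plan)
  train <- subset_trials(trials, plan$train_idx)
  test <- subset_trials(trials, plan$test_idx)

  fit_train <- hka(models, train, beta = beta, kernel = kernel)

  maps <- lapply(stats::setNames(cultures, cultures), function(cu)
    ablation_map(models, subset_trials(train, which(train$culture == cu)),
                 kernel = kernel))
  accents <- derive_accents(maps, epsilon)
  optimized <- lapply(stats::setNames(cultures, cultures), function(cu)
    lapply(models, optimize_model, accents = accents, culture = cu))

  fit_test_original <- hka(models, test, beta = beta, kernel = kernel)
  opt_tabs <- lapply(cultures, function(cu) {
    fit <- hka(optimized[[cu]], subset_trials(test, which(test$culture == cu)),
               beta = beta, kernel = kernel)
    tab <- fit$auroc
    # report accented fits under the base model name so per-participant
    # model averages align across cultures
    tab$model <- sub(" \\[[^]]*-accented\\]$", "", tab$model)
    tab
  })
  fit_test_optimized <- structure(list(
    auroc = do.call(rbind, opt_tabs), skipped = NULL,
    models = unlist(optimized, recursive = FALSE),
    beta = beta, kernel = if (is.function(kernel)) "custom" else kernel,
    ranking = "margin", n_trials = nrow(test), data = NULL,
    call = match.call()), class = "hka")

  structure(list(
    plan = plan, maps = maps, accents = accents, optimized = optimized,
    fit_train = fit_train,
    fit_test_original = fit_test_original,
    fit_test_optimized = fit_test_optimized,
    comparison_pre = compare_cultures(fit_train, cultures),
    comparison_pre_test = compare_cultures(fit_test_original, cultures),
    comparison_post = compare_cultures(fit_test_optimized, cultures),
    cultures = cultures, epsilon = epsilon),
    class = "hk_exploration")
}

#' @export
print.hk_exploration <- function(x, digits = 3, ...) {
  cat("Prediction-explanation-exploration cycle\n")
  print(x$plan)
  cat("\nMean AUROC, original models (train split):",
      round(mean(x$fit_train$auroc$auroc), digits), "\n")
  cat("Mean AUROC, original models (test split): ",
      round(mean(x$fit_test_original$auroc$auroc), digits), "\n")
  cat("Mean AUROC, accented models (test split): ",
      round(mean(x$fit_test_optimized$auroc$auroc), digits), "\n")
  sig <- function(cmp) paste(cmp$category[!is.na(cmp$p) & cmp$p < 0.05],
                             collapse = ", ")
  cat("\nCulture differences at alpha = 0.05 (uncorrected):\n")
  cat("  before optimization:", if (nzchar(sig(x$comparison_pre))) sig(x$comparison_pre) else "none", "\n")
  cat("  after optimization: ", if (nzchar(sig(x$comparison_post))) sig(x$comparison_post) else "none", "\n")
  invisible(x)
}
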