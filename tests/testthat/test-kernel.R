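toy_model <- function() {
  au_model_from_spec("toy", "basic6",
                     list(happy = "6 + 12", sadness = "1 + 15",
                          disgust = "9 + 25"))
}

test_that("cosine similarity matches hand-computed values", {
  u9 <- au_config_vector(9)
  expect_equal(cosine_similarity(u9, u9), 1.0)
  expect_equal(cosine_similarity(u9, au_config_vector(25)), 0.0)
  expect_equal(cosine_similarity(au_config_vector(12),
                                 au_config_vector(c(6, 12))),
               1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cosine_similarity(rep(0, 33), u9), 0)  # zero-norm convention
  expect_error(cosine_similarity(1:3, 1:4), "length")
})

test_that("softmax predictions match hand-evaluated values", {
  m2 <- au_model_from_spec("pair", "basic6",
                           list(happy = "6 + 12", sadness = "1 + 15"))
  # equal scores -> uniform
  p <- hk_predict(m2, rep(0, 33) |> matrix(nrow = 1))
  expect_equal(unname(p[1, ]), c(0.5, 0.5))
  # single covered category -> probability 1
  m1 <- au_model_from_spec("one", "basic6", list(happy = "6 + 12"))
  expect_equal(unname(hk_predict(m1, c("6" = 1, "12" = 1))[1, 1]), 1.0)
  # scores (1, 0) at beta = 1 -> (e/(e+1), 1/(e+1))
  s <- matrix(au_config_vector(c(6, 12)), nrow = 1)
  p <- hk_predict(m2, s)
  expect_equal(unname(p[1, ]), c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-5)
  expect_equal(unname(round(p[1, ], 5)), c(0.73106, 0.26894))
  expect_error(hk_predict(m2, s, beta = 0), "beta")
})

test_that("prediction rows always sum to one", {
  set.seed(5)
  model <- hk_models("basic6")[["Matsumoto et al. (2008)"]]
  S <- matrix(runif(50 * 33), 50)
  for (beta in c(0.5, 1, 4)) {
    p <- hk_predict(model, S, beta = beta)
    expect_equal(rowSums(p), rep(1, 50), tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("adding a configuration never decreases a category's score", {
  set.seed(6)
  S <- matrix(runif(30 * 33), 30)
  base <- au_model("m", "basic6", list(happy = au_config_vector(c(6, 12))))
  more <- au_model("m2", "basic6",
                   list(happy = rbind(au_config_vector(c(6, 12)),
                                      au_config_vector(25))))
  s1 <- hk_predict(base, S, type = "score")[, "happy"]
  s2 <- hk_predict(more, S, type = "score")[, "happy"]
  expect_true(all(s2 >= s1 - 1e-12))
})

test_that("AUROC matches hand-evaluated examples and flags undefined cells", {
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.7, 6), c(1, 0, 1, 0, 1, 0)), 0.5)  # pure ties
  expect_true(is.na(auroc(1:4, c(1, 1, 1, 1))))
  expect_true(is.na(auroc(1:4, c(0, 0, 0, 0))))
})

test_that("AUROC agrees exactly with the brute-force pairwise oracle", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:50, 1)
    # discretized scores induce ties; labels guaranteed two-class
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))[sample.int(n)]
    expect_identical(auroc(scores, labels), auroc_oracle(scores, labels))
  }
})

test_that("AUROC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(104)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("AUROC is antisymmetric and monotone-transform invariant", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    scores <- runif(n)  # continuous, tie-free
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    a <- auroc(scores, labels)
    expect_equal(a + auroc(-scores, labels), 1)
    expect_equal(auroc(plogis(7 * scores), labels), a)
  }
})

test_that("ranking by margin makes evaluation invariant to softmax beta", {
  trials <- simulate_experiment(n_participants = 3, n_trials = 120, seed = 2)
  model <- toy_model()
  f1 <- hka(model, trials, beta = 1)
  f2 <- hka(model, trials, beta = 9)
  expect_identical(f1$auroc$auroc, f2$auroc$auroc)
})

test_that("argmax-consistent responses give AUROC 1 per category", {
  # noiseless deterministic responders under the evaluated model itself
  model <- hk_models("basic6")[["Jack et al. (2014)"]]
  spec <- responder_spec(model, beta = Inf, lapse = 0, other_threshold = 0)
  trials <- simulate_experiment(n_participants = 2, n_trials = 300,
                                cultures = "WE", responders = spec, seed = 4)
  fit <- hka(model, trials)
  expect_true(all(fit$auroc$auroc == 1))
})

test_that("responses shuffled independently of stimuli score near chance", {
  set.seed(8)
  S <- matrix(runif(4000 * 33), 4000)
  resp <- sample(hk_categories("basic6"), 4000, replace = TRUE)
  trials <- make_trials(S, resp)
  fit <- hka(toy_model(), trials)
  expect_equal(mean(fit$auroc$auroc), 0.5, tolerance = 0.02)
})

test_that("a binary model scores both its categories identically", {
  set.seed(9)
  S <- matrix(runif(400 * 33), 400)
  resp <- sample(c("happy", "sadness"), 400, replace = TRUE)
  trials <- make_trials(S, resp)
  m2 <- au_model_from_spec("pair", "basic6",
                           list(happy = "6 + 12", sadness = "1 + 15"))
  fit <- hka(m2, trials)
  by_cat <- split(fit$auroc$auroc, fit$auroc$category)
  expect_equal(by_cat$happy, by_cat$sadness, tolerance = 1e-12)
})

test_that("single-class cells are skipped and recorded, not imputed", {
  S <- matrix(runif(40 * 33), 40)
  trials <- make_trials(S, rep(c("happy", "sadness"), 20))
  fit <- hka(toy_model(), trials)   # disgust never chosen
  expect_false("disgust" %in% fit$auroc$category)
  expect_true("disgust" %in% fit$skipped$category)
  # trials outside covered categories are filtered; nothing left -> error
  m1 <- au_model_from_spec("one", "basic6", list(disgust = "9 + 25"))
  expect_error(hka(m1, trials), "no trials")
})

test_that("evaluation summaries and predict method are consistent", {
  trials <- simulate_experiment(n_participants = 3, n_trials = 150, seed = 12)
  model <- hk_models("basic6")[["Jack et al. (2014)"]]
  fit <- hka(model, trials, keep_data = TRUE)
  sm <- summary(fit)
  expect_equal(unname(sm$by_model_category[1, ]),
               unname(coef(fit)[1, ]))
  p <- predict(fit, trials)
  expect_equal(nrow(p), nrow(trials))  # prediction covers every stimulus
  r <- residuals(fit)
  expect_true(all(abs(r) <= 1))
  expect_output(print(fit), "Hypothesis kernel evaluation")
})
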