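# Fixture: n_obs observations of each of a set of stimulus patterns, with a
# given response-generating function.
repeated_trials <- function(stim_S, n_observers, respond, task = "basic6") {
  n <- nrow(stim_S)
  S <- stim_S[rep(seq_len(n), n_observers), , drop = FALSE]
  pid <- rep(sprintf("p%02d", seq_len(n_observers)), each = n)
  resp <- respond(S, pid)
  make_trials(S, resp, participant_id = pid)
}

test_that("optimal predictions are the empirical label distribution per stimulus", {
  # 3 observations "happy", 1 "surprise" on one key -> (0.75, 0.25)
  S <- matrix(runif(33), 1)[rep(1, 4), ]
  trials <- make_trials(S, c("happy", "happy", "happy", "surprise"),
                        participant_id = paste0("p", 1:4))
  p <- optimal_predictions(trials)
  expect_equal(unname(p[1, c("happy", "surprise")]), c(0.75, 0.25))
  expect_equal(rowSums(p), rep(1, 4))
  # unanimity -> one-hot
  trials2 <- make_trials(S, rep("fear", 4), participant_id = paste0("p", 1:4))
  expect_equal(unname(optimal_predictions(trials2)[, "fear"]), rep(1, 4))
  expect_error(optimal_predictions(trials[0, ]), "empty")
})

test_that("ceiling matches the closed-form value of a two-stimulus mixture", {
  # P(A|s1) = 0.9, P(A|s2) = 0.1, balanced observations of both stimuli:
  # AUROC of the conditional-probability score is
  # P(pos from s1) * P(neg from s2) + 0.5 * P(tie) = 0.81 + 0.09 = 0.90
  set.seed(21)
  s1 <- matrix(runif(33), 1); s2 <- matrix(runif(33), 1)
  S <- rbind(s1[rep(1, 10), ], s2[rep(1, 10), ])
  resp <- c(rep("happy", 9), "sadness", "happy", rep("sadness", 9))
  trials <- make_trials(S, resp, participant_id = rep(paste0("p", 1:10), 2))
  nc <- noise_ceiling(trials, n_boot = 10, seed = 1)
  expect_equal(nc$per_category$ceiling, c(0.9, 0.9))
})

test_that("deterministic raters saturate the ceiling at 1", {
  set.seed(22)
  stim_S <- matrix(runif(40 * 33), 40)
  cats <- hk_categories("basic6")
  fixed <- cats[1 + (seq_len(40) %% 6)]
  trials <- repeated_trials(stim_S, 8, function(S, pid)
    rep(fixed, length(pid) / 40))
  nc <- noise_ceiling(trials, n_boot = 10, seed = 1)
  expect_equal(nc$per_category$ceiling, rep(1, length(unique(fixed))))
})

test_that("labels independent of stimuli give a ceiling near chance", {
  set.seed(23)
  stim_S <- matrix(runif(150 * 33), 150)
  trials <- repeated_trials(stim_S, 30, function(S, pid)
    sample(hk_categories("basic6"), nrow(S), replace = TRUE))
  nc <- noise_ceiling(trials, n_boot = 5, seed = 1)
  expect_equal(mean(nc$per_category$ceiling), 0.5, tolerance = 0.03)
})

test_that("the plug-in ceiling bounds every AU model on the same trials", {
  set.seed(24)
  model <- hk_models("basic6")[["Jack et al. (2014)"]]
  spec <- responder_spec(model, beta = 5, lapse = 0.2, other_threshold = 0)
  stim_S <- as.matrix(simulate_stimuli(100, seed = 24)[, au_columns()])
  trials <- repeated_trials(stim_S, 20, function(S, pid)
    simulate_responses(S, spec))
  nc <- noise_ceiling(trials, n_boot = 5, seed = 1)
  fit <- hka(hk_models("basic6"), trials)
  by_cat <- stats::aggregate(auroc ~ category, fit$auroc, mean)
  ceil <- stats::setNames(nc$per_category$ceiling, nc$per_category$category)
  expect_true(all(by_cat$auroc <= ceil[by_cat$category] + 0.02))
})

test_that("the ceiling is invariant to relabeling participants", {
  set.seed(25)
  stim_S <- matrix(runif(30 * 33), 30)
  trials <- repeated_trials(stim_S, 6, function(S, pid)
    sample(hk_categories("basic6"), nrow(S), replace = TRUE))
  nc1 <- noise_ceiling(trials, n_boot = 3, seed = 9)
  perm <- trials
  perm$participant_id <- sample(sprintf("q%02d", 1:6))[
    as.integer(factor(perm$participant_id))]
  nc2 <- noise_ceiling(perm, n_boot = 3, seed = 9)
  expect_equal(nc1$per_category$ceiling, nc2$per_category$ceiling)
})

test_that("bootstrap is deterministic given a seed and reports spread", {
  set.seed(26)
  stim_S <- matrix(runif(25 * 33), 25)
  trials <- repeated_trials(stim_S, 8, function(S, pid)
    sample(c("happy", "fear"), nrow(S), replace = TRUE, prob = c(0.7, 0.3)))
  nc1 <- noise_ceiling(trials, n_boot = 20, seed = 5)
  nc2 <- noise_ceiling(trials, n_boot = 20, seed = 5)
  expect_identical(nc1$per_category, nc2$per_category)
  expect_true(all(nc1$per_category$sd >= 0))
})

test_that("singleton-dominated designs are flagged and degenerate ones warned", {
  set.seed(27)
  S <- matrix(runif(50 * 33), 50)
  trials <- make_trials(S, sample(c("happy", "fear"), 50, replace = TRUE),
                        participant_id = rep(c("p1", "p2"), 25))
  expect_warning(nc <- noise_ceiling(trials, n_boot = 2, seed = 1), "singleton")
  expect_true(nc$degenerate)
  expect_equal(nc$singleton_fraction, 1)
  # singleton keys contribute their own label: ceiling saturates at 1
  expect_equal(nc$per_category$ceiling, c(1, 1))
})

test_that("leave-one-participant-out mode is conservative and counts drops", {
  set.seed(28)
  shared <- matrix(runif(20 * 33), 20)
  own <- matrix(runif(33), 1)  # one singleton stimulus, p1 only
  S <- rbind(shared, own, shared)
  pid <- c(rep("p1", 21), rep("p2", 20))
  resp <- sample(c("happy", "fear"), 41, replace = TRUE)
  trials <- make_trials(S, resp, participant_id = pid)
  nc <- noise_ceiling(trials, n_boot = 2, seed = 1,
                      mode = "leave_one_participant_out")
  expect_equal(nc$n_dropped, 1L)
  expect_identical(nc$mode, "leave_one_participant_out")
  plug <- suppressWarnings(noise_ceiling(trials, n_boot = 2, seed = 1))
  expect_true(mean(nc$per_category$ceiling) <=
                mean(plug$per_category$ceiling) + 1e-9)
})

test_that("per-culture grouping is honored and named in the report", {
  set.seed(29)
  stim_S <- matrix(runif(10 * 33), 10)
  t1 <- repeated_trials(stim_S, 4, function(S, pid)
    sample(c("happy", "fear"), nrow(S), replace = TRUE))
  t2 <- t1; t2$culture <- "EA"; t2$participant_id <- sub("p", "e", t2$participant_id)
  trials <- rbind(t1, t2)
  attr(trials, "task") <- "basic6"
  nc <- noise_ceiling(trials, n_boot = 2, seed = 1, grouping = "per_culture")
  expect_identical(nc$grouping, "per_culture")
  path <- withr::local_tempfile(fileext = ".json")
  write_noise_ceiling(nc, path)
  rep <- jsonlite::read_json(path)
  expect_identical(rep$grouping, "per_culture")
  expect_identical(rep$mode, "plug_in")
})
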