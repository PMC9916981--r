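fake_map <- function(delta) {
  structure(list(delta = delta, per_model = NULL, non_evaluable = NULL,
                 categories = rownames(delta)), class = "ablation_map")
}

test_that("ablation removes an AU from the target category only", {
  m <- au_model_from_spec("toy", "basic6",
                          list(disgust = "9 + 25", happy = "6 + 12"))
  a <- au_ablate(m, "disgust", 9)
  expect_equal(unname(a$configs$disgust[1, ]), unname(au_config_vector(25)))
  expect_equal(a$configs$happy, m$configs$happy)
  # bilateral number removes both laterals
  a2 <- au_ablate(m, "happy", 12)
  expect_equal(unname(a2$configs$happy[1, ]), unname(au_config_vector(6)))
})

test_that("ablation deduplicates and rejects degenerate cases", {
  m <- au_model("toy", "basic6",
                list(disgust = rbind(au_config_vector(9),
                                     au_config_vector(c(9, 25)))))
  a <- au_ablate(m, "disgust", 25)
  expect_equal(nrow(a$configs$disgust), 1)
  expect_equal(unname(a$configs$disgust[1, ]), unname(au_config_vector(9)))
  one <- au_model("one", "basic6", list(disgust = au_config_vector(9)))
  expect_error(au_ablate(one, "disgust", 9), "non-evaluable")
  expect_error(au_ablate(m, "disgust", 12), "no configuration")
  expect_error(au_ablate(m, "happy", 9), "not covered")
})

test_that("re-adding an ablated AU reproduces the original evaluation exactly", {
  trials <- simulate_experiment(n_participants = 3, n_trials = 150, seed = 31)
  m <- hk_models("basic6")[["Cordaro et al. (2018) ref."]]
  restored <- au_ablate(m, "disgust", 15)
  restored$configs$disgust[, "15"] <- 1  # undo the ablation
  f1 <- hka(m, trials)
  f2 <- hka(restored, trials)
  expect_identical(f1$auroc$auroc, f2$auroc$auroc)
})

test_that("the ablation map marks absent AUs undefined and finds planted dependence", {
  model <- au_model_from_spec(
    "planted", "basic6",
    list(disgust = "9 + 25", happy = "6 + 12", sadness = "1 + 15",
         anger = "4 + 23", fear = "5 + 20", surprise = "2 + 26"))
  spec <- responder_spec(model, beta = 20, lapse = 0.05, other_threshold = 0)
  trials <- simulate_experiment(n_participants = 8, n_trials = 250,
                                cultures = "WE", responders = spec, seed = 32)
  map <- ablation_map(model, trials)
  # AU9 drives disgust in the generating behavior: ablating it must hurt
  expect_lt(map$delta["disgust", "9"], 0)
  # AUs never part of the category's model are undefined
  expect_true(is.na(map$delta["disgust", "4"]))
  expect_true(is.na(map$delta["happy", "9"]))
  expect_true(all(is.finite(map$delta[!is.na(map$delta)])))
})

test_that("map cells average deltas across the models containing the AU", {
  trials <- simulate_experiment(n_participants = 2, n_trials = 200, seed = 33)
  m1 <- au_model("a", "basic6", list(happy = au_config_vector(c(6, 12)),
                                     sadness = au_config_vector(c(1, 15))))
  m2 <- au_model("b", "basic6", list(happy = rbind(au_config_vector(c(6, 12)),
                                                   au_config_vector(12)),
                                     sadness = au_config_vector(c(1, 15))))
  map <- ablation_map(list(a = m1, b = m2), trials)
  both <- map$per_model[map$per_model$category == "happy" &
                          map$per_model$au == "6L", ]
  expect_equal(nrow(both), 2)
  expect_equal(map$delta["happy", "6L"], mean(both$delta))
})

test_that("accent classification follows the sign rule with a dead zone", {
  delta <- matrix(NA_real_, 2, 33, dimnames = list(c("disgust", "happy"), au_labels()))
  delta["disgust", "9"] <- -0.03
  delta["disgust", "25"] <- 0.01
  delta["happy", "12L"] <- 0.04
  acc0 <- derive_accents(list(WE = fake_map(delta)), epsilon = 0)
  expect_identical(acc0$sets$WE$disgust$critical, "9")
  expect_identical(acc0$sets$WE$disgust$detrimental, "25")
  acc2 <- derive_accents(list(WE = fake_map(delta)), epsilon = 0.02)
  expect_identical(acc2$sets$WE$disgust$critical, "9")
  expect_length(acc2$sets$WE$disgust$detrimental, 0)
  # all-undefined -> empty sets
  empty <- derive_accents(fake_map(matrix(NA_real_, 1, 33,
                                          dimnames = list("fear", au_labels()))))
  expect_length(empty$sets$all$fear$critical, 0)
  expect_length(empty$sets$all$fear$detrimental, 0)
})

test_that("optimization adds critical and removes detrimental AUs", {
  m <- au_model_from_spec("toy", "basic6", list(disgust = "10 + 25"))
  delta <- matrix(NA_real_, 1, 33, dimnames = list("disgust", au_labels()))
  delta[1, "9"] <- -0.05
  delta[1, "25"] <- +0.05
  acc <- derive_accents(list(EA = fake_map(delta)))
  opt <- optimize_model(m, acc, "EA")
  got <- au_labels()[opt$configs$disgust[1, ] != 0]
  expect_setequal(got, c("9", "10L", "10R"))
  expect_match(opt$name, "EA-accented", fixed = TRUE)
})

test_that("optimization is identity under empty accents and idempotent", {
  m <- au_model_from_spec("toy", "basic6", list(disgust = "9 + 25"))
  none <- derive_accents(fake_map(matrix(NA_real_, 1, 33,
                                         dimnames = list("disgust", au_labels()))))
  opt <- optimize_model(m, none, "all")
  expect_equal(opt$configs, m$configs)
  # a critical AU already present changes nothing after dedup
  delta <- matrix(NA_real_, 1, 33, dimnames = list("disgust", au_labels()))
  delta[1, "9"] <- -0.05
  acc <- derive_accents(list(x = fake_map(delta)))
  o1 <- optimize_model(m, acc, "x")
  o2 <- optimize_model(o1, acc, "x")
  expect_equal(o1$configs, o2$configs)
  expect_equal(o1$configs, m$configs)
})

test_that("a category emptied by optimization keeps its best original configuration", {
  m <- au_model("toy", "basic6",
                list(disgust = rbind(au_config_vector(c(9, 25)),
                                     au_config_vector(25))))
  delta <- matrix(NA_real_, 1, 33, dimnames = list("disgust", au_labels()))
  delta[1, "9"] <- 0.05
  delta[1, "25"] <- 0.05
  acc <- derive_accents(list(x = fake_map(delta)))
  opt <- optimize_model(m, acc, "x")
  expect_identical(attr(opt, "kept_original"), "disgust")
  # the kept configuration is the one with fewest detrimental AUs: {25}
  expect_equal(unname(opt$configs$disgust[1, ]), unname(au_config_vector(25)))
})
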