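test_that("age transform is the anchored piecewise log/linear map", {
  expect_equal(age_transform(20), 0)
  expect_equal(age_transform(41), 1)
  expect_equal(age_transform(0), log(1 / 21))
  expect_error(age_transform(-1), "non-negative")
  # strictly increasing and continuous at the anchor
  ages <- seq(0, 120, by = 0.5)
  expect_true(all(diff(age_transform(ages)) > 0))
  expect_equal(age_transform(20 + 1e-9), age_transform(20), tolerance = 1e-6)
})

test_that("inverse transform round-trips on [0, 120] to 1e-9", {
  ages <- seq(0, 120, length.out = 1201)
  expect_equal(inverse_age_transform(age_transform(ages)), ages,
               tolerance = 1e-9)
  adult <- 35
  expect_equal(inverse_age_transform(age_transform(ages, adult), adult), ages,
               tolerance = 1e-9)
})

noiseless_model <- function(seed = 7, n_cpg = 10L) {
  cfg <- sim_config(seed = seed, clock_cpg_count = n_cpg,
                    clock_signal_count = n_cpg, clock_extra_cpgs = 2L,
                    noise_sd = 0)
  list(cfg = cfg, tm = make_true_clock_model(cfg))
}

test_that("noiseless generation is exactly affine in transformed age", {
  nm <- noiseless_model()
  beta <- generate_beta_matrix(c(20, 41), nm$tm, noise_sd = 0, seed = 1)
  cpg <- nm$tm$whitelist[1]
  slope <- nm$tm$slopes[cpg]
  expect_equal(beta[cpg, 2] - beta[cpg, 1],
               unname(slope) * (age_transform(41) - age_transform(20)),
               tolerance = 1e-12)
  expect_error(generate_beta_matrix(c(-5, 10), nm$tm, 0, seed = 1),
               "non-negative")
  expect_identical(generate_beta_matrix(c(30, 50), nm$tm, 0.05, seed = 4),
                   generate_beta_matrix(c(30, 50), nm$tm, 0.05, seed = 4))
})

test_that("a noise-free clock round-trips chronological age to numerical tolerance", {
  nm <- noiseless_model()
  tp <- generate_training_panel(nm$cfg, nm$tm, n = 80)
  # with an effectively unpenalized fit the linear map is recovered exactly
  m <- train_filtered_clock(tp$beta, tp$ages, nm$tm$whitelist, lambda = 1e-12)
  expect_lt(max(abs(predict_age(m, tp$beta) - tp$ages)), 1e-6)
})

test_that("cross-validated training recovers ages and respects the support bound", {
  nm <- noiseless_model()
  tp <- generate_training_panel(nm$cfg, nm$tm, n = 80)
  m <- train_filtered_clock(tp$beta, tp$ages, nm$tm$whitelist, seed = 5)
  expect_lt(mean(abs(predict_age(m, tp$beta) - tp$ages)), 0.1)
  expect_lte(m$nonzero_count, length(nm$tm$whitelist))
  expect_gte(cor(predict_age(m, tp$beta), tp$ages), 0.95)
})

test_that("training is invariant to duplicating every sample at fixed penalty", {
  nm <- noiseless_model(seed = 8)
  tp <- generate_training_panel(nm$cfg, nm$tm, n = 40)
  dup <- cbind(tp$beta, tp$beta)
  colnames(dup) <- c(colnames(tp$beta), paste0(colnames(tp$beta), "b"))
  m1 <- train_filtered_clock(tp$beta, tp$ages, nm$tm$whitelist, lambda = 0.01)
  m2 <- train_filtered_clock(dup, c(tp$ages, tp$ages), nm$tm$whitelist,
                             lambda = 0.01)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-6)
  expect_equal(m1$intercept, m2$intercept, tolerance = 1e-6)
})

test_that("training validates its inputs", {
  nm <- noiseless_model()
  tp <- generate_training_panel(nm$cfg, nm$tm, n = 20)
  expect_error(train_filtered_clock(tp$beta, tp$ages,
                                    c(nm$tm$whitelist, "cg_absent")),
               "cg_absent")
  expect_error(train_filtered_clock(tp$beta[, 1:5], tp$ages[1:5],
                                    nm$tm$whitelist), "at least 10")
  expect_error(train_filtered_clock(tp$beta, rep(50, 20), nm$tm$whitelist),
               "constant")
})

test_that("predict_age ignores non-whitelist rows and flags missing CpGs", {
  nm <- noiseless_model()
  tp <- generate_training_panel(nm$cfg, nm$tm, n = 40)
  m <- train_filtered_clock(tp$beta, tp$ages, nm$tm$whitelist, seed = 5)
  pert <- tp$beta
  extra <- setdiff(rownames(pert), m$whitelist)
  pert[extra, ] <- runif(length(extra) * ncol(pert))
  expect_equal(predict_age(m, pert), predict_age(m, tp$beta))
  expect_error(predict_age(m, tp$beta[-1, , drop = FALSE]), "missing whitelist")
  imputed <- predict_age(m, tp$beta[-1, , drop = FALSE], impute = TRUE)
  expect_equal(length(imputed), ncol(tp$beta))
  # constant model predicts its intercept age for any input
  flat <- clock_model(m$whitelist, intercept = age_transform(50),
                      coefficients = numeric(0))
  expect_equal(unname(predict_age(flat, tp$beta)), rep(50, ncol(tp$beta)))
})

test_that("cohort deltas are after-minus-before with strict decrease counting", {
  nm <- noiseless_model()
  tp <- generate_training_panel(nm$cfg, nm$tm, n = 40)
  m <- train_filtered_clock(tp$beta, tp$ages, nm$tm$whitelist, lambda = 1e-12)
  res0 <- suppressWarnings(cohort_age_deltas(m, tp$beta, tp$beta))
  expect_equal(res0$deltas$delta, rep(0, 40), tolerance = 1e-9)
  expect_equal(res0$group_summary$fraction_decreasing[1], 0)
  beta2 <- generate_beta_matrix(tp$ages - 3, nm$tm, 0, seed = 2,
                                sample_ids = colnames(tp$beta))
  res <- cohort_age_deltas(m, tp$beta, beta2)
  expect_equal(res$deltas$delta, rep(-3, 40), tolerance = 1e-5)
  expect_equal(res$group_summary$fraction_decreasing[1], 1)
  colnames(beta2) <- rev(colnames(beta2))
  expect_error(cohort_age_deltas(m, tp$beta, beta2), "identical sample columns")
})

test_that("clock model TSV serialization round-trips bit-exactly", {
  nm <- noiseless_model()
  tp <- generate_training_panel(nm$cfg, nm$tm, n = 40)
  m <- train_filtered_clock(tp$beta, tp$ages, nm$tm$whitelist, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clock_model(m, path)
  m2 <- read_clock_model(path)
  expect_identical(m2$coefficients, m$coefficients)
  expect_identical(m2$intercept, m$intercept)
  expect_identical(m2$whitelist, m$whitelist)
  expect_identical(m2$cpg_means, m$cpg_means)
  expect_equal(predict_age(m2, tp$beta), predict_age(m, tp$beta))
})
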