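test_that("the WQS index is the weighted decile sum", {
  q <- cbind(Cd = c(0L, 5L, 9L), Sb = c(9L, 5L, 0L))
  expect_equal(compute_wqs_index(q, c(Cd = 0.25, Sb = 0.75)),
               c(6.75, 5, 2.25))
  # degenerate one-hot mixture reproduces the column
  expect_equal(compute_wqs_index(q, c(Cd = 1, Sb = 0)), as.numeric(q[, "Cd"]))
  # convexity: constant ranks map to themselves for any simplex weights
  qc <- cbind(Cd = rep(4L, 3), Sb = rep(4L, 3))
  expect_equal(compute_wqs_index(qc, c(Cd = 0.3, Sb = 0.7)), rep(4, 3))
  expect_error(compute_wqs_index(q, c(0.5, 0.3, 0.2)), "columns")
  expect_error(compute_wqs_index(q, c(Cd = 0.8, Sb = 0.8)), "sum to 1")
})

test_that("noiseless training identifies a one-hot mixture", {
  set.seed(1)
  n <- 200
  q <- vapply(1:6, function(i) sample(0:9, n, TRUE), numeric(n))
  colnames(q) <- metal_names("toxic")
  y <- 100 - q[, "Cd"]
  cfg <- wqs_config(n_boot = 10, penalty = 0)
  boot <- train_weights(q, y, covariates = NULL, direction = -1,
                        config = cfg, seed = 2)
  expect_true(all(boot$weights[boot$converged, "Cd"] >= 0.95))
  expect_equal(unname(boot$beta1[boot$converged]),
               rep(-1, sum(boot$converged)), tolerance = 1e-4)
})

test_that("simplex and direction invariants hold across bootstraps", {
  prob <- two_metal_problem(3, n = 150)
  cfg <- wqs_config(n_boot = 30, penalty = 100)
  boot <- train_weights(prob$q, prob$y, prob$x, direction = -1,
                        config = cfg, seed = 4)
  expect_true(all(abs(rowSums(boot$weights) - 1) < 1e-8))
  expect_true(all(boot$weights >= 0))
  expect_true(all(boot$beta1[boot$converged] <= 0))
  expect_gte(mean(boot$converged), 0.9)
})

test_that("an infinite penalty drives the weights to uniform", {
  prob <- two_metal_problem(5, n = 150)
  set.seed(55)
  q6 <- cbind(prob$q, matrix(sample(0:9, 150 * 4, TRUE), 150, 4))
  colnames(q6) <- metal_names("toxic")
  cfg <- wqs_config(n_boot = 5, penalty = 1e9)
  boot <- train_weights(q6, prob$y, prob$x, direction = -1,
                        config = cfg, seed = 6)
  expect_equal(boot$weights[boot$converged, ],
               matrix(1 / 6, sum(boot$converged), 6,
                      dimnames = list(NULL, colnames(q6))),
               tolerance = 1e-3)
})

test_that("training matches the profile-least-squares grid oracle", {
  cfg <- wqs_config(n_boot = 1, penalty = 0)
  for (s in 1:5) {
    prob <- two_metal_problem(s)
    boot <- train_weights(prob$q, prob$y, prob$x, direction = -1,
                          config = cfg, seed = s * 7)
    oracle <- grid_oracle_2metal(prob$q, prob$x, prob$y,
                                 boot$boot_indices[[1]])
    # the continuous optimizer may only improve on the 0.001-step grid
    expect_lte(boot$objective[1], oracle$obj_min + 1e-6)
    expect_lt(abs(boot$weights[1, "Cd"] - oracle$w_min), 0.02)
  }
})

test_that("bootstrap aggregation weights rows by squared signal", {
  boot <- structure(list(
    weights = rbind(c(0.8, 0.2), c(0.2, 0.8)),
    tstat = c(1, 2), converged = c(TRUE, TRUE)), class = "wqs_boot")
  colnames(boot$weights) <- c("Cd", "Sb")
  # mixing proportions 1/5 and 4/5
  expect_equal(unname(aggregate_weights(boot, "squared_t")),
               unname(0.2 * c(0.8, 0.2) + 0.8 * c(0.2, 0.8)))
  expect_equal(unname(aggregate_weights(boot, "uniform")), c(0.5, 0.5))
  # identical rows are a fixed point
  boot$weights <- rbind(c(0.6, 0.4), c(0.6, 0.4))
  expect_equal(unname(aggregate_weights(boot, "squared_t")), c(0.6, 0.4))
  # zero total signal falls back to uniform row weighting with a warning
  boot$tstat <- c(0, 0)
  expect_warning(w <- aggregate_weights(boot, "squared_t"),
                 class = "wqsmix_zero_signal")
  expect_equal(unname(w), c(0.6, 0.4))
})

test_that("joint validation recovers a noiseless generating model exactly", {
  coh <- generate_cohort(n = 150, seed = 7)
  q <- as.matrix(coh$deciles$ranks)
  w_ess <- setNames(rep(1 / 8, 8), metal_names("essential"))
  w_tox <- setNames(c(0.5, 0.3, 0.05, 0.05, 0.05, 0.05)[c(2, 3, 1, 4, 5, 6)],
                    metal_names("toxic"))
  w_tox <- w_tox / sum(w_tox)
  s_ess <- compute_wqs_index(q[, names(w_ess)], w_ess)
  s_tox <- compute_wqs_index(q[, names(w_tox)], w_tox)
  covars <- coh$data[, c("age", "bmi")]
  y <- 80 + 0.5 * s_ess - 1.2 * s_tox - 0.1 * s_tox^2 +
    0.3 * covars$age - 0.2 * covars$bmi
  # noiseless fit: summary.lm warns about the perfect fit, which is the point
  val <- suppressWarnings(validate_model(q, y, w_ess, w_tox, covars,
                                         quadratic = c(ess = FALSE, tox = TRUE)))
  est <- setNames(val$estimates$estimate, val$estimates$term)
  expect_equal(est[["(Intercept)"]], 80, tolerance = 1e-8)
  expect_equal(est[["wqs_ess"]], 0.5, tolerance = 1e-8)
  expect_equal(est[["wqs_tox"]], -1.2, tolerance = 1e-8)
  expect_equal(est[["I(wqs_tox^2)"]], -0.1, tolerance = 1e-8)
  expect_equal(est[["age"]], 0.3, tolerance = 1e-8)
})

test_that("omitting a needed quadratic term costs AIC", {
  coh <- generate_cohort(n = 300, seed = 8)
  q <- as.matrix(coh$deciles$ranks)
  w_ess <- setNames(rep(1 / 8, 8), metal_names("essential"))
  w_tox <- setNames(rep(1 / 6, 6), metal_names("toxic"))
  s_ess <- compute_wqs_index(q[, names(w_ess)], w_ess)
  set.seed(9)
  y <- 100 - 0.6 * (s_ess - 4.5)^2 + rnorm(300, 0, 2)
  with_q <- validate_model(q, y, w_ess, w_tox,
                           quadratic = c(ess = TRUE, tox = FALSE))
  without_q <- validate_model(q, y, w_ess, w_tox,
                              quadratic = c(ess = FALSE, tox = FALSE))
  expect_lt(with_q$aic, without_q$aic)
})

test_that("rank-deficient validation designs name the offending column", {
  coh <- generate_cohort(n = 100, seed = 10)
  q <- as.matrix(coh$deciles$ranks)
  w_ess <- setNames(rep(1 / 8, 8), metal_names("essential"))
  w_tox <- setNames(rep(1 / 6, 6), metal_names("toxic"))
  covars <- data.frame(age = coh$data$age, age_copy = coh$data$age)
  expect_error(
    validate_model(q, coh$data$VCI, w_ess, w_tox, covars),
    class = "wqsmix_rank_deficient")
  expect_error(
    validate_model(q[1:10, ], coh$data$VCI[1:10], w_ess, w_tox, min_n = 20),
    "too small")
})

test_that("repeated holdout recovers a strong toxic signal", {
  coh <- generate_cohort(n = 500, truth = strong_toxic_truth(), seed = 11)
  fit <- repeated_holdout(coh$data, "VCI", config = reduced_config(),
                          seed = 12)
  terms <- tidy(fit)
  tox <- terms[terms$term == "wqs_tox", ]
  expect_lt(tox$conf.high, 0) # interval excludes zero
  expect_equal(tox$estimate, -1, tolerance = 0.5)
  wt <- tidy(fit, "weights")
  wt <- wt[wt$index == "toxic", ]
  expect_setequal(wt$metal[order(-wt$weight)][1:2], c("Cd", "Sb"))
  # simplex conservation after aggregation across holdouts
  expect_equal(sum(wt$weight), 1, tolerance = 1e-8)
  expect_true(all(wt$weight >= 0))
  # every holdout index value respects the decile bounds
  expect_true(all(fit$n_valid >= fit$config$min_validation_n))
})

test_that("repeated holdout is deterministic under a fixed master seed", {
  coh <- generate_cohort(n = 201, seed = 13)
  f1 <- repeated_holdout(coh$data, "PSI", config = tiny_config(), seed = 14)
  f2 <- repeated_holdout(coh$data, "PSI", config = tiny_config(), seed = 14)
  expect_identical(f1$terms, f2$terms)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$holdouts, f2$holdouts)
  f3 <- repeated_holdout(coh$data, "PSI", config = tiny_config(), seed = 15)
  expect_false(identical(f1$terms, f3$terms))
})

test_that("validation split sizes follow the 60/40 rule at n = 201", {
  coh <- generate_cohort(n = 201, seed = 16)
  fit <- repeated_holdout(coh$data, "VCI", config = tiny_config(), seed = 17)
  expect_true(all(fit$n_valid == 201 - floor(0.6 * 201)))
  expect_true(all(is.finite(fit$terms$estimate)))
})

test_that("AIC direction selection explores combinations and finds the sign", {
  coh <- generate_cohort(n = 500, truth = strong_toxic_truth(), seed = 18)
  cfg <- wqs_config(n_boot_select = 10, n_holdout_select = 5)
  sel <- select_direction(coh$data, "VCI", config = cfg, seed = 19)
  expect_equal(nrow(sel$aic_table), 4) # both indices auto: 2^2 combinations
  expect_equal(sel$directions[["tox"]], -1)
  cfg2 <- wqs_config(n_boot_select = 10, n_holdout_select = 5,
                     direction_ess = "negative")
  sel2 <- select_direction(coh$data, "VCI", config = cfg2, seed = 19)
  expect_equal(nrow(sel2$aic_table), 2)
})

test_that("significance is the percentile interval excluding zero", {
  fit <- structure(list(terms = tibble::tibble(
    term = c("a", "b", "c"),
    estimate = c(-0.23, -0.28, 0),
    conf.low = c(-0.38, -1.18, 0),
    conf.high = c(-0.03, 0.42, 0))), class = "wqs_fit")
  sig <- wqs_significance(fit)
  expect_equal(sig$significant, c(TRUE, FALSE, FALSE))
})

test_that("tidy and glance expose the fit in broom shape", {
  coh <- generate_cohort(n = 201, seed = 20)
  fit <- repeated_holdout(coh$data, "VCI", config = tiny_config(), seed = 21)
  td <- tidy(fit)
  expect_true(all(c("outcome", "term", "estimate", "conf.low", "conf.high",
                    "significant") %in% names(td)))
  expect_true(all(td$conf.low <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$outcome, "VCI")
  expect_equal(gl$n_holdout, 4L)
  expect_s3_class(autoplot(fit), "ggplot")
})
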