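test_that("copula reproduces target Spearman structure", {
  specs <- default_metal_specs()
  id <- diag(14); dimnames(id) <- list(specs$metal, specs$metal)
  x <- sample_exposures(specs, id, n = 50000, seed = 1)
  rho <- spearman_matrix(x)
  expect_lt(max(abs(rho[upper.tri(rho)])), 0.02)

  r <- id
  r["Cd", "Pb"] <- r["Pb", "Cd"] <- 0.5
  x2 <- sample_exposures(specs, r, n = 50000, seed = 2)
  rho2 <- spearman_matrix(x2)
  expect_equal(rho2["Cd", "Pb"], 0.5, tolerance = 0.03)
  off <- abs(rho2[upper.tri(rho2)])
  expect_lt(sort(off, decreasing = TRUE)[2], 0.03)  # everything else near 0
})

test_that("non-positive-semi-definite targets are rejected with a diagnostic", {
  specs <- default_metal_specs()
  bad <- diag(14); bad[1, 2] <- bad[2, 1] <- 0.7; bad[1, 3] <- bad[3, 1] <- 0.7
  bad[2, 3] <- bad[3, 2] <- -0.7
  expect_error(sample_exposures(specs, bad, n = 10),
               "positive semi-definite.*eigenvalue")
  asym <- diag(14); asym[1, 2] <- 0.2
  expect_error(sample_exposures(specs, asym, n = 10), "symmetric")
})

test_that("marginals converge to the GM and IQR targets", {
  specs <- default_metal_specs()
  x <- sample_exposures(specs, n = 50000, seed = 3)
  for (m in c("As", "Zn", "Mn")) {
    i <- match(m, specs$metal)
    expect_equal(exp(mean(log(x[[m]]))), specs$gm_target[i], tolerance = 0.03)
    expect_equal(unname(diff(quantile(x[[m]], c(0.25, 0.75), type = 7))),
                 specs$iqr_target[i], tolerance = 0.03)
  }
})

test_that("LOD substitution follows the rule arithmetic", {
  specs <- default_metal_specs()[default_metal_specs()$metal == "Cd", ]
  specs$lod <- 0.05
  # above LOD: unchanged
  x <- tibble::tibble(Cd = 10)
  expect_equal(censor_at_lod(x, specs, 1, rule = "zero")$Cd, 10)
  # forced substitution to zero
  specs$lod <- 0.04
  x <- tibble::tibble(Cd = 0.01)
  expect_equal(censor_at_lod(x, specs, 1, rule = "zero")$Cd, 0)
  # ug/L round trip: value 0.01 ug/g at creatinine 2 g/L is 0.02 ug/L < 0.04,
  # replaced by (0.04/2) ug/L = 0.02 ug/L, re-divided: 0.01 ug/g
  expect_equal(censor_at_lod(x, specs, 2, rule = "lod_over_2")$Cd, 0.01)
  expect_equal(censor_at_lod(x, specs, 2, rule = "lod_over_sqrt2")$Cd,
               (0.04 / sqrt(2)) / 2)
  expect_error(censor_at_lod(x, specs, 0, rule = "zero"), "creatinine")
})

test_that("raising the LOD never decreases the substituted fraction", {
  specs <- default_metal_specs()
  x <- sample_exposures(specs, n = 2000, seed = 4)
  creat <- simulate_creatinine(2000, seed = 5)
  frac_sub <- function(lod_mult) {
    sp <- specs; sp$lod <- sp$lod * lod_mult
    cen <- censor_at_lod(x, sp, creat, rule = "lod_over_2")
    colMeans(as.matrix(cen) != as.matrix(x))
  }
  f1 <- frac_sub(1); f5 <- frac_sub(5); f25 <- frac_sub(25)
  expect_true(all(f5 >= f1))
  expect_true(all(f25 >= f5))
})

test_that("null outcome process matches the instrument conventions", {
  coh <- generate_cohort(n = 20000, seed = 6)
  q <- coh$deciles$ranks
  covars <- coh$data[, covariate_names()]
  y_w <- generate_outcomes(q, covars, effect_truth(), scale = "wppsi", seed = 7)
  expect_equal(mean(y_w), 100, tolerance = 0.005)
  expect_equal(sd(y_w), 15, tolerance = 0.04)
  y_n <- generate_outcomes(q, covars,
                           effect_truth(intercept = 10, resid_sd = 3),
                           scale = "nepsy", seed = 8)
  expect_equal(mean(y_n), 10, tolerance = 0.005)
  expect_equal(sd(y_n), 3, tolerance = 0.04)
})

test_that("noiseless outcomes are an exact affine function of deciles", {
  coh <- generate_cohort(n = 100, seed = 9)
  tw <- c(0, 1, 0, 0, 0, 0) # one-hot on Cd
  truth <- effect_truth(weights_toxic = tw, beta1_tox = -1,
                        intercept = 50, resid_sd = 0)
  y <- generate_outcomes(coh$deciles$ranks, coh$data[, covariate_names()],
                         truth, seed = 1)
  expect_equal(y, 50 - coh$deciles$ranks$Cd, tolerance = 1e-12)
  # mismatched weight length is rejected
  expect_error(effect_truth(weights_toxic = c(0.5, 0.5)), "length 6")
})

test_that("cohort generation is deterministic and calibrated", {
  c1 <- generate_cohort(n = 201, seed = 1)
  c2 <- generate_cohort(n = 201, seed = 1)
  expect_identical(c1$data, c2$data)
  c3 <- generate_cohort(n = 201, seed = 2)
  expect_false(identical(c1$data, c3$data))
  expect_equal(nrow(generate_cohort(seed = 1)$data), 201)
  expect_error(generate_cohort(n = 10, seed = 1), "n")

  big <- simulate_covariates(20000, seed = 10)
  expect_equal(mean(big$age), 31.58, tolerance = 0.004)
  expect_equal(mean(big$smoking), 0.323, tolerance = 0.05)
  expect_equal(mean(big$child_sex), 0.468, tolerance = 0.05)
})

test_that("cohort and truth round-trip through their text formats", {
  coh <- generate_cohort(n = 50, truth = strong_toxic_truth(), seed = 11)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cohort.csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh$data), tolerance = 1e-12)
  truth2 <- read_truth(paste0(path, ".truth.yml"))
  expect_equal(truth2$weights_toxic, coh$truth$weights_toxic, tolerance = 1e-9)
  expect_equal(truth2$beta1_tox, coh$truth$beta1_tox)
})
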