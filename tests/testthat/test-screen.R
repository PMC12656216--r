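test_that("linear signals yield edf near 1, curvature inflates edf", {
  set.seed(1)
  x <- sample(0:9, 1000, TRUE)
  lin <- fit_gam_smooth(x, 2 * x + rnorm(1000, 0, 0.1))
  expect_true(lin$converged)
  expect_gte(lin$edf, 1.0)
  expect_lte(lin$edf, 1.3)

  x2 <- sample(0:9, 500, TRUE)
  quad <- fit_gam_smooth(x2, -(x2 - 4.5)^2 + rnorm(500))
  expect_gt(quad$edf, 1.5)
  expect_lt(quad$p_value, 0.05)
})

test_that("smooth-term test keeps its nominal size under the null", {
  set.seed(2)
  p <- vapply(1:120, function(i) {
    x <- sample(0:9, 300, TRUE)
    fit_gam_smooth(x, rnorm(300))$p_value
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.005)
  expect_lte(mean(p < 0.05), 0.11)
})

test_that("edf decreases with the smoothing parameter and hits the linear limit", {
  set.seed(3)
  x <- sample(0:9, 400, TRUE)
  y <- -(x - 4.5)^2 + rnorm(400)
  edfs <- vapply(c(1e-4, 1e-2, 1, 100, 1e6),
                 function(sp) fit_gam_smooth(x, y, sp = sp)$edf, numeric(1))
  expect_true(all(diff(edfs) <= 1e-6))
  # infinite-penalty limit reproduces the straight-line fit
  gam_inf <- fit_gam_smooth(x, y, sp = 1e14)$fit[[1]]
  expect_equal(unname(fitted(gam_inf)), unname(fitted(lm(y ~ x))),
               tolerance = 1e-6)
})

test_that("restricted cubic splines are linear beyond the boundary knots", {
  set.seed(4)
  second_diff <- function(v) diff(diff(v))
  for (n_knots in 3:5) {
    x <- runif(400, 0, 9)
    y <- -(x - 4.5)^2 + rnorm(400)
    rf <- fit_rcs(x, y, n_knots = n_knots)
    expect_length(rf$knots, n_knots)
    # evaluate through the basis well beyond the boundary knots
    rcs_eval <- function(grid) {
      X <- cbind(1, grid, rcs_basis(grid, rf$knots))
      drop(X %*% rf$coefficients[seq_len(ncol(X))])
    }
    below <- rcs_eval(seq(min(rf$knots) - 5, min(rf$knots), length.out = 30))
    above <- rcs_eval(seq(max(rf$knots), max(rf$knots) + 5, length.out = 30))
    expect_lt(max(abs(second_diff(below))), 1e-8)
    expect_lt(max(abs(second_diff(above))), 1e-8)
  }
})

test_that("the RCS non-linearity test discriminates curvature from lines", {
  set.seed(5)
  p_lin <- p_quad <- numeric(20)
  for (i in 1:20) {
    x <- sample(0:9, 500, TRUE)
    p_lin[i] <- fit_rcs(x, 1.5 * x + rnorm(500), n_knots = 4)$p_nonlinear
    p_quad[i] <- fit_rcs(x, -(x - 4.5)^2 + rnorm(500), n_knots = 4)$p_nonlinear
  }
  expect_gte(mean(p_lin > 0.05), 0.9)
  expect_equal(mean(p_quad < 0.05), 1)
})

test_that("heavily tied exposures degrade to an explicit knot error", {
  x <- c(rep(0, 395), 1:5)
  expect_error(fit_rcs(x, rnorm(400), n_knots = 4),
               class = "wqsmix_degenerate_knots")
  expect_error(fit_rcs(runif(100), rnorm(100), n_knots = 7), "3, 4 or 5")
})

test_that("run_screen covers the grid and derives the quadratic config", {
  truth <- effect_truth(beta2_ess = -0.25, resid_sd = 5)
  coh <- generate_cohort(n = 500, truth = truth, seed = 6)
  screen <- run_screen(coh$data, outcomes = c("VCI", "PSI"))
  expect_s3_class(screen, "screen_table")
  expect_equal(nrow(screen), 14 * 2)
  expect_true(all(screen$converged))
  expect_true(all(screen$p_value >= 0 & screen$p_value <= 1, na.rm = TRUE))
  # a strong quadratic essential-index effect flags essential metals
  expect_true(any(screen$nonlinear[screen$group == "essential"]))
  expect_true(all(quadratic_outcomes(screen) %in% c("VCI", "PSI")))
  expect_gte(length(quadratic_outcomes(screen)), 1)
  # flagged pairs carry an RCS confirmation p-value
  flagged <- screen$nonlinear
  expect_true(all(!is.na(screen$rcs_p[flagged])))
  expect_true(all(is.na(screen$rcs_p[!flagged])))
  # flag definition is a pure function of edf and p
  expect_equal(screen$nonlinear,
               screen$edf >= 1.5 & screen$p_value < 0.05)
})

test_that("null cohorts produce only alpha-level flags", {
  coh <- generate_cohort(n = 500, seed = 7)
  screen <- run_screen(coh$data, outcomes = c("VCI", "WMI", "FSIQ"))
  expect_lte(mean(screen$nonlinear), 0.15)
})
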