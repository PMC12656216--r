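# Shared fixtures for the suite; everything is generated in code.

# truth with a strong toxic-index signal: Cd 0.5, Sb 0.3, rest ~uniform,
# beta1_tox = -1 on the WPPSI scale, residual SD 5 so the weight ordering
# is identifiable at n = 500
strong_toxic_truth <- function(resid_sd = 5) {
  tw <- rep(0.05, 6)
  names(tw) <- metal_names("toxic")
  tw[c("Cd", "Sb")] <- c(0.5, 0.3)
  effect_truth(weights_toxic = tw / sum(tw), beta1_tox = -1,
               resid_sd = resid_sd)
}

# reduced-repetition configuration used by simulation-heavy checks
reduced_config <- function(...) {
  wqs_config(n_boot = 20, n_holdout = 20,
             direction_ess = "negative", direction_tox = "negative", ...)
}

# tiny configuration for orchestration/determinism checks
tiny_config <- function(...) {
  wqs_config(n_boot = 4, n_holdout = 4,
             direction_ess = "negative", direction_tox = "negative", ...)
}

# 2-metal training fixture with a known negative mixture effect
two_metal_problem <- function(seed, n = 120, resid_sd = 3) {
  set.seed(seed)
  q <- cbind(Cd = sample(0:9, n, TRUE), Sb = sample(0:9, n, TRUE))
  x <- cbind(age = rnorm(n))
  y <- 100 - 0.8 * (0.6 * q[, 1] + 0.4 * q[, 2]) + 0.3 * x[, 1] +
    rnorm(n, 0, resid_sd)
  list(q = q, x = x, y = y)
}

# independent profile-least-squares oracle over the 2-metal weight simplex:
# for each candidate w1, fit the index model by lm() with the negative sign
# constraint (boundary beta1 = 0 when violated) and return half the RSS
grid_oracle_2metal <- function(q, x, y, idx, grid = seq(0, 1, by = 0.001)) {
  rss0 <- sum(resid(lm(y[idx] ~ x[idx, 1]))^2)
  obj <- vapply(grid, function(w1) {
    s <- q[idx, 1] * w1 + q[idx, 2] * (1 - w1)
    f <- lm(y[idx] ~ s + x[idx, 1])
    rss <- if (coef(f)[["s"]] < 0) sum(resid(f)^2) else rss0
    0.5 * rss
  }, numeric(1))
  list(grid = grid, objective = obj,
       w_min = grid[which.min(obj)], obj_min = min(obj))
}
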