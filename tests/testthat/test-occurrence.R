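test_that("IRLS solves the intercept-only model in closed form", {
  y <- c(3L, 0L, 5L, 2L, 4L)
  E <- 7
  fit <- fit_poisson_fixed(matrix(1, 5, 1,
                                  dimnames = list(NULL, "(Intercept)")),
                           y, offset = rep(log(E), 5))
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), log(mean(y) / E), tolerance = 1e-10)
})

test_that("IRLS matches a brute-force likelihood grid on a 1-parameter toy", {
  set.seed(2)
  x <- runif(12, -1, 1)
  y <- rpois(12, exp(0.8 * x))
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  fit <- fit_poisson_fixed(X, y)
  grid <- seq(-3, 3, by = 1e-5)
  ll <- vapply(grid, function(b) sum(y * b * x - exp(b * x)), numeric(1))
  expect_equal(unname(fit$coef), grid[which.max(ll)], tolerance = 1e-4)
})

test_that("IRLS refuses rank-deficient designs and names the culprit", {
  X <- cbind("(Intercept)" = 1, a = 1:4, b = 2 * (1:4))
  expect_error(fit_poisson_fixed(X, c(1L, 2L, 1L, 3L)), "collinear.*b")
  expect_error(fit_poisson_fixed(X[, 1:2], c(1.5, 2, 1, 3)), "integer")
})

test_that("IRLS matches glm and its Wald intervals attain nominal coverage", {
  set.seed(77)
  n <- 260
  x <- rnorm(n)
  off <- log(runif(n, 5, 50))
  beta_true <- c(-2, 0.5)
  X <- cbind("(Intercept)" = 1, x = x)
  # cross-check a single fit against the standard GLM implementation
  y <- rpois(n, exp(X %*% beta_true + off))
  g <- stats::glm(y ~ x, family = poisson(), offset = off)
  fit <- fit_poisson_fixed(X, y, off)
  expect_equal(unname(fit$coef), unname(coef(g)), tolerance = 1e-8)
  # glm stops on a deviance criterion, ours on the score: the final
  # weights differ in the last IRLS step, so SEs agree only to ~1e-4
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)

  covered <- vapply(1:500, function(i) {
    y <- rpois(n, exp(X %*% beta_true + off))
    f <- fit_poisson_fixed(X, y, off)
    se <- sqrt(fit_poisson_fixed(X, y, off)$vcov["x", "x"])
    abs(f$coef["x"] - beta_true[2]) <= 1.96 * se
  }, logical(1))
  expect_equal(mean(covered), 0.95, tolerance = 0.04)
})

test_that("doubling exposures shifts only the intercept, by exactly -log 2", {
  study <- small_study(seed = 61)
  fit <- fit_fid_model(study$approaches)
  tol <- conditional_modes(fit)
  foc <- split_by_distance(study$focals)
  foc <- downsample_focals(foc, c("2018" = 28L, "2019" = 25L), seed = 2)
  cnt <- count_all_occurrences(foc)
  cnt5 <- cnt[cnt$buffer == "n5", ]
  des <- occurrence_design(cnt5, tol)
  f1 <- fit_poisson_fixed(des$X, des$y, des$offset)
  f2 <- fit_poisson_fixed(des$X, des$y, des$offset + log(2))
  expect_equal(unname(f2$coef["(Intercept)"]),
               unname(f1$coef["(Intercept)"]) - log(2), tolerance = 1e-9)
  expect_equal(f1$coef[-1], f2$coef[-1], tolerance = 1e-9)
})

test_that("the occurrence design is the uncentred three-way factorial", {
  study <- small_study(seed = 15)
  fit <- fit_fid_model(study$approaches)
  tol <- conditional_modes(fit)
  foc <- split_by_distance(study$focals)
  cnt <- count_all_occurrences(foc)
  des <- occurrence_design(cnt[cnt$buffer == "n1", ], tol)
  expect_equal(colnames(des$X),
               c("(Intercept)", "stratumclose", "tolerance", "year2019",
                 "stratumclose:tolerance", "stratumclose:year2019",
                 "tolerance:year2019", "stratumclose:tolerance:year2019"))
  # reference level is the far stratum and the first year
  expect_equal(nrow(des$X), 12 * 2 * 2)
  expect_equal(des$offset, log(des$data$exposure))
  # tolerance enters raw (uncentred): column equals the merged estimates
  expect_equal(des$X[, "tolerance"], des$data$tolerance,
               ignore_attr = TRUE)
})

test_that("bootstrap and GLMM backends produce consistent draws tables", {
  study <- small_study(seed = 33)
  fit <- fit_fid_model(study$approaches)
  tol <- conditional_modes(fit)
  foc <- split_by_distance(study$focals)
  foc <- downsample_focals(foc, c("2018" = 28L, "2019" = 25L), seed = 3)
  cnt <- count_all_occurrences(foc)
  cnt5 <- cnt[cnt$buffer == "n5", ]

  occ <- fit_occurrence_model(cnt5, tol, backend = "bootstrap",
                              n_draws = 300, seed = 5)
  expect_s3_class(occ, "occurrence_fit")
  expect_equal(sort(colnames(occ$draws)), sort(names(occ$coef)))
  expect_true(all(occ$summary$hdi_low <= occ$summary$estimate &
                    occ$summary$estimate <= occ$summary$hdi_high))
  expect_true(all(occ$summary$pd >= 50 & occ$summary$pd <= 100))
  expect_true(all(occ$summary$rope_fraction >= 0 &
                    occ$summary$rope_fraction <= 1))
  # bootstrap mean is consistent with the maximum-likelihood point estimate
  mc_se <- apply(occ$draws, 2, sd) / sqrt(nrow(occ$draws))
  expect_true(all(abs(colMeans(occ$draws) - occ$coef) <=
                    4 * mc_se + 0.02))
  # reproducible under the same seed
  occ2 <- fit_occurrence_model(cnt5, tol, backend = "bootstrap",
                               n_draws = 300, seed = 5)
  expect_identical(occ$draws, occ2$draws)

  skip_if_not_installed("glmmTMB")
  gl <- suppressWarnings(fit_occurrence_model(cnt5, tol, backend = "glmm",
                                              n_draws = 300, seed = 5))
  expect_equal(sort(colnames(gl$draws)), sort(colnames(occ$draws)))
  # fixed-effect point estimates of the two inference routes agree loosely
  expect_lt(max(abs(gl$coef - occ$coef[names(gl$coef)])), 0.5)
})

test_that("HDI matches its anchors and the sliding-window oracle", {
  expect_equal(hdi(rep(3.2, 50)), c(3.2, 3.2))
  expect_equal(hdi(1:100, 0.89), c(1, 89))
  expect_error(hdi(1:100, 1.2), "mass")

  set.seed(4)
  u <- runif(1e5)
  expect_equal(diff(hdi(u, 0.89)), 0.89, tolerance = 0.01)

  # exhaustive window oracle on irregular draws
  set.seed(9)
  x <- sort(rgamma(200, 2))
  k <- ceiling(0.89 * 200)
  widths <- vapply(1:(200 - k + 1), function(i) x[i + k - 1] - x[i],
                   numeric(1))
  i <- which.min(widths)
  expect_equal(hdi(x, 0.89), c(x[i], x[i + k - 1]))

  # HDI width is monotone in mass
  w <- vapply(c(0.5, 0.7, 0.89, 0.95), function(m) diff(hdi(x, m)),
              numeric(1))
  expect_true(all(diff(w) >= 0))
})

test_that("probability of direction counts dominant signs, zeros split", {
  expect_equal(pd(c(1, 2, 3)), 100)
  expect_equal(pd(c(-1, -2, 1, 2)), 50)
  expect_equal(pd(c(-1, 2, 3, 4)), 75)
  expect_equal(pd(c(0, 0, 1, 1)), 75)  # zeros split evenly
  # symmetry: pd(x) == pd(-x)
  set.seed(3)
  x <- rnorm(1000, 0.3)
  expect_equal(pd(x), pd(-x))
})

test_that("HDI of negated draws is the swapped negated interval", {
  set.seed(8)
  x <- rgamma(500, 3)
  h <- hdi(x)
  hn <- hdi(-x)
  expect_equal(hn, -rev(h))
})

test_that("ROPE fraction agrees with direct enumeration", {
  expect_equal(rope_fraction(rep(0, 20)), 1)
  expect_equal(rope_fraction(runif(50, 0.2, 0.9)), 0)
  set.seed(6)
  x <- rnorm(2000, 0.05, 0.2)
  h <- hdi(x, 0.89)
  inside <- x[x >= h[1] & x <= h[2]]
  expect_equal(rope_fraction(x),
               sum(inside >= -0.1 & inside <= 0.1) / length(inside))
  # full-posterior variant
  expect_equal(rope_fraction(x, within_hdi = FALSE),
               mean(x >= -0.1 & x <= 0.1))
})

test_that("Bayesian R2 hits its analytic anchors", {
  pred <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(bayes_r2(pred, c(0, 0))$mean, 1)
  v <- apply(pred, 1, var)
  expect_equal(bayes_r2(pred, v)$mean, 0.5)
  expect_error(bayes_r2(matrix(1, 2, 4), c(0, 0)), "zero total variance")
})
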