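test_that("binary covariate fits are logistic regressions with the stated terms", {
  dgp <- gf_dgp("survival_basic", n = 400)
  dat <- generate_dataset(dgp, seed = 3)
  tab <- gf_data(dat, "id", "t0", c("L1", "L2", "A"), "Y", basecovs = "L3")
  hist <- infer_history(dgp$config$covparams$covmodels, c("L1", "L2", "A"))
  aug <- add_history_columns(tab, hist)
  fitrows <- aug[aug$t0 >= 1, ]
  spec <- gf_cov_spec("L1", "binary", L1 ~ lag1_A + lag1_L1 + lag1_L2 + L3 + t0)
  cf <- fit_covariate_model(spec, fitrows)
  expect_length(cf$coefficients, 6L)       # intercept + 5 terms
  expect_identical(dim(cf$vcov), c(6L, 6L))
  expect_true(isSymmetric(cf$vcov))
  expect_true(all(eigen(cf$vcov, only.values = TRUE)$values > -1e-10))
  expect_identical(cf$n_fit, nrow(fitrows))
})

test_that("degenerate responses and unknown columns raise fitting errors", {
  df <- data.frame(id = 1:30, t0 = 1, Z = 0, X = rnorm(30), Y = 0)
  spec <- gf_cov_spec("Z", "binary", Z ~ X)
  expect_error(fit_covariate_model(spec, df), "degenerate response")
  spec2 <- gf_cov_spec("Z", "binary", Z ~ missing_col)
  expect_error(fit_covariate_model(spec2, df), "missing_col")
  expect_error(gf_cov_spec("Z", "exotic", Z ~ X), "covtype")
})

test_that("a noiseless linear covariate fits with zero residual scale and rmse", {
  df <- data.frame(id = 1:50, t0 = 1, X = rnorm(50))
  df$Z <- 2 + 3 * df$X
  cf <- fit_covariate_model(gf_cov_spec("Z", "normal", Z ~ X), df)
  expect_lt(cf$residual_scale, 1e-8)
  expect_lt(cf$rmse, 1e-8)
  expect_equal(unname(cf$coefficients), c(2, 3), tolerance = 1e-8)
  expect_equal(cf$observed_range, range(df$Z))
})

test_that("predicted probabilities equal empirical stratum means for a saturated fit", {
  # oracle: closed-form saturated logistic fit on a 2x2 table
  df <- data.frame(id = 1:100, t0 = 1,
                   X = rep(c(0, 1), each = 50),
                   Z = c(rep(c(0, 1), times = c(40, 10)),
                         rep(c(0, 1), times = c(15, 35))))
  cf <- fit_covariate_model(gf_cov_spec("Z", "binary", Z ~ X), df)
  p <- predict_probability(cf, data.frame(X = c(0, 1)))
  expect_equal(p, c(10 / 50, 35 / 50), tolerance = 1e-6)
  expect_error(predict_probability(cf, data.frame(W = 1)), "X")
})

test_that("rmse equals the direct residual computation and ignores row order", {
  set.seed(9)
  df <- data.frame(id = 1:200, t0 = 1, X = 1, Z = rnorm(200, sd = 2))
  cf <- fit_covariate_model(gf_cov_spec("Z", "normal", Z ~ 1), df)
  v <- mean((df$Z - mean(df$Z))^2)
  expect_equal(compute_rmse(cf), sqrt(v), tolerance = 1e-10)
  cf2 <- fit_covariate_model(gf_cov_spec("Z", "normal", Z ~ 1),
                             df[sample(nrow(df)), ])
  expect_equal(compute_rmse(cf2), compute_rmse(cf))
})

test_that("each family's sampler recovers the parameters it was fitted to", {
  set.seed(20)
  n <- 20000
  X <- rnorm(n)
  df <- data.frame(id = seq_len(n), t0 = 1, X = X)

  # binary
  df$Z <- rbinom(n, 1, plogis(-0.4 + 0.8 * X))
  cf <- fit_covariate_model(gf_cov_spec("Z", "binary", Z ~ X), df)
  draws <- draw_covariate(cf, df)
  cf2 <- fit_covariate_model(gf_cov_spec("Z2", "binary", Z2 ~ X),
                             transform(df, Z2 = draws))
  se <- sqrt(diag(cf2$vcov))
  expect_true(all(abs(cf2$coefficients - cf$coefficients) < 3 * se))

  # normal: coefficients and residual scale
  df$Z <- 1 + 2 * X + rnorm(n, sd = 0.7)
  cf <- fit_covariate_model(gf_cov_spec("Z", "normal", Z ~ X), df)
  draws <- draw_covariate(cf, df)
  cf2 <- fit_covariate_model(gf_cov_spec("Z2", "normal", Z2 ~ X),
                             transform(df, Z2 = draws))
  se <- sqrt(diag(cf2$vcov))
  expect_true(all(abs(cf2$coefficients - cf$coefficients) < 3 * se))
  expect_lt(abs(cf2$residual_scale - cf$residual_scale) / cf$residual_scale,
            0.05)
  expect_true(all(draws >= cf$observed_range[1] &
                    draws <= cf$observed_range[2]))

  # zero-inflated normal: draws respect the zero mass and nonzero range
  b <- rbinom(n, 1, plogis(0.3 + 0.5 * X))
  df$Z <- b * (1 + 0.5 * X + rnorm(n, sd = 0.8))
  cf <- fit_covariate_model(gf_cov_spec("Z", "zero_inflated_normal", Z ~ X),
                            df)
  draws <- draw_covariate(cf, df)
  expect_equal(mean(draws != 0), mean(b), tolerance = 0.02)
  nz <- draws[draws != 0]
  expect_true(all(nz >= cf$observed_range[1] & nz <= cf$observed_range[2]))

  # truncated normal draws stay on the stated side of the point
  df$Z <- pmax(0.5, 1 + X + rnorm(n))
  cf <- fit_covariate_model(gf_cov_spec("Z", "truncated_normal", Z ~ X,
                                        type_params = list(point = 0.5,
                                                           direction = "left")),
                            df)
  draws <- draw_covariate(cf, df)
  expect_true(all(draws >= 0.5))

  # bounded normal draws stay inside the observed range
  df$Z <- pmin(pmax(0.3 * X, -1), 1)
  cf <- fit_covariate_model(gf_cov_spec("Z", "bounded_normal", Z ~ X), df)
  draws <- draw_covariate(cf, df)
  expect_true(all(draws >= -1 & draws <= 1))
})

test_that("categorical fits use reference-level coding and probabilities sum to 1", {
  set.seed(30)
  n <- 5000
  X <- rnorm(n)
  e1 <- -0.3 + 0.6 * X; e2 <- -0.7 - 0.4 * X
  d <- 1 + exp(e1) + exp(e2)
  u <- runif(n)
  Z <- ifelse(u < 1 / d, "a", ifelse(u < (1 + exp(e1)) / d, "b", "c"))
  df <- data.frame(id = seq_len(n), t0 = 1, X = X, Z = Z)
  cf <- fit_covariate_model(gf_cov_spec("Z", "categorical", Z ~ X), df)
  expect_identical(cf$levels, c("a", "b", "c"))
  probs <- predict(cf$fit, newdata = df[1:50, ], type = "probs")
  expect_true(all(abs(rowSums(probs) - 1) < 1e-12))
  draws <- draw_covariate(cf, df)
  expect_true(all(draws %in% c("a", "b", "c")))
  expect_equal(mean(draws == "b"), mean(Z == "b"), tolerance = 0.03)
})

test_that("degenerate draw rules hold: p=0, absorbing state, collapsed ranges", {
  df <- data.frame(id = 1:60, t0 = 1, X = rnorm(60),
                   Z = rep(c(0, 1), 30))
  cf <- fit_covariate_model(gf_cov_spec("Z", "binary", Z ~ X), df)
  cf$fit$coefficients[] <- c(-50, 0)      # p ~ 0
  expect_true(all(draw_covariate(cf, df) == 0))

  df$lag1_Z <- rep(c(0, 1), each = 30)
  df$Z <- c(rep(c(0, 1), 15), rep(1, 30))
  cfa <- fit_covariate_model(gf_cov_spec("Z", "absorbing", Z ~ X), df)
  expect_identical(cfa$n_fit, 30L)        # fitted on lag1 == 0 rows only
  prev1 <- data.frame(X = rnorm(10), lag1_Z = 1)
  expect_true(all(draw_covariate(cfa, prev1) == 1))

  # constant covariate simulated as that constant
  dfc <- data.frame(id = 1:30, t0 = 1, X = rnorm(30), Z = 4)
  cfc <- fit_covariate_model(gf_cov_spec("Z", "bounded_normal", Z ~ X), dfc)
  expect_true(all(draw_covariate(cfc, dfc) == 4))
})

test_that("categorical_time is a deterministic recoding of the time index", {
  spec <- gf_cov_spec("period", "categorical_time",
                      type_params = list(breaks = c(2, 5)))
  cf <- fit_covariate_model(spec, data.frame(id = 1, t0 = 1))
  expect_identical(draw_covariate(cf, data.frame(x = 1:3), k = 0),
                   rep("0", 3))
  expect_identical(draw_covariate(cf, data.frame(x = 1:3), k = 3),
                   rep("1", 3))
  expect_identical(draw_covariate(cf, data.frame(x = 1:3), k = 6),
                   rep("2", 3))
})

test_that("outcome and competing-event models fit on the correct row sets", {
  dgp <- gf_dgp("survival_compevent", n = 500)
  dat <- generate_dataset(dgp, seed = 6)
  tab <- gf_data(dat, "id", "t0", c("L1", "L2", "A"), "Y",
                 basecovs = "L3", compevent_name = "D")
  os <- gf_outcome_spec("survival", "Y", compevent_name = "D")
  yfit <- fit_outcome_model(os, Y ~ A + L1 + L2 + L3 + t0, tab, "t0", 6L)
  expect_identical(yfit$family, "binomial_logit")
  expect_identical(yfit$n_fit, sum(!is.na(dat$Y)))
  expect_length(yfit$coefficients, 6L)

  dfit <- fit_compevent_model(D ~ A + L1 + L3, tab, "D")
  expect_identical(dfit$n_fit, sum(!is.na(dat$D)))
  expect_error(fit_compevent_model(D ~ A, tab[0, ], "D"), "usable rows")
  expect_error(fit_compevent_model(D2 ~ A, tab, "D2"), "not found")

  # end-of-follow-up: single cross-sectional fit at K, gaussian for continuous
  dgp2 <- gf_dgp("continuous_eof_categorical", n = 300)
  dat2 <- generate_dataset(dgp2, seed = 6)
  tab2 <- gf_data(dat2, "id", "t0", c("L1", "L2", "A"), "Y", basecovs = "L3")
  tab2 <- add_lagged(tab2, c("A", "L1", "L2"), 1)
  os2 <- gf_outcome_spec("continuous_eof", "Y")
  yfit2 <- fit_outcome_model(os2, Y ~ A + L2 + L3, tab2, "t0", 6L)
  expect_identical(yfit2$family, "gaussian_identity")
  expect_identical(yfit2$n_fit, 300L)

  expect_error(fit_outcome_model(os, Y ~ A, transform(tab, Y = 0), "t0", 6L),
               "degenerate")
})
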