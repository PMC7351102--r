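test_that("lagged, cumavg and lag_cumavg columns follow their definitions", {
  df <- data.frame(id = 1, t0 = 0:2, Z = c(5, 7, 9), A = c(1, 2, 3),
                   Y = 0)
  tab <- gf_data(df, "id", "t0", c("Z", "A"), "Y")
  out <- add_lagged(tab, "Z", 1)
  expect_equal(out$lag1_Z, c(0, 5, 7))
  out2 <- add_lagged(tab, "A", 2)
  expect_equal(out2$lag2_A[3], 1)

  df3 <- data.frame(id = 1, t0 = 0:1, Z = c(2, 4), Y = 0)
  tab3 <- gf_data(df3, "id", "t0", "Z", "Y")
  expect_equal(add_cumavg(tab3, "Z")$cumavg_Z, c(2, 3))
  expect_equal(add_lag_cumavg(tab3, "Z", 1)$lag_cumavg1_Z, c(0, 2))

  df4 <- data.frame(id = 1, t0 = 0:3, Z = 1:4, Y = 0)
  tab4 <- gf_data(df4, "id", "t0", "Z", "Y")
  expect_equal(add_cumavg(tab4, "Z")$cumavg_Z[4], 2.5)
  df5 <- data.frame(id = 1, t0 = 0:2, Z = c(1, 5, 3), Y = 0)
  tab5 <- gf_data(df5, "id", "t0", "Z", "Y")
  expect_equal(add_lag_cumavg(tab5, "Z", 1)$lag_cumavg1_Z[3], 3)
  expect_equal(add_lag_cumavg(tab5, "Z", 2)$lag_cumavg2_Z[2], 0)

  # constant covariate: cumavg is the constant at every k
  df6 <- data.frame(id = 1, t0 = 0:4, Z = 7, Y = 0)
  tab6 <- gf_data(df6, "id", "t0", "Z", "Y")
  expect_equal(add_cumavg(tab6, "Z")$cumavg_Z, rep(7, 5))

  expect_error(add_lagged(tab6, "nope", 1), "unknown variable")
})

test_that("lags read pre-baseline rows; cumulative averages start at k = 0", {
  df <- data.frame(id = 1, t0 = -1:2, Z = c(4, 10, 20, 30), Y = 0)
  tab <- gf_data(df, "id", "t0", "Z", "Y")
  out <- add_lagged(tab, "Z", 1)
  # oracle: naive shift including the pre-baseline row
  expect_equal(out$lag1_Z, c(0, 4, 10, 20))
  expect_equal(out$lag1_Z[out$t0 == 0], 4)
  ca <- add_cumavg(tab, "Z")$cumavg_Z
  expect_equal(ca[tab$t0 >= 0], naive_cumavg(tab$Z, tab$t0)[tab$t0 >= 0])
  expect_equal(ca[tab$t0 == 0], 10)  # pre-baseline value excluded
})

test_that("incremental history state reproduces the batch columns exactly", {
  set.seed(71)
  for (rep in 1:20) {
    n_t <- sample(2:6, 1)
    r <- sample(1:2, 1)
    z <- round(rnorm(n_t), 3)
    w <- rbinom(n_t, 1, 0.5)
    df <- data.frame(id = 1, t0 = seq_len(n_t) - 1, Z = z, W = w, Y = 0)
    tab <- gf_data(df, "id", "t0", c("Z", "W"), "Y")
    batch <- add_lag_cumavg(add_cumavg(add_lagged(tab, c("Z", "W"), r),
                                       "Z"), "Z", r)
    hist <- list(lag = stats::setNames(c(r, r), c("Z", "W")),
                 lagavg = stats::setNames(r, "Z"), cumavg = "Z")
    state <- hs_init(1L, hist)
    for (k in seq_len(n_t) - 1) {
      feats <- hs_lag_features(state)
      for (i in seq_len(r)) {
        expect_equal(feats[[paste0("lag", i, "_Z")]],
                     batch[[paste0("lag", i, "_Z")]][k + 1])
        expect_equal(feats[[paste0("lag", i, "_W")]],
                     batch[[paste0("lag", i, "_W")]][k + 1])
        expect_equal(feats[[paste0("lag_cumavg", i, "_Z")]],
                     batch[[paste0("lag_cumavg", i, "_Z")]][k + 1])
      }
      cur <- list(Z = z[k + 1], W = w[k + 1])
      expect_equal(hs_cumavg_current(state, "Z", cur$Z),
                   batch$cumavg_Z[k + 1])
      state <- hs_push(state, cur)
    }
  }
})

test_that("incremental state seeded from pre-baseline rows matches the batch result", {
  df <- data.frame(id = 1, t0 = -2:2, Z = c(1, 2, 3, 4, 5), Y = 0)
  tab <- gf_data(df, "id", "t0", "Z", "Y")
  batch <- add_lag_cumavg(add_lagged(tab, "Z", 2), "Z", 1)
  hist <- list(lag = c(Z = 2L), lagavg = c(Z = 1L), cumavg = character(0))
  state <- hs_init(1L, hist)
  for (pre in c(1, 2)) state <- hs_push(state, list(Z = pre),
                                        update_cumavg = FALSE)
  for (k in 0:2) {
    feats <- hs_lag_features(state)
    row <- which(tab$t0 == k)
    expect_equal(feats$lag1_Z, batch$lag1_Z[row])
    expect_equal(feats$lag2_Z, batch$lag2_Z[row])
    expect_equal(feats$lag_cumavg1_Z, batch$lag_cumavg1_Z[row])
    state <- hs_push(state, list(Z = tab$Z[row]))
  }
})

test_that("history columns never use information from later times", {
  set.seed(5)
  df <- data.frame(id = rep(1:3, each = 5), t0 = rep(0:4, 3),
                   Z = rnorm(15), Y = 0)
  tab <- gf_data(df, "id", "t0", "Z", "Y")
  full <- add_lag_cumavg(add_cumavg(add_lagged(tab, "Z", 2), "Z"), "Z", 1)
  for (cut in 1:4) {
    trunc <- gf_data(df[df$t0 <= cut, ], "id", "t0", "Z", "Y")
    part <- add_lag_cumavg(add_cumavg(add_lagged(trunc, "Z", 2), "Z"),
                           "Z", 1)
    keep <- full[full$t0 <= cut, names(part)]
    expect_equal(as.data.frame(part), as.data.frame(keep),
                 ignore_attr = TRUE)
  }
})

test_that("history requirements are inferred from model formulas", {
  h <- infer_history(list(Y ~ lag1_A + lag2_L + cumavg_L + lag_cumavg3_L,
                          L ~ lag1_L), covnames = c("A", "L"))
  expect_identical(h$lag[["A"]], 1L)
  expect_identical(h$lag[["L"]], 2L)
  expect_identical(h$lagavg[["L"]], 3L)
  expect_identical(h$cumavg, "L")
  # names that merely resemble the scheme but are not covariates are ignored
  h2 <- infer_history(list(Y ~ lag1_X), covnames = c("A", "L"))
  expect_length(h2$lag, 0)
})
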