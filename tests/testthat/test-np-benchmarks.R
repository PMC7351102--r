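test_that("without censoring the NP risk equals the fraction failed by k", {
  dgp <- gf_dgp("survival_basic", n = 400)
  dat <- generate_dataset(dgp, seed = 21)
  tab <- gf_data(dat, "id", "t0", c("L1", "L2", "A"), "Y", basecovs = "L3")
  npr <- np_risk(tab, surv_ospec())
  # oracle: direct counting of first-event times per subject
  ev <- tapply(seq_len(nrow(dat)), dat$id, function(ix) {
    rows <- dat[ix, ]
    hit <- which(!is.na(rows$Y) & rows$Y == 1)
    if (length(hit)) rows$t0[hit[1]] else NA
  })
  frac <- vapply(0:6, function(k) mean(!is.na(ev) & ev <= k), numeric(1))
  expect_equal(npr$risk, frac, tolerance = 1e-12)
  expect_true(all(diff(npr$risk) >= 0))
  expect_true(all(diff(npr$n_risk) <= 0))
})

test_that("the product-limit NP risk agrees with survfit under censoring", {
  dgp <- gf_dgp("survival_basic", n = 500, censor_prob = 0.08)
  dat <- generate_dataset(dgp, seed = 22)
  tab <- gf_data(dat, "id", "t0", c("L1", "L2", "A"), "Y", basecovs = "L3")
  npr <- np_risk(tab, surv_ospec())
  # oracle: Kaplan-Meier on (last time, event status) per subject
  per <- do.call(rbind, lapply(split(dat, dat$id), function(rows) {
    last <- rows[nrow(rows), ]
    data.frame(time = last$t0,
               status = as.integer(!is.na(last$Y) && last$Y == 1))
  }))
  km <- survival::survfit(survival::Surv(time, status) ~ 1, data = per)
  km_risk <- 1 - summary(km, times = 0:6, extend = TRUE)$surv
  expect_equal(npr$risk, km_risk, tolerance = 1e-10)
})

test_that("with modelled competing events the Aalen-Johansen form is used", {
  df <- data.frame(id = rep(1:4, times = c(1, 2, 2, 2)),
                   t0 = c(0, 0, 1, 0, 1, 0, 1),
                   L = 0, A = 0,
                   D = c(0, 0, 1, 0, 0, 0, 0),
                   Y = c(1, 0, NA, 0, 1, 0, 0))
  tab <- gf_data(df, "id", "t0", c("L", "A"), "Y", compevent_name = "D")
  npr <- np_risk(tab, surv_ospec(compevent = "D"))
  # by hand: h0 = 1/4; at t=1 three at risk, hD = 1/3, h = 1/3
  # R(0) = 1/4 ; R(1) = 1/4 + (1 - 1/4) * 1/3
  expect_equal(npr$risk, c(1 / 4, 1 / 4 + 3 / 4 * 1 / 3), tolerance = 1e-12)
  expect_identical(npr$compevents, c(0L, 1L))
})

test_that("risk set exhaustion yields missing risks with a warning", {
  df <- data.frame(id = 1:2, t0 = 0, L = 0, A = 0, Y = c(1, 1))
  tab <- gf_data(df, "id", "t0", c("L", "A"), "Y")
  expect_equal(np_risk(tab, surv_ospec(), 1)$risk, 1)  # all fail at once
  # defensive path: a (malformed) table with no records at an intermediate
  # time reports missing risks from there on
  df2 <- data.frame(id = c(1, 2, 2), t0 = c(0, 0, 2), L = 0, A = 0,
                    Y = c(1, 0, 0))
  tab2 <- gf_data(df2, "id", "t0", c("L", "A"), "Y")
  expect_warning(npr <- np_risk(tab2, surv_ospec(), 3), "at risk")
  expect_true(all(is.na(npr$risk[2:3])))
  expect_equal(npr$risk[1], 0.5)
})

test_that("NP covariate means are per-time averages among subjects at risk", {
  tab <- make_small_table()
  m <- np_covariate_means(tab)
  expect_equal(m$L, c(mean(c(0, 1, 0)), mean(c(1, 0, 0)), mean(c(1, 1))))
  # constant covariate: mean is that constant at every k
  dfc <- data.frame(id = rep(1:2, each = 3), t0 = rep(0:2, 2), Z = 5,
                    A = 0, Y = 0)
  tabc <- gf_data(dfc, "id", "t0", c("Z", "A"), "Y")
  expect_equal(np_covariate_means(tabc)$Z, rep(5, 3))
  # single subject: means equal that subject's trajectory
  df1 <- data.frame(id = 1, t0 = 0:2, Z = c(3, 1, 4), A = 0, Y = 0)
  tab1 <- gf_data(df1, "id", "t0", c("Z", "A"), "Y")
  expect_equal(np_covariate_means(tab1)$Z, c(3, 1, 4))
  # permutation invariance
  perm <- dfc[sample(nrow(dfc)), ]
  tabp <- gf_data(perm, "id", "t0", c("Z", "A"), "Y")
  expect_equal(np_covariate_means(tabp), np_covariate_means(tabc))
  # categorical expansion to per-level proportions
  dfk <- data.frame(id = rep(1:2, each = 2), t0 = rep(0:1, 2),
                    Z = c("a", "b", "a", "a"), A = 0, Y = 0)
  tabk <- gf_data(dfk, "id", "t0", c("Z", "A"), "Y")
  mk <- np_covariate_means(tabk, categorical = "Z")
  expect_equal(mk[["Z==a"]], c(1, 0.5))
  expect_equal(mk[["Z==b"]], c(0, 0.5))
})

test_that("NP end-of-follow-up mean uses uncensored final rows only", {
  dgp <- gf_dgp("binary_eof", n = 200)
  dat <- generate_dataset(dgp, seed = 23)
  tab <- gf_data(dat, "id_num", "time", c("cov1", "cov2", "treat"),
                 "outcome", basecovs = "cov3")
  os <- gf_outcome_spec("binary_eof", "outcome")
  expect_equal(np_eof_mean(tab, os),
               mean(dat$outcome[dat$time == 6], na.rm = TRUE))
  # all outcomes identical
  dat2 <- dat; dat2$outcome[dat2$time == 6] <- 0.7
  tab2 <- gf_data(dat2, "id_num", "time", c("cov1", "cov2", "treat"),
                  "outcome", basecovs = "cov3")
  expect_equal(np_eof_mean(tab2, os), 0.7)
  dat3 <- dat; dat3$outcome <- NA
  tab3 <- gf_data(dat3, "id_num", "time", c("cov1", "cov2", "treat"),
                  "outcome", basecovs = "cov3")
  expect_error(np_eof_mean(tab3, os), "uncensored")
  expect_error(np_eof_mean(tab, surv_ospec()), "end-of-follow-up")
})
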