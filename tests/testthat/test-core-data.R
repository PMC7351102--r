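test_that("load_table reads CSVs, types the time index and preserves missing outcomes", {
  dgp <- gf_dgp("survival_binary_small", n = 40)
  dat <- generate_dataset(dgp, seed = 4)
  dat$Y[nrow(dat)] <- NA   # censored-style blank
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(dat, path, row.names = FALSE, na = "")
  tab <- load_table(path, id = "id", time_name = "t0",
                    covnames = c("L1", "A"), outcome_name = "Y")
  expect_s3_class(tab, "gf_data")
  expect_identical(attr(tab, "n"), 40L)
  expect_identical(attr(tab, "K"), 2L)
  expect_identical(nrow(tab), nrow(dat))
  expect_true(is.na(tab$Y[nrow(tab)]))          # blank loaded as missing
  expect_type(tab$t0, "integer")

  # round-trip: write then re-load reproduces the table
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(tab), path2, row.names = FALSE, na = "")
  tab2 <- load_table(path2, id = "id", time_name = "t0",
                     covnames = c("L1", "A"), outcome_name = "Y")
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
})

test_that("load_table and gf_data reject malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,t0,L,A,Y", path)   # header only, no rows
  expect_error(load_table(path, "id", "t0", c("L", "A"), "Y"), "no rows")
  expect_error(load_table(tempfile(), "id", "t0", c("L", "A"), "Y"),
               "not found")
  df <- data.frame(id = 1, t0 = 0, L = 1, Y = 0)
  expect_error(gf_data(df, "id", "t0", c("L", "A"), "Y"), "A")
  df$t0 <- 0.5
  expect_error(gf_data(df, "id", "t0", "L", "Y"), "integer")
})

test_that("validation passes clean tables and enumerates coding violations", {
  tab <- make_small_table()
  rep0 <- validate_gf_data(tab, surv_ospec())
  expect_true(rep0$pass)
  expect_identical(nrow(rep0$violations), 0L)

  # generator output is always clean, across outcome types
  for (nm in c("survival_basic", "survival_compevent", "binary_eof")) {
    dgp <- gf_dgp(nm, n = 120)
    dat <- generate_dataset(dgp, seed = 8)
    cfg <- dgp$config
    tab_g <- gf_data(dat, cfg$id, cfg$time_name, cfg$covnames,
                     cfg$outcome_name, basecovs = cfg$basecovs,
                     compevent_name = cfg$compevent_name)
    os <- gf_outcome_spec(dgp$outcome_type, cfg$outcome_name,
                          compevent_name = cfg$compevent_name)
    expect_true(validate_gf_data(tab_g, os)$pass)
  }

  # gap in the time index
  df <- data.frame(id = 1, t0 = c(0, 2, 3), L = 0, A = 0, W = 1,
                   Y = c(0, 0, 0))
  bad <- gf_data(df, "id", "t0", c("L", "A"), "Y", basecovs = "W")
  v <- validate_gf_data(bad, surv_ospec())
  expect_false(v$pass)
  expect_true("time_gap" %in% v$violations$rule)

  # records after the event row
  df2 <- data.frame(id = 1, t0 = 0:3, L = 0, A = 0, W = 1,
                    Y = c(0, 0, 1, 0))
  v2 <- validate_gf_data(gf_data(df2, "id", "t0", c("L", "A"), "Y",
                                 basecovs = "W"), surv_ospec())
  expect_true("records_after_event" %in% v2$violations$rule)

  # baseline covariate varying within subject
  df3 <- data.frame(id = 1, t0 = 0:1, L = 0, A = 0, W = c(1, 2),
                    Y = c(0, 0))
  v3 <- validate_gf_data(gf_data(df3, "id", "t0", c("L", "A"), "Y",
                                 basecovs = "W"), surv_ospec())
  expect_true("baseline_constant" %in% v3$violations$rule)

  # competing-event row must carry a missing outcome and be last
  df4 <- data.frame(id = 1, t0 = 0:1, L = 0, A = 0, W = 1,
                    D = c(0, 1), Y = c(0, 0))
  tab4 <- gf_data(df4, "id", "t0", c("L", "A"), "Y", basecovs = "W",
                  compevent_name = "D")
  v4 <- validate_gf_data(tab4, surv_ospec(compevent = "D"))
  expect_true("compevent_outcome_na" %in% v4$violations$rule)
})

test_that("outcome specification enforces competing-event rules", {
  expect_error(gf_outcome_spec("binary_eof", "Y", compevent_name = "D"),
               "compevent")
  expect_error(gf_outcome_spec("survival", "Y", compevent_name = "D",
                               treat_compevent_as_censoring = TRUE),
               "compevent")
  os <- gf_outcome_spec("survival", "Y", compevent_name = "D")
  expect_identical(os$compevent_name, "D")
})

test_that("resolve_horizon defaults to K+1 and validates overrides", {
  tab <- make_small_table()       # K = 2
  expect_identical(resolve_horizon(tab), 3L)
  expect_identical(resolve_horizon(tab, 3), 3L)
  expect_identical(resolve_horizon(tab, 2), 2L)
  expect_error(resolve_horizon(tab, 4), "time_points")
  expect_error(resolve_horizon(tab, 0), "time_points")
})

test_that("per-subject row counts equal the first event/censoring interval + 1", {
  dgp <- gf_dgp("survival_basic", n = 200, censor_prob = 0.05)
  dat <- generate_dataset(dgp, seed = 10)
  counts <- table(dat$id)
  for (sid in names(counts)) {
    rows <- dat[dat$id == sid, ]
    last <- rows[nrow(rows), ]
    expect_identical(unname(counts[[sid]]), last$t0 + 1L)
    if (nrow(rows) > 1L) {
      expect_true(all(rows$Y[-nrow(rows)] == 0))   # event only on last row
    }
  }
})
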