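#' Ratio and difference contrasts against a reference intervention
#'
#' @param estimates numeric vector (one estimate per intervention) or matrix
#'   (interventions in rows, time points in columns).
#' @param ref 0-based index of the reference intervention.
#' @return list with elements `ratio` and `difference`, shaped like
#'   `estimates`. The reference entries are exactly 1 and 0. If a reference
#'   estimate is 0, the corresponding ratios are reported as missing with a
#'   warning; differences are still computed.
#' @export
gf_contrasts <- function(estimates, ref = 0L) {
  vec <- is.vector(estimates)
  if (vec) estimates <- matrix(estimates, ncol = 1L)
  refrow <- estimates[ref + 1L, ]
  if (any(refrow == 0)) {
    warning("reference estimate is 0 at some time points; ",
            "ratios reported as missing", call. = FALSE)
  }
  denom <- ifelse(refrow == 0, NA_real_, refrow)
  ratio <- sweep(estimates, 2L, denom, "/")
  difference <- sweep(estimates, 2L, refrow, "-")
  ratio[ref + 1L, ] <- 1
  difference[ref + 1L, ] <- 0
  if (vec) {
    ratio <- as.vector(ratio); difference <- as.vector(difference)
  }
  list(ratio = ratio, difference = difference)
}

## Assemble gf_cov_spec objects from the parallel covnames/covtypes/covparams
## arguments.
.build_cov_specs <- function(covnames, covtypes, covparams) {
  if (length(covtypes) != length(covnames)) {
    stop("covnames and covtypes must have the same length", call. = FALSE)
  }
  covmodels <- covparams$covmodels
  if (!is.null(covmodels) && length(covmodels) != length(covnames)) {
    stop("covparams$covmodels must have the same length as covnames",
         call. = FALSE)
  }
  specs <- vector("list", length(covnames))
  for (j in seq_along(covnames)) {
    tp <- list()
    if (!is.null(covparams$point)) tp$point <- covparams$point[[j]]
    if (!is.null(covparams$direction)) tp$direction <- covparams$direction[[j]]
    if (!is.null(covparams$breaks)) tp$breaks <- covparams$breaks[[j]]
    f <- if (!is.null(covmodels)) covmodels[[j]] else NULL
    if (inherits(f, "formula") || is.null(f)) {
      specs[[j]] <- gf_cov_spec(covnames[j], covtypes[j], f,
                                type_params = tp[!vapply(tp, function(z) {
                                  is.null(z) || all(is.na(z))
                                }, logical(1))])
    } else {
      stop("covparams$covmodels must contain formulas", call. = FALSE)
    }
  }
  names(specs) <- covnames
  specs
}

## One full parametric g-formula pass: history columns, model fits, and
## Monte Carlo simulation under every intervention. Shared by the point
## estimate and each bootstrap replicate.
.gf_engine <- function(table, ospec, covspecs, ymodel, compevent_model,
                       int_set, time_points, s, hist, keep_cohorts = FALSE) {
  time_name <- attr(table, "time_name")
  basecovs <- attr(table, "basecovs")
  K <- attr(table, "K")
  categorical <- names(covspecs)[vapply(covspecs, function(sp) {
    sp$covtype %in% c("categorical", "categorical_time")
  }, logical(1))]
  for (v in categorical) {
    if (covspecs[[v]]$covtype == "categorical_time") {
      table[[v]] <- as.character(findInterval(table[[time_name]],
                                              covspecs[[v]]$type_params$breaks))
    } else {
      table[[v]] <- as.character(table[[v]])
    }
  }
  obs_hist <- add_history_columns(table, hist)
  fit_rows_cov <- obs_hist[obs_hist[[time_name]] >= 1L, , drop = FALSE]
  covfits <- lapply(covspecs, fit_covariate_model, fitdata = fit_rows_cov)
  fit_rows_y <- obs_hist[obs_hist[[time_name]] >= 0L, , drop = FALSE]
  yfit <- fit_outcome_model(ospec, ymodel, fit_rows_y, time_name, K)
  dfit <- NULL
  if (!is.null(compevent_model)) {
    dfit <- fit_compevent_model(compevent_model, fit_rows_y,
                                ospec$compevent_name)
  }

  baseline <- sample_baseline(table, s)
  sim_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  cohorts <- vector("list", length(int_set))
  for (j in seq_along(int_set)) {
    set.seed(sim_seed)
    cohorts[[j]] <- simulate_cohort(covfits, yfit, dfit, ospec, int_set[[j]],
                                    baseline, time_points, time_name,
                                    basecovs, hist)
  }
  est <- if (ospec$outcome_type == "survival") {
    do.call(rbind, lapply(cohorts, estimate_intervention, ospec = ospec))
  } else {
    matrix(vapply(cohorts, estimate_intervention, numeric(1), ospec = ospec),
           ncol = 1L)
  }
  ctr <- gf_contrasts(est, attr(int_set, "ref_int"))
  list(est = est, ratio = ctr$ratio, difference = ctr$difference,
       covfits = covfits, yfit = yfit, dfit = dfit,
       cohorts = if (keep_cohorts) cohorts,
       categorical = categorical)
}

## Resample whole subjects with replacement, assigning fresh ids.
.resample_subjects <- function(table) {
  idc <- attr(table, "id")
  groups <- .subject_rows(table)
  pick <- sample.int(length(groups), length(groups), replace = TRUE)
  rows <- unlist(groups[pick], use.names = FALSE)
  new <- as.data.frame(table)[rows, , drop = FALSE]
  new[[idc]] <- rep(seq_along(pick), lengths(groups[pick]))
  gf_data(new, id = idc, time_name = attr(table, "time_name"),
          covnames = attr(table, "covnames"),
          outcome_name = attr(table, "outcome_name"),
          basecovs = attr(table, "basecovs"),
          compevent_name = attr(table, "compevent_name"))
}

#' Estimate effects of sustained treatment strategies via the parametric
#' g-formula
#'
#' Implements the two-step parametric g-formula: (1) fit parametric models
#' for the conditional distribution of each time-varying covariate given
#' history, for the discrete-time outcome hazard (survival outcomes) or the
#' end-of-follow-up outcome mean, and optionally for the competing-event
#' hazard; (2) standardise over the covariate distribution under each
#' user-specified intervention by Monte Carlo simulation, starting each
#' simulated history from the observed baseline distribution and replacing
#' simulated treatment values with the values the strategy assigns. Risks
#' are accumulated from the predicted hazards along each simulated history.
#'
#' Confidence intervals use the nonparametric bootstrap: whole subjects are
#' resampled with replacement, all models are refitted and the simulation is
#' rerun per replicate; standard errors are replicate standard deviations
#' and intervals are percentile intervals.
#'
#' @param obs_data long-format person-time data.frame (or a [gf_data]).
#' @param id,time_name,outcome_name,basecovs,compevent_name column roles, as
#'   in [gf_data()].
#' @param outcome_type `"survival"`, `"continuous_eof"` or `"binary_eof"`.
#' @param covnames,covtypes time-varying covariate names and families (see
#'   [gf_cov_spec()]), in factorisation order.
#' @param covparams list with `covmodels` (one formula per covariate) and
#'   optional per-covariate family parameters `point`, `direction`,
#'   `breaks`.
#' @param ymodel outcome model formula.
#' @param compevent_model optional competing-event hazard formula; requires
#'   `compevent_name`. Omit both to treat competing events as censoring
#'   events.
#' @param intvars,interventions,int_descript,int_times,ref_int intervention
#'   set, as in [build_intervention_set()].
#' @param time_points follow-up horizon `k*` (survival outcomes only;
#'   defaults to `K + 1`).
#' @param nsimul Monte Carlo sample size `s`; defaults to the baseline
#'   sample size `n`.
#' @param nsamples number of bootstrap replicates (0 = point estimates
#'   only).
#' @param parallel logical; distribute bootstrap replicates over `ncores`
#'   workers. Results are invariant to the worker count.
#' @param ncores number of bootstrap workers.
#' @param seed integer seed controlling all randomness of the run.
#' @param sim_data logical; keep the simulated histories (retrievable with
#'   [sim_data()]).
#' @return An object of class `gformula` (and
#'   `gformula_survival`, `gformula_continuous_eof` or
#'   `gformula_binary_eof`), with `print`, `summary`, `coef`, `vcov` and
#'   `plot` methods. Main elements: `result` (per-intervention, per-time
#'   estimates, nonparametric benchmarks, contrasts and bootstrap
#'   SEs/intervals), `coefs`, `stderrs`, `vcovs`, `rmses`, `fits`,
#'   `np_cov_means` and simulated natural-course covariate means
#'   (`sim_cov_means`) for diagnostics.
#' @examples
#' dgp <- gf_dgp("survival_binary_small", n = 300)
#' dat <- generate_dataset(dgp, seed = 1)
#' fit <- gformula(dat,
#'   id = "id", time_name = "t0", outcome_name = "Y",
#'   outcome_type = "survival",
#'   covnames = c("L1", "A"), covtypes = c("binary", "binary"),
#'   covparams = list(covmodels = c(L1 ~ lag1_A + lag1_L1,
#'                                  A ~ L1 + lag1_A)),
#'   ymodel = Y ~ A + L1 + lag1_A,
#'   intvars = list("A", "A"),
#'   interventions = list(list(static(0)), list(static(1))),
#'   int_descript = c("Never treat", "Always treat"),
#'   seed = 1)
#' fit
#' @export
gformula <- function(obs_data, id, time_name, outcome_name,
                     outcome_type = c("survival", "continuous_eof",
                                      "binary_eof"),
                     covnames, covtypes, covparams, ymodel,
                     compevent_name = NULL, compevent_model = NULL,
                     intvars = NULL, interventions = NULL,
                     int_descript = NULL, int_times = NULL, ref_int = 0L,
                     basecovs = NULL, time_points = NULL,
                     nsimul = NULL, nsamples = 0L, parallel = FALSE,
                     ncores = 1L, seed = NULL, sim_data = FALSE) {
  cl <- match.call()
  outcome_type <- match.arg(outcome_type)
  if (!is.null(compevent_model) && is.null(compevent_name)) {
    stop("compevent_model given but no compevent_name column specified",
         call. = FALSE)
  }
  if (!is.null(compevent_name) && is.null(compevent_model)) {
    stop("compevent_name given without compevent_model; to treat competing ",
         "events as censoring events, code them as censoring and omit both",
         call. = FALSE)
  }
  table <- if (inherits(obs_data, "gf_data")) {
    obs_data
  } else {
    gf_data(obs_data, id = id, time_name = time_name, covnames = covnames,
            outcome_name = outcome_name, basecovs = basecovs,
            compevent_name = compevent_name)
  }
  ospec <- gf_outcome_spec(outcome_type, outcome_name,
                           compevent_name = compevent_name,
                           treat_compevent_as_censoring = FALSE,
                           time_points = time_points)
  val <- validate_gf_data(table, ospec)
  if (!val$pass) {
    stop("input data violate the longitudinal coding rules (",
         nrow(val$violations), " violation(s)); first: ",
         val$violations$message[1L], " [id ", val$violations$id[1L],
         ", time ", val$violations$time[1L], "]", call. = FALSE)
  }
  K <- attr(table, "K")
  tpoints <- if (outcome_type == "survival") {
    resolve_horizon(table, time_points)
  } else {
    K + 1L
  }

  covspecs <- .build_cov_specs(covnames, covtypes, covparams)
  formulas <- c(Filter(Negate(is.null), lapply(covspecs, `[[`, "formula")),
                list(ymodel), if (!is.null(compevent_model)) {
                  list(compevent_model)
                })
  hist <- infer_history(formulas, covnames)
  for (v in covnames) {
    if (covspecs[[v]]$covtype == "absorbing") {
      hist$lag[v] <- max(1L, hist$lag[v], 0L, na.rm = TRUE)
    }
    if (covspecs[[v]]$covtype == "categorical" &&
        !is.null(hist$lag[v]) && !is.na(hist$lag[v]) &&
        !"0" %in% as.character(unique(table[[v]]))) {
      warning("categorical covariate '", v, "' has no level '0'; lag ",
              "padding introduces a level '0' on early rows", call. = FALSE)
    }
  }

  int_set <- build_intervention_set(intvars, interventions, int_descript,
                                    int_times, tpoints, covnames, ref_int)
  n <- attr(table, "n")
  s <- if (is.null(nsimul)) n else as.integer(nsimul)

  if (!is.null(seed)) set.seed(seed)
  main <- .gf_engine(table, ospec, covspecs, ymodel, compevent_model,
                     int_set, tpoints, s, hist, keep_cohorts = TRUE)

  ## nonparametric natural-course benchmarks
  categorical <- main$categorical
  if (outcome_type == "survival") {
    npr <- np_risk(table, ospec, tpoints)
    np_est <- npr$risk
  } else {
    np_est <- np_eof_mean(table, ospec)
  }
  np_cov <- np_covariate_means(table, tpoints, categorical = categorical)

  ## bootstrap
  boot <- NULL
  nsamples <- as.integer(nsamples)
  if (nsamples > 0L) {
    boot_seeds <- sample.int(.Machine$integer.max - 1L, nsamples)
    one_rep <- function(b) {
      set.seed(boot_seeds[b])
      tryCatch({
        bt <- .resample_subjects(table)
        r <- .gf_engine(bt, ospec, covspecs, ymodel, compevent_model,
                        int_set, tpoints, s, hist)
        list(est = r$est, ratio = r$ratio, difference = r$difference)
      }, error = function(e) NULL)
    }
    reps <- if (parallel && ncores > 1L) {
      parallel::mclapply(seq_len(nsamples), one_rep,
                         mc.cores = ncores, mc.preschedule = FALSE)
    } else {
      lapply(seq_len(nsamples), one_rep)
    }
    ok <- !vapply(reps, is.null, logical(1))
    boot <- list(B = nsamples, failed = sum(!ok))
    if (any(ok)) {
      stack <- function(field) {
        simplify2array(lapply(reps[ok], `[[`, field))  # n_int x T x B
      }
      for (field in c("est", "ratio", "difference")) {
        arr <- stack(field)
        boot[[paste0(field, "_se")]] <- apply(arr, c(1, 2), stats::sd)
        boot[[paste0(field, "_lo")]] <-
          apply(arr, c(1, 2), stats::quantile, probs = 0.025, na.rm = TRUE)
        boot[[paste0(field, "_hi")]] <-
          apply(arr, c(1, 2), stats::quantile, probs = 0.975, na.rm = TRUE)
      }
      boot$replicates <- reps[ok]
    }
  }

  ## results table
  n_int <- length(int_set)
  descs <- vapply(int_set, `[[`, "", "description")
  if (outcome_type == "survival") {
    res <- expand.grid(k = seq.int(0L, tpoints - 1L),
                       interv = seq.int(0L, n_int - 1L))
    res <- res[order(res$k, res$interv), , drop = FALSE]
    rownames(res) <- NULL
    res$description <- descs[res$interv + 1L]
    res$np_estimate <- ifelse(res$interv == 0L, np_est[res$k + 1L], NA_real_)
    pick <- cbind(res$interv + 1L, res$k + 1L)
    res$estimate <- main$est[pick]
    res$ratio <- main$ratio[pick]
    res$difference <- main$difference[pick]
    if (!is.null(boot) && !is.null(boot$est_se)) {
      res$se <- boot$est_se[pick]
      res$ci_lower <- boot$est_lo[pick]; res$ci_upper <- boot$est_hi[pick]
      res$ratio_se <- boot$ratio_se[pick]
      res$ratio_ci_lower <- boot$ratio_lo[pick]
      res$ratio_ci_upper <- boot$ratio_hi[pick]
      res$difference_se <- boot$difference_se[pick]
      res$difference_ci_lower <- boot$difference_lo[pick]
      res$difference_ci_upper <- boot$difference_hi[pick]
    }
  } else {
    res <- data.frame(k = K, interv = seq.int(0L, n_int - 1L),
                      description = descs,
                      np_estimate = c(np_est, rep(NA_real_, n_int - 1L)),
                      estimate = main$est[, 1L],
                      ratio = main$ratio[, 1L],
                      difference = main$difference[, 1L])
    if (!is.null(boot) && !is.null(boot$est_se)) {
      res$se <- boot$est_se[, 1L]
      res$ci_lower <- boot$est_lo[, 1L]; res$ci_upper <- boot$est_hi[, 1L]
      res$ratio_se <- boot$ratio_se[, 1L]
      res$ratio_ci_lower <- boot$ratio_lo[, 1L]
      res$ratio_ci_upper <- boot$ratio_hi[, 1L]
      res$difference_se <- boot$difference_se[, 1L]
      res$difference_ci_lower <- boot$difference_lo[, 1L]
      res$difference_ci_upper <- boot$difference_hi[, 1L]
    }
  }

  models <- c(main$covfits, list(outcome = main$yfit),
              if (!is.null(main$dfit)) list(compevent = main$dfit))
  models <- Filter(function(m) !is.null(m$coefficients), models)
  out <- structure(list(
    call = cl,
    outcome_type = outcome_type,
    result = res,
    estimates = main$est,
    np_estimate = np_est,
    np_cov_means = np_cov,
    sim_cov_means = sim_covariate_means(main$cohorts[[1L]]),
    coefs = lapply(models, `[[`, "coefficients"),
    stderrs = lapply(models, function(m) {
      se <- sqrt(diag(m$vcov)); names(se) <- names(m$coefficients); se
    }),
    vcovs = lapply(models, `[[`, "vcov"),
    rmses = vapply(models, `[[`, numeric(1), "rmse"),
    fits = list(covariates = main$covfits, outcome = main$yfit,
                compevent = main$dfit),
    interventions = int_set,
    header = list(n = n, nsimul = s, nsamples = nsamples,
                  ref_int = attr(int_set, "ref_int"),
                  time_points = tpoints, K = K,
                  boot_failed = if (!is.null(boot)) boot$failed else 0L,
                  seed = seed),
    boot = boot,
    time_name = attr(table, "time_name"),
    cohorts = if (sim_data) main$cohorts else NULL,
    sim_data = if (sim_data) .cohorts_long(main$cohorts) else NULL
  ), class = c(paste0("gformula_", outcome_type), "gformula"))
  out
}

## Long-format export of simulated histories across interventions.
.cohorts_long <- function(cohorts) {
  parts <- lapply(seq_along(cohorts), function(j) {
    co <- cohorts[[j]]
    T_ <- if (!is.null(co$p)) ncol(co$p) else ncol(co$covariates[[1L]])
    df <- expand.grid(sim_id = seq_len(co$s), k = seq.int(0L, T_ - 1L))
    df <- df[order(df$sim_id, df$k), , drop = FALSE]
    df <- cbind(interv = j - 1L, description = co$description, df)
    for (v in names(co$covariates)) df[[v]] <- as.vector(co$covariates[[v]])
    for (v in names(co$natural_treatment)) {
      df[[paste0("natural_", v)]] <- as.vector(co$natural_treatment[[v]])
    }
    if (!is.null(co$p)) df$p_hat <- as.vector(co$p)
    if (!is.null(co$q)) df$q_hat <- as.vector(co$q)
    rownames(df) <- NULL
    df
  })
  all_cols <- unique(unlist(lapply(parts, names)))
  parts <- lapply(parts, function(df) {
    for (nm in setdiff(all_cols, names(df))) df[[nm]] <- NA
    df[, all_cols, drop = FALSE]
  })
  do.call(rbind, parts)
}

#' Retrieve simulated histories from a gformula fit
#'
#' @param object a `gformula` object fitted with `sim_data = TRUE`.
#' @return long data.frame of simulated histories (one row per intervention,
#'   simulated subject and follow-up time).
#' @export
sim_data <- function(object) {
  if (is.null(object$sim_data)) {
    stop("refit with sim_data = TRUE to keep simulated histories",
         call. = FALSE)
  }
  object$sim_data
}
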