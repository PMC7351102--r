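#' Structural data-generating processes with known counterfactual truth
#'
#' Named longitudinal data-generating processes (DGPs) with
#' treatment-confounder feedback, used to validate the estimation engine:
#' the same structural equations that generate observed data also yield the
#' true counterfactual risk or mean under any treatment rule (via
#' [true_counterfactual()]), so engine estimates with correctly specified
#' models can be checked against ground truth.
#'
#' Shipped DGPs:
#' * `"survival_basic"` — binary time-varying confounder `L1`, continuous
#'   confounder `L2`, continuous baseline covariate `L3`, binary treatment
#'   `A`, survival outcome `Y`; maximum of `K + 1 = 7` follow-up times.
#' * `"survival_compevent"` — as above plus a competing event `D` whose
#'   cause-specific hazard depends on treatment and covariates.
#' * `"binary_eof"` — binary covariate `cov1`, zero-inflated continuous
#'   covariate `cov2`, baseline `cov3`, binary treatment `treat`, binary
#'   outcome `outcome` measured at the end of follow-up.
#' * `"continuous_eof_categorical"` — three-level categorical covariate
#'   `L1`, continuous `L2`, baseline `L3`, binary treatment `A`, continuous
#'   end-of-follow-up outcome `Y`.
#' * `"survival_binary_small"` — one binary confounder `L1` and binary
#'   treatment `A` with `K = 2` and no baseline covariate: the state space
#'   is small enough for exact enumeration of all covariate/treatment paths.
#'
#' Event risks sit in the 0.2-0.7 range so that intervention contrasts are
#' well separated. Each object carries a ready-made, correctly specified
#' [gformula()] configuration in `$config`.
#'
#' @param name DGP name (see above).
#' @param n number of subjects.
#' @param K maximum follow-up index (default 6; 2 for
#'   `"survival_binary_small"`).
#' @param censor_prob per-interval probability of independent censoring
#'   (survival DGPs only; default 0).
#' @return An object of class `gf_dgp`.
#' @export
gf_dgp <- function(name = c("survival_basic", "survival_compevent",
                            "binary_eof", "continuous_eof_categorical",
                            "survival_binary_small"),
                   n = 2500L, K = NULL, censor_prob = 0) {
  name <- match.arg(name)
  if (is.null(K)) K <- if (name == "survival_binary_small") 2L else 6L
  outcome_type <- switch(name,
                         binary_eof = "binary_eof",
                         continuous_eof_categorical = "continuous_eof",
                         "survival")
  config <- switch(
    name,
    survival_basic = ,
    survival_compevent = list(
      id = "id", time_name = "t0", outcome_name = "Y",
      covnames = c("L1", "L2", "A"),
      covtypes = c("binary", "bounded normal", "binary"),
      covparams = list(covmodels = c(L1 ~ lag1_A + lag1_L1 + lag1_L2 + L3,
                                     L2 ~ lag1_A + L1 + lag1_L2 + L3,
                                     A ~ lag1_A + L1 + L2 + L3)),
      ymodel = Y ~ A + L1 + L2 + L3 + t0,
      basecovs = "L3",
      compevent_name = if (name == "survival_compevent") "D",
      compevent_model = if (name == "survival_compevent") D ~ A + L1 + L3),
    binary_eof = list(
      id = "id_num", time_name = "time", outcome_name = "outcome",
      covnames = c("cov1", "cov2", "treat"),
      covtypes = c("binary", "zero-inflated normal", "binary"),
      covparams = list(covmodels = c(
        cov1 ~ lag1_treat + lag1_cov1 + lag1_cov2 + cov3,
        cov2 ~ lag1_treat + cov1 + lag1_cov2 + cov3,
        treat ~ lag1_treat + cov1 + cov2 + cov3)),
      ymodel = outcome ~ treat + cov1 + cov2 + cov3,
      basecovs = "cov3"),
    continuous_eof_categorical = list(
      id = "id", time_name = "t0", outcome_name = "Y",
      covnames = c("L1", "L2", "A"),
      covtypes = c("categorical", "normal", "binary"),
      covparams = list(covmodels = c(L1 ~ lag1_A + lag1_L1 + L3,
                                     L2 ~ lag1_A + L1 + lag1_L2 + L3,
                                     A ~ lag1_A + L1 + L2 + L3)),
      ymodel = Y ~ A + lag1_A + L1 + L2 + L3,
      basecovs = "L3"),
    survival_binary_small = list(
      id = "id", time_name = "t0", outcome_name = "Y",
      covnames = c("L1", "A"),
      covtypes = c("binary", "binary"),
      covparams = list(covmodels = c(L1 ~ lag1_A + lag1_L1,
                                     A ~ L1 + lag1_A)),
      ymodel = Y ~ A + L1 + lag1_A,
      basecovs = NULL)
  )
  structure(list(name = name, n = as.integer(n), K = as.integer(K),
                 outcome_type = outcome_type,
                 censor_prob = censor_prob, config = config),
            class = "gf_dgp")
}

#' @export
print.gf_dgp <- function(x, ...) {
  cat("Structural DGP '", x$name, "': n = ", x$n, ", K = ", x$K,
      ", outcome type = ", x$outcome_type, "\n", sep = "")
  invisible(x)
}

## ---- structural path simulation --------------------------------------------
## Each .paths_* function simulates s complete covariate/treatment paths
## (no event truncation) under a treatment-assignment rule
## a_assign(k, natural_values, covariate_env) and returns per-time hazard
## matrices (survival) or end-of-follow-up outcome means. The observed-data
## generator and the counterfactual-truth computation share this code;
## truth uses the hazards directly, the generator additionally draws event,
## competing-event and censoring indicators and truncates records.

.paths_survival_basic <- function(dgp, s, a_assign) {
  K <- dgp$K
  compevent <- dgp$name == "survival_compevent"
  L3 <- stats::rnorm(s)
  L1 <- L2 <- A <- P <- matrix(NA_real_, s, K + 1L)
  Q <- if (compevent) matrix(NA_real_, s, K + 1L)
  lagA <- lagL1 <- lagL2 <- numeric(s)
  for (k in 0:K) {
    if (k == 0L) {
      L1[, 1L] <- as.numeric(stats::runif(s) <
                               stats::plogis(-0.4 + 0.4 * L3))
      L2[, 1L] <- 0.5 * L3 + stats::rnorm(s)
    } else {
      L1[, k + 1L] <- as.numeric(stats::runif(s) < stats::plogis(
        -0.5 - 0.9 * lagA + 0.8 * lagL1 + 0.3 * lagL2 + 0.3 * L3))
      L2[, k + 1L] <- 0.2 - 0.5 * lagA + 0.6 * L1[, k + 1L] +
        0.4 * lagL2 + 0.2 * L3 + stats::rnorm(s, sd = 0.8)
    }
    a_nat <- as.numeric(stats::runif(s) < stats::plogis(
      -0.8 + 1.2 * lagA + 0.8 * L1[, k + 1L] + 0.3 * L2[, k + 1L] -
        0.2 * L3))
    A[, k + 1L] <- a_assign(k, a_nat,
                            list(L1 = L1[, k + 1L], L2 = L2[, k + 1L],
                                 L3 = L3, lagA = lagA))
    P[, k + 1L] <- stats::plogis(-1.8 - 0.8 * A[, k + 1L] +
                                   0.7 * L1[, k + 1L] + 0.3 * L2[, k + 1L] +
                                   0.2 * L3 - 0.05 * k)
    if (compevent) {
      Q[, k + 1L] <- stats::plogis(-2.6 + 0.4 * A[, k + 1L] +
                                     0.5 * L1[, k + 1L] + 0.2 * L3)
    }
    lagA <- A[, k + 1L]; lagL1 <- L1[, k + 1L]; lagL2 <- L2[, k + 1L]
  }
  list(cov = list(L1 = L1, L2 = L2, A = A), base = data.frame(L3 = L3),
       p = P, q = Q)
}

.paths_survival_binary_small <- function(dgp, s, a_assign) {
  K <- dgp$K
  L1 <- A <- P <- matrix(NA_real_, s, K + 1L)
  lagA <- lagL <- numeric(s)
  for (k in 0:K) {
    L1[, k + 1L] <- if (k == 0L) {
      as.numeric(stats::runif(s) < 0.5)
    } else {
      as.numeric(stats::runif(s) <
                   stats::plogis(-0.3 - 0.8 * lagA + 0.9 * lagL))
    }
    a_nat <- as.numeric(stats::runif(s) < stats::plogis(
      -0.4 + 1.0 * lagA + 0.8 * L1[, k + 1L]))
    A[, k + 1L] <- a_assign(k, a_nat, list(L1 = L1[, k + 1L], lagA = lagA))
    P[, k + 1L] <- stats::plogis(-1.1 - 0.7 * A[, k + 1L] +
                                   0.8 * L1[, k + 1L] - 0.4 * lagA)
    lagA <- A[, k + 1L]; lagL <- L1[, k + 1L]
  }
  list(cov = list(L1 = L1, A = A), base = NULL, p = P, q = NULL)
}

.paths_binary_eof <- function(dgp, s, a_assign) {
  K <- dgp$K
  cov3 <- stats::rnorm(s)
  c1 <- c2 <- tr <- matrix(NA_real_, s, K + 1L)
  lagT <- lag1 <- lag2 <- numeric(s)
  for (k in 0:K) {
    if (k == 0L) {
      c1[, 1L] <- as.numeric(stats::runif(s) <
                               stats::plogis(-0.2 + 0.3 * cov3))
      b <- as.numeric(stats::runif(s) < stats::plogis(0.4 + 0.3 * cov3))
      c2[, 1L] <- b * (1 + 0.4 * cov3 + stats::rnorm(s))
    } else {
      c1[, k + 1L] <- as.numeric(stats::runif(s) < stats::plogis(
        -0.6 - 0.7 * lagT + 0.9 * lag1 + 0.2 * lag2 + 0.3 * cov3))
      b <- as.numeric(stats::runif(s) < stats::plogis(
        0.3 - 0.4 * lagT + 0.5 * c1[, k + 1L] + 0.1 * lag2 + 0.2 * cov3))
      c2[, k + 1L] <- b * (0.5 - 0.3 * lagT + 0.4 * c1[, k + 1L] +
                             0.3 * lag2 + 0.2 * cov3 +
                             stats::rnorm(s, sd = 0.9))
    }
    t_nat <- as.numeric(stats::runif(s) < stats::plogis(
      -0.8 + 1.0 * lagT + 0.7 * c1[, k + 1L] + 0.2 * c2[, k + 1L] +
        0.2 * cov3))
    tr[, k + 1L] <- a_assign(k, t_nat,
                             list(cov1 = c1[, k + 1L], cov2 = c2[, k + 1L],
                                  cov3 = cov3, lagT = lagT))
    lagT <- tr[, k + 1L]; lag1 <- c1[, k + 1L]; lag2 <- c2[, k + 1L]
  }
  eof_mean <- stats::plogis(-1.6 - 0.7 * tr[, K + 1L] + 0.6 * c1[, K + 1L] +
                              0.25 * c2[, K + 1L] + 0.3 * cov3)
  list(cov = list(cov1 = c1, cov2 = c2, treat = tr),
       base = data.frame(cov3 = cov3), eof_mean = eof_mean)
}

.paths_continuous_eof <- function(dgp, s, a_assign) {
  K <- dgp$K
  L3 <- stats::rnorm(s)
  L1 <- matrix(NA_character_, s, K + 1L)
  L2 <- A <- matrix(NA_real_, s, K + 1L)
  lagA <- numeric(s); lagL1 <- rep("0", s); lagL2 <- numeric(s)
  draw_cat <- function(e1, e2) {
    d <- 1 + exp(e1) + exp(e2)
    u <- stats::runif(length(e1))
    ifelse(u < 1 / d, "0", ifelse(u < (1 + exp(e1)) / d, "1", "2"))
  }
  for (k in 0:K) {
    if (k == 0L) {
      L1[, 1L] <- draw_cat(-0.2 + 0.3 * L3, -0.6 + 0.4 * L3)
      L2[, 1L] <- 0.4 * L3 + stats::rnorm(s)
    } else {
      i1 <- as.numeric(lagL1 == "1"); i2 <- as.numeric(lagL1 == "2")
      L1[, k + 1L] <- draw_cat(
        -0.4 + 0.4 * lagA + 0.6 * i1 + 0.3 * i2 + 0.2 * L3,
        -0.8 - 0.3 * lagA + 0.3 * i1 + 0.7 * i2 + 0.3 * L3)
      j1 <- as.numeric(L1[, k + 1L] == "1")
      j2 <- as.numeric(L1[, k + 1L] == "2")
      L2[, k + 1L] <- 0.3 - 0.4 * lagA + 0.5 * j1 + 0.8 * j2 +
        0.4 * lagL2 + 0.2 * L3 + stats::rnorm(s, sd = 0.9)
    }
    j1 <- as.numeric(L1[, k + 1L] == "1")
    j2 <- as.numeric(L1[, k + 1L] == "2")
    a_nat <- as.numeric(stats::runif(s) < stats::plogis(
      -0.6 + 0.9 * lagA + 0.4 * j1 + 0.6 * j2 + 0.3 * L2[, k + 1L] -
        0.2 * L3))
    A[, k + 1L] <- a_assign(k, a_nat,
                            list(L1 = L1[, k + 1L], L2 = L2[, k + 1L],
                                 L3 = L3, lagA = lagA))
    lagA <- A[, k + 1L]; lagL1 <- L1[, k + 1L]; lagL2 <- L2[, k + 1L]
  }
  jK1 <- as.numeric(L1[, K + 1L] == "1"); jK2 <- as.numeric(L1[, K + 1L] == "2")
  lag_prev_A <- if (K >= 1L) A[, K] else numeric(s)
  eof_mean <- -2 - 1.0 * A[, K + 1L] - 0.6 * lag_prev_A + 0.5 * jK1 +
    0.8 * jK2 + 0.4 * L2[, K + 1L] + 0.3 * L3
  list(cov = list(L1 = L1, L2 = L2, A = A), base = data.frame(L3 = L3),
       eof_mean = eof_mean, eof_sd = 1)
}

.dgp_paths <- function(dgp, s, a_assign = function(k, nat, env) nat) {
  switch(dgp$name,
         survival_basic = ,
         survival_compevent = .paths_survival_basic(dgp, s, a_assign),
         survival_binary_small = .paths_survival_binary_small(dgp, s,
                                                              a_assign),
         binary_eof = .paths_binary_eof(dgp, s, a_assign),
         continuous_eof_categorical = .paths_continuous_eof(dgp, s,
                                                            a_assign))
}

## Normalise an intervention label into an assignment rule on the DGP's
## treatment: "natural", "never", "always", or list(min=, max=) (threshold).
.dgp_rule <- function(intervention) {
  if (is.character(intervention)) {
    switch(intervention,
           natural = function(k, nat, env) nat,
           never = function(k, nat, env) rep(0, length(nat)),
           always = function(k, nat, env) rep(1, length(nat)),
           stop("unknown intervention label: ", intervention,
                call. = FALSE))
  } else if (is.list(intervention) && !is.null(intervention$min)) {
    function(k, nat, env) pmin(pmax(nat, intervention$min),
                               intervention$max)
  } else if (is.function(intervention)) {
    intervention
  } else {
    stop("cannot interpret intervention", call. = FALSE)
  }
}

#' Generate an observed longitudinal dataset from a structural DGP
#'
#' Simulates covariate and treatment paths under the natural course, draws
#' censoring, competing-event and outcome indicators interval by interval,
#' and assembles the long-format person-time table obeying all input coding
#' rules (records stop at the first event; the outcome is missing on
#' censored and competing-event rows; end-of-follow-up outcomes appear only
#' on the final row).
#'
#' @param dgp a [gf_dgp] object.
#' @param seed integer seed.
#' @return data.frame in long format, ready for [gformula()] with the
#'   configuration in `dgp$config`.
#' @export
generate_dataset <- function(dgp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- dgp$n; K <- dgp$K
  paths <- .dgp_paths(dgp, n)
  cfg <- dgp$config
  survival <- dgp$outcome_type == "survival"
  compevent <- !is.null(paths$q)

  if (survival) {
    ## per-interval order: censoring, then competing event, then outcome
    u_c <- matrix(stats::runif(n * (K + 1L)), n)
    u_d <- matrix(stats::runif(n * (K + 1L)), n)
    u_y <- matrix(stats::runif(n * (K + 1L)), n)
    end_k <- rep(K, n)
    status <- rep("admin", n)   # administrative end of follow-up
    alive <- rep(TRUE, n)
    for (k in 0:K) {
      cens <- alive & (u_c[, k + 1L] < dgp$censor_prob)
      end_k[cens] <- k; status[cens] <- "censor"; alive[cens] <- FALSE
      if (compevent) {
        dead <- alive & (u_d[, k + 1L] < paths$q[, k + 1L])
        end_k[dead] <- k; status[dead] <- "compevent"; alive[dead] <- FALSE
      }
      ev <- alive & (u_y[, k + 1L] < paths$p[, k + 1L])
      end_k[ev] <- k; status[ev] <- "event"; alive[ev] <- FALSE
    }
    nrows <- end_k + 1L
    subj <- rep(seq_len(n), nrows)
    krow <- sequence(nrows) - 1L
    pickcell <- cbind(subj, krow + 1L)
    last <- krow == (end_k[subj])
    Y <- numeric(length(subj))
    Y[last & status[subj] == "event"] <- 1
    Y[last & status[subj] %in% c("censor", "compevent")] <- NA
    df <- data.frame(id = subj)
    df[[cfg$time_name]] <- krow
    for (v in names(paths$cov)) df[[v]] <- paths$cov[[v]][pickcell]
    if (!is.null(paths$base)) {
      for (b in names(paths$base)) df[[b]] <- paths$base[[b]][subj]
    }
    if (compevent) {
      D <- numeric(length(subj))
      D[last & status[subj] == "compevent"] <- 1
      D[last & status[subj] == "censor"] <- NA
      df$D <- D
    }
    df$Y <- Y
    names(df)[1L] <- cfg$id
    names(df)[names(df) == "Y"] <- cfg$outcome_name
  } else {
    subj <- rep(seq_len(n), each = K + 1L)
    krow <- rep(0:K, n)
    pickcell <- cbind(subj, krow + 1L)
    df <- data.frame(id = subj)
    df[[cfg$time_name]] <- krow
    for (v in names(paths$cov)) df[[v]] <- paths$cov[[v]][pickcell]
    for (b in names(paths$base)) df[[b]] <- paths$base[[b]][subj]
    yfin <- if (dgp$outcome_type == "binary_eof") {
      as.numeric(stats::runif(n) < paths$eof_mean)
    } else {
      paths$eof_mean + stats::rnorm(n, sd = paths$eof_sd)
    }
    y <- rep(NA_real_, length(subj))
    y[krow == K] <- yfin[subj[krow == K]]
    df[[cfg$outcome_name]] <- y
    names(df)[1L] <- cfg$id
  }
  rownames(df) <- NULL
  df
}

#' True counterfactual risk or mean under a treatment rule
#'
#' Computes the ground-truth counterfactual quantity directly from the
#' structural equations of a [gf_dgp], either by large Monte Carlo
#' simulation from the true equations (`"large_mc"`, with a Monte Carlo
#' standard error) or by exact enumeration of all covariate/treatment paths
#' (`"enumeration"`, discrete DGPs only).
#'
#' @param dgp a [gf_dgp].
#' @param intervention `"natural"`, `"never"`, `"always"`, a list
#'   `list(min =, max =)` for a threshold rule, or a function
#'   `f(k, natural, env)`.
#' @param method `"large_mc"` or `"enumeration"`.
#' @param s Monte Carlo sample size for `"large_mc"`.
#' @param compevent_mode for `"survival_compevent"`: `"modeled"` returns the
#'   cause-specific cumulative incidence (total effect); `"censoring"`
#'   returns the risk under elimination of competing events (direct
#'   effect).
#' @param seed integer seed for `"large_mc"`.
#' @return list with `estimate` (risk by `k = 0..K` for survival; scalar
#'   mean otherwise) and `se` (Monte Carlo standard error; 0 for
#'   enumeration).
#' @export
true_counterfactual <- function(dgp, intervention = "natural",
                                method = c("large_mc", "enumeration"),
                                s = 1e6,
                                compevent_mode = c("modeled", "censoring"),
                                seed = NULL) {
  method <- match.arg(method)
  compevent_mode <- match.arg(compevent_mode)
  rule <- .dgp_rule(intervention)
  if (method == "enumeration") {
    if (dgp$name != "survival_binary_small") {
      stop("enumeration is only available for the discrete DGP ",
           "'survival_binary_small'", call. = FALSE)
    }
    return(.enumerate_small(dgp, rule))
  }
  if (!is.null(seed)) set.seed(seed)
  paths <- .dgp_paths(dgp, s, rule)
  if (dgp$outcome_type == "survival") {
    q <- paths$q
    if (!is.null(q) && compevent_mode == "censoring") q <- NULL
    mode <- if (is.null(q)) "no_compevent" else "compevent_modeled"
    r <- risk_from_hazards(paths$p, q, mode = mode)
    list(estimate = colMeans(r), se = apply(r, 2L, stats::sd) / sqrt(s))
  } else {
    list(estimate = mean(paths$eof_mean),
         se = stats::sd(paths$eof_mean) / sqrt(s))
  }
}

## Exact g-formula sum for the small binary DGP: recursion over the
## (L, A) path space with the true structural probabilities.
.enumerate_small <- function(dgp, rule) {
  K <- dgp$K
  pL <- function(k, lagA, lagL) {
    if (k == 0L) 0.5 else stats::plogis(-0.3 - 0.8 * lagA + 0.9 * lagL)
  }
  pA <- function(k, L, lagA) stats::plogis(-0.4 + 1.0 * lagA + 0.8 * L)
  haz <- function(k, A, L, lagA) stats::plogis(-1.1 - 0.7 * A + 0.8 * L -
                                                 0.4 * lagA)
  risk <- numeric(K + 1L)
  recurse <- function(k, lagA, lagL, prob, surv) {
    if (k > K || prob == 0) return(invisible(NULL))
    for (L in 0:1) {
      pl <- pL(k, lagA, lagL)
      wL <- if (L == 1) pl else 1 - pl
      for (Anat in 0:1) {
        pa <- pA(k, L, lagA)
        wA <- if (Anat == 1) pa else 1 - pa
        A <- rule(k, Anat, list(L1 = L, lagA = lagA))
        w <- prob * wL * wA
        h <- haz(k, A, L, lagA)
        risk[(k + 1L):(K + 1L)] <<- risk[(k + 1L):(K + 1L)] + w * surv * h
        recurse(k + 1L, A, L, w, surv * (1 - h))
      }
    }
  }
  recurse(0L, 0, 0, 1, 1)
  list(estimate = risk, se = rep(0, K + 1L))
}
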