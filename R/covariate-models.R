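#' Covariate distribution specification
#'
#' One time-varying covariate's conditional distribution family and model
#' formula. The order of the specifications passed to [gformula()] defines
#' the factorisation order of the joint covariate distribution: the model for
#' the j-th covariate at time k may condition on current-time values of
#' covariates earlier in the order and on history functions of all
#' covariates.
#'
#' Supported families (`covtype`):
#' * `"binary"` — logistic regression, Bernoulli draws.
#' * `"normal"` — linear regression; draws from a normal with the residual
#'   standard deviation, clamped to the range observed in the fitting data.
#' * `"categorical"` — multinomial logistic regression
#'   (reference level = first observed level in sort order).
#' * `"bounded_normal"` — the covariate is standardised to `[0, 1]` via its
#'   observed (min, max) before a linear fit; draws are made on the
#'   standardised scale, clamped to `[0, 1]` and back-transformed.
#' * `"zero_inflated_normal"` — a logistic model for `I(Z != 0)` plus a
#'   linear model fitted on the nonzero rows; a draw is the product of a
#'   Bernoulli nonzero indicator and a normal draw clamped to the observed
#'   nonzero range.
#' * `"truncated_normal"` — linear fit; draws from a one-sided truncated
#'   normal with `type_params = list(point =, direction = "left"|"right")`
#'   (`"left"`: support `[point, Inf)`; `"right"`: support `(-Inf, point]`).
#' * `"absorbing"` — logistic fit restricted to rows whose previous value is
#'   0; once the covariate reaches 1 it stays 1.
#' * `"categorical_time"` — no stochastic model; a deterministic recoding of
#'   the time index into intervals given by `type_params = list(breaks =)`
#'   (value = `findInterval(k, breaks)`, as character).
#'
#' @param name covariate column name.
#' @param covtype one of the eight families above (`"bounded normal"`,
#'   `"zero-inflated normal"`, `"truncated normal"` and `"categorical time"`
#'   are accepted as aliases).
#' @param formula model formula with the covariate as response; predictors
#'   may use earlier-order covariates, the generated history columns
#'   (`lag{i}_X`, `cumavg_X`, `lag_cumavg{i}_X`), baseline covariates, the
#'   time index, and transformations such as spline bases.
#' @param type_params family-specific parameters (see above).
#' @return An object of class `gf_cov_spec`.
#' @export
gf_cov_spec <- function(name, covtype, formula = NULL, type_params = list()) {
  covtype <- gsub("[ -]", "_", covtype)
  allowed <- c("binary", "normal", "categorical", "bounded_normal",
               "zero_inflated_normal", "truncated_normal", "absorbing",
               "categorical_time")
  if (!covtype %in% allowed) {
    stop("unknown covtype '", covtype, "'; allowed: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  if (covtype == "truncated_normal") {
    if (is.null(type_params$point) || is.null(type_params$direction) ||
        !type_params$direction %in% c("left", "right")) {
      stop("truncated_normal requires type_params$point and ",
           "type_params$direction ('left' or 'right')", call. = FALSE)
    }
  }
  if (covtype == "categorical_time" && is.null(type_params$breaks)) {
    stop("categorical_time requires type_params$breaks (interval cut points)",
         call. = FALSE)
  }
  if (is.null(formula) && covtype != "categorical_time") {
    stop("a model formula is required for covtype '", covtype, "'",
         call. = FALSE)
  }
  structure(list(name = name, covtype = covtype, formula = formula,
                 type_params = type_params),
            class = "gf_cov_spec")
}

.check_degenerate <- function(y, name) {
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("degenerate response: covariate/model '", name,
         "' has no variation in its fitting rows", call. = FALSE)
  }
}

.fit_glm <- function(formula, data, family, what) {
  fit <- tryCatch(
    stats::glm(formula, family = family, data = data,
               na.action = stats::na.omit),
    error = function(e) stop("model fit failed for ", what, ": ",
                             conditionMessage(e), call. = FALSE))
  if (family$family == "binomial" && !fit$converged) {
    stop("logistic fit did not converge for ", what, call. = FALSE)
  }
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design for ", what, "; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  fit
}

#' Fit the conditional model for one time-varying covariate
#'
#' Fits the family-specific model for a covariate given history, on the
#' supplied fitting rows (rows with time index `k >= 1`, since baseline
#' values are resampled from the observed baseline distribution rather than
#' simulated).
#'
#' @param spec a [gf_cov_spec].
#' @param fitdata data.frame of fitting rows with all history columns
#'   present.
#' @return An object of class `gf_cov_fit` carrying the fitted model(s),
#'   coefficients, variance-covariance matrix, residual scale and observed
#'   range (normal families), RMSE on the fitting rows, and the number of
#'   rows used.
#' @export
fit_covariate_model <- function(spec, fitdata) {
  v <- spec$name
  out <- list(spec = spec, fit = NULL, zero_model = NULL,
              coefficients = NULL, vcov = NULL, residual_scale = NA_real_,
              observed_range = c(NA_real_, NA_real_), levels = NULL,
              rmse = NA_real_, n_fit = 0L)
  ctype <- spec$covtype
  if (ctype == "categorical_time") {
    out$n_fit <- 0L
    out$rmse <- 0
    class(out) <- "gf_cov_fit"
    return(out)
  }
  if (!v %in% names(fitdata)) {
    stop("covariate '", v, "' not found in fitting data", call. = FALSE)
  }
  miss <- setdiff(all.vars(spec$formula), names(fitdata))
  if (length(miss) > 0L) {
    stop("formula for '", v, "' references unknown column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  fitdata <- fitdata[!is.na(fitdata[[v]]), , drop = FALSE]

  if (ctype == "absorbing") {
    lagcol <- paste0("lag1_", v)
    if (!lagcol %in% names(fitdata)) {
      stop("absorbing covariate '", v, "' requires its lag1 column in the ",
           "fitting data", call. = FALSE)
    }
    fitdata <- fitdata[as.numeric(fitdata[[lagcol]]) == 0, , drop = FALSE]
  }
  if (nrow(fitdata) == 0L) {
    stop("no usable fitting rows for covariate '", v, "'", call. = FALSE)
  }
  out$n_fit <- nrow(fitdata)

  if (ctype %in% c("binary", "absorbing")) {
    .check_degenerate(fitdata[[v]], v)
    fit <- .fit_glm(spec$formula, fitdata, stats::binomial(), v)
    out$fit <- fit
    out$coefficients <- stats::coef(fit)
    out$vcov <- stats::vcov(fit)
    p <- stats::fitted(fit)
    out$rmse <- sqrt(mean((fitdata[[v]] - p)^2))
  } else if (ctype == "normal") {
    fit <- stats::lm(spec$formula, data = fitdata)
    if (any(is.na(stats::coef(fit)))) {
      stop("singular design for '", v, "'", call. = FALSE)
    }
    out$fit <- fit
    out$coefficients <- stats::coef(fit)
    out$vcov <- stats::vcov(fit)
    out$residual_scale <- summary(fit)$sigma
    out$observed_range <- range(fitdata[[v]])
    out$rmse <- sqrt(mean(stats::residuals(fit)^2))
  } else if (ctype == "bounded_normal") {
    rng <- range(fitdata[[v]])
    out$observed_range <- rng
    if (diff(rng) == 0) {
      out$rmse <- 0
      class(out) <- "gf_cov_fit"
      return(out)
    }
    fitdata$.std01 <- (fitdata[[v]] - rng[1]) / diff(rng)
    f <- stats::update(spec$formula, .std01 ~ .)
    fit <- stats::lm(f, data = fitdata)
    if (any(is.na(stats::coef(fit)))) {
      stop("singular design for '", v, "'", call. = FALSE)
    }
    out$fit <- fit
    out$coefficients <- stats::coef(fit)
    out$vcov <- stats::vcov(fit)
    out$residual_scale <- summary(fit)$sigma
    out$rmse <- sqrt(mean(stats::residuals(fit)^2)) * diff(rng)
  } else if (ctype == "zero_inflated_normal") {
    fitdata$.nonzero <- as.numeric(fitdata[[v]] != 0)
    .check_degenerate(fitdata$.nonzero, paste0(v, " (zero indicator)"))
    fz <- stats::update(spec$formula, .nonzero ~ .)
    zero_fit <- .fit_glm(fz, fitdata, stats::binomial(),
                         paste0(v, " (zero model)"))
    nz <- fitdata[fitdata$.nonzero == 1, , drop = FALSE]
    fit <- stats::lm(spec$formula, data = nz)
    if (any(is.na(stats::coef(fit)))) {
      stop("singular design for '", v, "'", call. = FALSE)
    }
    out$zero_model <- zero_fit
    out$fit <- fit
    out$coefficients <- stats::coef(fit)
    out$vcov <- stats::vcov(fit)
    out$residual_scale <- summary(fit)$sigma
    out$observed_range <- range(nz[[v]])
    pred <- stats::predict(zero_fit, newdata = fitdata, type = "response") *
      stats::predict(fit, newdata = fitdata)
    out$rmse <- sqrt(mean((fitdata[[v]] - pred)^2))
  } else if (ctype == "truncated_normal") {
    fit <- stats::lm(spec$formula, data = fitdata)
    if (any(is.na(stats::coef(fit)))) {
      stop("singular design for '", v, "'", call. = FALSE)
    }
    out$fit <- fit
    out$coefficients <- stats::coef(fit)
    out$vcov <- stats::vcov(fit)
    out$residual_scale <- summary(fit)$sigma
    out$observed_range <- range(fitdata[[v]])
    out$rmse <- sqrt(mean(stats::residuals(fit)^2))
  } else if (ctype == "categorical") {
    y <- factor(fitdata[[v]])
    if (nlevels(y) < 2L) {
      stop("degenerate response: covariate/model '", v,
           "' has no variation in its fitting rows", call. = FALSE)
    }
    fitdata[[v]] <- y
    ## do.call embeds the formula object in the call so that
    ## predict.multinom can rebuild the model frame on new data
    fit <- do.call(nnet::multinom,
                   list(formula = spec$formula, data = fitdata,
                        trace = FALSE, maxit = 500))
    out$fit <- fit
    out$levels <- levels(y)
    cf <- stats::coef(fit)
    if (is.matrix(cf)) {
      cc <- as.vector(t(cf))
      names(cc) <- as.vector(t(outer(rownames(cf), colnames(cf), paste,
                                     sep = ":")))
    } else {
      cc <- cf
      names(cc) <- paste(out$levels[2], names(cf), sep = ":")
    }
    out$coefficients <- cc
    out$vcov <- stats::vcov(fit)
    probs <- stats::predict(fit, newdata = fitdata, type = "probs")
    if (!is.matrix(probs)) probs <- cbind(1 - probs, probs)
    pobs <- probs[cbind(seq_len(nrow(fitdata)),
                        match(as.character(y), out$levels))]
    out$rmse <- sqrt(mean((1 - pobs)^2))
  }
  class(out) <- "gf_cov_fit"
  out
}

#' Fit the pooled outcome model
#'
#' For survival outcomes, fits a pooled-over-time logistic regression for the
#' discrete-time hazard on all person-time rows with a non-missing outcome.
#' For end-of-follow-up outcomes, fits a single cross-sectional model on rows
#' with time index `K` and non-missing outcome (binomial/logit for binary,
#' gaussian/identity for continuous).
#'
#' @param ospec a [gf_outcome_spec].
#' @param formula outcome model formula.
#' @param fitdata data.frame of person-time rows (with history columns).
#' @param time_name time index column name.
#' @param K maximum follow-up index.
#' @return An object of class `gf_outcome_fit`.
#' @export
fit_outcome_model <- function(ospec, formula, fitdata, time_name, K) {
  ycol <- ospec$outcome_name
  if (ospec$outcome_type == "survival") {
    rows <- fitdata[!is.na(fitdata[[ycol]]), , drop = FALSE]
    family <- stats::binomial()
  } else {
    rows <- fitdata[fitdata[[time_name]] == K & !is.na(fitdata[[ycol]]), ,
                    drop = FALSE]
    family <- if (ospec$outcome_type == "binary_eof") {
      stats::binomial()
    } else {
      stats::gaussian()
    }
  }
  if (nrow(rows) == 0L) {
    stop("no usable rows to fit the outcome model", call. = FALSE)
  }
  if (family$family == "binomial") .check_degenerate(rows[[ycol]], ycol)
  fit <- .fit_glm(formula, rows, family, "outcome model")
  rmse <- sqrt(mean((rows[[ycol]] - stats::fitted(fit))^2))
  structure(list(formula = formula,
                 family = if (family$family == "binomial") {
                   "binomial_logit"
                 } else {
                   "gaussian_identity"
                 },
                 fit = fit, coefficients = stats::coef(fit),
                 vcov = stats::vcov(fit), rmse = rmse, n_fit = nrow(rows)),
            class = "gf_outcome_fit")
}

#' Fit the competing-event hazard model
#'
#' Pooled-over-time logistic regression for the discrete-time cause-specific
#' hazard of the competing event, fitted on all person-time rows with a
#' non-missing competing-event indicator (the rows on which a competing
#' event could occur).
#'
#' @param formula competing-event model formula.
#' @param fitdata data.frame of person-time rows with history columns.
#' @param compevent_name competing-event indicator column.
#' @return An object of class `gf_compevent_fit`.
#' @export
fit_compevent_model <- function(formula, fitdata, compevent_name) {
  if (!compevent_name %in% names(fitdata)) {
    stop("competing-event column '", compevent_name, "' not found",
         call. = FALSE)
  }
  rows <- fitdata[!is.na(fitdata[[compevent_name]]), , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no usable rows to fit the competing-event model", call. = FALSE)
  }
  .check_degenerate(rows[[compevent_name]], compevent_name)
  fit <- .fit_glm(formula, rows, stats::binomial(), "competing-event model")
  rmse <- sqrt(mean((rows[[compevent_name]] - stats::fitted(fit))^2))
  structure(list(formula = formula, fit = fit,
                 coefficients = stats::coef(fit), vcov = stats::vcov(fit),
                 rmse = rmse, n_fit = nrow(rows)),
            class = "gf_compevent_fit")
}

#' Predicted probability from a fitted logistic model
#'
#' Inverse-logit of the linear predictor evaluated on new feature rows.
#'
#' @param model a `gf_outcome_fit`, `gf_compevent_fit` or binary
#'   `gf_cov_fit`.
#' @param newdata data.frame of feature rows.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(model, newdata) {
  fit <- model$fit
  miss <- setdiff(all.vars(stats::formula(fit))[-1L], names(newdata))
  if (length(miss) > 0L) {
    stop("missing feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  as.numeric(stats::predict(fit, newdata = newdata, type = "response"))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Draw simulated covariate values from a fitted covariate model
#'
#' Vectorised sampling rule for each distribution family, used inside the
#' Monte Carlo simulation step. Each call consumes a fixed number of random
#' variates per row regardless of the drawn values, so that seed-matched
#' simulations under different interventions stay aligned.
#'
#' @param covfit a `gf_cov_fit`.
#' @param newdata data.frame of feature rows (one per simulated subject).
#' @param k current follow-up time (used by `categorical_time`).
#' @return vector of simulated values (numeric, or character levels for
#'   categorical families).
#' @export
draw_covariate <- function(covfit, newdata, k = NULL) {
  spec <- covfit$spec
  ctype <- spec$covtype
  s <- nrow(newdata)
  if (ctype == "categorical_time") {
    return(rep(as.character(findInterval(k, spec$type_params$breaks)), s))
  }
  if (ctype %in% c("binary", "absorbing")) {
    p <- predict_probability(covfit, newdata)
    val <- as.numeric(stats::runif(s) < p)
    if (ctype == "absorbing") {
      prev <- as.numeric(newdata[[paste0("lag1_", spec$name)]])
      val[prev == 1] <- 1
    }
    return(val)
  }
  if (ctype == "normal") {
    if (diff(covfit$observed_range) == 0) {
      return(rep(covfit$observed_range[1], s))
    }
    mu <- as.numeric(stats::predict(covfit$fit, newdata = newdata))
    x <- mu + stats::rnorm(s) * covfit$residual_scale
    return(.clamp(x, covfit$observed_range[1], covfit$observed_range[2]))
  }
  if (ctype == "bounded_normal") {
    rng <- covfit$observed_range
    if (diff(rng) == 0) return(rep(rng[1], s))
    mu <- as.numeric(stats::predict(covfit$fit, newdata = newdata))
    x01 <- .clamp(mu + stats::rnorm(s) * covfit$residual_scale, 0, 1)
    return(rng[1] + x01 * diff(rng))
  }
  if (ctype == "zero_inflated_normal") {
    pnz <- as.numeric(stats::predict(covfit$zero_model, newdata = newdata,
                                     type = "response"))
    ind <- as.numeric(stats::runif(s) < pnz)
    mu <- as.numeric(stats::predict(covfit$fit, newdata = newdata))
    x <- .clamp(mu + stats::rnorm(s) * covfit$residual_scale,
                covfit$observed_range[1], covfit$observed_range[2])
    return(ind * x)
  }
  if (ctype == "truncated_normal") {
    mu <- as.numeric(stats::predict(covfit$fit, newdata = newdata))
    sd <- covfit$residual_scale
    point <- spec$type_params$point
    u <- stats::runif(s)
    pcut <- stats::pnorm((point - mu) / sd)
    if (spec$type_params$direction == "left") {
      q <- pcut + u * (1 - pcut)
    } else {
      q <- u * pcut
    }
    q <- .clamp(q, 1e-12, 1 - 1e-12)
    return(mu + sd * stats::qnorm(q))
  }
  if (ctype == "categorical") {
    probs <- stats::predict(covfit$fit, newdata = newdata, type = "probs")
    if (!is.matrix(probs)) {
      probs <- if (s == 1L && length(probs) > 1L) {
        matrix(probs, nrow = 1L)
      } else {
        cbind(1 - probs, probs)
      }
    }
    cum <- t(apply(probs, 1L, cumsum))
    u <- stats::runif(s)
    idx <- rowSums(u > cum) + 1L
    return(covfit$levels[idx])
  }
  stop("unknown covariate family: ", ctype, call. = FALSE)
}

#' Root-mean-square error of a fitted model on its fitting rows
#'
#' @param model a `gf_cov_fit`, `gf_outcome_fit` or `gf_compevent_fit`.
#' @return non-negative scalar.
#' @export
compute_rmse <- function(model) model$rmse
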