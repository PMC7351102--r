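#' Intervention rules
#'
#' Treatment strategies are built from per-treatment rules applied at chosen
#' follow-up times:
#'
#' * `static(values)` — a deterministic static rule; `values` is the vector
#'   of treatment values to assign, of length equal to the horizon `k*`
#'   (a single value is recycled).
#' * `threshold(min, max)` — assigns the natural value of treatment when it
#'   falls inside `[min, max]`, and otherwise the nearer bound. `-Inf` /
#'   `Inf` disable a bound; `threshold(-Inf, Inf)` reproduces the natural
#'   course exactly.
#' * `natural()` — the natural course: the simulated (model-predicted) value
#'   is assigned. Estimates under the natural course are always computed by
#'   default, as intervention 0.
#' * an arbitrary function `f(k, natural_value, history)` — a custom
#'   (dynamic) rule; it receives the follow-up time, the vector of natural
#'   treatment values across the simulated subjects, and the simulated
#'   history so far (a data.frame with one row per subject), and must return
#'   the assigned values as a vector of the same length.
#'
#' The natural value of treatment at `k` — the value that would have been
#' observed had the intervention been discontinued directly before `k` — is
#' always drawn first from the fitted treatment model (consuming the random
#' number stream) even under static rules, so that seed-matched runs under
#' different interventions remain comparable.
#'
#' @param values vector of assigned values (static rule).
#' @param min,max bounds of the threshold range.
#' @return A rule object of class `gf_rule`.
#' @name intervention_rules
NULL

#' @rdname intervention_rules
#' @export
static <- function(values) {
  structure(list(kind = "static", values = values), class = "gf_rule")
}

#' @rdname intervention_rules
#' @export
threshold <- function(min = -Inf, max = Inf) {
  if (min > max) stop("threshold requires min <= max", call. = FALSE)
  structure(list(kind = "threshold", min = min, max = max),
            class = "gf_rule")
}

#' @rdname intervention_rules
#' @export
natural <- function() {
  structure(list(kind = "natural"), class = "gf_rule")
}

## Normalise user rule input: a gf_rule, a gfoRmula-style list whose first
## element is one of the exported rule functions (e.g. list(static, 0, 0, 0))
## or a string kind, or a bare custom function.
as_gf_rule <- function(x, time_points) {
  if (inherits(x, "gf_rule")) {
    r <- x
  } else if (is.function(x)) {
    r <- structure(list(kind = "custom", fn = x), class = "gf_rule")
  } else if (is.list(x) || is.vector(x)) {
    x <- as.list(x)
    head <- x[[1L]]
    rest <- unlist(x[-1L], use.names = FALSE)
    if (identical(head, static) || identical(head, "static")) {
      r <- static(rest)
    } else if (identical(head, threshold) || identical(head, "threshold")) {
      if (length(rest) != 2L) {
        stop("threshold rule requires (min, max)", call. = FALSE)
      }
      r <- threshold(rest[1L], rest[2L])
    } else if (identical(head, natural) || identical(head, "natural")) {
      r <- natural()
    } else if (is.function(head)) {
      r <- structure(list(kind = "custom", fn = head, params = rest),
                     class = "gf_rule")
    } else {
      stop("cannot interpret intervention rule", call. = FALSE)
    }
  } else {
    stop("cannot interpret intervention rule", call. = FALSE)
  }
  if (r$kind == "static") {
    if (length(r$values) == 1L) r$values <- rep(r$values, time_points)
    if (length(r$values) != time_points) {
      stop("static rule value vector must have length time_points = ",
           time_points, call. = FALSE)
    }
  }
  r
}

#' Evaluate an intervention rule at one follow-up time
#'
#' @param rule a `gf_rule`.
#' @param k follow-up time (0-based).
#' @param natural_value vector of natural treatment values across simulated
#'   subjects.
#' @param history data.frame of the simulated history so far (one row per
#'   subject); passed to custom rules.
#' @return vector of assigned treatment values.
#' @export
evaluate_rule <- function(rule, k, natural_value, history = NULL) {
  switch(rule$kind,
         static = rep(rule$values[k + 1L], length(natural_value)),
         threshold = pmin(pmax(natural_value, rule$min), rule$max),
         natural = natural_value,
         custom = {
           out <- rule$fn(k, natural_value, history)
           if (length(out) != length(natural_value)) {
             stop("custom rule returned ", length(out), " values for ",
                  length(natural_value), " subjects", call. = FALSE)
           }
           out
         },
         stop("unknown rule kind: ", rule$kind, call. = FALSE))
}

#' Build the full intervention set
#'
#' Assembles the list of strategies to compare, always placing the implicit
#' natural course first (intervention 0). Each user intervention may act
#' jointly on several treatment variables, each with its own rule and
#' applicable times (defaulting to all follow-up times).
#'
#' @param intvars list with one element per intervention; each element is a
#'   character vector of the treatment variable(s) intervened upon.
#' @param interventions list with one element per intervention; each element
#'   is a list with one rule per treatment variable (see
#'   [intervention_rules]).
#' @param int_descript character vector of intervention descriptions.
#' @param int_times optional list (parallel to `interventions`) of lists of
#'   integer vectors: the follow-up times at which each component rule is
#'   applied.
#' @param time_points horizon `k*`.
#' @param covnames declared time-varying covariates (treatment variables
#'   must be among them).
#' @param ref_int index of the reference intervention for ratio/difference
#'   contrasts (0 = natural course, the default).
#' @return list of `gf_intervention` objects; element 1 is the natural
#'   course. The reference index is stored in the `ref_int` attribute.
#' @export
build_intervention_set <- function(intvars = NULL, interventions = NULL,
                                   int_descript = NULL, int_times = NULL,
                                   time_points, covnames, ref_int = 0L) {
  n_int <- length(interventions)
  if (length(intvars) != n_int) {
    stop("intvars and interventions must have the same length", call. = FALSE)
  }
  specs <- list(structure(list(description = "Natural course",
                               components = list()),
                          class = "gf_intervention"))
  for (j in seq_len(n_int)) {
    vars <- intvars[[j]]
    rules <- interventions[[j]]
    if (!is.list(rules) ||
        (length(vars) == 1L && !is.list(rules[[1L]]) &&
         !inherits(rules[[1L]], "gf_rule") && !is.function(rules[[1L]]))) {
      rules <- list(rules)
    }
    if (length(rules) != length(vars)) {
      stop("intervention ", j, ": ", length(vars), " treatment variable(s) ",
           "but ", length(rules), " rule(s)", call. = FALSE)
    }
    comps <- vector("list", length(vars))
    for (q in seq_along(vars)) {
      if (!vars[q] %in% covnames) {
        stop("intervention variable '", vars[q],
             "' is not a declared time-varying covariate", call. = FALSE)
      }
      times <- if (!is.null(int_times)) {
        as.integer(int_times[[j]][[q]])
      } else {
        seq.int(0L, time_points - 1L)
      }
      if (any(times < 0L | times >= time_points)) {
        stop("int_times must lie in 0..time_points-1", call. = FALSE)
      }
      comps[[q]] <- list(var = vars[q],
                         rule = as_gf_rule(rules[[q]], time_points),
                         times = times)
    }
    desc <- if (!is.null(int_descript) && length(int_descript) >= j) {
      int_descript[j]
    } else {
      paste("Intervention", j)
    }
    specs[[j + 1L]] <- structure(list(description = desc, components = comps),
                                 class = "gf_intervention")
  }
  ref_int <- as.integer(ref_int)
  if (ref_int < 0L || ref_int > n_int) {
    stop("ref_int must be in 0..", n_int, call. = FALSE)
  }
  attr(specs, "ref_int") <- ref_int
  specs
}

#' Apply an intervention to natural treatment values at one time
#'
#' For each component of the strategy whose applicable times include `k`,
#' replaces the natural value by the rule's assigned value; at other times
#' the natural value is kept. Values of variables not intervened upon are
#' never altered.
#'
#' @param spec a `gf_intervention`.
#' @param k follow-up time.
#' @param natural_values named list of natural value vectors, one per
#'   treatment variable drawn so far at time `k`.
#' @param history data.frame of the simulated history so far.
#' @return named list of assigned value vectors (same names as
#'   `natural_values`).
#' @export
apply_interventions <- function(spec, k, natural_values, history = NULL) {
  assigned <- natural_values
  for (comp in spec$components) {
    if (!comp$var %in% names(natural_values)) next
    if (k %in% comp$times) {
      assigned[[comp$var]] <- evaluate_rule(comp$rule, k,
                                            natural_values[[comp$var]],
                                            history)
    }
  }
  assigned
}
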