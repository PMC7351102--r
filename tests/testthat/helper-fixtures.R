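# Shared builders for small longitudinal fixtures and DGP-based fits.

# Minimal survival table: one binary covariate L, binary treatment A.
make_small_table <- function() {
  df <- data.frame(
    id = rep(c("a", "b", "c"), times = c(3, 2, 3)),
    t0 = c(0, 1, 2, 0, 1, 0, 1, 2),
    L = c(0, 1, 1, 1, 0, 0, 0, 1),
    A = c(0, 0, 1, 1, 1, 0, 1, 1),
    W = c(2.5, 2.5, 2.5, -1, -1, 0.3, 0.3, 0.3),
    Y = c(0, 0, 0, 0, 1, 0, 0, NA))
  gf_data(df, id = "id", time_name = "t0", covnames = c("L", "A"),
          outcome_name = "Y", basecovs = "W")
}

surv_ospec <- function(compevent = NULL) {
  gf_outcome_spec("survival", "Y", compevent_name = compevent)
}

# Fit a shipped DGP with its own correctly specified configuration and
# never-treat / always-treat static strategies.
fit_dgp <- function(dgp, dat, nsimul = 10000, seed = 2, nsamples = 0,
                    interventions = NULL, intvars = NULL,
                    int_descript = NULL, ...) {
  cfg <- dgp$config
  treat <- cfg$covnames[length(cfg$covnames)]
  if (is.null(interventions)) {
    intvars <- list(treat, treat)
    interventions <- list(list(static(0)), list(static(1)))
    int_descript <- c("Never treat", "Always treat")
  }
  gformula(dat, id = cfg$id, time_name = cfg$time_name,
           outcome_name = cfg$outcome_name, outcome_type = dgp$outcome_type,
           covnames = cfg$covnames, covtypes = cfg$covtypes,
           covparams = cfg$covparams, ymodel = cfg$ymodel,
           compevent_name = cfg$compevent_name,
           compevent_model = cfg$compevent_model, basecovs = cfg$basecovs,
           intvars = intvars, interventions = interventions,
           int_descript = int_descript, nsimul = nsimul, seed = seed,
           nsamples = nsamples, ...)
}
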