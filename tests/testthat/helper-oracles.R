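# Independent oracles used by the tests. These deliberately avoid the
# package's simulation / history machinery: histories are built by naive
# per-subject shifting, and the g-formula sum is evaluated by brute-force
# enumeration of all covariate/treatment paths.

# Naive per-subject lag: shift the vector, reading pre-baseline values when
# available, padding with 0.
naive_lag <- function(z, i) c(rep(0, min(i, length(z))),
                              z[seq_len(max(0, length(z) - i))])

naive_cumavg <- function(z, times) {
  out <- numeric(length(z))
  fup <- which(times >= 0)
  out[fup] <- cumsum(z[fup]) / seq_along(fup)
  out
}

# Exact g-formula sum over all (L, A-natural) paths for a fitted
# two-covariate binary model (survival_binary_small shape), using the fitted
# glm objects via predict(). Baselines are the observed (L1_0, A_0) rows.
# rule(k, a_natural) returns the assigned treatment value.
enum_gformula_fitted <- function(fit, dat, rule, K) {
  mL <- fit$fits$covariates$L1$fit
  mA <- fit$fits$covariates$A$fit
  mY <- fit$fits$outcome$fit
  pr <- function(m, nd) as.numeric(predict(m, newdata = nd,
                                           type = "response"))
  risk <- numeric(K + 1)
  recurse <- function(k, lagA, lagL, w, surv) {
    if (k > K || w <= 0) return(invisible(NULL))
    for (L in 0:1) {
      pL <- pr(mL, data.frame(t0 = k, lag1_A = lagA, lag1_L1 = lagL))
      wL <- if (L == 1) pL else 1 - pL
      for (Anat in 0:1) {
        pA <- pr(mA, data.frame(t0 = k, L1 = L, lag1_A = lagA))
        wA <- if (Anat == 1) pA else 1 - pA
        A <- rule(k, Anat)
        h <- pr(mY, data.frame(t0 = k, A = A, L1 = L, lag1_A = lagA))
        w2 <- w * wL * wA
        risk[(k + 1):(K + 1)] <<- risk[(k + 1):(K + 1)] + w2 * surv * h
        recurse(k + 1, A, L, w2, surv * (1 - h))
      }
    }
  }
  base <- dat[dat$t0 == 0, c("L1", "A")]
  cells <- aggregate(cbind(n = rep(1, nrow(base))), by = base, FUN = sum)
  for (r in seq_len(nrow(cells))) {
    L0 <- cells$L1[r]; A0nat <- cells$A[r]
    w0 <- cells$n[r] / nrow(base)
    A0 <- rule(0, A0nat)
    h0 <- pr(mY, data.frame(t0 = 0, A = A0, L1 = L0, lag1_A = 0))
    risk <- risk + w0 * h0
    recurse(1, A0, L0, w0, 1 - h0)
  }
  risk
}
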