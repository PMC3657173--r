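# Shared builders for the test suite. All fixtures are generated in code;
# event counts are kept small except where a check is about the assay's
# standard 15,000-event acquisition.

quick_sample <- function(p, n = 2000L, seed = 1L, condition = "control",
                         model = fluorescence_model()) {
  generate_sample(sample_plan(sprintf("s_p%s_seed%d", p, seed),
                              condition = condition,
                              true_positive_fraction = p,
                              n_events = n, seed = seed),
                  model)
}

# event table with prescribed PE values and constant SSC
pe_table <- function(pe, ssc = 400) {
  event_table(cbind(SSC = rep(ssc, length(pe)), PE = pe))
}

# dummy-coded OLS solved by hand from the normal equations (test oracle,
# independent of stats::lm)
ols_oracle <- function(y, group, reference = "control") {
  lev <- c(reference, setdiff(unique(group), reference))
  X <- cbind(1, sapply(lev[-1], function(g) as.numeric(group == g)))
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(xtx)) * sigma2)
  tval <- as.vector(beta) / se
  list(groups = lev[-1], beta = unname(as.vector(beta)[-1]), se = unname(se[-1]),
       t = unname(tval[-1]), p = unname(2 * pt(-abs(tval[-1]), df)), df = df)
}

subjects_fixture <- function() {
  set.seed(99)
  data.frame(
    condition = rep(c("control", "BM", "UCMD"), c(4, 3, 5)),
    pct_nonperm = c(rnorm(4, 65, 8), rnorm(3, 54, 6), rnorm(5, 20, 7))
  )
}
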