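# Shared objects for the test suite. All fixtures are built in code.

crit_nlivr <- nlivr_criterion()
crit_nlivr_pec <- nlivr_criterion(pe_constraint = TRUE)
crit_tighter <- fixed_criterion()                 # EMA NTI comparator
crit_abe <- fixed_criterion(c(0.80, 1.25))

# a small deterministic trial used by several io/decision tests
toy_trial <- function(n = 12, gmr = 0.95, cv = 0.2, seed = 101) {
  simulate_trial(n = n, gmr = gmr, cv_wr = cv, seed = seed)
}

# stats row built by hand (bypasses simulation)
stats_row <- function(pe, se, df = 27, s2_wr = 0.01, n = 30) {
  tibble::tibble(pe = pe, se_pe = se, df_pe = df, s2_wr = s2_wr,
                 df_wr = n - 3, n = n)
}

expect_within <- function(x, target, tol) {
  expect_lt(abs(x - target), tol)
}
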