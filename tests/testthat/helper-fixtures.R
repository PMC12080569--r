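# Shared fixtures, built in code. Small cohorts keep unit tests fast;
# full-size (n = 85) cohorts are reserved for the acceptance suite.

make_small_table <- function(n_subjects = 8, seed = 11,
                             months = c(1, 2, 3)) {
  spec <- cohort_spec(n_subjects = n_subjects, seed = seed,
                      visit_months = months)
  coh <- draw_cohort(spec)
  list(spec = spec, cohort = coh,
       table = generate_event_table(coh, spec))
}

# Three-row hand-written table: one dose, one concentration, one HbA1c.
tiny_table <- function(pk_dv = 3.2) {
  event_table(data.frame(
    ID = 1, TIME = c(0, 1, 1), EVID = c(1, 0, 0), DVID = c(NA, 1, 2),
    AMT = c(5e6, NA, NA), DV = c(NA, pk_dv, 6.8), WT = 77
  ))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
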