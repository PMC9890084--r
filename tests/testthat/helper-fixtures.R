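# Shared fixtures, built in code. Expensive objects (cohorts, trained
# models) are cached per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a small deterministic cohort for unit tests
small_cohort <- function() {
  fixture("small_cohort", function() {
    gen_cohort(cohort_config(
      n_subjects = 10,
      fractions = c(0.6, 0.2, 0.2), seed = 301
    ))
  })
}

# one subject reused across tests
one_subject <- function() {
  fixture("one_subject", function() simulate_subject(cohort_config(), seed = 7))
}

# gamma-variate fixture AIF used by several oracles
fixture_aif <- function(dt = 1) {
  gen_aif_concentration(
    gamma_variate_params(t0 = 3, alpha = 2.5, beta = 1.2, peak = 5),
    seq(0, 48, by = dt)
  )
}

# dense-grid half-maximum FWHM oracle (1 ms grid, linear crossing search)
fwhm_oracle <- function(f, t_max = 60) {
  t <- seq(0, t_max, by = 1e-3)
  y <- f(t)
  above <- which(y >= max(y) / 2)
  t[max(above)] - t[min(above)]
}
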