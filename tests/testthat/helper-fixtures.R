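# Shared fixtures and independent oracles for the test suite.

# ---- independent brute-force OLS oracle --------------------------------
# Solves the normal equations directly on an explicitly built dummy matrix;
# the implementation under test goes through lm()'s QR or FWL demeaning.

dummy_block <- function(f) {
  f <- factor(f)
  lev <- levels(f)[-1]
  if (!length(lev)) return(NULL)
  m <- vapply(lev, function(l) as.numeric(f == l), numeric(length(f)))
  colnames(m) <- lev
  m
}

brute_design_parametric <- function(tab, twin_parity = FALSE) {
  age <- pmin(49, pmax(16, tab$mother_age))
  X <- cbind(intercept = 1, twin = tab$twin)
  if (twin_parity) X <- cbind(X, twin_parity = tab$twin * tab$parity)
  X <- cbind(X, dummy_block(tab$parity), dummy_block(age))
  X
}

brute_design_cells <- function(tab) {
  age <- pmin(49, pmax(16, tab$mother_age))
  cell <- factor(paste(tab$parity, age, sep = ":"))
  m <- vapply(levels(cell), function(l) as.numeric(cell == l),
              numeric(nrow(tab)))
  cbind(twin = tab$twin, m)
}

brute_ols <- function(y, X) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# ---- hand-built exact tables -------------------------------------------
# Within every parity x age cell the twin rows' outcome exceeds the
# singleton rows' by exactly `gap`; the cell baseline is additive in parity
# and age unless `interactive` is set.

exact_table <- function(gap = 1, n_per_cell = 3, interactive = FALSE) {
  grid <- expand.grid(parity = 0:3, mother_age = c(24L, 28L, 32L))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- grid$parity[i]; a <- grid$mother_age[i]
    base <- 2 + p + 0.25 * (a - 24) / 4 +
      if (interactive) 0.5 * p * (a == 32) else 0
    tibble::tibble(
      family_id = i * 100L + seq_len(n_per_cell + 1L),
      twin = c(rep(0L, n_per_cell), 1L),
      parity = p,
      mother_age = a,
      births = c(rep(base, n_per_cell), base + gap),
      survivors = c(rep(base - 1, n_per_cell), base - 1 + gap),
      next_interval_months = 24L
    )
  })
  dplyr::bind_rows(rows)
}

# ---- cached large simulations ------------------------------------------
# Big cohorts are simulated once per test run and reused across files.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

natural_cohort_50k <- function() {
  cached("nat50k", function() {
    simulate_cohort(cohort_preset("england_pre1880", n_families = 50000,
                                  seed = 1, controller_fraction = 0))
  })
}

# Complete-control cohort realizing the plan-completion assumptions of the
# closed-form pole: no adult mortality, early marriage, late and uniform
# sterility, small targets, so ~99.5% of couples attain their target.
full_control_cohort_50k <- function() {
  cached("fc50k", function() {
    simulate_cohort(cohort_preset(
      "england_pre1880", n_families = 50000, seed = 1,
      controller_fraction = 1, adult_annual_death_hazard = 0,
      wife_marriage_age_mean = 20, wife_marriage_age_sd = 1,
      sterility_age_mean = 45, sterility_age_sd = 1,
      target_distribution = function(k) pmin(3L, 1L + rpois(k, 2))))
  })
}

natural_table_50k <- function() {
  cached("nat50k_tab", function() build_analysis_table(natural_cohort_50k()))
}

full_control_table_50k <- function() {
  cached("fc50k_tab", function() build_analysis_table(full_control_cohort_50k()))
}
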