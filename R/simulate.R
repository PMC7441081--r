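#' Simulate a cohort of marital fertility histories
#'
#' Runs the monthly-step microsimulation described in [sim_config()] and
#' returns the resulting birth histories as a [twin_cohort()]. With
#' `controller_fraction = 0` the cohort realises natural fertility: a twin
#' birth raises a family's expected total births by 1 regardless of the
#' parity at which it occurs, because conception resumes on the same schedule
#' after a twin delivery as after a singleton. With controllers, exposure
#' ceases once the surviving-children target is met, so twins partly crowd
#' out later births.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`. `NULL` uses the
#'   current RNG state.
#' @return A [twin_cohort()]. Families with no delivery are retained in the
#'   `families` table. Parents' ages at death are recorded in completed
#'   years; deaths after age 80 are censored to `NA` (no burial record), as
#'   reproduction is over by then and only early deaths matter for sample
#'   filters.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_families = 200, seed = 42))
#' cohort_mean_births(cohort)
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  cfg <- validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)

  n <- cfg$n_families
  wife_mar_mo <- as.integer(round(12 * pmin(45, pmax(
    15, rnorm(n, cfg$wife_marriage_age_mean, cfg$wife_marriage_age_sd)))))
  husb_mar_mo <- pmax(16L * 12L, wife_mar_mo + as.integer(round(
    12 * rnorm(n, cfg$husband_age_gap_mean, cfg$husband_age_gap_sd))))
  ster_age_yrs <- pmax(cfg$fecundability_decline_start + 1,
                       rnorm(n, cfg$sterility_age_mean, cfg$sterility_age_sd))
  ster_mo <- as.integer(round(12 * ster_age_yrs))  # wife age in months

  haz <- cfg$adult_annual_death_hazard
  if (haz > 0) {
    h_m <- 1 - (1 - haz)^(1 / 12)
    mother_death_mo <- rgeom(n, h_m) + 1L  # months since marriage
    father_death_mo <- rgeom(n, h_m) + 1L
  } else {
    mother_death_mo <- rep(Inf, n)
    father_death_mo <- rep(Inf, n)
  }

  is_controller <- runif(n) < cfg$controller_fraction
  target_n <- rep(NA_integer_, n)
  if (any(is_controller)) {
    draw <- cfg$target_distribution %||%
      function(k) 1L + rpois(k, cfg$target_mean - 1)
    tg <- as.integer(draw(sum(is_controller)))
    if (any(is.na(tg) | tg < 1)) {
      abort("`target_distribution` must return integer targets >= 1.")
    }
    target_n[is_controller] <- tg
  }
  twin_mult <- if (cfg$family_twin_log_sd > 0) {
    exp(rnorm(n, 0, cfg$family_twin_log_sd) - cfg$family_twin_log_sd^2 / 2)
  } else {
    rep(1, n)
  }

  # last month (since marriage) in which conception is biologically possible
  last_conception <- pmin(ster_mo, 12L * as.integer(cfg$max_wife_age)) - wife_mar_mo
  death_end <- pmin(mother_death_mo, father_death_mo)
  reactive <- cfg$stopping_rule == "reactive" && any(is_controller)

  max_t <- max(0L, max(pmin(last_conception, death_end - 1))) + cfg$gestation_months + 1L

  preg_due <- rep(NA_integer_, n)
  preg_twin <- logical(n)
  mz_share <- rep(0, n)  # per-pregnancy MZ share, set at conception
  next_susceptible <- rep(1L, n)
  parity <- integer(n)
  stopped <- logical(n)
  eventual_surv <- integer(n)
  alive_children <- integer(n)
  death_bucket <- if (reactive) vector("list", max_t + 170L) else NULL

  rec <- vector("list", max_t)

  decline_mo <- 12 * cfg$fecundability_decline_start

  for (t in seq_len(max_t)) {
    # deliveries due this month (mother must be alive)
    due <- which(!is.na(preg_due) & preg_due == t & mother_death_mo > t)
    if (length(due)) {
      tw <- preg_twin[due]
      k <- length(due)
      s1 <- sample(c("M", "F"), k, replace = TRUE)
      s2 <- rep(NA_character_, k)
      if (any(tw)) {
        mz <- runif(sum(tw)) < mz_share[due][tw]
        s2tw <- ifelse(mz, s1[tw], sample(c("M", "F"), sum(tw), replace = TRUE))
        s2[tw] <- s2tw
      }
      p1 <- ifelse(tw, cfg$theta_t, cfg$theta_s)
      v1 <- runif(k) < p1
      v2 <- rep(NA, k)
      v2[tw] <- runif(sum(tw)) < cfg$theta_t
      surv_add <- as.integer(v1) + ifelse(tw, as.integer(v2), 0L)

      rec[[t]] <- list(fam = due, month = rep(t, k), parity = parity[due],
                       age = (wife_mar_mo[due] + t) %/% 12L,
                       n = ifelse(tw, 2L, 1L),
                       s1 = s1, s2 = s2, v1 = v1, v2 = v2)

      parity[due] <- parity[due] + 1L
      eventual_surv[due] <- eventual_surv[due] + surv_add
      if (reactive) {
        alive_children[due] <- alive_children[due] + ifelse(tw, 2L, 1L)
        dying <- c(due[!v1], due[tw][!v2[tw]])
        if (length(dying)) {
          dm <- t + sample.int(168L, length(dying), replace = TRUE)
          for (i in seq_along(dying)) {
            death_bucket[[dm[i]]] <- c(death_bucket[[dm[i]]], dying[i])
          }
        }
      }
      # perfect-foresight controllers stop once children already born will
      # eventually reach the target
      if (!reactive) {
        hit <- due[is_controller[due] & eventual_surv[due] >= target_n[due]]
        stopped[hit] <- TRUE
      }
      pp <- pmax(1L, as.integer(round(rnorm(k, cfg$postpartum_mean, cfg$postpartum_sd))))
      next_susceptible[due] <- t + 1L + pp
      preg_due[due] <- NA_integer_
    }

    if (reactive && t <= length(death_bucket) && !is.null(death_bucket[[t]])) {
      for (f in death_bucket[[t]]) alive_children[f] <- alive_children[f] - 1L
    }

    # conceptions
    open <- is.na(preg_due) & !stopped & next_susceptible <= t &
      t <= last_conception & t < death_end
    if (reactive) {
      open <- open & !(is_controller & !is.na(target_n) &
                         alive_children >= target_n)
    }
    idx <- which(open)
    if (length(idx)) {
      age_mo <- wife_mar_mo[idx] + t
      frac <- pmin(1, pmax(0, (ster_mo[idx] - age_mo) /
                             pmax(1, ster_mo[idx] - decline_mo)))
      f <- cfg$fecundability * ifelse(age_mo <= decline_mo, 1, frac)
      conc <- idx[runif(length(idx)) < f]
      if (length(conc)) {
        age_yrs <- (wife_mar_mo[conc] + t) / 12
        p_twin <- pmin(1, pmax(0, twin_mult[conc] * (
          cfg$twin_base_rate +
            cfg$twin_age_gradient * (age_yrs - cfg$twin_ref_age) +
            cfg$twin_parity_gradient * parity[conc])))
        preg_twin[conc] <- runif(length(conc)) < p_twin
        mz_share[conc] <- ifelse(p_twin > 0,
                                 pmin(1, cfg$mz_twin_rate / p_twin), 0)
        preg_due[conc] <- t + cfg$gestation_months
      }
    }
  }

  censor <- function(mar_mo, death_mo) {
    age <- (mar_mo + death_mo) %/% 12L
    age[!is.finite(death_mo) | age > 80L] <- NA_integer_
    as.integer(age)
  }
  families <- tibble::tibble(
    family_id = seq_len(n),
    unit = cfg$unit,
    is_controller = is_controller,
    target_n = target_n,
    mother_age_at_death = censor(wife_mar_mo, mother_death_mo),
    father_age_at_death = censor(husb_mar_mo, father_death_mo)
  )

  rec <- rec[!vapply(rec, is.null, logical(1))]
  pull <- function(field) do.call(c, lapply(rec, `[[`, field))
  rec_fam <- pull("fam"); rec_month <- pull("month")
  ord <- order(rec_fam, rec_month)
  deliveries <- tibble::tibble(
    family_id = rec_fam[ord],
    delivery_index = pull("parity")[ord],
    mother_age = pull("age")[ord],
    months_since_marriage = rec_month[ord],
    n_children = pull("n")[ord],
    sex_1 = pull("s1")[ord],
    sex_2 = pull("s2")[ord],
    survives_1 = pull("v1")[ord],
    survives_2 = pull("v2")[ord]
  )
  if (nrow(deliveries) == 0) {
    deliveries <- tibble::tibble(
      family_id = integer(0), delivery_index = integer(0),
      mother_age = integer(0), months_since_marriage = integer(0),
      n_children = integer(0), sex_1 = character(0), sex_2 = character(0),
      survives_1 = logical(0), survives_2 = logical(0))
  }

  twin_cohort(families, deliveries)
}
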