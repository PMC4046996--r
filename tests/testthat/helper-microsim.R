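# Individual-level microsimulation oracle: simulates n_households single
# child households under exactly the cohort model's rules (event order
# fire -> injury -> severity -> background mortality -> alarm decay/repair;
# cycle-start rewards; event-cycle accrual of the severe decrement and the
# ongoing annual cost; discounting on the birth clock). Vectorised over
# households. Returns per-household quantities so Monte-Carlo standard
# errors can be formed.

microsim_households <- function(n_households, draw, p_start, life_table,
                                utility_norms, seed) {
  stopifnot(nrow(draw) == 1)
  set.seed(seed)
  u_age <- numeric(100)
  for (i in seq_len(nrow(utility_norms)))
    u_age[(utility_norms$age_lo[i]:utility_norms$age_hi[i]) + 1L] <-
      utility_norms$utility[i]
  qx_at <- function(a) life_table$qx[match(a, life_table$age)]
  splits <- list(
    func = unlist(draw[paste0("severity_split_func_",
                              c("minor", "moderate", "severe", "fatal"))]),
    nonfunc = unlist(draw[paste0("severity_split_nonfunc_",
                                 c("minor", "moderate", "severe", "fatal"))]))
  p_inj <- c(func = draw$p_injury_func, nonfunc = draw$p_injury_nonfunc)

  n <- n_households
  alarm_func <- stats::runif(n) < p_start
  alive <- rep(TRUE, n)
  severe <- rep(FALSE, n)
  qalys <- numeric(n)
  cost_injury_nhs <- numeric(n)
  cost_severe_annual <- numeric(n)
  cost_fatality <- numeric(n)
  cost_fire_op <- numeric(n)
  cost_fire_hh <- numeric(n)
  ev <- list(fires = numeric(n), minor = numeric(n), moderate = numeric(n),
             severe = numeric(n), fatal = numeric(n))
  r <- draw$r

  for (t in 0:4) {
    disc <- (1 + r)^(-t)
    # cycle-start rewards
    qalys <- qalys + disc * alive * (u_age[t + 1L] - draw$du_severe * severe)
    cost_severe_annual <- cost_severe_annual +
      disc * alive * severe * draw$c_severe_annual
    # fire -> injury -> severity
    fire <- alive & (stats::runif(n) < draw$p_fire)
    inj <- fire & (stats::runif(n) <
                     ifelse(alarm_func, p_inj["func"], p_inj["nonfunc"]))
    u <- stats::runif(n)
    cum_f <- cumsum(splits$func)
    cum_n <- cumsum(splits$nonfunc)
    sev_idx <- ifelse(alarm_func,
                      1L + (u > cum_f[1]) + (u > cum_f[2]) + (u > cum_f[3]),
                      1L + (u > cum_n[1]) + (u > cum_n[2]) + (u > cum_n[3]))
    sev_idx[!inj] <- 0L
    ev$fires <- ev$fires + fire
    ev$minor <- ev$minor + (sev_idx == 1L)
    ev$moderate <- ev$moderate + (sev_idx == 2L)
    ev$severe <- ev$severe + (sev_idx == 3L)
    ev$fatal <- ev$fatal + (sev_idx == 4L)
    cost_fire_op <- cost_fire_op + disc * fire * draw$c_fire_rescue
    cost_fire_hh <- cost_fire_hh + disc * fire * draw$c_property
    cost_injury_nhs <- cost_injury_nhs + disc *
      ((sev_idx == 1L) * draw$c_minor + (sev_idx == 2L) * draw$c_moderate +
         (sev_idx == 3L) * draw$c_severe_acute)
    cost_fatality <- cost_fatality + disc * (sev_idx == 4L) * draw$c_fatal_event
    new_severe <- (sev_idx == 3L) & !severe
    # event-cycle accruals for the newly severe
    qalys <- qalys - disc * draw$du_severe * new_severe
    cost_severe_annual <- cost_severe_annual +
      disc * new_severe * draw$c_severe_annual
    severe <- severe | new_severe
    alive[sev_idx == 4L] <- FALSE
    # background mortality, then alarm decay/repair
    alive <- alive & (stats::runif(n) >= qx_at(t))
    flip <- stats::runif(n)
    alarm_func <- ifelse(alarm_func, flip >= draw$d_decay,
                         flip < draw$d_repair)
  }

  life_years <- numeric(n)
  for (a in 5:99) {
    disc <- (1 + r)^(-a)
    qalys <- qalys + disc * alive * (u_age[a + 1L] - draw$du_severe * severe)
    cost_severe_annual <- cost_severe_annual +
      disc * alive * severe * draw$c_severe_annual
    life_years <- life_years + alive
    alive <- alive & (stats::runif(n) >= qx_at(a))
  }

  tibble::tibble(
    qalys = qalys,
    cost_NHS_PSS = cost_injury_nhs + cost_severe_annual,
    cost_other_public = cost_fire_op,
    cost_household = cost_fire_hh + cost_fatality,
    n_fires = ev$fires, n_minor = ev$minor, n_moderate = ev$moderate,
    n_severe = ev$severe, n_fatal = ev$fatal,
    life_years = life_years
  )
}

# compare a cohort expectation against the microsimulation mean within
# `k` Monte-Carlo standard errors (plus a hair of absolute slack for
# quantities whose sampling SD is exactly zero)
expect_within_mc_se <- function(cohort_value, sim_values, k = 4,
                                label = "quantity") {
  se <- stats::sd(sim_values) / sqrt(length(sim_values))
  tol <- k * se + 1e-12
  testthat::expect_lt(abs(mean(sim_values) - cohort_value), tol,
                      label = paste0(label, " |microsim - cohort|"))
}
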