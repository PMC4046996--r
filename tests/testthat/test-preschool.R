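test_that("a cycle with no fires, no decay and no mortality leaves the state unchanged", {
  d <- tiny_draws(p_fire = 0, d_decay = 0, d_repair = 0)
  st <- preschool_state(0.7)
  step <- step_preschool(st, d, qx = 0, u_age = 1)
  expect_equal(step$state, st)
  expect_equal(step$qalys, 1)
  expect_equal(sum(as.matrix(step$costs)), 0)
})

test_that("occupancy is conserved and dead is absorbing after any step", {
  set.seed(21)
  for (rep in 1:30) {
    occ <- runif(5)
    occ <- occ / sum(occ)
    st <- tibble::tibble(func_never = occ[1], nonfunc_never = occ[2],
                         func_post = occ[3], nonfunc_post = occ[4],
                         dead = occ[5])
    d <- tiny_draws(p_fire = runif(1, 0, 0.5), d_decay = runif(1),
                    d_repair = runif(1))
    step <- step_preschool(st, d, qx = runif(1, 0, 0.1), u_age = 0.9)
    expect_equal(rowSums(as.matrix(step$state)), 1, tolerance = 1e-10)
    expect_gte(step$state$dead, st$dead)  # absorbing
    expect_true(all(as.matrix(step$state) >= 0))
  }
  bad <- tibble::tibble(func_never = 0.5, nonfunc_never = 0.4,
                        func_post = 0, nonfunc_post = 0, dead = 0)
  expect_error(step_preschool(bad, tiny_draws(), 0, 1), "sum to 1")
})

test_that("one-cycle death mass matches exhaustive enumeration of the event tree", {
  # all-fatal severity split, everyone starts without a functioning alarm
  d <- tiny_draws(p_fire = 0.1, p_injury_nonfunc = 0.91,
                  d_decay = 0, d_repair = 0,
                  severity_split_nonfunc_minor = 0,
                  severity_split_nonfunc_moderate = 0,
                  severity_split_nonfunc_severe = 0,
                  severity_split_nonfunc_fatal = 1)
  st <- preschool_state(0)
  step <- step_preschool(st, d, qx = 0, u_age = 1)
  expect_equal(step$state$dead, 0.1 * 0.91)
  expect_equal(step$events$fatal, 0.091)

  # full enumeration oracle on a mixed state with background mortality
  d2 <- tiny_draws(p_fire = 0.2, d_decay = 0, d_repair = 0)
  qx <- 0.01
  orc_f <- oracle_one_cycle(0.6, "func", d2, qx)
  orc_n <- oracle_one_cycle(0.4, "nonfunc", d2, qx)
  expect_equal(orc_f$total_path_prob, 1, tolerance = 1e-12)
  st2 <- preschool_state(0.6)
  step2 <- step_preschool(st2, d2, qx = qx, u_age = 1)
  expect_equal(step2$state$dead, orc_f$dead + orc_n$dead, tolerance = 1e-12)
  expect_equal(step2$events$fatal,
               orc_f$events[["fatal"]] + orc_n$events[["fatal"]])
  expect_equal(step2$events$severe,
               orc_f$events[["severe"]] + orc_n$events[["severe"]])
  expect_equal(step2$state$func_post + step2$state$nonfunc_post,
               orc_f$new_severe * (1 - qx) + orc_n$new_severe * (1 - qx),
               tolerance = 1e-12)
})

test_that("five-cycle discounted QALYs follow the annuity closed forms", {
  lt <- flat_life_table(0)
  un <- flat_norms(1)
  d0 <- tiny_draws(p_fire = 0, r = 0)
  res0 <- run_preschool(1, d0, lt, un)
  expect_equal(res0$qalys, 5, tolerance = 1e-12)

  d <- tiny_draws(p_fire = 0, r = 0.035)
  res <- run_preschool(1, d, lt, un)
  expect_equal(res$qalys, sum(1.035^-(0:4)), tolerance = 1e-10)
  expect_equal(res$terminal_healthy, 1)
})

test_that("without decay or fires the alarm occupancy is frozen across cycles", {
  d <- tiny_draws(p_fire = 0, d_decay = 0, d_repair = 0)
  tr <- preschool_trace(0.65, d, flat_life_table(0), flat_norms(1))
  expect_equal(tr$func_never, rep(0.65, 6))
  expect_equal(tr$nonfunc_never, rep(0.35, 6))
  # and with decay but no repair, functioning mass decays geometrically
  d2 <- tiny_draws(p_fire = 0, d_decay = 0.1, d_repair = 0)
  tr2 <- preschool_trace(1, d2, flat_life_table(0), flat_norms(1))
  expect_equal(tr2$func_never, 0.9^(0:5), tolerance = 1e-12)
})

test_that("equal injury risk and severity by alarm state removes any alarm health effect", {
  d <- tiny_draws(p_injury_func = 0.91, p_injury_nonfunc = 0.91,
                  severity_split_func_minor = 0.65,
                  severity_split_func_moderate = 0.24,
                  severity_split_func_severe = 0.08,
                  severity_split_func_fatal = 0.03)
  lt <- life_table_fixture()
  un <- utility_norms_fixture()
  lo <- run_preschool(0.2, d, lt, un)
  hi <- run_preschool(0.9, d, lt, un)
  for (col in c("qalys", "n_minor", "n_moderate", "n_severe", "n_fatal",
                "terminal_healthy", "terminal_postsevere", "terminal_dead",
                "cost_injury_nhs", "cost_severe_annual"))
    expect_equal(lo[[col]], hi[[col]], tolerance = 1e-12,
                 label = paste("alarm-coverage invariance of", col))
})

test_that("lowering the functioning-alarm injury risk never hurts", {
  lt <- life_table_fixture()
  un <- utility_norms_fixture()
  set.seed(31)
  for (rep in 1:20) {
    p_hi <- runif(1, 0.2, 0.9)
    p_lo <- runif(1, 0, p_hi)
    hi <- run_preschool(0.8, tiny_draws(p_injury_func = p_hi), lt, un)
    lo <- run_preschool(0.8, tiny_draws(p_injury_func = p_lo), lt, un)
    expect_gte(lo$qalys, hi$qalys)
    expect_lte(lo$cost_injury_nhs, hi$cost_injury_nhs)
  }
})

test_that("a life table not covering ages 0-4 is rejected", {
  lt <- life_table_fixture()
  expect_error(run_preschool(0.8, tiny_draws(), lt[lt$age >= 2, ],
                             flat_norms(1)), "missing age")
})
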