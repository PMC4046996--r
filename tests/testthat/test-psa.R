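test_that("a small PSA run has the contracted shape and is seed-deterministic", {
  post <- effectiveness_posterior(n_draws = 10, seed = 2)
  psa1 <- run_psa(parameter_fixture(), post, n_draws = 10, seed = 4)
  psa2 <- run_psa(parameter_fixture(), post, n_draws = 10, seed = 4)
  expect_equal(nrow(psa1$outcomes), 70)
  expect_identical(psa1$outcomes, psa2$outcomes)
  expect_setequal(unique(psa1$outcomes$strategy_id), 1:7)
  expect_error(run_psa(parameter_fixture(), post, n_draws = 20, seed = 1),
               "paired")
})

test_that("a degenerate parameter table collapses the PSA to identical rows", {
  tab <- degenerate_table()
  def <- posterior_defaults()
  post <- effectiveness_posterior(sds = setNames(rep(0, 6), names(def$means)),
                                  n_draws = 8, seed = 1)
  psa <- run_psa(tab, post, n_draws = 8, seed = 1)
  per_strat <- split(psa$outcomes, psa$outcomes$strategy_id)
  for (s in per_strat) {
    expect_equal(length(unique(s$qalys)), 1)
    expect_equal(length(unique(s$cost_total)), 1)
  }
  means <- mean_outcomes(psa)
  one <- evaluate_strategy("E + FE", sample_draw(tab, seed = 99),
                           pi_k = post[["E + FE"]][1])
  expect_equal(means$qalys[means$label == "E + FE"], one$qalys)
  expect_equal(means$cost_total[means$label == "E + FE"], one$cost_total)
})

test_that("usual care is invariant to the effectiveness posterior", {
  p1 <- effectiveness_posterior(n_draws = 15, seed = 5)
  p2 <- effectiveness_posterior(n_draws = 15, seed = 77)
  a <- run_psa(parameter_fixture(), p1, n_draws = 15, seed = 3)
  b <- run_psa(parameter_fixture(), p2, n_draws = 15, seed = 3)
  uc <- function(x) x$outcomes[x$outcomes$strategy_id == 1, ]
  expect_identical(uc(a), uc(b))
  # while an active strategy does respond
  efe <- function(x) x$outcomes[x$outcomes$strategy_id == 3, ]
  expect_false(identical(efe(a)$cost_total, efe(b)$cost_total))
})

test_that("children per household scales child-level outcomes exactly", {
  d1 <- tiny_draws(h = 1)
  d18 <- tiny_draws(h = 1.8)
  pi_k <- 0.45
  o1 <- evaluate_strategy("E + FE", d1, pi_k)
  o18 <- evaluate_strategy("E + FE", d18, pi_k)
  expect_equal(o18$qalys, 1.8 * o1$qalys, tolerance = 1e-12)
  expect_equal(o18$cost_NHS_PSS, 1.8 * o1$cost_NHS_PSS, tolerance = 1e-12)
  expect_equal(o18$cost_intervention, o1$cost_intervention)
  expect_equal(o18$cost_other_public, o1$cost_other_public)  # per-fire cost
  expect_equal(o18$n_fatal, 1.8 * o1$n_fatal, tolerance = 1e-12)
  # household costs mix: property damage unscaled, fatality costs scaled
  d1h <- tiny_draws(h = 1, c_property = 0)
  d18h <- tiny_draws(h = 1.8, c_property = 0)
  expect_equal(evaluate_strategy("E + FE", d18h, pi_k)$cost_household,
               1.8 * evaluate_strategy("E + FE", d1h, pi_k)$cost_household,
               tolerance = 1e-12)
})

test_that("perspectives nest: NHS/PSS within public sector within extended household", {
  post <- effectiveness_posterior(n_draws = 12, seed = 6)
  run_with <- function(p)
    run_psa(parameter_fixture(), post, n_draws = 12, seed = 2,
            settings = psa_settings(perspective = p))$outcomes
  nhs <- run_with("NHS_PSS")
  pub <- run_with("public_sector")
  ext <- run_with("extended_household")
  expect_true(all(nhs$cost_total <= pub$cost_total))
  expect_true(all(pub$cost_total <= ext$cost_total))
  # the NHS/PSS perspective omits exactly the fire & rescue category
  expect_equal(pub$cost_total - nhs$cost_total, pub$cost_other_public)
  # the extended perspective adds exactly the household category
  expect_equal(ext$cost_total - pub$cost_total, ext$cost_household)
  # itemised categories always reconstruct the public-sector total
  expect_equal(pub$cost_total,
               pub$cost_intervention + pub$cost_NHS_PSS + pub$cost_other_public,
               tolerance = 1e-9)
})

test_that("zero costs and zero utilities give an all-zero outcome", {
  d <- tiny_draws(c_E = 0, c_FE = 0, c_F = 0, c_HI = 0, c_minor = 0,
                  c_moderate = 0, c_severe_acute = 0, c_fatal_event = 0,
                  c_severe_annual = 0, c_fire_rescue = 0, c_property = 0,
                  du_severe = 0)
  o <- evaluate_strategy("E + FE + F + HI", d, 0.5,
                         utility_norms = flat_norms(0))
  expect_equal(o$qalys, 0)
  expect_equal(o$cost_total, 0)
})

test_that("QALYs respond monotonically to effectiveness when the alarm protects", {
  d <- tiny_draws()  # p_injury_func 0.45 < p_injury_nonfunc 0.91
  q <- vapply(seq(0, 1, by = 0.2), function(p)
    evaluate_strategy("E", d, p)$qalys, numeric(1))
  expect_true(all(diff(q) >= 0))
})

test_that("PSA CSV round-trips with its metadata sidecar", {
  post <- effectiveness_posterior(n_draws = 5, seed = 8)
  psa <- run_psa(parameter_fixture(), post, n_draws = 5, seed = 8)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_psa(psa, tf)
  back <- read_psa(tf)
  expect_equal(back$outcomes, psa$outcomes, tolerance = 1e-12)
  expect_equal(back$settings$seed, 8)
  expect_equal(back$settings$perspective, "public_sector")
  g <- glance(psa)
  expect_equal(g$n_draws, 5)
  expect_equal(g$n_strategies, 7)
  expect_equal(nrow(tidy(psa)), 35)
})
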