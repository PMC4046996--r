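test_that("mean outcomes are plain arithmetic means", {
  q <- matrix(c(1, 3, 2, 2), ncol = 2)  # strategies: (1,3) and (2,2)
  cost <- matrix(c(10, 30, 5, 15), ncol = 2)
  out <- toy_outcomes(q, cost)
  m <- mean_outcomes(out)
  expect_equal(m$qalys, c(2, 2))
  expect_equal(m$cost_total, c(20, 10))

  # identical rows: mean equals any row
  out2 <- toy_outcomes(matrix(4, 6, 2), matrix(9, 6, 2))
  expect_equal(mean_outcomes(out2)$qalys, c(4, 4))

  # streaming-sum oracle at scale
  set.seed(12)
  qm <- matrix(rnorm(5000 * 3, 20, 2), ncol = 3)
  cm <- matrix(rlnorm(5000 * 3, 8, 0.5), ncol = 3)
  m3 <- mean_outcomes(toy_outcomes(qm, cm))
  stream <- function(x) { s <- 0; for (v in x) s <- s + v; s / length(x) }
  for (j in 1:3) {
    expect_equal(m3$qalys[j], stream(qm[, j]), tolerance = 1e-9)
    expect_equal(m3$cost_total[j], stream(cm[, j]), tolerance = 1e-9)
  }
})

test_that("icer division and sign semantics", {
  expect_equal(icer(777, 0.023), 777 / 0.023)  # 33,782.6...
  expect_equal(icer(0, 0.5), 0)
  expect_equal(icer(-10, 0.5), -20)
  expect_true(is.na(icer(5, 0)))
})

test_that("a single strategy is its own frontier with no ICER", {
  fr <- compute_frontier(tibble::tibble(label = "only", qalys = 1, cost = 5))
  expect_equal(fr$status, "frontier")
  expect_true(is.na(fr$icer))
})

test_that("frontier statuses agree with the gift-wrapping envelope oracle", {
  set.seed(99)
  for (rep in 1:200) {
    k <- sample(2:8, 1)
    q <- runif(k, 10, 20)
    cost <- runif(k, 100, 1000)
    fr <- compute_frontier(tibble::tibble(label = paste0("S", 1:k),
                                          qalys = q, cost = cost))
    oracle <- oracle_frontier_status(q, cost)
    got <- fr$status[match(paste0("S", 1:k), fr$label)]
    expect_identical(got, oracle)
    # ICERs strictly increase along the frontier
    ic <- fr$icer[!is.na(fr$icer)]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
    # statuses partition the set
    expect_equal(length(got), k)
  }
})

test_that("the frontier is invariant to cohort rescaling", {
  set.seed(5)
  q <- runif(6, 10, 20); cost <- runif(6, 100, 1000)
  f1 <- compute_frontier(tibble::tibble(label = paste0("S", 1:6),
                                        qalys = q, cost = cost))
  f2 <- compute_frontier(tibble::tibble(label = paste0("S", 1:6),
                                        qalys = 1000 * q, cost = 1000 * cost))
  expect_identical(f1$status, f2$status)
  expect_equal(f2$icer, f1$icer, tolerance = 1e-12)  # cost/QALY ratio unchanged
})

test_that("net monetary benefit follows threshold * QALY - cost", {
  out <- toy_outcomes(matrix(c(1, 2), 1), matrix(c(30000, 10), 1))
  n0 <- nmb(out, 0)
  expect_equal(n0$nmb, c(-30000, -10))
  n30 <- nmb(out, 30000)
  expect_equal(n30$nmb[1], 0)  # 1 QALY at cost 30,000, threshold 30,000
  expect_error(nmb(out, -5), ">= 0")
})

test_that("NMB ranking at a threshold matches the frontier choice for deterministic draws", {
  set.seed(14)
  for (rep in 1:50) {
    k <- sample(3:7, 1)
    q <- runif(k, 10, 20); cost <- runif(k, 1e3, 5e4)
    lam <- runif(1, 0, 5000)
    out <- toy_outcomes(matrix(q, 1), matrix(cost, 1))
    best_nmb <- which.max(lam * q - cost)
    fr <- compute_frontier(tibble::tibble(label = paste0("S", 1:k),
                                          qalys = q, cost = cost))
    # walk up the frontier while the ICER is below the threshold
    steps <- fr[fr$status == "frontier", ]
    chosen <- steps$label[max(which(is.na(steps$icer) | steps$icer <= lam))]
    expect_identical(paste0("S", best_nmb), chosen)
  }
})

test_that("acceptability probabilities are frequencies that sum to one", {
  # one draw: indicator vector
  out <- toy_outcomes(matrix(c(1, 2, 3), 1), matrix(c(0, 0, 0), 1))
  cc <- ceac(out, 1000)
  expect_equal(cc$probability, c(0, 0, 1))

  # hand-counted: A beats B in exactly 3 of 10 draws at lambda = 1
  qa <- c(5, 5, 5, 1, 1, 1, 1, 1, 1, 1)  # A wins first 3 draws
  qb <- rep(2, 10)
  out2 <- toy_outcomes(cbind(qa, qb), matrix(0, 10, 2), labels = c("A", "B"))
  cc2 <- ceac(out2, 1)
  expect_equal(cc2$probability[cc2$label == "A"], 0.3)
  expect_equal(cc2$probability[cc2$label == "B"], 0.7)

  # grid: columns sum to 1 everywhere, values in [0, 1]
  set.seed(3)
  out3 <- toy_outcomes(matrix(rnorm(200, 20), ncol = 4),
                       matrix(rlnorm(200, 7), ncol = 4))
  grid <- seq(0, 50000, by = 10000)
  cc3 <- ceac(out3, grid)
  sums <- tapply(cc3$probability, cc3$threshold, sum)
  expect_equal(as.vector(sums), rep(1, length(grid)), tolerance = 1e-9)
  expect_true(all(cc3$probability >= 0 & cc3$probability <= 1))

  # exact NMB ties go to the cheaper strategy
  out4 <- toy_outcomes(matrix(c(1, 1), 1), matrix(c(10, 5), 1),
                       labels = c("dear", "cheap"))
  cc4 <- ceac(out4, 0)  # NMB = -cost: cheap wins outright
  expect_equal(cc4$probability[cc4$label == "cheap"], 1)
  out5 <- toy_outcomes(matrix(c(2, 1), 1), matrix(c(10, 5), 1),
                       labels = c("dear", "cheap"))
  cc5 <- ceac(out5, 5)  # NMB tie (0, 0): cheaper strategy wins
  expect_equal(cc5$probability[cc5$label == "cheap"], 1)
})

test_that("EVPI is the expected gain of perfect information and never negative", {
  # no uncertainty: EVPI = 0
  out <- toy_outcomes(matrix(c(1, 1, 2, 2), 2), matrix(c(5, 5, 8, 8), 2))
  expect_equal(evpi(out, 1000)$evpi, 0)

  # two equiprobable draws with NMB (10, 0) and (0, 10): EVPI = 10 - 5 = 5
  out2 <- toy_outcomes(matrix(c(10, 0, 0, 10), 2), matrix(0, 2, 2))
  expect_equal(evpi(out2, 1)$evpi, 5)

  # random matrices match the explicit argmax oracle
  set.seed(41)
  for (rep in 1:25) {
    q <- matrix(rnorm(60, 20), ncol = 3)
    cost <- matrix(rlnorm(60, 7), ncol = 3)
    lam <- runif(1, 0, 4000)
    got <- evpi(toy_outcomes(q, cost), lam)$evpi
    expect_equal(got, oracle_evpi(q, cost, lam), tolerance = 1e-9)
    expect_gte(got, 0)
  }
})

test_that("population EVPI is a discounted sum over the decision horizon", {
  expect_equal(population_evpi(2, annual_population = 100, horizon_years = 1,
                               discount_rate = 0), 200)
  expect_equal(population_evpi(1, annual_population = 31000,
                               horizon_years = 10, discount_rate = 0.035),
               31000 * sum(1.035^-(0:9)), tolerance = 1e-12)
  expect_equal(population_evpi(0), 0)
  expect_gte(population_evpi(1, annual_population = 1, horizon_years = 1), 1)
})

test_that("evpi_curve and tidiers return well-formed tibbles", {
  set.seed(4)
  out <- toy_outcomes(matrix(rnorm(80, 20), ncol = 4),
                      matrix(rlnorm(80, 7), ncol = 4))
  curve <- evpi_curve(out, c(0, 1000, 2000))
  expect_equal(nrow(curve), 3)
  expect_true(all(curve$evpi >= 0))
  fr <- compute_frontier(mean_outcomes(out))
  expect_s3_class(tidy(fr), "tbl_df")
  g <- glance(fr)
  expect_equal(g$n_strategies, 4)
  expect_equal(g$n_frontier + g$n_dominated + g$n_extendedly_dominated, 4)
})
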