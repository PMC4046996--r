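# Deterministic hand-set parameter draws and degenerate tables used across
# the unit tests.

# one (or n) fully specified parameter-draw rows with overridable values
tiny_draws <- function(n = 1, ...) {
  base <- list(
    draw = seq_len(n),
    p_prev = 0.8, p_accept = 0.9, d_decay = 0.1, d_repair = 0.1,
    p_fire = 0.002, p_injury_func = 0.45, p_injury_nonfunc = 0.91,
    severity_split_func_minor = 0.74, severity_split_func_moderate = 0.20,
    severity_split_func_severe = 0.05, severity_split_func_fatal = 0.01,
    severity_split_nonfunc_minor = 0.65,
    severity_split_nonfunc_moderate = 0.24,
    severity_split_nonfunc_severe = 0.08,
    severity_split_nonfunc_fatal = 0.03,
    c_E = 10, c_FE = 25, c_F = 40, c_HI = 30,
    c_minor = 100, c_moderate = 1000, c_severe_acute = 30000,
    c_fatal_event = 5000, c_severe_annual = 2000,
    c_fire_rescue = 2000, c_property = 8000,
    du_severe = 0.15, r = 0.035, h = 1, cohort_size = 1e5
  )
  ov <- list(...)
  for (nm in names(ov)) base[[nm]] <- ov[[nm]]
  tibble::as_tibble(lapply(base, function(x) rep_len(x, n)))
}

# a parameter table in which every distribution is degenerate (fixed),
# matching tiny_draws() point values; severity splits as component rows
degenerate_table <- function(...) {
  vals <- tiny_draws(1, ...)
  nms <- setdiff(names(vals), "draw")
  tibble::tibble(
    name = nms,
    family = "fixed",
    hyperparameters = lapply(nms, function(nm) unname(vals[[nm]])),
    category = "none",
    source = "test point values"
  )
}

flat_life_table <- function(qx = 0) tibble::tibble(age = 0:99, qx = qx)

flat_norms <- function(u = 1) {
  tibble::tibble(age_lo = 0, age_hi = 99, utility = u)
}

# outcomes tibble builder for decision-analytics tests: q and cost are
# draws x strategies matrices
toy_outcomes <- function(q, cost, labels = NULL) {
  k <- ncol(q)
  labels <- labels %||% paste0("S", seq_len(k))
  purrr::map_dfr(seq_len(k), function(j) {
    tibble::tibble(strategy_id = j, label = labels[j],
                   draw = seq_len(nrow(q)),
                   qalys = q[, j], cost_total = cost[, j])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
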