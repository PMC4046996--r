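# The probabilistic sensitivity engine: compose tree -> pre-school ->
# lifetime for every (strategy, draw) pair, apply the children-per-household
# multiplier and the cost-perspective filter, and collect the draws x
# strategies outcome matrix.

#' Analysis settings
#'
#' @param perspective which cost categories enter `cost_total`:
#'   `"public_sector"` (NHS/PSS + other public sector, the base case),
#'   `"NHS_PSS"` (health and personal social care only), or
#'   `"extended_household"` (public sector plus household costs: property
#'   damage, fatality-related costs). Productivity costs are never included.
#'   The intervention's own delivery cost is part of every perspective.
#' @param cost_basis who incurs delivery costs, see [evaluate_tree()].
#' @param hr_postsevere hazard ratio on post-severe mortality, see
#'   [run_lifetime()].
#' @param equalise_severity if `TRUE`, the non-functioning-alarm severity
#'   split is replaced by the functioning-alarm split (used with the
#'   equal-injury-risk scenario to remove *all* alarm effect on health).
#' @return A list of class `psa_settings`.
#' @export
psa_settings <- function(perspective = c("public_sector", "NHS_PSS",
                                         "extended_household"),
                         cost_basis = c("accepters", "offered"),
                         hr_postsevere = 1,
                         equalise_severity = FALSE) {
  structure(list(perspective = match.arg(perspective),
                 cost_basis = match.arg(cost_basis),
                 hr_postsevere = hr_postsevere,
                 equalise_severity = equalise_severity),
            class = "psa_settings")
}

perspective_categories <- function(perspective) {
  switch(perspective,
         public_sector = c("intervention", "NHS_PSS", "other_public"),
         NHS_PSS = c("intervention", "NHS_PSS"),
         extended_household = c("intervention", "NHS_PSS", "other_public",
                                "household"),
         abort(paste0("unknown perspective: ", perspective)))
}

#' Evaluate one strategy across parameter draws
#'
#' Composes the three model stages for a strategy and returns per-draw
#' household-level outcomes. Child-level quantities (QALYs, injury and
#' fatality costs, ongoing severe-injury costs, event counts) are multiplied
#' by `h`, the number of children under five per household; household-level
#' quantities (delivery cost, fire & rescue attendance, property damage) are
#' not. `cost_total` sums the categories active under the settings'
#' perspective.
#'
#' @param strategy a strategy id, label or [strategies()] row.
#' @param draws parameter draws.
#' @param pi_k enablement probabilities (posterior column for this
#'   strategy), length 1 or `nrow(draws)`.
#' @param life_table,utility_norms model inputs.
#' @param settings a [psa_settings()] object.
#' @return A tibble per draw: `strategy_id`, `label`, `draw`, `qalys`,
#'   `cost_total`, itemised `cost_intervention`, `cost_NHS_PSS`,
#'   `cost_other_public`, `cost_household`, expected event counts and
#'   `life_years`.
#' @export
evaluate_strategy <- function(strategy, draws, pi_k,
                              life_table = life_table_fixture(),
                              utility_norms = utility_norms_fixture(),
                              settings = psa_settings()) {
  strat <- resolve_strategy(strategy)
  draws <- check_draws(draws)
  if (isTRUE(settings$equalise_severity)) draws <- equalise_severity(draws)
  tree <- evaluate_tree(strat, draws, pi_k, cost_basis = settings$cost_basis)
  pre <- run_preschool(tree, draws, life_table, utility_norms)
  life <- run_lifetime(pre, draws, life_table, utility_norms,
                       hr_postsevere = settings$hr_postsevere)
  h <- draws$h
  cost_cat <- tibble(
    intervention = tree$cost_intervention,
    NHS_PSS = h * (pre$cost_injury_nhs + pre$cost_severe_annual +
                     life$cost_severe_annual),
    other_public = pre$cost_fire_other_public,
    household = pre$cost_fire_household + h * pre$cost_fatality
  )
  active <- perspective_categories(settings$perspective)
  tibble(
    strategy_id = strat$id,
    label = strat$label,
    draw = if ("draw" %in% names(draws)) draws$draw else seq_len(nrow(draws)),
    qalys = h * (pre$qalys + life$qalys),
    cost_total = rowSums(cost_cat[active]),
    cost_intervention = cost_cat$intervention,
    cost_NHS_PSS = cost_cat$NHS_PSS,
    cost_other_public = cost_cat$other_public,
    cost_household = cost_cat$household,
    n_fires = pre$n_fires,
    n_minor = h * pre$n_minor, n_moderate = h * pre$n_moderate,
    n_severe = h * pre$n_severe, n_fatal = h * pre$n_fatal,
    life_years = h * life$life_years
  )
}

equalise_severity <- function(draws) {
  for (lab in severity_labels)
    draws[[paste0("severity_split_nonfunc_", lab)]] <-
      draws[[paste0("severity_split_func_", lab)]]
  draws
}

#' Run the probabilistic sensitivity analysis
#'
#' Samples one parameter draw per posterior row (draw `i` is paired with
#' posterior row `i`; no resampling) and evaluates every strategy on every
#' draw. Fully deterministic given `seed`.
#'
#' @param table a parameter table ([parameter_fixture()]).
#' @param posterior effectiveness posterior draws
#'   ([effectiveness_posterior()]); its row count sets the number of
#'   simulations (5,000 in the base case).
#' @param life_table,utility_norms model inputs.
#' @param n_draws number of parameter draws; must equal `nrow(posterior)`.
#' @param seed integer seed for parameter sampling.
#' @param settings a [psa_settings()] object.
#' @param strategy_set strategies to evaluate (default all seven).
#' @return An object of class `psa_result`: a list with `outcomes` (tibble,
#'   `n_draws` x strategies rows), `draws` (the sampled parameters) and
#'   `settings` (seed, counts, perspective, cohort size, scenario tag).
#' @examples
#' psa <- run_psa(parameter_fixture(), effectiveness_posterior(n_draws = 20),
#'                n_draws = 20, seed = 1)
#' mean_outcomes(psa)
#' @export
run_psa <- function(table, posterior,
                    life_table = life_table_fixture(),
                    utility_norms = utility_norms_fixture(),
                    n_draws = nrow(posterior), seed = 1L,
                    settings = psa_settings(),
                    strategy_set = strategies()) {
  validate_posterior_for(posterior, strategy_set)
  if (n_draws != nrow(posterior))
    abort(paste0("posterior has ", nrow(posterior), " draws but n_draws = ",
                 n_draws, "; one parameter draw is paired with one ",
                 "posterior row"))
  draws <- sample_draws(table, n_draws, seed)
  outcomes <- purrr::map_dfr(seq_len(nrow(strategy_set)), function(i) {
    strat <- strategy_set[i, ]
    evaluate_strategy(strat, draws, posterior[[strat$label]],
                      life_table, utility_norms, settings)
  })
  structure(
    list(outcomes = outcomes, draws = draws,
         settings = c(unclass(settings),
                      list(seed = seed, n_draws = n_draws,
                           cohort_size = draws$cohort_size[1],
                           h = draws$h[1], scenario = "base"))),
    class = "psa_result")
}

validate_posterior_for <- function(posterior, strategy_set) {
  miss <- setdiff(strategy_set$label, colnames(posterior))
  if (length(miss))
    abort(paste0("posterior missing strategy column(s): ",
                 paste(miss, collapse = ", ")))
  m <- as.matrix(posterior[strategy_set$label])
  if (anyNA(m) || any(m < 0) || any(m > 1))
    abort("posterior entries must lie in [0, 1]")
  invisible(posterior)
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$settings
  cat("<psa_result> ", s$n_draws, " draws x ",
      length(unique(x$outcomes$strategy_id)), " strategies",
      " (seed ", s$seed, ", scenario ", s$scenario,
      ", perspective ", s$perspective, ")\n", sep = "")
  print(mean_outcomes(x), ...)
  invisible(x)
}

#' Write / read PSA outcomes as CSV (+ JSON metadata sidecar)
#'
#' The CSV holds one row per (draw, strategy) with all outcome columns; the
#' sidecar `<path>.json` records seed and settings so a run can be
#' reconstructed and compared byte-for-byte.
#'
#' @param psa a `psa_result`.
#' @param path CSV file path.
#' @return `read_psa()` returns a `psa_result` (without the parameter
#'   draws); `write_psa()` returns `path` invisibly.
#' @export
write_psa <- function(psa, path) {
  stopifnot(inherits(psa, "psa_result"))
  readr::write_csv(psa$outcomes, path)
  jsonlite::write_json(psa$settings, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_psa
#' @export
read_psa <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  outcomes <- readr::read_csv(path, col_types = readr::cols(
    label = "c", .default = "d"), progress = FALSE)
  meta_path <- paste0(path, ".json")
  settings <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(outcomes = as_tibble(outcomes), draws = NULL,
                 settings = settings),
            class = "psa_result")
}
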