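# The base case, the five one-way sensitivity analyses and the cost
# perspectives, as declarative parameter-table overrides run end-to-end.

#' The named analysis scenarios
#'
#' Base case plus the five one-way sensitivity analyses:
#' \describe{
#'   \item{base}{no overrides}
#'   \item{SA1}{smoke-alarm prevalence reduced from 80% to 50%}
#'   \item{SA2}{probability of accepting the intervention reduced from 90%
#'     to 50%}
#'   \item{SA3}{decay/repair of safety equipment reduced from 0.1 to zero
#'     (both directions)}
#'   \item{SA4}{children under five per household increased from 1 to 1.8}
#'   \item{SA5}{same probability of child injury following a fire for
#'     functioning and non-functioning alarm households, 0.91 (severity
#'     splits stay alarm-specific unless `equalise_severity` is set)}
#' }
#'
#' @return A tibble with columns `scenario` and `overrides` (list-column of
#'   named fixed values).
#' @export
scenario_definitions <- function() {
  tibble(
    scenario = c("base", "SA1", "SA2", "SA3", "SA4", "SA5"),
    overrides = list(
      list(),
      list(p_prev = 0.5),
      list(p_accept = 0.5),
      list(d_decay = 0, d_repair = 0),
      list(h = 1.8),
      list(p_injury_func = 0.91, p_injury_nonfunc = 0.91)
    )
  )
}

#' Apply a scenario's overrides to a parameter table
#'
#' Replaces each overridden parameter's distribution with a degenerate
#' (`fixed`) spec at the scenario value; everything else is untouched, so
#' two runs sharing a seed differ only through the overrides.
#'
#' @param table a parameter table.
#' @param scenario a scenario name from [scenario_definitions()].
#' @return The overridden parameter table.
#' @examples
#' tab <- apply_scenario(parameter_fixture(), "SA1")
#' tab[tab$name == "p_prev", ]
#' @export
apply_scenario <- function(table, scenario) {
  defs <- scenario_definitions()
  hit <- match(scenario, defs$scenario)
  if (is.na(hit))
    abort(paste0("unknown scenario '", scenario, "'; valid names: ",
                 paste(defs$scenario, collapse = ", ")))
  ov <- defs$overrides[[hit]]
  for (nm in names(ov)) {
    i <- match(nm, table$name)
    if (is.na(i)) abort(paste0("override targets missing parameter: ", nm))
    table$family[i] <- "fixed"
    table$hyperparameters[[i]] <- ov[[nm]]
    table$source[i] <- paste0("scenario ", scenario, " override")
  }
  validate_parameter_table(table)
  table
}

#' Run a scenario end-to-end
#'
#' Applies the scenario overrides, runs the full PSA, and computes the
#' frontier, acceptability curves and EVPI. All randomness is controlled by
#' `seed` (parameter draws) and the posterior object passed in (or the
#' seed-derived default).
#'
#' @param scenario a scenario name from [scenario_definitions()].
#' @param table a parameter table (default the synthetic fixture).
#' @param posterior effectiveness posterior; defaults to the synthetic
#'   posterior with `n_draws` rows generated from `seed`.
#' @param life_table,utility_norms model inputs (default fixtures).
#' @param n_draws number of PSA draws (default 5,000).
#' @param seed integer seed.
#' @param settings a [psa_settings()] object (perspective etc.).
#' @param thresholds willingness-to-pay grid for the CEAC.
#' @param evpi_threshold threshold at which EVPI is evaluated (default
#'   GBP 30,000/QALY).
#' @return An object of class `scenario_result`: list with elements `psa`,
#'   `frontier`, `ceac`, `evpi` (per-decision and population) and
#'   `scenario`.
#' @examples
#' res <- run_scenario("SA1", n_draws = 50, seed = 1)
#' res$frontier
#' @export
run_scenario <- function(scenario = "base",
                         table = parameter_fixture(),
                         posterior = NULL,
                         life_table = life_table_fixture(),
                         utility_norms = utility_norms_fixture(),
                         n_draws = 5000L, seed = 1L,
                         settings = psa_settings(),
                         thresholds = seq(0, 100000, by = 2500),
                         evpi_threshold = 30000) {
  table <- apply_scenario(table, scenario)
  if (is.null(posterior))
    posterior <- effectiveness_posterior(n_draws = n_draws,
                                         seed = seed + 1000000L)
  psa <- run_psa(table, posterior, life_table, utility_norms,
                 n_draws = n_draws, seed = seed, settings = settings)
  psa$settings$scenario <- scenario
  frontier <- compute_frontier(mean_outcomes(psa))
  acc <- ceac(psa, thresholds)
  ev <- evpi(psa, evpi_threshold)
  ev$population_evpi <- population_evpi(ev$evpi,
                                        discount_rate = psa$draws$r[1])
  structure(list(scenario = scenario, psa = psa, frontier = frontier,
                 ceac = acc, evpi = ev),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> scenario:", x$scenario, "\n\nFrontier:\n")
  print(as_tibble(x$frontier))
  cat("\nEVPI at GBP", format(x$evpi$threshold, big.mark = ","),
      "per QALY:", signif(x$evpi$evpi, 4), "per household\n")
  invisible(x)
}

#' Frontier report in the conventional incremental-analysis layout
#'
#' One row per strategy with expected QALYs and costs, incremental values
#' along the frontier, the ICER (or dominance status) and, when a PSA is
#' supplied, the probability of being cost-effective at the given
#' thresholds.
#'
#' @param frontier a `cea_frontier`.
#' @param psa optionally, the `psa_result` the frontier came from.
#' @param thresholds thresholds for the probability columns (default
#'   GBP 30,000 and 50,000).
#' @return A tibble, one row per strategy in effectiveness order.
#' @export
frontier_report <- function(frontier, psa = NULL,
                            thresholds = c(30000, 50000)) {
  rep_tab <- as_tibble(frontier)
  if (!is.null(psa)) {
    for (lam in thresholds) {
      cc <- ceac(psa, lam)
      rep_tab[[paste0("p_ce_", lam)]] <-
        cc$probability[match(rep_tab$label, cc$label)]
    }
  }
  rep_tab
}
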