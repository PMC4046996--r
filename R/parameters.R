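# Declarative uncertain-parameter specs, fixture generation, CSV round-trip
# and probabilistic sampling. Every model input flows through the parameter
# table so scenario overrides and PSA sampling share one mechanism.

#' Names every downstream model stage requires in a parameter table
#'
#' @return Character vector of required parameter names.
#' @export
required_parameters <- function() {
  c("p_prev", "p_accept", "d_decay", "d_repair", "p_fire",
    "p_injury_func", "p_injury_nonfunc",
    "severity_split_func", "severity_split_nonfunc",
    "c_E", "c_FE", "c_F", "c_HI",
    "c_minor", "c_moderate", "c_severe_acute", "c_fatal_event",
    "c_severe_annual", "du_severe", "r", "h", "cohort_size")
}

severity_labels <- c("minor", "moderate", "severe", "fatal")

cost_categories <- c("none", "NHS_PSS", "other_public", "household",
                     "productivity")

dist_families <- c("fixed", "beta", "gamma", "lognormal", "normal",
                   "dirichlet")

# family -> required hyperparameter count (NA = >= 2, dirichlet)
family_arity <- c(fixed = 1L, beta = 2L, gamma = 2L, lognormal = 2L,
                  normal = 2L, dirichlet = NA_integer_)

param_row <- function(name, family, hyper, category, source) {
  tibble(name = name, family = family, hyperparameters = list(hyper),
         category = category, source = source)
}

#' Synthetic base-case parameter table
#'
#' Builds the package's self-contained parameter fixture. Quantities printed
#' in the base case — alarm prevalence 0.80, intervention acceptance 0.90,
#' alarm decay and repair 0.1/year, probability of child injury given a fire
#' in a non-functioning-alarm household 0.91, discount rate 3.5%, one child
#' under five per household, reporting cohort of 100,000 — are encoded as
#' `fixed` (degenerate) distributions. Everything else (fire risk, injury
#' risk with a functioning alarm, severity splits, unit costs, the severe
#' injury utility decrement) is a *synthetic fixture value*, chosen to be
#' epidemiologically plausible for a UK-like setting, not sourced from any
#' published input table: house fires are rare (~2 per 1,000 households per
#' year), a functioning alarm roughly halves the injury risk given a fire,
#' and severe plus fatal outcomes are a small fraction of injuries.
#'
#' @return A parameter-table tibble with columns `name`, `family`,
#'   `hyperparameters` (list-column of numeric vectors), `category`
#'   (cost-category tag) and `source`.
#' @examples
#' parameter_fixture()
#' @export
parameter_fixture <- function() {
  fx <- "synthetic fixture"
  bind_rows(
    param_row("p_prev", "fixed", 0.80, "none", "base case: 80% prevalence"),
    param_row("p_accept", "fixed", 0.90, "none", "base case: 90% acceptance"),
    param_row("d_decay", "fixed", 0.10, "none", "base case decay/repair factor"),
    param_row("d_repair", "fixed", 0.10, "none", "base case decay/repair factor"),
    param_row("p_fire", "beta", c(4, 1996), "none", fx),
    param_row("p_injury_func", "beta", c(45, 55), "none", fx),
    param_row("p_injury_nonfunc", "fixed", 0.91, "none",
              "base case: injury risk, non-functioning alarm"),
    param_row("severity_split_func", "dirichlet", c(148, 40, 10, 2), "none", fx),
    param_row("severity_split_nonfunc", "dirichlet", c(130, 48, 16, 6), "none", fx),
    param_row("c_E", "gamma", c(16, 1.6), "other_public", fx),
    param_row("c_FE", "gamma", c(25, 1.0), "other_public", fx),
    param_row("c_F", "gamma", c(16, 0.4), "other_public", fx),
    param_row("c_HI", "gamma", c(36, 1.2), "other_public", fx),
    param_row("c_minor", "gamma", c(16, 0.16), "NHS_PSS", fx),
    param_row("c_moderate", "gamma", c(16, 0.016), "NHS_PSS", fx),
    param_row("c_severe_acute", "lognormal",
              c(log(30000) - 0.5 * 0.25^2, 0.25), "NHS_PSS", fx),
    param_row("c_fatal_event", "gamma", c(25, 0.005), "household", fx),
    param_row("c_severe_annual", "gamma", c(16, 0.008), "NHS_PSS", fx),
    param_row("c_fire_rescue", "gamma", c(25, 0.0125), "other_public", fx),
    param_row("c_property", "lognormal",
              c(log(8000) - 0.5 * 0.3^2, 0.3), "household", fx),
    param_row("du_severe", "beta", c(15, 85), "none", fx),
    param_row("r", "fixed", 0.035, "none", "standard annual discount rate"),
    param_row("h", "fixed", 1, "none", "base case: children under 5 per household"),
    param_row("cohort_size", "fixed", 100000, "none", "reporting scale")
  )
}

validate_spec_row <- function(name, family, hyper) {
  if (!family %in% dist_families)
    abort(paste0("parameter '", name, "': unknown distribution family '",
                 family, "'"))
  arity <- family_arity[[family]]
  if (is.na(arity)) {
    if (length(hyper) < 2)
      abort(paste0("parameter '", name,
                   "': dirichlet requires at least 2 hyperparameters"))
  } else if (length(hyper) != arity) {
    abort(paste0("parameter '", name, "': family '", family, "' requires ",
                 arity, " hyperparameter(s), got ", length(hyper)))
  }
  if (family %in% c("beta", "gamma", "dirichlet") && any(hyper <= 0))
    abort(paste0("parameter '", name, "': '", family,
                 "' hyperparameters must be positive"))
  if (family %in% c("lognormal", "normal") && hyper[2] < 0)
    abort(paste0("parameter '", name, "': scale hyperparameter must be >= 0"))
  invisible(TRUE)
}

#' Validate a parameter table
#'
#' Checks column structure, distribution families and hyperparameter arity,
#' cost-category tags, and that every name in [required_parameters()] is
#' present.
#'
#' @param table a parameter-table tibble (see [parameter_fixture()]).
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending parameter.
#' @export
validate_parameter_table <- function(table) {
  needed <- c("name", "family", "hyperparameters", "category", "source")
  miss_col <- setdiff(needed, names(table))
  if (length(miss_col))
    abort(paste0("parameter table missing column(s): ",
                 paste(miss_col, collapse = ", ")))
  if (anyDuplicated(table$name))
    abort(paste0("duplicated parameter name: ",
                 table$name[duplicated(table$name)][1]))
  bad_cat <- setdiff(unique(table$category), cost_categories)
  if (length(bad_cat))
    abort(paste0("unknown cost category: ", paste(bad_cat, collapse = ", ")))
  purrr::pwalk(list(table$name, table$family, table$hyperparameters),
               validate_spec_row)
  # a severity split is satisfied either by its dirichlet parent row or by
  # four fixed per-component rows (the degenerate-table form)
  satisfied <- function(nm) {
    if (nm %in% table$name) return(TRUE)
    grepl("^severity_split", nm) &&
      all(paste0(nm, "_", severity_labels) %in% table$name)
  }
  missing <- Filter(Negate(satisfied), required_parameters())
  if (length(missing))
    abort(paste0("missing parameter: ", paste(missing, collapse = ", ")))
  invisible(table)
}

#' Read / write a parameter table as CSV
#'
#' The on-disk format has columns `name,family,hyperparameters,category,source`
#' with hyperparameters semicolon-separated. Values survive the round trip to
#' full double precision.
#'
#' @param table a parameter-table tibble.
#' @param path file path.
#' @return `read_parameter_table()` returns a validated parameter-table
#'   tibble; `write_parameter_table()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_parameter_table(parameter_fixture(), tf)
#' tab <- read_parameter_table(tf)
#' @export
write_parameter_table <- function(table, path) {
  validate_parameter_table(table)
  out <- table %>%
    mutate(hyperparameters = purrr::map_chr(
      .data$hyperparameters,
      ~ paste(sprintf("%.17g", .x), collapse = ";")))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  needed <- c("name", "family", "hyperparameters", "category", "source")
  miss <- setdiff(needed, names(raw))
  if (length(miss))
    abort(paste0("parameter CSV missing column(s): ",
                 paste(miss, collapse = ", ")))
  tab <- raw %>%
    mutate(hyperparameters = purrr::map(
      strsplit(.data$hyperparameters, ";", fixed = TRUE),
      function(x) {
        v <- suppressWarnings(as.numeric(x))
        if (anyNA(v)) abort("non-numeric hyperparameter in parameter CSV")
        v
      })) %>%
    as_tibble()
  validate_parameter_table(tab)
  tab
}

# declared support by parameter name; guards mis-specified hyperparameters
support_check <- function(name, x) {
  prob_like <- grepl("^(p_|d_)", name) || name == "du_severe" ||
    grepl("^severity_split", name)
  if (prob_like && (any(x < 0) || any(x > 1)))
    abort(paste0("parameter '", name, "': sampled value outside [0, 1]"))
  if (grepl("^c_", name) && any(x < 0))
    abort(paste0("parameter '", name, "': sampled cost is negative"))
  if (name == "r" && any(x < 0)) abort("discount rate r must be >= 0")
  if (name == "h" && any(x < 1)) abort("children per household h must be >= 1")
  invisible(TRUE)
}

sample_family <- function(family, hyper, n) {
  switch(family,
    fixed = rep(hyper[1], n),
    beta = rbeta(n, hyper[1], hyper[2]),
    gamma = rgamma(n, shape = hyper[1], rate = hyper[2]),
    lognormal = rlnorm(n, meanlog = hyper[1], sdlog = hyper[2]),
    normal = rnorm(n, mean = hyper[1], sd = hyper[2]),
    abort(paste0("unsupported family: ", family))
  )
}

#' Sample parameter draws for probabilistic analysis
#'
#' Draws `n_draws` independent realisations of every parameter in the table.
#' Scalar families (`fixed`, `beta`, `gamma`, `lognormal`, `normal`) become
#' one column each; `dirichlet` parameters expand into one column per
#' component (for the 4-component severity splits these are suffixed
#' `_minor`, `_moderate`, `_severe`, `_fatal`), summing to 1 by construction.
#' Sampling is fully determined by `seed`; `fixed` parameters return their
#' value exactly.
#'
#' @param table a validated parameter table.
#' @param n_draws number of draws.
#' @param seed integer seed controlling all sampling.
#' @return A tibble with `n_draws` rows: a `draw` index column plus one
#'   column per scalar parameter / dirichlet component.
#' @examples
#' draws <- sample_draws(parameter_fixture(), n_draws = 100, seed = 1)
#' @export
sample_draws <- function(table, n_draws, seed) {
  validate_parameter_table(table)
  stopifnot(n_draws >= 1)
  withr_seed(seed)
  cols <- list(draw = seq_len(n_draws))
  for (i in seq_len(nrow(table))) {
    nm <- table$name[i]
    fam <- table$family[i]
    hyper <- table$hyperparameters[[i]]
    if (fam == "dirichlet") {
      k <- length(hyper)
      g <- matrix(rgamma(n_draws * k, shape = rep(hyper, each = n_draws),
                         rate = 1), nrow = n_draws)
      g <- g / rowSums(g)
      suffix <- if (k == 4L) severity_labels else as.character(seq_len(k))
      for (j in seq_len(k)) {
        cn <- paste0(nm, "_", suffix[j])
        support_check(nm, g[, j])
        cols[[cn]] <- g[, j]
      }
    } else {
      x <- sample_family(fam, hyper, n_draws)
      support_check(nm, x)
      cols[[nm]] <- x
    }
  }
  as_tibble(cols)
}

#' @rdname sample_draws
#' @export
sample_draw <- function(table, seed) sample_draws(table, n_draws = 1L, seed = seed)

# set.seed without clobbering the caller's RNG state
withr_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed))
  invisible(seed)
}

draw_columns <- function() {
  c("p_prev", "p_accept", "d_decay", "d_repair", "p_fire",
    "p_injury_func", "p_injury_nonfunc",
    paste0("severity_split_func_", severity_labels),
    paste0("severity_split_nonfunc_", severity_labels),
    "c_E", "c_FE", "c_F", "c_HI", "c_minor", "c_moderate", "c_severe_acute",
    "c_fatal_event", "c_severe_annual", "du_severe", "r", "h", "cohort_size")
}

check_draws <- function(draws) {
  miss <- setdiff(draw_columns(), names(draws))
  if (length(miss))
    abort(paste0("draws tibble missing parameter column(s): ",
                 paste(miss, collapse = ", ")))
  # optional per-fire cost columns default to zero if the table omitted them
  for (opt in c("c_fire_rescue", "c_property"))
    if (!opt %in% names(draws)) draws[[opt]] <- 0
  for (st in c("func", "nonfunc")) {
    s <- rowSums(draws[paste0("severity_split_", st, "_", severity_labels)])
    if (any(abs(s - 1) > 1e-12))
      abort(paste0("severity split (", st, ") does not sum to 1"))
  }
  draws
}
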