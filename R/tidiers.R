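# broom-style accessors for the fitted/derived objects.

#' Tidy a PSA result
#'
#' @param x a `psa_result`.
#' @param ... unused.
#' @return The per-(draw, strategy) outcomes tibble.
#' @export
tidy.psa_result <- function(x, ...) x$outcomes

#' @rdname tidy.psa_result
#' @export
glance.psa_result <- function(x, ...) {
  s <- x$settings
  tibble(n_draws = s$n_draws,
         n_strategies = length(unique(x$outcomes$strategy_id)),
         seed = s$seed, scenario = s$scenario %||% "base",
         perspective = s$perspective, h = s$h %||% NA_real_,
         cohort_size = s$cohort_size %||% NA_real_)
}

#' Tidy a cost-effectiveness frontier
#'
#' @param x a `cea_frontier`.
#' @param ... unused.
#' @return The frontier tibble (label, qalys, cost, status, increments,
#'   ICER).
#' @export
tidy.cea_frontier <- function(x, ...) {
  class(x) <- setdiff(class(x), "cea_frontier")
  as_tibble(x)
}

#' @rdname tidy.cea_frontier
#' @export
glance.cea_frontier <- function(x, ...) {
  tibble(n_strategies = nrow(x),
         n_frontier = sum(x$status == "frontier"),
         n_dominated = sum(x$status == "dominated"),
         n_extendedly_dominated = sum(x$status == "extendedly_dominated"),
         max_icer = suppressWarnings(max(x$icer, na.rm = TRUE)))
}

#' Tidy acceptability curves / EVPI curves
#'
#' @param x a `cea_ceac` or `cea_evpi`.
#' @param ... unused.
#' @return The underlying tibble.
#' @export
tidy.cea_ceac <- function(x, ...) {
  class(x) <- setdiff(class(x), "cea_ceac")
  as_tibble(x)
}

#' @rdname tidy.cea_ceac
#' @export
tidy.cea_evpi <- function(x, ...) {
  class(x) <- setdiff(class(x), "cea_evpi")
  as_tibble(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
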