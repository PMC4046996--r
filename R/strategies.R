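#' The seven smoke-alarm promotion strategies
#'
#' Returns the comparator set evaluated by the model: usual care plus six
#' active interventions built from four components — education (`E`),
#' free/low-cost equipment (`FE`), equipment fitting (`F`) and home safety
#' inspection (`HI`).
#'
#' @return A tibble with one row per strategy and columns
#'   \describe{
#'     \item{id}{integer 1..7, the conventional strategy numbering}
#'     \item{label}{display label, e.g. `"E + FE"`}
#'     \item{components}{list-column of character vectors, subset of
#'       `c("E", "FE", "F", "HI")`; empty for usual care}
#'     \item{n_components}{number of components, a crude complexity measure}
#'   }
#' @examples
#' strategies()
#' @export
strategies <- function() {
  comp <- list(
    character(0),
    "E",
    c("E", "FE"),
    c("E", "FE", "HI"),
    c("E", "FE", "F"),
    c("E", "HI"),
    c("E", "FE", "F", "HI")
  )
  tibble(
    id = 1:7,
    label = c("UC", "E", "E + FE", "E + FE + HI", "E + FE + F",
              "E + HI", "E + FE + F + HI"),
    components = comp,
    n_components = lengths(comp)
  )
}

#' @rdname strategies
#' @format NULL
strategy_components <- c("E", "FE", "F", "HI")

#' Resolve a strategy given by id, label or row
#'
#' @param strategy an integer id in 1..7, a label such as `"E + FE"`, or a
#'   one-row tibble as returned by [strategies()].
#' @return A one-row strategy tibble.
#' @keywords internal
resolve_strategy <- function(strategy) {
  strat <- strategies()
  if (is.data.frame(strategy)) {
    if (nrow(strategy) != 1L || !all(c("id", "components") %in% names(strategy)))
      abort("`strategy` data frame must be a single row of strategies()")
    bad <- setdiff(unlist(strategy$components), strategy_components)
    if (length(bad))
      abort(paste0("unknown strategy component: ", paste(bad, collapse = ", ")))
    return(as_tibble(strategy))
  }
  if (is.numeric(strategy)) {
    if (!strategy %in% strat$id) abort("strategy id must be in 1..7")
    return(strat[strat$id == strategy, ])
  }
  if (is.character(strategy)) {
    key <- gsub("\\s", "", strategy)
    hit <- match(key, gsub("\\s", "", strat$label))
    if (is.na(hit)) abort(paste0("unknown strategy label: ", strategy))
    return(strat[hit, ])
  }
  abort("`strategy` must be an id, a label or a strategies() row")
}
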