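# Background mortality and age-specific utility norms. Both are plain
# tables: a life table (age, qx) covering ages 0-99 and a piecewise-constant
# utility-norm step function by age band.

#' Synthetic period life table, ages 0 to 99
#'
#' A UK-like synthetic life table: elevated infant mortality, very low
#' child/young-adult mortality, and a Gompertz-type exponential increase in
#' adulthood. Fixture values, not official national statistics.
#'
#' @return A tibble with columns `age` (0..99) and `qx` (annual probability
#'   of death between exact ages `age` and `age + 1`).
#' @examples
#' lt <- life_table_fixture()
#' plot(lt$age, lt$qx, log = "y", type = "l")
#' @export
life_table_fixture <- function() {
  age <- 0:99
  qx <- pmin(0.7, pmax(2e-5 * exp(0.1 * age), 1.2e-4))
  qx[age == 0] <- 0.0045
  tibble(age = age, qx = qx)
}

#' Read and validate a life table CSV
#'
#' @param path CSV with columns `age`, `qx`.
#' @param ages required age coverage (default 0..99).
#' @return A validated life-table tibble.
#' @export
read_life_table <- function(path, ages = 0:99) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lt <- readr::read_csv(path, col_types = readr::cols(age = "i", qx = "d"),
                        progress = FALSE)
  validate_life_table(lt, ages)
}

validate_life_table <- function(lt, ages = 0:99) {
  if (!all(c("age", "qx") %in% names(lt)))
    abort("life table must have columns age, qx")
  miss <- setdiff(ages, lt$age)
  if (length(miss))
    abort(paste0("life table missing age(s): ",
                 paste(utils::head(miss, 5), collapse = ", ")))
  if (any(lt$qx < 0 | lt$qx > 1)) abort("life-table qx outside [0, 1]")
  as_tibble(lt[order(lt$age), ])
}

#' Synthetic age-band utility norms
#'
#' Population-average health-related quality-of-life weights as a step
#' function of age, shaped like published UK population norms (declining
#' from ~0.94 in childhood to ~0.73 beyond age 75). Fixture values.
#'
#' @return A tibble with columns `age_lo`, `age_hi`, `utility`.
#' @export
utility_norms_fixture <- function() {
  tibble(
    age_lo = c(0, 25, 35, 45, 55, 65, 75),
    age_hi = c(24, 34, 44, 54, 64, 74, 99),
    utility = c(0.94, 0.93, 0.91, 0.85, 0.80, 0.78, 0.73)
  )
}

#' Read and validate age-band utility norms
#'
#' @param path CSV with columns `age_lo`, `age_hi`, `utility`.
#' @return A validated utility-norms tibble covering ages 0..99 with
#'   non-overlapping bands.
#' @export
read_utility_norms <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  un <- readr::read_csv(path, col_types = readr::cols(
    age_lo = "i", age_hi = "i", utility = "d"), progress = FALSE)
  validate_utility_norms(un)
}

validate_utility_norms <- function(un) {
  if (!all(c("age_lo", "age_hi", "utility") %in% names(un)))
    abort("utility norms must have columns age_lo, age_hi, utility")
  if (any(un$utility < 0 | un$utility > 1))
    abort("utility norms outside [0, 1]")
  covered <- unlist(purrr::map2(un$age_lo, un$age_hi, seq))
  if (anyDuplicated(covered)) abort("utility-norm age bands overlap")
  miss <- setdiff(0:99, covered)
  if (length(miss))
    abort(paste0("utility norms missing age(s): ",
                 paste(utils::head(miss, 5), collapse = ", ")))
  as_tibble(un[order(un$age_lo), ])
}

# utility norm per single year of age, as a length-100 vector (age 0..99)
utility_by_age <- function(norms) {
  norms <- validate_utility_norms(norms)
  u <- numeric(100)
  for (i in seq_len(nrow(norms)))
    u[(norms$age_lo[i]:norms$age_hi[i]) + 1L] <- norms$utility[i]
  u
}
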