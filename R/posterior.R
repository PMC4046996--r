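# Synthetic stand-in for the effectiveness evidence-synthesis posterior:
# correlated draws of per-strategy log-odds ratios, mapped through the
# inverse logit against a baseline, giving pi_k — the probability that a
# non-owning, accepting household ends up with a functioning alarm under
# strategy k. Usual care carries no intervention effect, so its column is
# identically zero.

#' Default hyperparameters of the synthetic effectiveness posterior
#'
#' Mean log-odds ratios for the six active strategies are ordered by
#' intervention complexity (component count), reflecting the finding of the
#' effectiveness synthesis literature that more multifaceted interventions
#' have a higher probability of increasing functioning-alarm possession.
#' All values are synthetic fixture choices.
#'
#' @return A list with elements `means` (named log-odds ratios, active
#'   strategies only), `sds`, `correlation` (6 x 6 exchangeable, rho = 0.6)
#'   and `baseline_logodds` (enablement log-odds under usual-care-like
#'   conditions, `qlogis(0.15)`).
#' @export
posterior_defaults <- function() {
  active <- strategies() %>% filter(.data$id != 1L)
  means <- setNames(c(0.4, 0.9, 1.2, 1.3, 0.8, 1.6), active$label)
  sds <- setNames(rep(0.3, 6), active$label)
  corr <- matrix(0.6, 6, 6, dimnames = list(active$label, active$label))
  diag(corr) <- 1
  list(means = means, sds = sds, correlation = corr,
       baseline_logodds = qlogis(0.15))
}

#' Generate a synthetic effectiveness posterior
#'
#' Draws `n_draws` samples of correlated log-odds ratios from a multivariate
#' normal (the conventional scale for network-meta-analysis output), adds the
#' baseline log-odds and applies the inverse logit, yielding enablement
#' probabilities `pi_k` in `[0, 1]` for each active strategy. The usual-care
#' column is identically 0.
#'
#' @param means named numeric of per-strategy mean log-odds ratios (active
#'   strategies, in [strategies()] order).
#' @param sds standard deviations on the log-odds scale, `>= 0`.
#' @param correlation correlation matrix across active strategies; must be
#'   positive definite.
#' @param baseline_logodds baseline enablement log-odds added before the
#'   inverse logit.
#' @param n_draws number of posterior draws (default 5,000, matching the
#'   Monte-Carlo simulation count used downstream).
#' @param seed integer seed.
#' @return A tibble `[n_draws x 7]` with one named column per strategy label.
#' @examples
#' post <- effectiveness_posterior(n_draws = 100, seed = 1)
#' colMeans(post)
#' @export
effectiveness_posterior <- function(means = posterior_defaults()$means,
                                    sds = posterior_defaults()$sds,
                                    correlation = posterior_defaults()$correlation,
                                    baseline_logodds = posterior_defaults()$baseline_logodds,
                                    n_draws = 5000L,
                                    seed = 20140516L) {
  k <- length(means)
  stopifnot(length(sds) == k, all(sds >= 0))
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      any(abs(diag(correlation) - 1) > 1e-12))
    abort("`correlation` must be symmetric with unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    abort("`correlation` is not positive definite")
  sigma <- diag(sds, k) %*% correlation %*% diag(sds, k)
  withr_seed(seed)
  lor <- MASS::mvrnorm(n_draws, mu = means, Sigma = sigma)
  if (n_draws == 1L) lor <- matrix(lor, nrow = 1)
  pi_k <- plogis(baseline_logodds + lor)
  out <- cbind(UC = rep(0, n_draws), pi_k)
  colnames(out) <- strategies()$label
  as_tibble(as.data.frame(out, check.names = FALSE))
}

validate_posterior <- function(post) {
  labels <- strategies()$label
  if (!identical(colnames(post), labels))
    abort(paste0("posterior must have exactly the 7 strategy columns: ",
                 paste(labels, collapse = ", ")))
  if (nrow(post) == 0) abort("no draws in posterior")
  m <- as.matrix(post)
  if (anyNA(m)) abort("posterior contains missing values (ragged rows?)")
  if (any(m < 0) || any(m > 1)) abort("posterior entries must lie in [0, 1]")
  if (any(post$UC != 0)) abort("usual-care posterior column must be all zero")
  invisible(post)
}

#' Read / write effectiveness posterior draws as CSV
#'
#' One named column per strategy (7 columns); values survive the round trip
#' to full double precision.
#'
#' @param post a posterior tibble from [effectiveness_posterior()].
#' @param path file path.
#' @return `read_posterior()` returns a validated posterior tibble;
#'   `write_posterior()` returns `path` invisibly.
#' @export
write_posterior <- function(post, path) {
  validate_posterior(post)
  readr::write_csv(post, path)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1L)
  if (!length(first)) abort("no draws in posterior file")
  post <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = "d"),
                    progress = FALSE))
  validate_posterior(post)
  post
}
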