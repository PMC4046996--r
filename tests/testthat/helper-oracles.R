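# Independent oracles, deliberately implemented by different routes than
# the package code they check.

# Frontier oracle: pairwise strict dominance plus a gift-wrapping walk along
# the lower-right convex envelope (minimum incremental slope at each step),
# instead of the package's iterative extended-dominance deletion.
oracle_frontier_status <- function(q, cost) {
  n <- length(q)
  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i && ((q[j] > q[i] && cost[j] <= cost[i]) ||
                 (q[j] >= q[i] && cost[j] < cost[i]) ||
                 (q[j] == q[i] && cost[j] == cost[i] && j < i))
    }, logical(1)))
  }, logical(1))
  start <- which(cost == min(cost))
  if (length(start) > 1) start <- start[which.max(q[start])]
  frontier <- start
  cur <- start
  repeat {
    ahead <- which(q > q[cur])
    if (!length(ahead)) break
    slope <- (cost[ahead] - cost[cur]) / (q[ahead] - q[cur])
    best <- ahead[slope == min(slope)]
    if (length(best) > 1) best <- best[which.max(q[best])]
    frontier <- c(frontier, best)
    cur <- best
  }
  status <- rep("extendedly_dominated", n)
  status[dominated] <- "dominated"
  status[frontier] <- "frontier"
  status
}

# EVPI oracle: explicit per-draw argmax loop
oracle_evpi <- function(q, cost, threshold) {
  netb <- threshold * q - cost
  perfect <- mean(vapply(seq_len(nrow(netb)),
                         function(i) max(netb[i, ]), numeric(1)))
  current <- max(vapply(seq_len(ncol(netb)),
                        function(j) mean(netb[, j]), numeric(1)))
  perfect - current
}

# exhaustive enumeration of the one-cycle pre-school event tree for a
# single alarm state: returns expected end-of-cycle masses and event counts
oracle_one_cycle <- function(mass, alarm, draw, qx) {
  p_inj <- if (alarm == "func") draw$p_injury_func else draw$p_injury_nonfunc
  split <- unname(unlist(draw[paste0("severity_split_", alarm, "_",
                                     c("minor", "moderate", "severe",
                                       "fatal"))]))
  p_fire <- draw$p_fire
  paths <- list(
    list(p = 1 - p_fire, outcome = "none"),
    list(p = p_fire * (1 - p_inj), outcome = "fire_only"),
    list(p = p_fire * p_inj * split[1], outcome = "minor"),
    list(p = p_fire * p_inj * split[2], outcome = "moderate"),
    list(p = p_fire * p_inj * split[3], outcome = "severe"),
    list(p = p_fire * p_inj * split[4], outcome = "fatal")
  )
  dead_fire <- mass * p_fire * p_inj * split[4]
  alive <- mass - dead_fire
  list(
    total_path_prob = sum(vapply(paths, `[[`, numeric(1), "p")),
    dead = dead_fire + alive * qx,
    alive = alive * (1 - qx),
    new_severe = mass * p_fire * p_inj * split[3],
    events = c(fires = mass * p_fire,
               minor = mass * p_fire * p_inj * split[1],
               moderate = mass * p_fire * p_inj * split[2],
               severe = mass * p_fire * p_inj * split[3],
               fatal = dead_fire)
  )
}
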