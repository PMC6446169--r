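# Independent frontier oracle: a strategy is on the cost-effectiveness
# frontier iff it wins the net-monetary-benefit contest at some
# willingness-to-pay (the cheapest strategy wins as wtp -> 0). Candidate
# thresholds are taken between consecutive pairwise slopes.
oracle_frontier_set <- function(cost, qaly) {
  k <- length(cost)
  slopes <- c()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    dq <- qaly[j] - qaly[i]
    if (dq != 0) slopes <- c(slopes, (cost[j] - cost[i]) / dq)
  }
  s <- sort(unique(slopes[slopes > 0]))
  lams <- c(s / 2, s * 2, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            max(c(s, 1)) * 10)
  winners <- unique(vapply(lams, function(l) {
    nmb <- l * qaly - cost
    best <- which(nmb == max(nmb))
    best[which.min(cost[best])]
  }, integer(1)))
  sort(unique(c(winners, which(cost == min(cost))[1])))
}

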