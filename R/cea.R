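# Cost-effectiveness summary: incremental frontier with strict and extended
# dominance, net monetary benefit, and acceptability curves.

as_strategy_df <- function(results) {
  if (is.data.frame(results)) {
    stopifnot(all(c("strategy", "cost", "qaly") %in% names(results)))
    df <- results[, c("strategy", "cost", "qaly")]
  } else {
    df <- do.call(rbind, lapply(results, function(r) {
      data.frame(strategy = r$strategy, cost = r$mean_cost, qaly = r$mean_qaly,
                 stringsAsFactors = FALSE)
    }))
  }
  df$declared <- seq_len(nrow(df))
  df
}

#' Build the incremental cost-effectiveness frontier
#'
#' Orders strategies by mean cost, marks strictly dominated entries (at
#' least as costly and no more effective than some alternative), iteratively
#' removes extendedly dominated entries (those whose incremental
#' cost-effectiveness ratio to the previous frontier entry is at least the
#' next entry's), and computes ICERs along the surviving chain, each
#' referent to the next least costly nondominated option. ICERs along a
#' valid frontier are strictly increasing with effectiveness.
#'
#' @param results List of `cea_strategy_result` objects, or a data frame
#'   with columns `strategy`, `cost`, `qaly`.
#' @return A `cea_frontier` data frame: strategy, mean cost and QALYs,
#'   status (`reference`, `on_frontier`, `dominated`,
#'   `extendedly_dominated`), incremental cost/QALYs and ICER (frontier
#'   entries only).
#' @export
build_frontier <- function(results) {
  df <- as_strategy_df(results)
  k <- nrow(df)
  stopifnot(k >= 1)
  status <- rep("on_frontier", k)

  # exact (cost, qaly) duplicates: keep the earliest declared, flag the rest
  dup_key <- paste(df$cost, df$qaly)
  if (anyDuplicated(dup_key)) {
    message("identical (cost, QALY) pairs: tie broken by declared strategy order")
    status[duplicated(dup_key)] <- "dominated"
  }
  for (i in seq_len(k)) {
    if (status[i] != "on_frontier") next
    dominated <- any(df$cost <= df$cost[i] & df$qaly >= df$qaly[i] &
                       (df$cost < df$cost[i] | df$qaly > df$qaly[i]))
    if (dominated) status[i] <- "dominated"
  }
  # extended dominance on the cost-ordered nondominated chain
  repeat {
    idx <- which(status == "on_frontier")
    idx <- idx[order(df$cost[idx], df$qaly[idx])]
    if (length(idx) < 3) break
    c_ <- df$cost[idx]; q_ <- df$qaly[idx]
    icer <- (c_[-1] - c_[-length(c_)]) / (q_[-1] - q_[-length(q_)])
    viol <- which(icer[-length(icer)] >= icer[-1])
    if (!length(viol)) break
    status[idx[viol[1] + 1]] <- "extendedly_dominated"
  }
  idx <- which(status == "on_frontier")
  idx <- idx[order(df$cost[idx], df$qaly[idx])]
  status[idx[1]] <- "reference"

  out <- data.frame(strategy = df$strategy, mean_cost = df$cost,
                    mean_qaly = df$qaly, status = status,
                    incr_cost = NA_real_, incr_qaly = NA_real_,
                    icer = NA_real_, stringsAsFactors = FALSE)
  if (length(idx) > 1) {
    for (j in 2:length(idx)) {
      i <- idx[j]; prev <- idx[j - 1]
      out$incr_cost[i] <- df$cost[i] - df$cost[prev]
      out$incr_qaly[i] <- df$qaly[i] - df$qaly[prev]
      out$icer[i] <- out$incr_cost[i] / out$incr_qaly[i]
    }
  }
  class(out) <- c("cea_frontier", "data.frame")
  out
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`: the strategy maximizing net monetary benefit at a
#' willingness-to-pay threshold is the optimal one at that threshold.
#'
#' @param cost Cost in USD.
#' @param qaly Effectiveness in QALYs.
#' @param wtp Willingness-to-pay threshold in USD/QALY, nonnegative.
#' @return Net monetary benefit in USD.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("willingness-to-pay must be nonnegative")
  wtp * qaly - cost
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the fraction of PSA iterations in
#' which each strategy attains the maximal net monetary benefit. Ties are
#' broken toward the cheaper strategy (and then declared order), so the
#' probabilities sum to exactly 1 at every threshold.
#'
#' @param cost,qaly Iteration-by-strategy matrices of mean cost and QALYs.
#' @param wtp_grid Vector of willingness-to-pay thresholds.
#' @param strategies Strategy names; defaults to the matrix column names.
#' @return A `cea_ceac` data frame: `wtp` plus one probability column per
#'   strategy.
#' @export
ceac <- function(cost, qaly, wtp_grid, strategies = colnames(cost)) {
  cost <- as.matrix(cost); qaly <- as.matrix(qaly)
  stopifnot(nrow(cost) >= 1, length(wtp_grid) >= 1,
            all(dim(cost) == dim(qaly)))
  k <- ncol(cost)
  if (is.null(strategies)) strategies <- paste0("strategy_", seq_len(k))
  prob <- matrix(0, length(wtp_grid), k)
  ties_seen <- FALSE
  for (w in seq_along(wtp_grid)) {
    nmb <- net_monetary_benefit(cost, qaly, wtp_grid[w])
    rowmax <- do.call(pmax, as.data.frame(nmb))
    best <- nmb == rowmax
    if (any(rowSums(best) > 1)) ties_seen <- TRUE
    score <- ifelse(best, -cost, -Inf)  # among winners prefer the cheaper
    pick <- max.col(score, ties.method = "first")
    prob[w, ] <- tabulate(pick, k) / nrow(cost)
  }
  if (ties_seen)
    message("net-monetary-benefit ties broken toward the cheaper strategy")
  out <- data.frame(wtp = wtp_grid)
  out[strategies] <- as.data.frame(prob)
  class(out) <- c("cea_ceac", "data.frame")
  out
}

#' @export
print.cea_frontier <- function(x, ...) {
  cat("Cost-effectiveness frontier\n")
  y <- data.frame(
    strategy = x$strategy,
    cost = sprintf("$%.0f", x$mean_cost),
    QALY = sprintf("%.4f", x$mean_qaly),
    incr_cost = ifelse(is.na(x$incr_cost), "-", sprintf("$%.0f", x$incr_cost)),
    incr_QALY = ifelse(is.na(x$incr_qaly), "-", sprintf("%.4f", x$incr_qaly)),
    ICER = ifelse(is.na(x$icer), x$status, sprintf("$%.0f/QALY", x$icer)))
  print(y, row.names = FALSE)
  invisible(x)
}
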