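# Incremental cost-effectiveness ranking: strict and extended dominance,
# ICERs along the efficiency frontier, and net monetary benefit.

#' Incremental cost-effectiveness ratio between two strategies
#'
#' (cost_b - cost_a) / (qaly_b - qaly_a). Returns `NA` when the QALY
#' difference is zero (the ratio is undefined, not an error). A negative
#' ICER is ambiguous on its own — it arises both when b dominates a and
#' when a dominates b — so interpret it together with the dominance
#' status from [rank_strategies()].
#'
#' @param cost_a,qaly_a Cost and QALYs of the first strategy.
#' @param cost_b,qaly_b Cost and QALYs of the second strategy.
#' @return Scalar ICER in money per QALY, or `NA`.
#' @export
icer <- function(cost_a, qaly_a, cost_b, qaly_b) {
  d_e <- qaly_b - qaly_a
  if (d_e == 0) return(NA_real_)
  (cost_b - cost_a) / d_e
}

#' Net monetary benefit
#'
#' NMB = WTP x QALY - cost, the linearisation of the ICER decision rule
#' that underlies acceptability curves. Vectorised over strategies and
#' willingness-to-pay values (recycled).
#'
#' @param cost,qaly Strategy cost and QALYs.
#' @param wtp Willingness-to-pay per QALY (>= 0).
#' @return Numeric NMB.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(is.na(wtp)) || any(wtp < 0)) abort_invalid("`wtp` must be >= 0")
  if (any(is.na(cost)) || any(cost < 0)) abort_invalid("`cost` must be >= 0")
  wtp * qaly - cost
}

# B is weakly dominated by A: A costs no more, yields no fewer QALYs,
# and is strictly better in at least one coordinate.
dominates <- function(cost_a, qaly_a, cost_b, qaly_b) {
  cost_a <= cost_b & qaly_a >= qaly_b & (cost_a < cost_b | qaly_a > qaly_b)
}

#' Rank strategies with strict and extended dominance
#'
#' Sorts strategies by ascending cost (ties by descending QALY), labels
#' every strategy dominated by another (weak dominance: no worse on both
#' coordinates, strictly better on one) as `dominated`, then removes any
#' remaining strategy whose ICER against the previous frontier member
#' exceeds the ICER to the next one (`extendedly-dominated`, iterated to
#' convergence). Surviving strategies form the efficiency frontier; each
#' non-reference survivor gets an ICER against the previous frontier
#' member. Dominated strategies keep their incremental cost and effect
#' against the reference so a two-strategy comparison reads like a
#' published ranking table, but no ICER is reported for them — the
#' status column carries the verdict.
#'
#' @param results Data frame with columns `strategy`, `cost`, `qaly`
#'   (one row per strategy, distinct names), e.g. from
#'   [evaluate_strategies()].
#' @return A `cea_ranking`: a tibble with `strategy`, `cost`, `qaly`,
#'   `incremental_cost`, `incremental_qaly`, `icer`, `status` (one of
#'   `reference`, `non-dominated`, `dominated`, `extendedly-dominated`).
#' @export
rank_strategies <- function(results) {
  results <- as_tibble(results)
  req <- c("strategy", "cost", "qaly")
  if (!all(req %in% names(results))) {
    abort_invalid("`results` needs columns strategy, cost, qaly")
  }
  if (nrow(results) < 1) abort_invalid("at least one strategy is required")
  if (anyDuplicated(results$strategy)) abort_invalid("duplicate strategy names")
  if (any(results$cost < 0)) abort_invalid("strategy costs must be >= 0")

  df <- results %>%
    arrange(.data$cost, dplyr::desc(.data$qaly)) %>%
    mutate(status = NA_character_,
           incremental_cost = NA_real_, incremental_qaly = NA_real_,
           icer = NA_real_)

  # strict (weak) dominance against every other strategy
  for (i in seq_len(nrow(df))) {
    others <- setdiff(seq_len(nrow(df)), i)
    if (any(dominates(df$cost[others], df$qaly[others],
                      df$cost[i], df$qaly[i]))) {
      df$status[i] <- "dominated"
    }
  }

  # extended dominance on the survivors, iterated to convergence
  frontier <- which(is.na(df$status))
  repeat {
    if (length(frontier) < 3) break
    icers <- vapply(seq_along(frontier)[-1], function(k) {
      a <- frontier[k - 1]; b <- frontier[k]
      icer(df$cost[a], df$qaly[a], df$cost[b], df$qaly[b])
    }, numeric(1))
    # interior point k is extendedly dominated if its incoming ICER
    # exceeds its outgoing ICER
    drop_k <- NA_integer_
    for (k in seq_len(length(icers) - 1)) {
      inc <- icers[k]; out <- icers[k + 1]
      if (!is.na(inc) && !is.na(out) && inc > out) { drop_k <- k + 1; break }
    }
    if (is.na(drop_k)) break
    df$status[frontier[drop_k]] <- "extendedly-dominated"
    frontier <- frontier[-drop_k]
  }

  df$status[frontier[1]] <- "reference"
  if (length(frontier) > 1) df$status[frontier[-1]] <- "non-dominated"

  ref <- frontier[1]
  for (k in seq_along(frontier)[-1]) {
    a <- frontier[k - 1]; b <- frontier[k]
    df$incremental_cost[b] <- df$cost[b] - df$cost[a]
    df$incremental_qaly[b] <- df$qaly[b] - df$qaly[a]
    df$icer[b] <- icer(df$cost[a], df$qaly[a], df$cost[b], df$qaly[b])
  }
  dom <- which(df$status %in% c("dominated", "extendedly-dominated"))
  df$incremental_cost[dom] <- df$cost[dom] - df$cost[ref]
  df$incremental_qaly[dom] <- df$qaly[dom] - df$qaly[ref]

  structure(
    df %>% select("strategy", "cost", "qaly", "incremental_cost",
                  "incremental_qaly", "icer", "status"),
    class = c("cea_ranking", class(df))
  )
}

#' @export
print.cea_ranking <- function(x, ...) {
  cat("Cost-effectiveness ranking (costs and ICER to 2 decimals)\n")
  shown <- as_tibble(x) %>%
    mutate(across(c("cost", "qaly", "incremental_cost",
                    "incremental_qaly", "icer"), ~ round(.x, 2)))
  print(shown, n = Inf)
  invisible(x)
}

#' @describeIn rank_strategies Plain tibble of the ranking.
#' @param x A `cea_ranking`.
#' @param ... Unused.
#' @method tidy cea_ranking
#' @export
tidy.cea_ranking <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @describeIn rank_strategies One-row summary: frontier size, the
#'   cost-minimising and QALY-maximising strategies, and whether any
#'   strategy was dominated.
#' @method glance cea_ranking
#' @export
glance.cea_ranking <- function(x, ...) {
  tibble(
    n_strategies = nrow(x),
    n_frontier = sum(x$status %in% c("reference", "non-dominated")),
    any_dominated = any(x$status %in% c("dominated", "extendedly-dominated")),
    cheapest = x$strategy[which.min(x$cost)],
    most_effective = x$strategy[which.max(x$qaly)]
  )
}

#' @describeIn rank_strategies Cost-effectiveness plane with the
#'   efficiency frontier drawn through non-dominated strategies.
#' @param object A `cea_ranking`.
#' @method autoplot cea_ranking
#' @export
autoplot.cea_ranking <- function(object, ...) {
  df <- tidy(object)
  frontier <- df %>%
    filter(.data$status %in% c("reference", "non-dominated")) %>%
    arrange(.data$qaly)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$qaly, y = .data$cost)) +
    ggplot2::geom_line(data = frontier, colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$strategy),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "QALYs", y = "Cost (USD)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}
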