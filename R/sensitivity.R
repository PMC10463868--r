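# Deterministic (one-way / tornado) and probabilistic (Monte Carlo,
# acceptability curve) sensitivity analysis over a cea_model.
#
# Parameter targets address the model by path:
#   utility:<strategy>:<state>      a state utility
#   cost:<strategy>:<state>         a per-cycle state cost
#   upfront:<strategy>              the one-off cycle-0 cost
#   transition:<strategy>:<from>:<to>  one transition probability
#   row:<strategy>:<from>           a whole transition row (PSA only)

#' Describe one uncertain model parameter
#'
#' @param name Parameter label (used on tornado bars and in reports).
#' @param target Target path into the model (see Details in
#'   [draw_parameters()]).
#' @param low,high Range for one-way sensitivity analysis.
#' @param distribution PSA distribution: `"fixed"`, `"beta"`, `"gamma"`,
#'   or `"dirichlet_row"`.
#' @param mean,sd Moments for beta/gamma (method-of-moments matched);
#'   default `mean` is the model's base value.
#' @param concentration Numeric vector of Dirichlet concentrations for
#'   `dirichlet_row` targets (one per state in row order).
#' @return One-row tibble (a parameter table row); bind rows to build a
#'   parameter table.
#' @export
param_spec <- function(name, target, low = NA_real_, high = NA_real_,
                       distribution = "fixed", mean = NA_real_,
                       sd = NA_real_, concentration = NULL) {
  distribution <- match.arg(distribution,
                            c("fixed", "beta", "gamma", "dirichlet_row"))
  tibble(name = name, target = target, low = low, high = high,
         distribution = distribution, mean = mean, sd = sd,
         concentration = list(concentration))
}

#' Read a parameter table from CSV
#'
#' Columns `name,target,base,low,high,distribution,mean,sd,concentration`
#' (`base` is informational; `concentration` is a `;`-separated list for
#' `dirichlet_row` rows).
#'
#' @param path CSV path.
#' @return Parameter table tibble.
#' @export
read_param_specs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(concentration = readr::col_character()))
  req <- c("name", "target", "distribution")
  if (!all(req %in% names(df))) {
    abort_config("parameter CSV needs name, target, distribution columns")
  }
  conc <- if ("concentration" %in% names(df)) {
    lapply(df$concentration, function(s) {
      if (is.na(s) || s == "") NULL else as.numeric(strsplit(s, ";")[[1]])
    })
  } else {
    rep(list(NULL), nrow(df))
  }
  df$concentration <- conc
  for (col in c("low", "high", "mean", "sd")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  df[c("name", "target", "low", "high", "distribution", "mean", "sd",
       "concentration")]
}

parse_target <- function(target) {
  parts <- strsplit(target, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  ok <- switch(kind,
    utility = length(parts) == 3, cost = length(parts) == 3,
    upfront = length(parts) == 2,
    transition = length(parts) == 4, row = length(parts) == 3,
    FALSE)
  if (!isTRUE(ok)) {
    abort_config(sprintf("cannot parse parameter target `%s`", target))
  }
  list(kind = kind, strategy = parts[2],
       state = if (kind %in% c("utility", "cost")) parts[3],
       from = if (kind %in% c("transition", "row")) parts[3],
       to = if (kind == "transition") parts[4])
}

check_target <- function(model, tg) {
  if (!tg$strategy %in% names(model$strategies)) {
    abort_config(sprintf("target strategy `%s` not in the model", tg$strategy))
  }
  states <- model$spec$states$name
  for (s in c(tg$state, tg$from, tg$to)) {
    if (!is.null(s) && !s %in% states) {
      abort_config(sprintf("target state `%s` not in the model", s))
    }
  }
}

get_target <- function(model, target) {
  tg <- parse_target(target)
  check_target(model, tg)
  st <- model$strategies[[tg$strategy]]
  switch(tg$kind,
    utility = unname(st$payoffs$utility[tg$state]),
    cost = unname(st$payoffs$cost[tg$state]),
    upfront = st$payoffs$upfront,
    transition = unname(st$transition[tg$from, tg$to]),
    row = st$transition[tg$from, ])
}

# Assign a value to a target. Scalar transition targets renormalise the
# remaining non-death entries of the row proportionally, keeping the
# death probability fixed so the LTF-death-equality rule is preserved.
set_target <- function(model, target, value) {
  tg <- parse_target(target)
  check_target(model, tg)
  st <- model$strategies[[tg$strategy]]
  death <- model$spec$states$name[model$spec$states$absorbing]
  if (tg$kind == "utility") {
    st$payoffs$utility[tg$state] <- value
  } else if (tg$kind == "cost") {
    if (value < 0) abort_config("state costs must be >= 0")
    st$payoffs$cost[tg$state] <- value
  } else if (tg$kind == "upfront") {
    if (value < 0) abort_config("upfront cost must be >= 0")
    st$payoffs$upfront <- value
  } else if (tg$kind == "transition") {
    if (tg$to == death) {
      abort_config(paste0("perturbing a death-column entry would break the ",
                          "cohort death-rate assumption; vary `death_prob` ",
                          "targets through whole-row parameters instead"))
    }
    if (value < 0 || value > 1) abort_config("transition probabilities lie in [0,1]")
    row <- st$transition[tg$from, ]
    p_death <- row[death]
    others <- setdiff(names(row), c(death, tg$to))
    budget <- 1 - p_death - value
    if (budget < -1e-12) {
      abort_config("transition value leaves no probability for the rest of the row")
    }
    old_others <- sum(row[others])
    if (old_others > 0) {
      row[others] <- row[others] * (budget / old_others)
    } else if (budget > 1e-12) {
      abort_config("cannot renormalise a row whose other entries are all zero")
    }
    row[tg$to] <- value
    st$transition[tg$from, ] <- row
  } else { # row
    if (length(value) != ncol(st$transition)) {
      abort_config("row target value must cover every state")
    }
    if (any(value < 0) || abs(sum(value) - 1) > 1e-9) {
      abort_config("row target value must be a probability row summing to 1")
    }
    st$transition[tg$from, ] <- value
  }
  model$strategies[[tg$strategy]] <- st
  model
}

incremental_outcome <- function(model, outcome, wtp, comparator) {
  res <- evaluate_strategies(model)
  ref <- res[res$strategy == model$reference, ]
  cmp <- res[res$strategy == comparator, ]
  d_cost <- cmp$cost - ref$cost
  d_qaly <- cmp$qaly - ref$qaly
  switch(outcome,
    delta_cost = d_cost,
    delta_qaly = d_qaly,
    icer = icer(ref$cost, ref$qaly, cmp$cost, cmp$qaly),
    nmb = net_monetary_benefit(cmp$cost, cmp$qaly, wtp) -
          net_monetary_benefit(ref$cost, ref$qaly, wtp))
}

pick_comparator <- function(model, comparator) {
  if (!is.null(comparator)) {
    if (!comparator %in% names(model$strategies)) {
      abort_invalid("`comparator` must name a model strategy")
    }
    return(comparator)
  }
  others <- setdiff(names(model$strategies), model$reference)
  if (length(others) != 1) {
    abort_invalid("specify `comparator` when the model has more than two strategies")
  }
  others
}

#' One-way deterministic sensitivity of an incremental outcome
#'
#' Evaluates the chosen incremental outcome (comparator minus reference)
#' with the parameter at its low and at its high value, all other
#' parameters held at base, and reports both outcomes and the swing.
#' The model is never mutated.
#'
#' @param model A `cea_model`.
#' @param param One row of a parameter table (see [param_spec()]) with
#'   finite `low` and `high`; `dirichlet_row` targets are rejected here —
#'   vary scalar transition entries (the row is renormalised around
#'   them) instead.
#' @param outcome One of `"delta_cost"`, `"delta_qaly"`, `"icer"`,
#'   `"nmb"` (incremental net monetary benefit at `wtp`).
#' @param wtp Willingness-to-pay, needed for `outcome = "nmb"`.
#' @param comparator Comparator strategy (default: the only
#'   non-reference strategy).
#' @return One-row tibble: `param`, `outcome_low`, `outcome_high`,
#'   `swing`.
#' @export
one_way <- function(model, param, outcome = "delta_cost", wtp = NULL,
                    comparator = NULL) {
  stopifnot(inherits(model, "cea_model"))
  outcome <- match.arg(outcome, c("delta_cost", "delta_qaly", "icer", "nmb"))
  if (outcome == "nmb" && is.null(wtp)) abort_invalid("`nmb` outcome needs `wtp`")
  comparator <- pick_comparator(model, comparator)
  param <- as_tibble(param)
  if (nrow(param) != 1) abort_invalid("`param` must be a single parameter row")
  if (param$distribution == "dirichlet_row" ||
      parse_target(param$target)$kind == "row") {
    abort_config("one-way analysis takes scalar targets, not whole rows")
  }
  if (is.na(param$low) || is.na(param$high) || param$low > param$high) {
    abort_config("one-way analysis needs low <= high")
  }
  base <- get_target(model, param$target)
  if (param$low > base || param$high < base) {
    abort_config("parameter range must bracket the base value (low <= base <= high)")
  }
  at <- function(v) incremental_outcome(set_target(model, param$target, v),
                                        outcome, wtp, comparator)
  lo <- at(param$low); hi <- at(param$high)
  tibble(param = param$name, outcome_low = lo, outcome_high = hi,
         swing = abs(hi - lo))
}

#' Order tornado bars by influence
#'
#' Sorts one-way results by descending swing; ties keep their input
#' order (stable sort), so equally influential parameters are not
#' reshuffled.
#'
#' @param bars Tibble of one-way results (rows from [one_way()]).
#' @return A `cea_tornado` tibble sorted by descending swing.
#' @export
tornado <- function(bars) {
  bars <- as_tibble(bars)
  if (nrow(bars) < 1) abort_invalid("at least one tornado bar is required")
  req <- c("param", "outcome_low", "outcome_high", "swing")
  if (!all(req %in% names(bars))) {
    abort_invalid("bars need columns param, outcome_low, outcome_high, swing")
  }
  out <- bars[order(-bars$swing), , drop = FALSE]
  structure(out, class = c("cea_tornado", class(out)))
}

#' Run every one-way analysis and order the tornado
#'
#' @inheritParams one_way
#' @param params Parameter table (rows from [param_spec()]).
#' @return A `cea_tornado` tibble.
#' @export
tornado_analysis <- function(model, params, outcome = "delta_cost",
                             wtp = NULL, comparator = NULL) {
  bars <- purrr::map_dfr(seq_len(nrow(params)), function(i) {
    one_way(model, params[i, ], outcome = outcome, wtp = wtp,
            comparator = comparator)
  })
  tornado(bars)
}

#' @describeIn tornado Horizontal tornado diagram.
#' @param object A `cea_tornado`.
#' @param ... Unused.
#' @method autoplot cea_tornado
#' @export
autoplot.cea_tornado <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(param = factor(.data$param, levels = rev(.data$param)))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$outcome_low,
                                       xend = .data$outcome_high,
                                       y = .data$param, yend = .data$param),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::labs(x = "Incremental outcome", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

#' Method-of-moments hyperparameters
#'
#' `moment_match_beta()` solves mean/sd for the beta shape parameters
#' (alpha = m * nu, beta = (1 - m) * nu with nu = m(1-m)/s^2 - 1);
#' `moment_match_gamma()` solves for shape and rate.
#'
#' @param mean,sd Target moments (beta: mean in (0,1); both: sd > 0 and
#'   feasible).
#' @return Named list of hyperparameters.
#' @export
moment_match_beta <- function(mean, sd) {
  if (is.na(mean) || mean <= 0 || mean >= 1) abort_config("beta mean must lie in (0,1)")
  if (is.na(sd) || sd <= 0) abort_config("beta sd must be positive")
  nu <- mean * (1 - mean) / sd^2 - 1
  if (nu <= 0) abort_config("beta sd too large for this mean (no valid shape)")
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' @rdname moment_match_beta
#' @export
moment_match_gamma <- function(mean, sd) {
  if (is.na(mean) || mean <= 0) abort_config("gamma mean must be positive")
  if (is.na(sd) || sd <= 0) abort_config("gamma sd must be positive")
  list(shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Draw one sampled model for probabilistic sensitivity analysis
#'
#' Perturbs the model once: `fixed` parameters keep their base value,
#' `beta` and `gamma` parameters are sampled with method-of-moments
#' hyperparameters (defaulting the mean to the model's base value when
#' unspecified), and `dirichlet_row` parameters replace a whole
#' transition row with a draw whose components are normalised gammas, so
#' the row sums to 1 by construction. Parameters are consumed in
#' declaration order from R's global random stream; seed the stream (or
#' use [run_psa()], which does) for reproducibility.
#'
#' @param model A `cea_model`.
#' @param params Parameter table.
#' @return A perturbed `cea_model` (unvalidated; [run_psa()] validates
#'   and rejects infeasible draws).
#' @export
draw_parameters <- function(model, params) {
  params <- as_tibble(params)
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    base <- get_target(model, p$target)
    value <- switch(p$distribution,
      fixed = base,
      beta = {
        m <- if (is.na(p$mean)) base else p$mean
        hp <- moment_match_beta(m, p$sd)
        stats::rbeta(1, hp$alpha, hp$beta)
      },
      gamma = {
        m <- if (is.na(p$mean)) base else p$mean
        hp <- moment_match_gamma(m, p$sd)
        stats::rgamma(1, shape = hp$shape, rate = hp$rate)
      },
      dirichlet_row = {
        conc <- p$concentration[[1]]
        if (is.null(conc) || any(conc <= 0)) {
          abort_config("dirichlet_row needs positive concentrations")
        }
        g <- stats::rgamma(length(conc), shape = conc, rate = 1)
        g / sum(g)
      },
      abort_config(sprintf("unknown distribution `%s`", p$distribution)))
    if (!identical(value, base) || p$distribution != "fixed") {
      model <- set_target(model, p$target, value)
    }
  }
  model
}

# quadrant convention for (delta_qaly = x, delta_cost = y), comparator
# minus reference: I = (+,+), II = (+,-), III = (-,-), IV = (-,+).
# Zero deltas go to the adjacent lower-numbered quadrant and are
# flagged on_axis.
classify_quadrant <- function(delta_qaly, delta_cost) {
  q <- dplyr::case_when(
    delta_qaly > 0 & delta_cost >= 0 ~ "I",
    delta_qaly > 0 & delta_cost < 0 ~ "II",
    delta_qaly == 0 & delta_cost >= 0 ~ "I",
    delta_qaly == 0 & delta_cost < 0 ~ "II",
    delta_qaly < 0 & delta_cost < 0 ~ "III",
    delta_qaly < 0 & delta_cost == 0 ~ "III",
    TRUE ~ "IV"
  )
  tibble(quadrant = q, on_axis = delta_qaly == 0 | delta_cost == 0)
}

#' Probabilistic sensitivity analysis by Monte Carlo
#'
#' Draws `n_draws` sampled models ([draw_parameters()]), evaluates every
#' strategy through the Markov engine for each draw, and records
#' per-draw incremental cost and QALYs (comparator minus reference)
#' with their cost-effectiveness-plane quadrant. Draws whose transition
#' matrices fail validation are rejected and redrawn (reported in the
#' result; after `100 * n_draws` total attempts the run errors out).
#' The random stream is seeded once, parameters are consumed in
#' declaration order inside each draw, and draws form the outer loop, so
#' extending `n_draws` under the same seed keeps the first draws
#' identical.
#'
#' @param model A `cea_model`.
#' @param params Parameter table.
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed Integer seed for the run.
#' @param comparator Comparator strategy (default: the only
#'   non-reference strategy).
#' @return A `cea_psa` object: `samples` (draw x strategy cost/qaly),
#'   `deltas` (per-draw increments with quadrant), `base` (base-case
#'   evaluation), counts of rejected draws.
#' @export
run_psa <- function(model, params, n_draws = 1000, seed = 20210822,
                    comparator = NULL) {
  stopifnot(inherits(model, "cea_model"))
  if (n_draws < 1) abort_invalid("`n_draws` must be >= 1")
  comparator <- pick_comparator(model, comparator)
  set.seed(seed)
  max_attempts <- 100 * n_draws
  attempts <- 0L
  rejected <- 0L
  samples <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort_validation(sprintf(
          "PSA abandoned: %d draw attempts exceeded for %d draws", attempts - 1L, n_draws))
      }
      drawn <- draw_parameters(model, params)
      ok <- tryCatch({
        for (nm in names(drawn$strategies)) {
          validate_matrix(drawn$strategies[[nm]]$transition, drawn$spec,
                          death_prob = drawn$death_prob)
        }
        TRUE
      }, radcea_validation_error = function(e) FALSE)
      if (ok) break
      rejected <- rejected + 1L
    }
    samples[[d]] <- evaluate_strategies(drawn) %>% mutate(draw = d)
  }
  samples <- bind_rows(samples) %>% select("draw", "strategy", "cost", "qaly")
  wide <- samples %>%
    tidyr::pivot_wider(names_from = "strategy",
                       values_from = c("cost", "qaly"))
  d_cost <- wide[[paste0("cost_", comparator)]] -
    wide[[paste0("cost_", model$reference)]]
  d_qaly <- wide[[paste0("qaly_", comparator)]] -
    wide[[paste0("qaly_", model$reference)]]
  deltas <- bind_cols(
    tibble(draw = wide$draw, delta_cost = d_cost, delta_qaly = d_qaly),
    classify_quadrant(d_qaly, d_cost)
  )
  structure(
    list(samples = samples, deltas = deltas,
         base = evaluate_strategies(model),
         reference = model$reference, comparator = comparator,
         n_draws = n_draws, n_rejected = rejected, seed = seed),
    class = "cea_psa"
  )
}

#' @export
print.cea_psa <- function(x, ...) {
  cat("PSA:", x$n_draws, "draws (", x$n_rejected, "rejected ),",
      x$comparator, "vs", x$reference, "\n")
  print(quadrant_shares(x))
  invisible(x)
}

#' @describeIn run_psa Per-draw incremental results.
#' @param x A `cea_psa`.
#' @param ... Unused.
#' @method tidy cea_psa
#' @export
tidy.cea_psa <- function(x, ...) x$deltas

#' @describeIn run_psa One-row summary: mean increments and quadrant-IV
#'   share.
#' @method glance cea_psa
#' @export
glance.cea_psa <- function(x, ...) {
  tibble(
    n_draws = x$n_draws,
    n_rejected = x$n_rejected,
    mean_delta_cost = mean(x$deltas$delta_cost),
    mean_delta_qaly = mean(x$deltas$delta_qaly),
    share_quadrant_iv = mean(x$deltas$quadrant == "IV")
  )
}

#' Quadrant shares of the PSA cloud
#'
#' @param psa A `cea_psa`.
#' @return Tibble of quadrant shares (all four quadrants, summing to 1).
#' @export
quadrant_shares <- function(psa) {
  stopifnot(inherits(psa, "cea_psa"))
  tibble(quadrant = c("I", "II", "III", "IV")) %>%
    left_join(psa$deltas %>%
                group_by(.data$quadrant) %>%
                summarise(n = dplyr::n(), .groups = "drop"),
              by = "quadrant") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           share = .data$n / nrow(psa$deltas))
}

#' @describeIn run_psa Incremental cost-effectiveness plane scatter of
#'   the draws.
#' @param object A `cea_psa`.
#' @method autoplot cea_psa
#' @export
autoplot.cea_psa <- function(object, ...) {
  ggplot2::ggplot(object$deltas,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::labs(
      x = sprintf("Incremental QALYs (%s - %s)", object$comparator, object$reference),
      y = "Incremental cost (USD)",
      title = "Monte Carlo simulation on the CE plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability that each strategy
#' has the strictly highest net monetary benefit across the PSA draws;
#' exact NMB ties split their draw's probability mass equally, so the
#' probabilities sum to 1 at every WTP.
#'
#' @param psa A `cea_psa`.
#' @param wtp_grid Ascending non-negative WTP values; default 0 to three
#'   times the largest base-case strategy cost in 101 steps.
#' @return A `cea_ceac` tibble: `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  stopifnot(inherits(psa, "cea_psa"))
  if (is.null(wtp_grid)) {
    wtp_grid <- seq(0, 3 * max(psa$base$cost), length.out = 101)
  }
  if (any(wtp_grid < 0)) abort_invalid("WTP values must be >= 0")
  costs <- psa$samples %>%
    tidyr::pivot_wider(names_from = "strategy", values_from = "cost",
                       id_cols = "draw") %>% select(-"draw") %>% as.matrix()
  qalys <- psa$samples %>%
    tidyr::pivot_wider(names_from = "strategy", values_from = "qaly",
                       id_cols = "draw") %>% select(-"draw") %>% as.matrix()
  strategies <- colnames(costs)
  out <- purrr::map_dfr(wtp_grid, function(w) {
    nmb <- w * qalys - costs
    best <- nmb == matrixStats_rowMaxs(nmb)
    weights <- best / rowSums(best)   # ties split equally
    tibble(wtp = w, strategy = strategies,
           probability = unname(colMeans(weights)))
  })
  structure(out, class = c("cea_ceac", class(out)))
}

# row maxima without an extra dependency
matrixStats_rowMaxs <- function(m) {
  do.call(pmax, as.data.frame(m))
}

#' @describeIn ceac Acceptability curves, one per strategy.
#' @param object A `cea_ceac`.
#' @param ... Unused.
#' @method autoplot cea_ceac
#' @export
autoplot.cea_ceac <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness-to-pay (USD per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
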