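# Synthetic study generator: study-shaped per-patient cost records,
# EQ-5D-3L responses, absenteeism records, and valid transition
# matrices, all pure functions of a config + seed so every pipeline
# stage is testable with known ground truth.

#' Published per-category cost means used as generator defaults
#'
#' Per-patient mean costs (USD) by strategy arm and category, as printed
#' in the study's cost table; the synthetic cost generator centres its
#' draws on these.
#'
#' @return Tibble with `arm`, `category`, `mean_usd`.
#' @export
table1_cost_means <- function() {
  tibble(
    arm = rep(c("IMRT", "3D-CRT"), each = 7),
    category = rep(c("visits", "laboratory", "diagnosis", "radiotherapy",
                     "transport", "lodging", "productivity_loss"), 2),
    mean_usd = c(44.17, 138.99, 184.75, 12995.65, 46.22, 57.14, 294.41,
                 17.57, 83.12, 175.17, 9497.05, 24.89, 55.83, 296.57)
  )
}

default_level_probs <- function() {
  # severity-graded response profiles per toxicity state, shared by both
  # arms; arm-specific tables can be passed through the config
  sev <- list(
    LXLD = c(0.80, 0.15, 0.05),
    LXHD = c(0.60, 0.30, 0.10),
    HXLD = c(0.60, 0.30, 0.10),
    HXHD = c(0.35, 0.40, 0.25)
  )
  purrr::map_dfr(names(sev), function(st) {
    tibble(state_label = st,
           dimension = eq5d_dimensions(),
           p1 = sev[[st]][1], p2 = sev[[st]][2], p3 = sev[[st]][3])
  }) %>%
    tidyr::crossing(arm = c("IMRT", "3D-CRT")) %>%
    select("arm", "state_label", "dimension", "p1", "p2", "p3")
}

#' Configure the synthetic study
#'
#' Defaults emulate the study's shape: 97 respondents split 49/48
#' between the 3D-CRT (reference) and IMRT arms, per-category cost means
#' equal to the published cost-table cells with gamma noise at a
#' coefficient of variation of 0.4, severity-graded EQ-5D level
#' probabilities per toxicity state, and a 2% per-cycle cohort death
#' probability.
#'
#' @param n_patients Total respondents (default 97).
#' @param n_reference Respondents in the reference (3D-CRT) arm
#'   (default 49; the rest are IMRT).
#' @param cost_means Tibble `arm`, `category`, `mean_usd`
#'   (default [table1_cost_means()]).
#' @param cost_cv Coefficient of variation of per-patient costs
#'   (>= 0, default 0.4; 0 gives every patient the mean exactly).
#' @param eq5d_level_probs Tibble `arm`, `state_label`, `dimension`,
#'   `p1`, `p2`, `p3` with each probability triple summing to 1.
#' @param death_prob Per-cycle cohort death probability (default 0.02).
#' @param seed Integer seed making every generator deterministic.
#' @return A `synthetic_study_config` list.
#' @export
synthetic_study_config <- function(n_patients = 97, n_reference = 49,
                                   cost_means = table1_cost_means(),
                                   cost_cv = 0.4,
                                   eq5d_level_probs = default_level_probs(),
                                   death_prob = 0.02, seed = 20210822) {
  if (n_patients < 2 || n_reference < 1 || n_reference >= n_patients) {
    abort_config("need at least one patient in each arm")
  }
  if (cost_cv < 0) abort_config("`cost_cv` must be >= 0")
  cost_means <- as_tibble(cost_means)
  if (!all(c("arm", "category", "mean_usd") %in% names(cost_means)) ||
      any(cost_means$mean_usd < 0)) {
    abort_config("`cost_means` needs arm, category, mean_usd >= 0")
  }
  probs <- as_tibble(eq5d_level_probs)
  psum <- probs$p1 + probs$p2 + probs$p3
  if (any(abs(psum - 1) > 1e-9) || any(probs$p1 < 0 | probs$p2 < 0 | probs$p3 < 0)) {
    abort_config("EQ-5D level probabilities must be non-negative and sum to 1")
  }
  if (death_prob < 0 || death_prob >= 1) abort_config("`death_prob` must lie in [0,1)")
  structure(
    list(n_patients = n_patients, n_reference = n_reference,
         cost_means = cost_means, cost_cv = cost_cv,
         eq5d_level_probs = probs, death_prob = death_prob,
         seed = as.integer(seed)),
    class = "synthetic_study_config"
  )
}

synthetic_patients <- function(cfg) {
  tibble(
    patient_id = sprintf("P%04d", seq_len(cfg$n_patients)),
    arm = c(rep("3D-CRT", cfg$n_reference),
            rep("IMRT", cfg$n_patients - cfg$n_reference))
  )
}

rgamma_mean_cv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Generate per-patient cost and absenteeism records
#'
#' Direct cost categories are drawn per patient from gamma distributions
#' with the configured per-arm means and coefficient of variation
#' (cv = 0 degenerates to the mean exactly). The `productivity_loss`
#' mean is realised through absenteeism records (days x fixed daily
#' wages, 70% patient absence and 30% companion absence, gamma noise on
#' the days) so the human-capital valuation recovers the configured
#' indirect-cost mean in expectation.
#'
#' @param cfg A `synthetic_study_config`.
#' @return List with `items` (cost records tibble) and `absentee`
#'   (absenteeism tibble), both carrying `arm`.
#' @export
gen_cost_records <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_study_config"))
  set.seed(cfg$seed)
  patients <- synthetic_patients(cfg)
  direct_cats <- setdiff(cost_categories(), "productivity_loss")

  items <- patients %>%
    tidyr::crossing(category = direct_cats) %>%
    left_join(cfg$cost_means, by = c("arm", "category")) %>%
    mutate(mean_usd = ifelse(is.na(.data$mean_usd), 0, .data$mean_usd)) %>%
    arrange(.data$patient_id, .data$category)
  items$amount <- vapply(seq_len(nrow(items)), function(i) {
    rgamma_mean_cv(1, items$mean_usd[i], cfg$cost_cv)
  }, numeric(1))
  items <- items %>%
    mutate(currency = "USD") %>%
    select("patient_id", "arm", "category", "amount", "currency")

  patient_wage <- 10   # USD/day, fixed synthetic wages
  companion_wage <- 8
  prod_means <- cfg$cost_means %>% filter(.data$category == "productivity_loss")
  absentee <- patients %>%
    left_join(prod_means, by = "arm") %>%
    mutate(target = ifelse(is.na(.data$mean_usd), 0, .data$mean_usd))
  absentee$patient_days <- vapply(seq_len(nrow(absentee)), function(i) {
    rgamma_mean_cv(1, 0.7 * absentee$target[i] / patient_wage, cfg$cost_cv)
  }, numeric(1))
  absentee$companion_days <- vapply(seq_len(nrow(absentee)), function(i) {
    rgamma_mean_cv(1, 0.3 * absentee$target[i] / companion_wage, cfg$cost_cv)
  }, numeric(1))
  absentee <- absentee %>%
    mutate(patient_wage = patient_wage, companion_wage = companion_wage,
           nursing_days = 0, nursing_rate = 0) %>%
    select("patient_id", "arm", "patient_days", "patient_wage",
           "companion_days", "companion_wage", "nursing_days", "nursing_rate")
  list(items = items, absentee = absentee)
}

#' Generate EQ-5D-3L responses
#'
#' Each patient is assigned a toxicity state uniformly at random among
#' the configured state labels for their arm, then each of the five
#' dimensions is sampled independently from that (arm, state,
#' dimension)'s level-probability vector.
#'
#' @param cfg A `synthetic_study_config`.
#' @return Tibble `patient_id`, `arm`, `state_label`, `profile`.
#' @export
gen_eq5d_responses <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_study_config"))
  set.seed(cfg$seed + 1L)
  patients <- synthetic_patients(cfg)
  probs <- cfg$eq5d_level_probs
  purrr::map_dfr(seq_len(nrow(patients)), function(i) {
    arm <- patients$arm[i]
    labels <- unique(probs$state_label[probs$arm == arm])
    st <- sample(labels, 1)
    lv <- vapply(eq5d_dimensions(), function(dm) {
      p <- probs %>% filter(.data$arm == !!arm, .data$state_label == st,
                            .data$dimension == dm)
      if (nrow(p) != 1) {
        abort_config(sprintf("no level probabilities for (%s, %s, %s)", arm, st, dm))
      }
      sample(1:3, 1, prob = c(p$p1, p$p2, p$p3))
    }, integer(1))
    tibble(patient_id = patients$patient_id[i], arm = arm, state_label = st,
           profile = paste0(lv, collapse = ""))
  })
}

#' Generate valid transition matrices per strategy
#'
#' Builds one row-stochastic matrix per strategy over
#' `n_alive_states` toxicity states + LTF + death. Every alive state
#' (including LTF) moves to death with exactly `death_prob`; every
#' non-LTF alive state moves to LTF with `ltf_prob`; the remaining mass
#' stays put except a `mixing` fraction spread randomly over the other
#' toxicity states. The result passes [validate_matrix()] by
#' construction, including the LTF death-rate-equality rule.
#'
#' @param n_alive_states Number of toxicity states (default 4).
#' @param death_prob Per-cycle death probability (with
#'   `death_prob + ltf_prob < 1`).
#' @param ltf_prob Per-cycle probability of becoming lost to follow-up.
#' @param mixing Fraction of the residual mass moved between toxicity
#'   states (0 = pure self-transition).
#' @param seed Integer seed.
#' @param strategies Strategy names (one matrix each).
#' @return List with `states` (a state tibble) and `matrices` (named
#'   list of transition matrices).
#' @export
gen_transition_matrices <- function(n_alive_states = 4, death_prob = 0.02,
                                    ltf_prob = 0.03, mixing = 0.1,
                                    seed = 20210822,
                                    strategies = c("3D-CRT", "IMRT")) {
  if (death_prob < 0 || ltf_prob < 0 || death_prob + ltf_prob >= 1) {
    abort_config("need death_prob, ltf_prob >= 0 with death_prob + ltf_prob < 1")
  }
  if (mixing < 0 || mixing > 1) abort_config("`mixing` must lie in [0,1]")
  alive <- if (n_alive_states == 4) c("LXLD", "LXHD", "HXLD", "HXHD") else
    paste0("S", seq_len(n_alive_states))
  states <- health_states(c(alive, "LTF", "Death"), death = "Death", ltf = "LTF")
  n <- nrow(states)
  set.seed(seed)
  matrices <- lapply(strategies, function(st) {
    m <- matrix(0, n, n, dimnames = list(states$name, states$name))
    for (a in alive) {
      m[a, "Death"] <- death_prob
      m[a, "LTF"] <- ltf_prob
      resid <- 1 - death_prob - ltf_prob
      m[a, a] <- (1 - mixing) * resid
      others <- setdiff(alive, a)
      if (length(others) && mixing > 0) {
        w <- stats::rgamma(length(others), shape = 1, rate = 1)
        m[a, others] <- mixing * resid * w / sum(w)
      } else {
        m[a, a] <- m[a, a] + mixing * resid
      }
    }
    m["LTF", "Death"] <- death_prob
    m["LTF", "LTF"] <- 1 - death_prob
    m["Death", "Death"] <- 1
    transition_matrix(m, strategy = st)
  })
  names(matrices) <- strategies
  list(states = states, matrices = matrices)
}

#' The calibrated two-strategy model fixture
#'
#' A deterministic single-transient-state construction (one alive state
#' and death, no deaths over the horizon, five one-year cycles,
#' no discounting, no half-cycle correction) whose engine outputs equal
#' the study's base case exactly: cost 9209.76 and 3.63 QALYs for the
#' 3D-CRT reference arm, 12562.90 and 3.17 for IMRT. Ships with a PSA
#' parameter table of modest noise centred on the base values (beta on
#' utilities with sd 0.03, gamma on cycle costs with sd 5% of the mean)
#' and one-way ranges of the same spread for the tornado.
#'
#' @return List with `model` (a `cea_model`) and `params` (a parameter
#'   table).
#' @export
gen_calibrated_fixture <- function() {
  states <- health_states(c("Alive", "Death"))
  spec <- model_spec(states, cycle_length_years = 1, n_cycles = 5,
                     discount_rate = 0, half_cycle = FALSE,
                     initial_distribution = c(1, 0))
  m <- matrix(c(1, 0,
                0, 1), 2, 2, byrow = TRUE,
              dimnames = list(states$name, states$name))
  mk <- function(u, c_cycle) {
    list(transition = m,
         payoffs = state_payoffs(c(Alive = u), c(Alive = c_cycle), spec = spec))
  }
  model <- cea_model(
    spec,
    strategies = list(`3D-CRT` = mk(0.726, 1841.952),
                      IMRT = mk(0.634, 2512.58)),
    reference = "3D-CRT"
  )
  params <- bind_rows(
    param_spec("utility 3D-CRT", "utility:3D-CRT:Alive",
               low = 0.726 - 0.09, high = 0.726 + 0.09,
               distribution = "beta", mean = 0.726, sd = 0.03),
    param_spec("utility IMRT", "utility:IMRT:Alive",
               low = 0.634 - 0.09, high = 0.634 + 0.09,
               distribution = "beta", mean = 0.634, sd = 0.03),
    param_spec("cycle cost 3D-CRT", "cost:3D-CRT:Alive",
               low = 1841.952 * 0.85, high = 1841.952 * 1.15,
               distribution = "gamma", mean = 1841.952, sd = 1841.952 * 0.05),
    param_spec("cycle cost IMRT", "cost:IMRT:Alive",
               low = 2512.58 * 0.85, high = 2512.58 * 1.15,
               distribution = "gamma", mean = 2512.58, sd = 2512.58 * 0.05)
  )
  list(model = model, params = params)
}

#' A six-state toxicity demonstration model
#'
#' A deterministic demonstration model over the composite toxicity
#' states (LXLD, LXHD, HXLD, HXHD, LTF, Death): quarterly cycles over
#' five years, 3% annual discounting, 2% per-cycle death probability,
#' generated transition matrices, severity-graded state utilities, and
#' higher per-cycle costs in the IMRT arm. Its one-way parameter table
#' assigns the widest uncertainty ranges to the reference arm's LXLD
#' and HXLD utilities, so the tornado is expected to rank those two
#' parameters as most influential.
#'
#' @param seed Seed for the generated transition matrices.
#' @return List with `model` and `params` as in
#'   [gen_calibrated_fixture()].
#' @export
gen_toxicity_fixture <- function(seed = 104) {
  gt <- gen_transition_matrices(seed = seed)
  spec <- model_spec(gt$states, cycle_length_years = 0.25, n_cycles = 20,
                     discount_rate = 0.03, half_cycle = FALSE,
                     initial_distribution = c(1, 0, 0, 0, 0, 0))
  util <- c(LXLD = 0.85, LXHD = 0.72, HXLD = 0.70, HXHD = 0.55, LTF = 0.70)
  mk <- function(m, cost_per_cycle, upfront) {
    costs <- setNames(rep(cost_per_cycle, 5),
                      c("LXLD", "LXHD", "HXLD", "HXHD", "LTF"))
    list(transition = m,
         payoffs = state_payoffs(util, costs, upfront = upfront, spec = spec))
  }
  model <- cea_model(
    spec,
    strategies = list(`3D-CRT` = mk(gt$matrices[["3D-CRT"]], 55, 9000),
                      IMRT = mk(gt$matrices[["IMRT"]], 60, 12500)),
    reference = "3D-CRT",
    death_prob = 0.02
  )
  mk_util_param <- function(state, halfwidth) {
    base <- util[[state]]
    param_spec(paste("utility", state, "3D-CRT"),
               paste0("utility:3D-CRT:", state),
               low = base - halfwidth, high = base + halfwidth,
               distribution = "beta", mean = base, sd = halfwidth / 3)
  }
  params <- bind_rows(
    mk_util_param("LXLD", 0.15),
    mk_util_param("HXLD", 0.12),
    mk_util_param("LXHD", 0.04),
    mk_util_param("HXHD", 0.04),
    param_spec("cycle cost 3D-CRT", "cost:3D-CRT:LXLD",
               low = 50, high = 60, distribution = "gamma",
               mean = 55, sd = 3),
    param_spec("cycle cost IMRT", "cost:IMRT:LXLD",
               low = 55, high = 65, distribution = "gamma",
               mean = 60, sd = 3)
  )
  list(model = model, params = params)
}

#' Write the synthetic study inputs as delimited text
#'
#' Writes `costs.csv`, `absenteeism.csv`, and `eq5d.csv` in the formats
#' the readers expect.
#'
#' @param cfg A `synthetic_study_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_study <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- gen_cost_records(cfg)
  resp <- gen_eq5d_responses(cfg)
  paths <- file.path(dir, c("costs.csv", "absenteeism.csv", "eq5d.csv"))
  readr::write_csv(rec$items, paths[1])
  readr::write_csv(rec$absentee, paths[2])
  readr::write_csv(resp, paths[3])
  invisible(paths)
}

#' Write a decision model to YAML
#'
#' Serialises a `cea_model` in the layout [read_model_spec()] reads
#' (row-major transition matrices, per-strategy payoffs).
#'
#' @param model A `cea_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "cea_model"))
  spec <- model$spec
  death <- spec$states$name[spec$states$absorbing]
  ltf <- spec$states$name[spec$states$lost_to_follow_up]
  cfg <- list(
    states = lapply(spec$states$name, function(nm) list(name = nm)),
    death = death,
    cycle_length_years = spec$cycle_length_years,
    n_cycles = spec$n_cycles,
    discount_rate = spec$discount_rate,
    half_cycle = spec$half_cycle,
    initial_distribution = as.list(unname(spec$initial_distribution)),
    reference = model$reference,
    strategies = lapply(model$strategies, function(st) {
      list(
        transition_matrix = lapply(seq_len(nrow(st$transition)),
                                   function(i) as.list(unname(st$transition[i, ]))),
        state_utilities = as.list(st$payoffs$utility),
        state_costs = as.list(st$payoffs$cost),
        upfront_cost = st$payoffs$upfront
      )
    })
  )
  if (length(ltf)) cfg$ltf <- ltf
  if (!is.null(model$death_prob)) cfg$death_prob <- model$death_prob
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
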