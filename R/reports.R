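# Workflow entry points: run the full base case (costing -> utilities
# -> engine -> ranking) and the sensitivity suite, writing plain-text
# reports plus a manifest sufficient to reproduce them byte-for-byte.
# Inputs are never mutated.

write_manifest <- function(out_dir, inputs, config, seed = NULL) {
  inputs <- as.character(inputs)
  existing <- inputs[!is.na(inputs) & file.exists(inputs)]
  manifest <- list(
    package = "radcea",
    version = as.character(utils::packageVersion("radcea")),
    inputs = if (length(existing)) as.list(tools::md5sum(existing)) else list(),
    config = config,
    seed = seed
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, radcea_error = function(e) {
    rlang::abort(paste0("stage `", stage, "` failed: ", conditionMessage(e)),
                 class = class(e), parent = e)
  })
}

ranking_report <- function(ranking) {
  tidy(ranking) %>%
    mutate(across(c("cost", "qaly", "incremental_cost",
                    "incremental_qaly", "icer"), ~ round(.x, 2))) %>%
    select(strategy = "strategy", effectiveness = "qaly",
           incremental_effectiveness = "incremental_qaly",
           cost = "cost", incremental_cost = "incremental_cost",
           icer = "icer", dominance = "status")
}

#' Run the base-case analysis and write its reports
#'
#' Either pass a ready `cea_model`, or pass the file inputs
#' (`costs_csv`, `absenteeism_csv`, `eq5d_csv`, `model_yaml`,
#' `value_set_csv`) and the pipeline runs costing and utility
#' estimation first, filling any strategy whose YAML omits
#' `state_utilities` with the per-state means estimated from the EQ-5D
#' data. Writes `table1.csv` (per-arm cost breakdowns, when cost data
#' are given), `table2.csv` (the ranking with dominance verdicts),
#' `ce_plane.csv`, and `manifest.json` (input checksums + config echo),
#' all deterministic for identical inputs. Applied defaults are logged
#' with messages.
#'
#' @param out_dir Output directory (created if needed).
#' @param model Optional `cea_model` (skips the file route).
#' @param costs_csv,absenteeism_csv,eq5d_csv,model_yaml,value_set_csv
#'   Input paths for the file route.
#' @param irr_per_usd Exchange rate for IRR cost records.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `table1` (list of `cost_breakdown` by
#'   arm or `NULL`), `results`, and `ranking`.
#' @export
run_base_case <- function(out_dir, model = NULL, costs_csv = NULL,
                          absenteeism_csv = NULL, eq5d_csv = NULL,
                          model_yaml = NULL, value_set_csv = NULL,
                          irr_per_usd = 36692, quiet = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  table1 <- NULL

  if (is.null(model)) {
    if (is.null(model_yaml)) {
      abort_invalid("provide either `model` or `model_yaml`")
    }
    utilities <- NULL
    if (!is.null(eq5d_csv)) {
      vs <- with_stage("eq5d_utilities", {
        if (is.null(value_set_csv)) {
          say("no value set supplied; using the documented toy value set")
          toy_value_set()
        } else read_value_set(value_set_csv)
      })
      utilities <- with_stage("eq5d_utilities",
                              state_utilities(read_eq5d_responses(eq5d_csv), vs))
    }
    model <- with_stage("read_model_spec",
                        read_model_spec(model_yaml, state_utilities = utilities))
  }
  with_stage("validate_matrix", {
    for (nm in names(model$strategies)) {
      validate_matrix(model$strategies[[nm]]$transition, model$spec,
                      death_prob = model$death_prob)
    }
  })

  if (!is.null(costs_csv)) {
    items <- with_stage("costing", read_cost_records(costs_csv))
    absentee <- if (!is.null(absenteeism_csv)) {
      with_stage("costing", read_absenteeism(absenteeism_csv))
    }
    arms <- unique(items$arm)
    table1 <- with_stage("costing", lapply(setNames(arms, arms), function(a) {
      aggregate_costs(items[items$arm == a, ],
                      absentee[absentee$arm == a, ],
                      irr_per_usd = irr_per_usd)
    }))
    table1_df <- purrr::imap_dfr(table1, function(bd, a) {
      tidy(bd) %>% mutate(arm = a) %>% select("arm", "group", "item", "mean_usd")
    })
    readr::write_csv(table1_df, file.path(out_dir, "table1.csv"))
  }

  say("engine: ", model$spec$n_cycles, " cycles of ",
      model$spec$cycle_length_years, " years, discount ",
      model$spec$discount_rate, "/yr, half-cycle ",
      model$spec$half_cycle)
  results <- with_stage("markov_engine", evaluate_strategies(model))
  ranking <- with_stage("cea_ranking", rank_strategies(results))

  readr::write_csv(ranking_report(ranking), file.path(out_dir, "table2.csv"))
  readr::write_csv(results %>% select("strategy", "qaly", "cost"),
                   file.path(out_dir, "ce_plane.csv"))
  write_manifest(out_dir,
                 inputs = c(costs_csv, absenteeism_csv, eq5d_csv,
                            model_yaml, value_set_csv),
                 config = list(irr_per_usd = irr_per_usd,
                               n_cycles = model$spec$n_cycles,
                               cycle_length_years = model$spec$cycle_length_years,
                               discount_rate = model$spec$discount_rate,
                               half_cycle = model$spec$half_cycle,
                               reference = model$reference))
  invisible(list(table1 = table1, results = results, ranking = ranking))
}

#' Read EQ-5D responses from CSV
#'
#' Expects columns `patient_id,arm,state_label,profile`.
#'
#' @param path CSV path.
#' @return A tibble with `profile` as character.
#' @export
read_eq5d_responses <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(profile = readr::col_character()))
  req <- c("patient_id", "arm", "state_label", "profile")
  if (!all(req %in% names(df))) {
    abort_invalid(paste0("EQ-5D CSV must have columns: ", paste(req, collapse = ", ")))
  }
  df
}

#' Run the sensitivity suite and write its reports
#'
#' One-way analyses ordered into a tornado, the Monte Carlo PSA with
#' quadrant statistics, and the acceptability curves. Writes
#' `tornado.csv`, `psa_samples.csv`, `quadrants.csv`, `ceac.csv`, and
#' `manifest.json` recording the seed.
#'
#' @param out_dir Output directory.
#' @param model A `cea_model`.
#' @param params Parameter table ([param_spec()] rows) or a path to a
#'   parameter CSV.
#' @param n_draws PSA draws (default 1000).
#' @param seed PSA seed.
#' @param outcome One-way outcome (see [one_way()]).
#' @param wtp Willingness-to-pay for `outcome = "nmb"`.
#' @param wtp_grid CEAC grid (default as in [ceac()]).
#' @param comparator Comparator strategy for incremental quantities.
#' @return Invisibly, list with `tornado`, `psa`, `ceac`.
#' @export
run_sensitivity <- function(out_dir, model, params, n_draws = 1000,
                            seed = 20210822, outcome = "nmb", wtp = 10000,
                            wtp_grid = NULL, comparator = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.character(params)) {
    if (!file.exists(params)) {
      abort_invalid(paste0("parameter file not found: ", params))
    }
    params <- read_param_specs(params)
  }
  torn <- with_stage("sensitivity:one_way",
                     tornado_analysis(model, params, outcome = outcome,
                                      wtp = wtp, comparator = comparator))
  readr::write_csv(
    as_tibble(torn) %>% rename(outcome_at_low = "outcome_low",
                               outcome_at_high = "outcome_high"),
    file.path(out_dir, "tornado.csv"))

  psa <- with_stage("sensitivity:psa",
                    run_psa(model, params, n_draws = n_draws, seed = seed,
                            comparator = comparator))
  samples_out <- psa$samples %>%
    left_join(psa$deltas, by = "draw") %>%
    select("draw", "strategy", "cost", "qaly", "delta_cost", "delta_qaly",
           "quadrant")
  readr::write_csv(samples_out, file.path(out_dir, "psa_samples.csv"))
  readr::write_csv(quadrant_shares(psa), file.path(out_dir, "quadrants.csv"))

  cc <- with_stage("sensitivity:ceac", ceac(psa, wtp_grid = wtp_grid))
  readr::write_csv(as_tibble(cc), file.path(out_dir, "ceac.csv"))

  write_manifest(out_dir, inputs = character(0),
                 config = list(n_draws = n_draws, outcome = outcome,
                               wtp = wtp, comparator = psa$comparator,
                               reference = psa$reference),
                 seed = seed)
  invisible(list(tornado = torn, psa = psa, ceac = cc))
}
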