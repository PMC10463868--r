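# EQ-5D-3L utility scoring against additive-decrement (TTO-style) value
# sets, and per-health-state utility estimation.

eq5d_dimensions <- function() {
  c("mobility", "self_care", "usual_activities",
    "pain_discomfort", "anxiety_depression")
}

#' Construct an EQ-5D-3L additive-decrement value set
#'
#' The standard time-trade-off functional form: a profile's utility is the
#' full-health value minus a constant decrement if any dimension is above
#' level 1, minus per-dimension level-2/level-3 decrements, minus an N3
#' decrement applied once if any dimension is at level 3. The national
#' coefficients (e.g. an Iranian TTO tariff) plug in as data; none are
#' hard-coded here.
#'
#' @param decrements Data frame with columns `term` (one of `"constant"`,
#'   `"n3"`, `"dimension"`), `dimension` (an EQ-5D dimension name for
#'   `term == "dimension"`, otherwise ignored), `level` (2 or 3 for
#'   dimension terms), `decrement` (>= 0).
#' @param full_health_value Utility of profile 11111 (default 1).
#' @return A `value_set` object.
#' @examples
#' vs <- toy_value_set()
#' score_eq5d("21111", vs)   # 1 - 0.08 - 0.05 = 0.87
#' @export
eq5d_value_set <- function(decrements, full_health_value = 1) {
  decrements <- as_tibble(decrements)
  req <- c("term", "decrement")
  if (!all(req %in% names(decrements))) {
    abort_config("value set needs `term` and `decrement` columns")
  }
  if (any(is.na(decrements$decrement)) || any(decrements$decrement < 0)) {
    abort_config("decrements must be non-negative")
  }
  bad <- setdiff(decrements$term, c("constant", "n3", "dimension"))
  if (length(bad)) abort_config(paste0("unknown value-set term: ", paste(bad, collapse = ", ")))

  get1 <- function(term) {
    v <- decrements$decrement[decrements$term == term]
    if (length(v) == 0) 0 else if (length(v) == 1) v else
      abort_config(paste0("duplicate `", term, "` term in value set"))
  }
  dim_rows <- decrements[decrements$term == "dimension", , drop = FALSE]
  if (nrow(dim_rows)) {
    if (!all(c("dimension", "level") %in% names(dim_rows))) {
      abort_config("dimension terms need `dimension` and `level` columns")
    }
    if (!all(dim_rows$dimension %in% eq5d_dimensions())) {
      abort_config("unknown EQ-5D dimension in value set")
    }
    if (!all(dim_rows$level %in% c(2, 3))) {
      abort_config("dimension decrements are defined for levels 2 and 3 only")
    }
    if (anyDuplicated(dim_rows[c("dimension", "level")])) {
      abort_config("duplicate (dimension, level) decrement")
    }
  }
  # level-by-dimension lookup, 0 where unspecified
  dec <- matrix(0, nrow = 5, ncol = 3,
                dimnames = list(eq5d_dimensions(), c("1", "2", "3")))
  if (nrow(dim_rows)) {
    dec[cbind(dim_rows$dimension, as.character(dim_rows$level))] <- dim_rows$decrement
  }
  if (any(dec[, "3"] < dec[, "2"])) {
    abort_config("level-3 decrement must be >= level-2 decrement in every dimension")
  }
  structure(
    list(full_health_value = full_health_value,
         constant = get1("constant"),
         n3 = get1("n3"),
         dimension_decrements = dec),
    class = "value_set"
  )
}

#' @export
print.value_set <- function(x, ...) {
  cat("EQ-5D-3L additive-decrement value set\n")
  cat("  full health:", x$full_health_value,
      " constant:", x$constant, " N3:", x$n3, "\n")
  print(x$dimension_decrements[, c("2", "3")])
  invisible(x)
}

#' A small documented value set for testing and examples
#'
#' Synthetic coefficients in the standard TTO form (constant 0.08, N3
#' 0.10, per-dimension level-2/3 decrements). Not a national tariff; use
#' [eq5d_value_set()] or [read_value_set()] to plug in published
#' coefficients such as the Iranian TTO tariff.
#'
#' @return A `value_set` object.
#' @export
toy_value_set <- function() {
  eq5d_value_set(tibble(
    term = c("constant", "n3",
             rep("dimension", 10)),
    dimension = c(NA, NA, rep(eq5d_dimensions(), each = 2)),
    level = c(NA, NA, rep(c(2, 3), times = 5)),
    decrement = c(0.08, 0.10,
                  0.05, 0.15,   # mobility
                  0.04, 0.12,   # self_care
                  0.04, 0.13,   # usual_activities
                  0.06, 0.16,   # pain_discomfort
                  0.07, 0.12)   # anxiety_depression
  ))
}

#' Read a value set from CSV
#'
#' Expects columns `term,dimension,level,decrement` with
#' `term %in% c("constant","n3","dimension")`.
#'
#' @param path CSV path.
#' @param full_health_value Utility of profile 11111.
#' @return A `value_set` object.
#' @export
read_value_set <- function(path, full_health_value = 1) {
  eq5d_value_set(readr::read_csv(path, show_col_types = FALSE),
                 full_health_value = full_health_value)
}

parse_profiles <- function(profile) {
  if (is.numeric(profile)) profile <- sprintf("%05d", profile)
  profile <- as.character(profile)
  if (any(is.na(profile)) || any(nchar(profile) != 5) ||
      any(!grepl("^[123]{5}$", profile))) {
    abort_invalid("EQ-5D profiles must be 5 digits, each level in {1,2,3}")
  }
  lv <- matrix(as.integer(unlist(strsplit(profile, ""))),
               ncol = 5, byrow = TRUE)
  colnames(lv) <- eq5d_dimensions()
  lv
}

#' Score EQ-5D-3L profiles into utilities
#'
#' Utility = full-health value − constant·1\{any level > 1\} − sum of
#' per-dimension decrements − N3·1\{any level = 3\}. Utilities below zero
#' (states worse than dead) are permitted. Vectorised over profiles.
#'
#' @param profile Character vector of 5-digit profiles (e.g. `"21111"`),
#'   each digit a level in 1–3.
#' @param value_set A `value_set` object.
#' @return Numeric vector of utilities.
#' @export
score_eq5d <- function(profile, value_set) {
  if (!inherits(value_set, "value_set")) {
    abort_config("`value_set` must be built with eq5d_value_set()")
  }
  lv <- parse_profiles(profile)
  dec <- value_set$dimension_decrements
  per_dim <- vapply(seq_len(5), function(d) dec[d, lv[, d]], numeric(nrow(lv)))
  if (nrow(lv) == 1) per_dim <- matrix(per_dim, nrow = 1)
  any_problem <- apply(lv > 1, 1, any)
  any_l3 <- apply(lv == 3, 1, any)
  unname(value_set$full_health_value -
           value_set$constant * any_problem -
           rowSums(per_dim) -
           value_set$n3 * any_l3)
}

#' Mean utility of a set of EQ-5D responses
#'
#' Scores each profile and returns the sample mean, standard deviation
#' (0 when n = 1), and count — the form consumed as a per-health-state
#' utility payoff by the Markov engine.
#'
#' @param profile Character vector of 5-digit profiles (at least one).
#' @param value_set A `value_set` object.
#' @return One-row tibble with `mean`, `sd`, `n`.
#' @export
state_utility <- function(profile, value_set) {
  if (length(profile) < 1) abort_invalid("at least one response is required")
  u <- score_eq5d(profile, value_set)
  tibble(mean = mean(u),
         sd = if (length(u) == 1) 0 else stats::sd(u),
         n = length(u))
}

#' Per-state mean utilities from a response table
#'
#' Groups responses by strategy arm and health-state label and estimates
#' the mean utility of each group.
#'
#' @param responses Data frame with columns `arm`, `state_label`,
#'   `profile`.
#' @param value_set A `value_set` object.
#' @return Tibble with one row per (arm, state_label): `mean`, `sd`, `n`.
#' @export
state_utilities <- function(responses, value_set) {
  responses <- as_tibble(responses)
  req <- c("arm", "state_label", "profile")
  if (!all(req %in% names(responses))) {
    abort_invalid(paste0("responses need columns: ", paste(req, collapse = ", ")))
  }
  responses %>%
    mutate(utility = score_eq5d(.data$profile, value_set)) %>%
    group_by(.data$arm, .data$state_label) %>%
    summarise(mean = mean(.data$utility),
              sd = ifelse(dplyr::n() == 1, 0, stats::sd(.data$utility)),
              n = dplyr::n(), .groups = "drop")
}

#' Expected utility under independent per-dimension level probabilities
#'
#' Exhaustively enumerates all 3^5 = 243 profiles and returns the exact
#' expectation and variance of the scored utility when each dimension's
#' level is drawn independently from the given probability vectors. Used
#' as an analytic oracle for the synthetic response generator.
#'
#' @param level_probs 5 x 3 matrix (rows = dimensions in standard order,
#'   columns = levels 1..3), each row summing to 1.
#' @param value_set A `value_set` object.
#' @return List with `mean` and `var`.
#' @export
expected_utility_exact <- function(level_probs, value_set) {
  level_probs <- as.matrix(level_probs)
  if (!all(dim(level_probs) == c(5, 3)) ||
      any(abs(rowSums(level_probs) - 1) > 1e-9) || any(level_probs < 0)) {
    abort_config("`level_probs` must be 5x3 with rows summing to 1")
  }
  grid <- as.matrix(expand.grid(rep(list(1:3), 5)))
  profiles <- apply(grid, 1, paste0, collapse = "")
  u <- score_eq5d(profiles, value_set)
  p <- apply(grid, 1, function(lv) prod(level_probs[cbind(1:5, lv)]))
  m <- sum(p * u)
  list(mean = m, var = sum(p * (u - m)^2))
}
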