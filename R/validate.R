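# Estimator-validation experiments on synthetic data: CI coverage of the
# asymptotic PRR under a known rate multiplier, and the null-configuration
# panel check.

mean_reactions <- function(p) sum(seq_along(p) * p)

# Case count needed for an expected event count under the default
# reactions-per-case distribution of `base`.
cases_for_events <- function(events, base) {
  max(1L, as.integer(round(events / mean_reactions(base$reactions_per_case))))
}

# Run the estimator pipeline (group assignment, PT mapping, event table) on
# one in-memory synthetic database and return its PRR panel restricted to
# `groups`.
estimate_panel <- function(config, groups = treatment_groups(), ...) {
  x <- assign_groups(synth_cases(config))
  x <- map_reactions(x, load_disease_group_map())
  prr_panel(event_table(x), groups = groups, ...)
}

#' Confidence-interval coverage experiment for the PRR estimator
#'
#' Generates replicate synthetic databases in which one (group, category)
#' cell's reporting rate is inflated by a known multiplier, estimates the
#' PRR of that cell on each replicate, and counts how often the 95% CI
#' covers the configuration's asymptotic PRR. A well-calibrated interval
#' covers in about 95% of replicates.
#'
#' @param n_replicates Number of replicate databases.
#' @param seed Base seed; replicate r uses `seed * 1000 + r`.
#' @param background_events,group_events Expected event counts for the
#'   background stratum and the multiplied group.
#' @param multiplier Rate multiplier applied to the target cell.
#' @param group,category Target cell (default `G2` x `Skin`).
#' @param alpha Interval level passed to the estimator.
#' @return List: `covered` (replicates whose CI contains the truth),
#'   `n_replicates`, `truth` (asymptotic PRR), and `estimates` (per-replicate
#'   `prr`, `ci_low`, `ci_high`, `covered`).
#' @export
prr_coverage_experiment <- function(n_replicates = 100, seed = 1,
                                    background_events = 50000,
                                    group_events = 5000,
                                    multiplier = 3.5, group = "G2",
                                    category = "Skin", alpha = 0.05) {
  mult <- matrix(1, 5, 13,
                 dimnames = list(treatment_groups(), disease_categories()))
  mult[group, category] <- multiplier
  base <- synthetic_config()
  n_grp <- stats::setNames(cases_for_events(group_events, base), group)
  make_cfg <- function(r) {
    synthetic_config(seed = seed * 1000 + r,
                     n_background_cases = cases_for_events(background_events,
                                                           base),
                     n_group_cases = n_grp,
                     group_multipliers = mult,
                     duplicate_version_rate = 0, missing_age_rate = 0)
  }
  truth_tab <- asymptotic_prr(make_cfg(0))
  truth <- truth_tab$prr_asymptotic[truth_tab$group == group &
                                      truth_tab$category == category]
  est <- lapply(seq_len(n_replicates), function(r) {
    pan <- estimate_panel(make_cfg(r), groups = group, alpha = alpha)
    pan[pan$category == category, c("prr", "ci_low", "ci_high")]
  })
  est <- do.call(rbind, est)
  est$covered <- est$ci_low <= truth & truth <= est$ci_high
  list(covered = sum(est$covered), n_replicates = n_replicates,
       truth = truth, estimates = est)
}

#' Null-configuration panel check
#'
#' Generates one synthetic database with all rate multipliers at 1 — so every
#' (group, category) asymptotic PRR is exactly 1 — using equally sized
#' treatment groups large enough that each panel cell is estimated from
#' hundreds of events, and returns the estimated PRR panel. Under the null,
#' every estimate should sit close to 1.
#'
#' @param seed RNG seed.
#' @param group_events Expected events per treatment group (default 10,000).
#' @param background_events Expected background events (default 28,000; the
#'   total of about 78,000 events keeps each cell's sampling error small).
#' @return The estimated `prr_panel` over `G1`-`G5`.
#' @export
null_panel_check <- function(seed = 1, group_events = 10000,
                             background_events = 28000) {
  base <- synthetic_config()
  n_grp <- cases_for_events(group_events, base)
  cfg <- synthetic_config(
    seed = seed,
    n_background_cases = cases_for_events(background_events, base),
    n_group_cases = stats::setNames(rep(n_grp, 5), treatment_groups()),
    duplicate_version_rate = 0, missing_age_rate = 0)
  estimate_panel(cfg)
}
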