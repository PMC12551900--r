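# Synthetic FAERS generator: FAERS-format quarters with known ground truth,
# so ingestion, cohort construction, mapping, and the PRR estimator are all
# testable without downloading real archives.
#
# Background cases carry non-ARPI drugs; treatment-group cases carry the
# defining ARPI(s) plus co-medications and a prostate-cancer indication.
# Disease-category draws for group g use probabilities proportional to
# background_category_probs * group_multipliers[g, ], so the asymptotic PRR
# of every (group, category) cell follows from the config by mixture algebra
# and is stored alongside the data — recovery tests need no second simulator.

ARPI_BRANDS <- c(enzalutamide = "XTANDI", apalutamide = "ERLEADA",
                 darolutamide = "NUBEQA", abiraterone = "ZYTIGA")

CO_MEDICATIONS <- c("LEUPROLIDE", "PREDNISONE", "DEGARELIX", "DOCETAXEL",
                    "METFORMIN", "ATORVASTATIN", "LISINOPRIL", "OMEPRAZOLE")

BACKGROUND_INDICATIONS <- c("HYPERTENSION", "DIABETES MELLITUS",
                            "DEPRESSION", "RHEUMATOID ARTHRITIS")

PROSTATE_INDICATIONS <- c("PROSTATE CANCER",
                          "METASTATIC CASTRATION-RESISTANT PROSTATE CANCER",
                          "PROSTATIC NEOPLASM")

# PTs never present in the starter mapping; they exercise the "Others"
# catch-all.
OTHERS_PTS <- c("OFF LABEL USE", "PRODUCT DOSE OMISSION ISSUE",
                "INAPPROPRIATE SCHEDULE OF PRODUCT ADMINISTRATION",
                "PRODUCT PREPARATION ISSUE", "THERAPY INTERRUPTED")

# Default category reporting probabilities: the published event-by-group
# table's category totals over its 107,582 events.
default_category_probs <- function() {
  counts <- c(18215, 13399, 2794, 9900, 3226, 4198, 9710, 10638, 3146,
              11900, 5027, 5236, 10193)
  stats::setNames(counts / sum(counts), disease_categories())
}

# Default age-band mixture: the published characteristics table's age rows
# summed over groups (44,856 cases).
default_age_distribution <- function() {
  counts <- c(241, 2203, 9368, 16651, 16393)
  stats::setNames(counts / sum(counts), age_bands())
}

#' Configuration for the synthetic FAERS generator
#'
#' Defaults emulate the published ARPI prostate-cancer cohort: group case
#' counts are the published group sizes scaled down tenfold, category
#' probabilities and demographic marginals (age bands, seriousness, reporter
#' type, case priority) are the published table marginals, and the
#' reactions-per-case distribution has mean ~2.4 events per case (the
#' published events/case ratio). Rates the source tables do not pin down
#' (duplicate resubmission rate, missing-age rate) default to realistic
#' spontaneous-reporting values.
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param n_background_cases Unique non-ARPI cases forming the database
#'   background.
#' @param n_group_cases Named counts of unique cases per treatment group
#'   `G1`-`G5` (zeros allowed).
#' @param background_category_probs Length-13 probability vector over
#'   [disease_categories()] (normalized if needed).
#' @param group_multipliers 5 x 13 matrix (groups x categories) of positive
#'   reporting-rate multipliers; group g draws categories with probabilities
#'   proportional to `background_category_probs * group_multipliers[g, ]`.
#' @param age_distribution Length-5 mixture over the age bands.
#' @param reactions_per_case Probabilities for 1, 2, ... reactions per case.
#' @param duplicate_version_rate Fraction of cases shipped with an extra,
#'   superseded version-1 record.
#' @param missing_age_rate Fraction of cases with missing age.
#' @param window Two dates bounding receipt dates.
#' @param serious_rate,reporter_probs,priority_probs Demographic marginals.
#' @param brand_name_rate Fraction of ARPI drug rows written under the brand
#'   name rather than the generic, to exercise name normalization.
#' @param foreign_country_rate,female_background_rate Small contamination
#'   rates exercising the country filter and background heterogeneity.
#' @return A validated `synthetic_config` object.
#' @export
synthetic_config <- function(seed = 1L,
                             n_background_cases = 20000L,
                             n_group_cases = c(G1 = 2581L, G2 = 333L,
                                               G3 = 73L, G4 = 1429L,
                                               G5 = 69L),
                             background_category_probs =
                               default_category_probs(),
                             group_multipliers = NULL,
                             age_distribution = default_age_distribution(),
                             reactions_per_case = c(0.35, 0.25, 0.18,
                                                    0.12, 0.10),
                             duplicate_version_rate = 0.10,
                             missing_age_rate = 0.25,
                             window = as.Date(c("2014-04-30", "2024-04-30")),
                             serious_rate = 0.676,
                             reporter_probs = c(consumer = 0.525,
                                                healthcare_professional = 0.448,
                                                not_specified = 0.027),
                             priority_probs = c(direct = 0.167,
                                                expedited = 0.533,
                                                non_expedited = 0.300),
                             brand_name_rate = 0.5,
                             foreign_country_rate = 0.02,
                             female_background_rate = 0.10) {
  cats <- disease_categories()
  grps <- treatment_groups()
  if (is.null(group_multipliers)) {
    group_multipliers <- matrix(1, length(grps), length(cats),
                                dimnames = list(grps, cats))
  }
  if (!is.matrix(group_multipliers) ||
      !setequal(rownames(group_multipliers), grps)) {
    stop_fmt("group_multipliers must be a matrix with rows G1-G5")
  }
  unknown <- setdiff(colnames(group_multipliers), cats)
  if (length(unknown)) {
    stop_fmt("group_multipliers: unknown category '%s'", unknown[1])
  }
  if (!setequal(colnames(group_multipliers), cats)) {
    stop_fmt("group_multipliers must have one column per disease category")
  }
  group_multipliers <- group_multipliers[grps, cats]
  if (any(group_multipliers <= 0)) {
    stop_fmt("group_multipliers must be positive")
  }
  if (length(background_category_probs) != length(cats) ||
      any(background_category_probs < 0) ||
      sum(background_category_probs) <= 0) {
    stop_fmt("background_category_probs must be 13 non-negative weights")
  }
  background_category_probs <-
    stats::setNames(background_category_probs /
                      sum(background_category_probs), cats)
  if (length(age_distribution) != 5L || any(age_distribution < 0)) {
    stop_fmt("age_distribution must be 5 non-negative weights")
  }
  age_distribution <- stats::setNames(age_distribution /
                                        sum(age_distribution), age_bands())
  n_group_cases <- n_group_cases[grps]
  n_group_cases[is.na(n_group_cases)] <- 0L
  names(n_group_cases) <- grps
  stopifnot(n_background_cases >= 0, all(n_group_cases >= 0),
            duplicate_version_rate >= 0, duplicate_version_rate <= 1,
            missing_age_rate >= 0, missing_age_rate <= 1,
            all(reactions_per_case >= 0), sum(reactions_per_case) > 0)
  structure(list(
    seed = as.integer(seed),
    n_background_cases = as.integer(n_background_cases),
    n_group_cases = stats::setNames(as.integer(n_group_cases), grps),
    background_category_probs = background_category_probs,
    group_multipliers = group_multipliers,
    age_distribution = age_distribution,
    reactions_per_case = reactions_per_case / sum(reactions_per_case),
    duplicate_version_rate = duplicate_version_rate,
    missing_age_rate = missing_age_rate,
    window = as.Date(window),
    serious_rate = serious_rate,
    reporter_probs = reporter_probs / sum(reporter_probs),
    priority_probs = priority_probs / sum(priority_probs),
    brand_name_rate = brand_name_rate,
    foreign_country_rate = foreign_country_rate,
    female_background_rate = female_background_rate
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("synthetic FAERS config: seed %d, %d background + %s group cases\n",
              x$seed, x$n_background_cases,
              paste(names(x$n_group_cases), x$n_group_cases, sep = "=",
                    collapse = " ")))
  nonunit <- which(x$group_multipliers != 1, arr.ind = TRUE)
  if (nrow(nonunit)) {
    cat("  non-unit multipliers:\n")
    for (i in seq_len(nrow(nonunit))) {
      cat(sprintf("    %s x %s = %g\n",
                  rownames(x$group_multipliers)[nonunit[i, 1]],
                  colnames(x$group_multipliers)[nonunit[i, 2]],
                  x$group_multipliers[nonunit[i, 1], nonunit[i, 2]]))
    }
  }
  invisible(x)
}

# Per-stratum category probabilities implied by the config.
stratum_category_probs <- function(config) {
  p0 <- config$background_category_probs
  probs <- rbind(background = p0,
                 t(apply(config$group_multipliers, 1, function(mult) {
                   w <- p0 * mult
                   w / sum(w)
                 })))
  probs
}

#' Asymptotic PRR implied by a synthetic configuration
#'
#' The infinite-sample PRR of every (group, category) cell, computed
#' analytically from the config's mixture structure: the group's category
#' probability over the event-weighted average category probability of all
#' other strata (background plus the other groups). This is the ground truth
#' that estimator-recovery and CI-coverage experiments target.
#'
#' @param config A `synthetic_config`.
#' @return Data frame `group`, `category`, `prr_asymptotic`.
#' @export
asymptotic_prr <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  probs <- stratum_category_probs(config)
  w <- c(background = config$n_background_cases, config$n_group_cases)
  w <- w[w > 0]
  probs <- probs[names(w), , drop = FALSE]
  grps <- setdiff(names(w), "background")
  out <- expand.grid(category = disease_categories(), group = grps,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("group", "category")]
  out$prr_asymptotic <- mapply(function(g, cat) {
    rest <- setdiff(names(w), g)
    num <- probs[g, cat]
    den <- sum(w[rest] * probs[rest, cat]) / sum(w[rest])
    num / den
  }, out$group, out$category)
  rownames(out) <- NULL
  out
}

# Integer age ranges the bands are drawn from.
BAND_AGE_RANGE <- list(c(40L, 49L), c(50L, 59L), c(60L, 69L), c(70L, 79L),
                       c(80L, 94L))

#' Generate synthetic FAERS cases in memory
#'
#' Draws one full synthetic database (background plus treatment groups) as a
#' `faers_cases` container: demographics with configured marginals, injected
#' missing ages and superseded duplicate versions, ARPI/co-medication drug
#' lists with prostate-cancer indications on group cases, and reaction PTs
#' drawn per the config's category mixture. Deterministic given
#' `config$seed`.
#'
#' Ground-truth bookkeeping is attached as attributes: `ground_truth` (the
#' [asymptotic_prr()] table), and `truth` (a list with unique case counts per
#' stratum, injected duplicate-record and missing-age counts, and current
#' event counts per stratum).
#'
#' @param config A `synthetic_config`.
#' @return A `faers_cases` object with `ground_truth` and `truth` attributes.
#' @export
synth_cases <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cats <- disease_categories()
  n_str <- c(background = config$n_background_cases, config$n_group_cases)
  n_str <- n_str[n_str > 0]
  n <- sum(n_str)
  stratum <- rep(names(n_str), n_str)

  caseid <- sprintf("1%07d", seq_len(n))
  band_idx <- sample.int(5L, n, replace = TRUE,
                         prob = config$age_distribution)
  lo <- vapply(BAND_AGE_RANGE, `[`, integer(1), 1L)[band_idx]
  hi <- vapply(BAND_AGE_RANGE, `[`, integer(1), 2L)[band_idx]
  age <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  age_missing <- stats::runif(n) < config$missing_age_rate
  age[age_missing] <- NA_real_

  sex <- ifelse(stratum == "background" &
                  stats::runif(n) < config$female_background_rate,
                "female", "male")
  country <- ifelse(stats::runif(n) < config$foreign_country_rate,
                    "GB", "US")
  serious <- stats::runif(n) < config$serious_rate
  reporter <- sample(names(config$reporter_probs), n, replace = TRUE,
                     prob = config$reporter_probs)
  priority <- sample(names(config$priority_probs), n, replace = TRUE,
                     prob = config$priority_probs)
  span <- as.integer(config$window[2] - config$window[1])
  rdate <- config$window[1] + floor(stats::runif(n) * (span + 1L))

  dup <- stats::runif(n) < config$duplicate_version_rate
  version <- ifelse(dup, 2L, 1L)
  primaryid <- paste0(caseid, sprintf("%02d", version))

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, caseversion = version,
    receipt_date = rdate, age_years = as.numeric(age), sex = sex,
    country = country, reporter_type = reporter,
    seriousness = ifelse(serious, "serious", "non_serious"),
    case_priority = priority, stringsAsFactors = FALSE
  )

  # --- drugs ---------------------------------------------------------------
  is_grp <- stratum != "background"
  grp_idx <- which(is_grp)
  grp_arpis <- lapply(stratum[grp_idx], function(g) {
    switch(g, G1 = "enzalutamide", G2 = "apalutamide", G3 = "darolutamide",
           G4 = "abiraterone", G5 = c("abiraterone", "enzalutamide"))
  })
  arpi_case <- rep(grp_idx, lengths(grp_arpis))
  arpi_ing <- unlist(grp_arpis)
  use_brand <- stats::runif(length(arpi_ing)) < config$brand_name_rate
  arpi_name <- ifelse(use_brand, ARPI_BRANDS[arpi_ing], toupper(arpi_ing))
  arpi_rows <- data.frame(
    case = arpi_case, verbatim_name = arpi_name, role = "PS",
    indication = sample(PROSTATE_INDICATIONS, length(arpi_case),
                        replace = TRUE),
    stringsAsFactors = FALSE
  )
  n_co <- integer(n)
  n_co[grp_idx] <- sample(0:2, length(grp_idx), replace = TRUE)
  bg_idx <- which(!is_grp)
  n_co[bg_idx] <- sample(1:3, length(bg_idx), replace = TRUE)
  co_case <- rep(seq_len(n), n_co)
  co_rows <- data.frame(
    case = co_case,
    verbatim_name = sample(CO_MEDICATIONS, length(co_case), replace = TRUE),
    role = "C", indication = NA_character_, stringsAsFactors = FALSE
  )
  # Background cases: promote their first drug to suspect with an indication,
  # so every case has a suspect drug.
  first_bg <- !duplicated(co_rows$case) & co_rows$case %in% bg_idx
  co_rows$role[first_bg] <- "PS"
  co_rows$indication[first_bg] <- sample(BACKGROUND_INDICATIONS,
                                         sum(first_bg), replace = TRUE)
  drug_rows <- rbind(arpi_rows, co_rows)
  drug_rows <- drug_rows[order(drug_rows$case), , drop = FALSE]
  seq_in_case <- stats::ave(drug_rows$case, drug_rows$case,
                            FUN = seq_along)
  drugs <- data.frame(
    primaryid = primaryid[drug_rows$case],
    drug_seq = as.integer(seq_in_case),
    verbatim_name = drug_rows$verbatim_name,
    active_ingredient = normalize_drug_name(drug_rows$verbatim_name,
                                            load_drug_synonyms()),
    role = c(PS = "suspect", C = "concomitant")[drug_rows$role],
    indication_pt = drug_rows$indication,
    stringsAsFactors = FALSE
  )

  # --- reactions -----------------------------------------------------------
  k <- length(config$reactions_per_case)
  r_per_case <- sample.int(k, n, replace = TRUE,
                           prob = config$reactions_per_case)
  ev_case <- rep(seq_len(n), r_per_case)
  probs <- stratum_category_probs(config)
  ev_stratum <- stratum[ev_case]
  cat_idx <- integer(length(ev_case))
  for (s in rownames(probs)) {
    mask <- ev_stratum == s
    if (any(mask)) {
      cat_idx[mask] <- sample.int(length(cats), sum(mask), replace = TRUE,
                                  prob = probs[s, ])
    }
  }
  pools <- pt_pools()
  pt <- character(length(ev_case))
  for (ci in seq_along(cats)) {
    mask <- cat_idx == ci
    if (any(mask)) {
      pt[mask] <- sample(pools[[cats[ci]]], sum(mask), replace = TRUE)
    }
  }
  reactions <- data.frame(primaryid = primaryid[ev_case], pt = pt,
                          disease_group = NA_character_,
                          stringsAsFactors = FALSE)

  # --- superseded duplicate versions ---------------------------------------
  if (any(dup)) {
    old <- demo[dup, , drop = FALSE]
    old$caseversion <- 1L
    old$receipt_date <- old$receipt_date - 30L
    old$primaryid <- paste0(old$caseid, "01")
    oldmap <- stats::setNames(old$primaryid, demo$primaryid[dup])
    old_drugs <- drugs[drugs$primaryid %in% names(oldmap), , drop = FALSE]
    old_drugs$primaryid <- unname(oldmap[old_drugs$primaryid])
    old_reac <- reactions[reactions$primaryid %in% names(oldmap), ,
                          drop = FALSE]
    old_reac$primaryid <- unname(oldmap[old_reac$primaryid])
    demo <- rbind(demo, old)
    drugs <- rbind(drugs, old_drugs)
    reactions <- rbind(reactions, old_reac)
  }
  ord <- order(demo$primaryid)
  demo <- demo[ord, , drop = FALSE]
  drugs <- drugs[order(drugs$primaryid, drugs$drug_seq), , drop = FALSE]
  reactions <- reactions[order(reactions$primaryid), , drop = FALSE]
  rownames(demo) <- rownames(drugs) <- rownames(reactions) <- NULL

  events_per_stratum <- tapply(r_per_case, stratum, sum)
  out <- new_faers_cases(demo, drugs, reactions)
  attr(out, "ground_truth") <- asymptotic_prr(config)
  attr(out, "truth") <- list(
    unique_cases = stats::setNames(as.integer(n_str), names(n_str)),
    n_unique_total = n,
    duplicate_records = sum(dup),
    missing_age = sum(age_missing),
    events_per_stratum = stats::setNames(as.integer(events_per_stratum),
                                         names(events_per_stratum)),
    total_events = length(ev_case)
  )
  out
}

# Preferred-term pools per category: the packaged starter mapping's PTs for
# the twelve named groups, plus unmapped terms for "Others".
pt_pools <- function() {
  map <- load_disease_group_map()
  pools <- split(names(map), unname(unclass(map)))
  pools[["Others"]] <- OTHERS_PTS
  pools[disease_categories()]
}

#' Generate a synthetic FAERS quarter on disk
#'
#' Runs [synth_cases()] and writes the `$`-delimited DEMO/DRUG/REAC/INDI/OUTC
#' files (parseable by [read_faers_quarter()]) plus two ground-truth TSVs:
#' `ground_truth.tsv` (asymptotic PRR per group and category) and
#' `truth_counts.tsv` (unique case, duplicate, missing-age, and event
#' bookkeeping). Byte-identical output under a fixed seed.
#'
#' @param config A `synthetic_config`.
#' @param out_dir Output directory (created if needed).
#' @return Named vector of all written file paths, invisibly.
#' @export
generate_faers <- function(config, out_dir) {
  x <- synth_cases(config)
  paths <- write_faers_quarter(x, out_dir)
  gt <- attr(x, "ground_truth")
  gt$prr_asymptotic <- sprintf("%.10g", gt$prr_asymptotic)
  gt_path <- file.path(out_dir, "ground_truth.tsv")
  utils::write.table(gt, gt_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- attr(x, "truth")
  counts <- data.frame(
    metric = c(paste0("unique_cases_", names(tr$unique_cases)),
               "n_unique_total", "duplicate_records", "missing_age",
               paste0("events_", names(tr$events_per_stratum)),
               "total_events"),
    value = c(tr$unique_cases, tr$n_unique_total, tr$duplicate_records,
              tr$missing_age, tr$events_per_stratum, tr$total_events),
    stringsAsFactors = FALSE
  )
  tc_path <- file.path(out_dir, "truth_counts.tsv")
  utils::write.table(counts, tc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, ground_truth = gt_path, truth_counts = tc_path))
}
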