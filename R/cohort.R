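# Cohort construction: eligibility filters, ARPI treatment-group assignment,
# and age-band categorization.

US_COUNTRY_CODES <- c("US", "USA", "UNITED STATES", "UNITED STATES OF AMERICA")

PROSTATE_INDICATION_PATTERNS <- c("prostate cancer", "prostatic",
                                  "castration-resistant")

#' Assign an ARPI treatment group from a case's ingredient set
#'
#' Group definitions: `G1` enzalutamide, `G2` apalutamide, `G3` darolutamide,
#' `G4` abiraterone — each with other (non-ARPI) medications only; `G5` the
#' abiraterone + enzalutamide combination, provided neither apalutamide nor
#' darolutamide is present. Any other ARPI combination, or no ARPI at all, is
#' `excluded`. The result is invariant to ingredient order and to non-ARPI
#' co-medications.
#'
#' @param ingredients Character vector of normalized active ingredients on one
#'   case (duplicates and non-ARPI drugs allowed).
#' @return One of `"G1"`..`"G5"` or `"excluded"`.
#' @export
#' @examples
#' assign_treatment_group(c("enzalutamide", "prednisone", "leuprolide"))
#' assign_treatment_group(c("abiraterone", "enzalutamide", "prednisone"))
#' assign_treatment_group(c("enzalutamide", "apalutamide"))
assign_treatment_group <- function(ingredients) {
  arpis <- intersect(unique(ingredients), arpi_ingredients())
  if (length(arpis) == 1L) {
    return(paste0("G", match(arpis, arpi_ingredients())))
  }
  if (length(arpis) == 2L && all(c("abiraterone", "enzalutamide") %in% arpis)) {
    return("G5")
  }
  "excluded"
}

#' Assign treatment groups to every case in a container
#'
#' Vectorized application of [assign_treatment_group()] over the drug lists of
#' all cases; adds a `group` column to the demographic table.
#'
#' @param x A `faers_cases` object (ingredients already normalized).
#' @return `x` with `x$demo$group` set.
#' @export
assign_groups <- function(x) {
  stopifnot(inherits(x, "faers_cases"))
  pid <- x$demo$primaryid
  ing <- x$drugs$active_ingredient
  dpid <- x$drugs$primaryid
  has <- vapply(arpi_ingredients(), function(a) {
    pid %in% dpid[ing == a]
  }, logical(length(pid)))
  if (length(pid) == 1L) has <- matrix(has, nrow = 1L,
                                       dimnames = list(NULL, arpi_ingredients()))
  n_arpi <- rowSums(has)
  grp <- rep("excluded", length(pid))
  for (k in 1:4) {
    grp[n_arpi == 1L & has[, k]] <- paste0("G", k)
  }
  grp[n_arpi == 2L & has[, "enzalutamide"] & has[, "abiraterone"]] <- "G5"
  x$demo$group <- grp
  x
}

#' Categorize ages into the five analysis bands
#'
#' Bands partition the non-negative axis: `<50`, `50-59`, `60-69`, `70-79`,
#' `>=80`; each lower boundary belongs to the band it names (age 50 is
#' `50-59`, age 80 is `>=80`). Missing ages map to `"missing"`.
#'
#' @param age_years Numeric vector of ages in years (NA allowed).
#' @return Character vector of band labels.
#' @export
#' @examples
#' categorize_age(c(0, 49.9, 50, 60, 70, 79, 80))
categorize_age <- function(age_years) {
  if (any(!is.na(age_years) & age_years < 0)) {
    stop_fmt("negative age_years supplied to categorize_age()")
  }
  out <- as.character(cut(age_years, breaks = c(0, 50, 60, 70, 80, Inf),
                          labels = age_bands(), right = FALSE,
                          include.lowest = TRUE))
  out[is.na(age_years)] <- "missing"
  out
}

# primaryids holding >=1 ARPI drug entry with a prostate indication.
prostate_arpi_ids <- function(drugs, patterns, roles) {
  is_arpi <- drugs$active_ingredient %in% arpi_ingredients() &
    drugs$role %in% roles
  ind <- tolower(drugs$indication_pt)
  ind[is.na(ind)] <- ""
  hit <- rep(FALSE, nrow(drugs))
  for (p in tolower(patterns)) hit <- hit | grepl(p, ind, fixed = TRUE)
  unique(drugs$primaryid[is_arpi & hit])
}

#' Apply the cohort eligibility filters
#'
#' Sequentially retains cases (i) received within the closed date window
#' `[window_start, window_end]`, (ii) occurring in the United States (the
#' occurrence-country field, with reporter country as fallback at read time),
#' (iii) carrying a prostate-cancer indication on an ARPI drug entry, and
#' (iv) with non-missing age. Each filter's removal count is recorded in a
#' flow table so that removals + retained always reconcile to the input count.
#'
#' @param x A `faers_cases` object.
#' @param window_start,window_end Dates (or strings coercible to `Date`)
#'   bounding the study window, both ends inclusive.
#' @param countries Country strings accepted as United States.
#' @param indication_patterns Lower-case substrings identifying a
#'   prostate-cancer indication PT.
#' @param arpi_roles Drug roles in which an ARPI may appear for eligibility
#'   (default: any role, since group definitions inspect the full drug list).
#' @param require_indication,require_age Toggle filters (iii) and (iv); the
#'   full FAERS background used as the PRR comparator is filtered with
#'   `require_indication = FALSE`.
#' @return List with `cases` (the filtered `faers_cases`) and `flow`, a data
#'   frame of per-step counts (`step`, `removed`, `remaining`).
#' @export
filter_cohort <- function(x, window_start, window_end,
                          countries = US_COUNTRY_CODES,
                          indication_patterns = PROSTATE_INDICATION_PATTERNS,
                          arpi_roles = c("suspect", "concomitant",
                                         "interacting"),
                          require_indication = TRUE, require_age = TRUE) {
  stopifnot(inherits(x, "faers_cases"))
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (window_start > window_end) {
    stop_fmt("window_start (%s) is after window_end (%s)",
             window_start, window_end)
  }
  d <- x$demo
  n0 <- nrow(d)
  flow <- data.frame(step = "input", removed = 0L, remaining = n0,
                     stringsAsFactors = FALSE)
  note <- function(step, keep) {
    flow <<- rbind(flow, data.frame(step = step, removed = sum(!keep),
                                    remaining = sum(keep),
                                    stringsAsFactors = FALSE))
  }

  keep <- d$receipt_date >= window_start & d$receipt_date <= window_end
  note("outside date window", keep)
  d <- d[keep, , drop = FALSE]

  keep <- toupper(d$country) %in% toupper(countries)
  note("non-US country", keep)
  d <- d[keep, , drop = FALSE]

  if (require_indication) {
    eligible <- prostate_arpi_ids(x$drugs, indication_patterns, arpi_roles)
    keep <- d$primaryid %in% eligible
    note("no prostate-cancer ARPI indication", keep)
    d <- d[keep, , drop = FALSE]
  }

  if (require_age) {
    keep <- !is.na(d$age_years)
    note("missing age", keep)
    d <- d[keep, , drop = FALSE]
  }

  out <- new_faers_cases(
    d,
    x$drugs[x$drugs$primaryid %in% d$primaryid, , drop = FALSE],
    x$reactions[x$reactions$primaryid %in% d$primaryid, , drop = FALSE],
    x$diagnostics
  )
  rownames(out$demo) <- rownames(out$drugs) <- rownames(out$reactions) <- NULL
  list(cases = out, flow = flow)
}
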