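# Adverse-event grouping: MedDRA-style preferred terms (PTs) mapped into 12
# disease categories plus an "Others" catch-all.

#' Load a PT-to-disease-group mapping file
#'
#' Reads a two-column TSV (`pt`, `category`). PT keys are normalized
#' (uppercased, whitespace-collapsed); categories must match the thirteen
#' labels of [disease_categories()] byte-for-byte. A PT listed twice with
#' conflicting categories is a load error (every conflict is reported); exact
#' duplicates are collapsed.
#'
#' The package ships a starter mapping of common oncology-pharmacovigilance
#' PTs (`system.file("extdata", "disease_group_map.tsv", package =
#' "faersignal")`); the mapping is user-supplied data in real analyses, since
#' the MedDRA dictionary itself is licensed and cannot be bundled.
#'
#' @param path Path to the mapping TSV; `NULL` for the packaged starter map.
#' @return A `disease_group_map`: named character vector (PT -> category) with
#'   a `categories` attribute.
#' @export
load_disease_group_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "disease_group_map.tsv",
                                package = "faersignal")
  if (!file.exists(path)) stop_fmt("mapping file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("pt", "category") %in% names(df))) {
    stop_fmt("mapping file %s must have columns 'pt' and 'category'", path)
  }
  bad <- !(df$category %in% disease_categories())
  if (any(bad)) {
    i <- which(bad)[1]
    stop_fmt("mapping file %s row %d: unknown category '%s'",
             path, i, df$category[i])
  }
  pt <- normalize_key(df$pt)
  df <- df[!duplicated(paste(pt, df$category)), , drop = FALSE]
  pt <- normalize_key(df$pt)
  dup <- pt[duplicated(pt)]
  if (length(dup)) {
    stop_fmt("mapping file %s: conflicting categories for PT(s): %s",
             path, paste(unique(dup), collapse = ", "))
  }
  structure(stats::setNames(df$category, pt),
            categories = disease_categories(),
            class = "disease_group_map")
}

#' Assign disease groups to all reaction entries
#'
#' Every reaction PT gains a `disease_group`: its mapped category, or
#' `"Others"` when absent from the map. The counting convention allows more
#' than one adverse event per patient — each reaction entry contributes one
#' event count — unless `collapse_duplicates = TRUE`, which drops repeated
#' identical PTs within a case. Idempotent and order-independent.
#'
#' @param x A `faers_cases` object.
#' @param map A `disease_group_map` from [load_disease_group_map()].
#' @param collapse_duplicates Drop duplicate (case, PT) reaction entries
#'   before counting? Default `FALSE`.
#' @return `x` with `x$reactions$disease_group` filled in.
#' @export
map_reactions <- function(x, map, collapse_duplicates = FALSE) {
  stopifnot(inherits(x, "faers_cases"), inherits(map, "disease_group_map"))
  r <- x$reactions
  if (collapse_duplicates) {
    r <- r[!duplicated(paste(r$primaryid, r$pt)), , drop = FALSE]
    rownames(r) <- NULL
  }
  hit <- unclass(map)[r$pt]
  r$disease_group <- ifelse(is.na(hit), "Others", unname(hit))
  x$reactions <- r
  x
}

#' Long event table for counting and disproportionality
#'
#' One row per mapped reaction entry, carrying the owning case's treatment
#' group and age band. This is the common input of [events_by_stratum()] and
#' [prr_panel()]; for PRR use it must span the whole database (background
#' cases included, `group = "excluded"`), not only groups G1-G5.
#'
#' @param x A `faers_cases` object with groups assigned ([assign_groups()])
#'   and reactions mapped ([map_reactions()]).
#' @return Data frame with columns `primaryid`, `group`, `age_band`,
#'   `category`, `pt`.
#' @export
event_table <- function(x) {
  stopifnot(inherits(x, "faers_cases"))
  if (is.null(x$demo$group)) {
    stop_fmt("treatment groups not assigned; call assign_groups() first")
  }
  if (anyNA(x$reactions$disease_group)) {
    stop_fmt("reactions not mapped; call map_reactions() first")
  }
  i <- match(x$reactions$primaryid, x$demo$primaryid)
  data.frame(primaryid = x$reactions$primaryid,
             group = x$demo$group[i],
             age_band = categorize_age(x$demo$age_years[i]),
             category = x$reactions$disease_group,
             pt = x$reactions$pt,
             stringsAsFactors = FALSE)
}

#' Preferred-term frequency report
#'
#' Counts reaction entries per PT across the supplied cases, supporting the
#' screening rule that only PTs above a reporting floor (conventionally 100
#' reports) are worth individual mapping review; rarer PTs fall to "Others".
#'
#' @param x A `faers_cases` object.
#' @param min_count Only PTs with at least this many entries are returned.
#' @return Data frame (`pt`, `count`), most frequent first.
#' @export
pt_frequency <- function(x, min_count = 1L) {
  stopifnot(inherits(x, "faers_cases"))
  tb <- sort(table(x$reactions$pt), decreasing = TRUE)
  out <- data.frame(pt = names(tb), count = as.integer(tb),
                    stringsAsFactors = FALSE)
  out[out$count >= min_count, , drop = FALSE]
}
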