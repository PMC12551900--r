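# FAERS quarterly extract ingestion: `$`-delimited ASCII files (post-2012
# layout), joined into a columnar case container and deduplicated to one
# current record per case.

DEMO_COLS <- c("primaryid", "caseid", "caseversion", "fda_dt", "age",
               "age_cod", "sex", "occp_cod", "rept_cod", "occr_country",
               "reporter_country")
DRUG_COLS <- c("primaryid", "drug_seq", "role_cod", "drugname")
REAC_COLS <- c("primaryid", "pt")
INDI_COLS <- c("primaryid", "indi_drug_seq", "indi_pt")

# Divisors converting FAERS age-unit codes to years.
AGE_UNIT_DIV <- c(DEC = 0.1, YR = 1, MON = 12, WK = 52, DY = 365.25, HR = 8766)

new_faers_cases <- function(demo, drugs, reactions,
                            diagnostics = empty_diagnostics()) {
  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 diagnostics = diagnostics),
            class = "faers_cases")
}

empty_diagnostics <- function() {
  data.frame(file = character(), primaryid = character(),
             reason = character(), stringsAsFactors = FALSE)
}

diag_row <- function(file, primaryid, reason) {
  data.frame(file = file, primaryid = as.character(primaryid),
             reason = reason, stringsAsFactors = FALSE)
}

#' Ingest diagnostics
#'
#' Rows of the input files that were rejected or repaired during ingestion,
#' one record per problem with the file it came from and the reason. Malformed
#' rows are quarantined here rather than aborting the read, so a single bad
#' row cannot sink a quarter.
#'
#' @param x A `faers_cases` object.
#' @return A data frame with columns `file`, `primaryid`, `reason`.
#' @export
diagnostics <- function(x) {
  stopifnot(inherits(x, "faers_cases"))
  x$diagnostics
}

#' Write the diagnostics report as plain text
#'
#' One line per rejected or repaired row, `file<TAB>primaryid<TAB>reason`.
#'
#' @param x A `faers_cases` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(x, path) {
  d <- diagnostics(x)
  writeLines(paste(d$file, d$primaryid, d$reason, sep = "\t"), path)
  invisible(path)
}

#' Number of case records in a `faers_cases` container
#'
#' @param x A `faers_cases` object.
#' @return Integer count of (case, version) records currently held.
#' @export
n_cases <- function(x) {
  stopifnot(inherits(x, "faers_cases"))
  nrow(x$demo)
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("FAERS cases: %d records (%d unique case ids)\n",
              nrow(x$demo), length(unique(x$demo$caseid))))
  cat(sprintf("  drug entries:     %d\n", nrow(x$drugs)))
  cat(sprintf("  reaction entries: %d\n", nrow(x$reactions)))
  cat(sprintf("  diagnostics:      %d\n", nrow(x$diagnostics)))
  if ("group" %in% names(x$demo)) {
    tb <- table(x$demo$group)
    cat("  groups: ", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# Read one `$`-delimited FAERS ASCII table. The legacy (pre-2012) layout keys
# rows on ISR rather than primaryid and is rejected outright: the supported
# study window is entirely post-2012.
read_dollar_file <- function(path, required_cols, label) {
  if (!file.exists(path)) stop_fmt("%s file not found: %s", label, path)
  df <- utils::read.table(path, sep = "$", header = TRUE, quote = "",
                          comment.char = "", fill = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  names(df) <- tolower(names(df))
  if ("isr" %in% names(df) && !"primaryid" %in% names(df)) {
    stop_fmt("%s: legacy (pre-2012, ISR-keyed) FAERS layout is not supported",
             label)
  }
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop_fmt("%s (%s): missing required columns: %s", label, path,
             paste(missing, collapse = ", "))
  }
  df
}

parse_fda_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- grepl("^[0-9]{8}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

# Convert FAERS (age, age_cod) pairs to years; unknown codes treated as years.
age_to_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(age_cod))
  div <- AGE_UNIT_DIV[cod]
  div[is.na(div) | cod == ""] <- 1
  v / unname(div)
}

recode_sex <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("unknown", length(x))
  out[x == "M"] <- "male"
  out[x == "F"] <- "female"
  out
}

recode_reporter <- function(occp_cod) {
  x <- toupper(trimws(occp_cod))
  out <- rep("not_specified", length(x))
  out[x == "CN"] <- "consumer"
  out[x %in% c("MD", "PH", "OT", "HP", "RN")] <- "healthcare_professional"
  out
}

recode_priority <- function(rept_cod) {
  x <- toupper(trimws(rept_cod))
  out <- rep("non_expedited", length(x))
  out[x %in% c("DIR", "DIRECT")] <- "direct"
  out[x %in% c("EXP", "5DAY")] <- "expedited"
  out
}

recode_role <- function(role_cod) {
  x <- toupper(trimws(role_cod))
  out <- rep("concomitant", length(x))
  out[x %in% c("PS", "SS")] <- "suspect"
  out[x == "I"] <- "interacting"
  out
}

#' Read one FAERS quarterly extract
#'
#' Parses the `$`-delimited ASCII DEMO/DRUG/REAC/INDI files of a post-2012
#' FAERS quarterly extract, joins drug, indication, and reaction rows to their
#' demographic record by `primaryid`, and validates each record. Ages are
#' converted to years from the FAERS unit code (decades, months, weeks, days);
#' drug names are normalized against a synonym table. A case record is valid
#' only if it retains at least one non-empty drug entry and at least one
#' reaction; invalid records and unparseable rows are quarantined in the
#' diagnostics report (see [diagnostics()]), never silently dropped.
#'
#' Seriousness is taken from the optional OUTC (outcome) file: a case with any
#' outcome row is `serious`, otherwise `non_serious`.
#'
#' @param demo_path,drug_path,reac_path,indi_path Paths to the DEMO, DRUG,
#'   REAC, and INDI files of one quarter.
#' @param outc_path Optional path to the OUTC file; if `NULL`, all cases are
#'   recorded as `non_serious`.
#' @param synonyms Drug-synonym table, as returned by [load_drug_synonyms()];
#'   defaults to the table shipped with the package.
#' @return A `faers_cases` object: a list of three aligned data frames
#'   (`demo`, one row per (case, version) record; `drugs`; `reactions`) plus
#'   the ingest `diagnostics`.
#' @export
read_faers_quarter <- function(demo_path, drug_path, reac_path, indi_path,
                               outc_path = NULL,
                               synonyms = load_drug_synonyms()) {
  demo_raw <- read_dollar_file(demo_path, DEMO_COLS, "DEMO")
  drug_raw <- read_dollar_file(drug_path, DRUG_COLS, "DRUG")
  reac_raw <- read_dollar_file(reac_path, REAC_COLS, "REAC")
  indi_raw <- read_dollar_file(indi_path, INDI_COLS, "INDI")
  serious_ids <- character()
  if (!is.null(outc_path)) {
    outc_raw <- read_dollar_file(outc_path, "primaryid", "OUTC")
    serious_ids <- unique(trimws(outc_raw$primaryid))
  }

  diags <- list()

  # --- DEMO -----------------------------------------------------------------
  pid <- trimws(demo_raw$primaryid)
  ver <- suppressWarnings(as.integer(demo_raw$caseversion))
  bad_ver <- is.na(ver) | ver < 0
  if (any(bad_ver)) {
    diags[[length(diags) + 1L]] <-
      diag_row("DEMO", pid[bad_ver], "unparseable or negative caseversion")
  }
  rdate <- parse_fda_date(trimws(demo_raw$fda_dt))
  bad_date <- is.na(rdate)
  if (any(bad_date & !bad_ver)) {
    diags[[length(diags) + 1L]] <-
      diag_row("DEMO", pid[bad_date & !bad_ver], "unparseable fda_dt")
  }
  keep <- !bad_ver & !bad_date & pid != ""

  age_years <- age_to_years(demo_raw$age, demo_raw$age_cod)
  bad_age <- !is.na(age_years) & (age_years < 0 | age_years > 130)
  if (any(bad_age & keep)) {
    diags[[length(diags) + 1L]] <-
      diag_row("DEMO", pid[bad_age & keep],
               "age outside [0, 130] years; set to missing")
  }
  age_years[bad_age] <- NA_real_

  country <- trimws(demo_raw$occr_country)
  rep_country <- trimws(demo_raw$reporter_country)
  country[country == ""] <- rep_country[country == ""]

  demo <- data.frame(
    primaryid = pid,
    caseid = trimws(demo_raw$caseid),
    caseversion = ver,
    receipt_date = rdate,
    age_years = age_years,
    sex = recode_sex(demo_raw$sex),
    country = country,
    reporter_type = recode_reporter(demo_raw$occp_cod),
    seriousness = ifelse(pid %in% serious_ids, "serious", "non_serious"),
    case_priority = recode_priority(demo_raw$rept_cod),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]

  # --- DRUG + INDI ----------------------------------------------------------
  dr_pid <- trimws(drug_raw$primaryid)
  dr_name <- trimws(drug_raw$drugname)
  empty_name <- dr_name == ""
  if (any(empty_name)) {
    diags[[length(diags) + 1L]] <-
      diag_row("DRUG", dr_pid[empty_name], "empty drugname; entry dropped")
  }
  drugs <- data.frame(
    primaryid = dr_pid,
    drug_seq = suppressWarnings(as.integer(drug_raw$drug_seq)),
    verbatim_name = dr_name,
    role = recode_role(drug_raw$role_cod),
    stringsAsFactors = FALSE
  )[!empty_name, , drop = FALSE]
  drugs$active_ingredient <- normalize_drug_name(drugs$verbatim_name, synonyms)

  indi <- data.frame(
    primaryid = trimws(indi_raw$primaryid),
    drug_seq = suppressWarnings(as.integer(indi_raw$indi_drug_seq)),
    indication_pt = normalize_key(indi_raw$indi_pt),
    stringsAsFactors = FALSE
  )
  key_d <- paste(drugs$primaryid, drugs$drug_seq)
  key_i <- paste(indi$primaryid, indi$drug_seq)
  drugs$indication_pt <- indi$indication_pt[match(key_d, key_i)]

  # --- REAC -----------------------------------------------------------------
  re_pid <- trimws(reac_raw$primaryid)
  re_pt <- normalize_key(reac_raw$pt)
  empty_pt <- re_pt == ""
  if (any(empty_pt)) {
    diags[[length(diags) + 1L]] <-
      diag_row("REAC", re_pid[empty_pt], "empty reaction pt; entry dropped")
  }
  reactions <- data.frame(
    primaryid = re_pid,
    pt = re_pt,
    disease_group = rep(NA_character_, length(re_pid)),
    stringsAsFactors = FALSE
  )[!empty_pt, , drop = FALSE]

  # Orphan drug/reaction rows whose primaryid has no DEMO record.
  orphan_d <- !(drugs$primaryid %in% demo$primaryid)
  if (any(orphan_d)) {
    diags[[length(diags) + 1L]] <-
      diag_row("DRUG", unique(drugs$primaryid[orphan_d]),
               "no matching DEMO record")
  }
  orphan_r <- !(reactions$primaryid %in% demo$primaryid)
  if (any(orphan_r)) {
    diags[[length(diags) + 1L]] <-
      diag_row("REAC", unique(reactions$primaryid[orphan_r]),
               "no matching DEMO record")
  }
  drugs <- drugs[!orphan_d, , drop = FALSE]
  reactions <- reactions[!orphan_r, , drop = FALSE]

  # Case-level invariants: >=1 valid drug and >=1 reaction.
  no_drug <- !(demo$primaryid %in% drugs$primaryid)
  if (any(no_drug)) {
    diags[[length(diags) + 1L]] <-
      diag_row("DEMO", demo$primaryid[no_drug],
               "record invalid: no valid drug entries")
  }
  no_reac <- !(demo$primaryid %in% reactions$primaryid)
  if (any(no_reac)) {
    diags[[length(diags) + 1L]] <-
      diag_row("DEMO", demo$primaryid[no_reac],
               "record invalid: no reactions")
  }
  keep_case <- !no_drug & !no_reac
  demo <- demo[keep_case, , drop = FALSE]
  drugs <- drugs[drugs$primaryid %in% demo$primaryid, , drop = FALSE]
  reactions <- reactions[reactions$primaryid %in% demo$primaryid, , drop = FALSE]

  diagnostics <- if (length(diags)) do.call(rbind, diags) else empty_diagnostics()
  rownames(demo) <- rownames(drugs) <- rownames(reactions) <- NULL
  new_faers_cases(demo,
                  drugs[, c("primaryid", "drug_seq", "verbatim_name",
                            "active_ingredient", "role", "indication_pt")],
                  reactions, diagnostics)
}

#' Write a `faers_cases` container back to FAERS quarterly format
#'
#' Emits `$`-delimited DEMO/DRUG/REAC/INDI/OUTC files that
#' [read_faers_quarter()] parses back to an equivalent container (reactions'
#' assigned disease groups are a downstream annotation and are not persisted).
#'
#' @param x A `faers_cases` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_faers_quarter <- function(x, dir) {
  stopifnot(inherits(x, "faers_cases"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- x$demo
  demo_out <- data.frame(
    primaryid = d$primaryid,
    caseid = d$caseid,
    caseversion = d$caseversion,
    fda_dt = format(d$receipt_date, "%Y%m%d"),
    age = ifelse(is.na(d$age_years), "", sprintf("%.17g", d$age_years)),
    age_cod = ifelse(is.na(d$age_years), "", "YR"),
    sex = c(male = "M", female = "F", unknown = "UNK")[d$sex],
    occp_cod = c(consumer = "CN", healthcare_professional = "MD",
                 not_specified = "")[d$reporter_type],
    rept_cod = c(direct = "DIR", expedited = "EXP",
                 non_expedited = "PER")[d$case_priority],
    occr_country = d$country,
    reporter_country = d$country,
    stringsAsFactors = FALSE
  )
  dr <- x$drugs
  drug_out <- data.frame(
    primaryid = dr$primaryid, drug_seq = dr$drug_seq,
    role_cod = c(suspect = "PS", concomitant = "C",
                 interacting = "I")[dr$role],
    drugname = dr$verbatim_name, stringsAsFactors = FALSE
  )
  has_ind <- !is.na(dr$indication_pt)
  indi_out <- data.frame(
    primaryid = dr$primaryid[has_ind], indi_drug_seq = dr$drug_seq[has_ind],
    indi_pt = dr$indication_pt[has_ind], stringsAsFactors = FALSE
  )
  reac_out <- data.frame(primaryid = x$reactions$primaryid,
                         pt = x$reactions$pt, stringsAsFactors = FALSE)
  serious <- d$primaryid[d$seriousness == "serious"]
  outc_out <- data.frame(primaryid = serious,
                         outc_cod = rep("OT", length(serious)),
                         stringsAsFactors = FALSE)
  paths <- c(demo = file.path(dir, "DEMO.txt"),
             drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"),
             indi = file.path(dir, "INDI.txt"),
             outc = file.path(dir, "OUTC.txt"))
  wr <- function(df, path) {
    utils::write.table(df, path, sep = "$", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  wr(demo_out, paths["demo"]); wr(drug_out, paths["drug"])
  wr(reac_out, paths["reac"]); wr(indi_out, paths["indi"])
  wr(outc_out, paths["outc"])
  invisible(paths)
}

#' Deduplicate versioned case reports
#'
#' FAERS ships every resubmission of a case; analysis uses one current record
#' per case id. Keeps, per `caseid`, the record with the highest
#' `caseversion`; ties broken by latest `receipt_date`, then by the
#' lexicographically largest `primaryid`. Idempotent.
#'
#' @param x A `faers_cases` object.
#' @return A `faers_cases` object with exactly one record per `caseid`;
#'   diagnostics are carried through unchanged.
#' @export
deduplicate_cases <- function(x) {
  stopifnot(inherits(x, "faers_cases"))
  d <- x$demo
  ord <- order(d$caseid, d$caseversion, d$receipt_date, d$primaryid,
               method = "radix", decreasing = c(FALSE, TRUE, TRUE, TRUE))
  d <- d[ord, , drop = FALSE]
  d <- d[!duplicated(d$caseid), , drop = FALSE]
  out <- new_faers_cases(
    x$demo[x$demo$primaryid %in% d$primaryid, , drop = FALSE],
    x$drugs[x$drugs$primaryid %in% d$primaryid, , drop = FALSE],
    x$reactions[x$reactions$primaryid %in% d$primaryid, , drop = FALSE],
    x$diagnostics
  )
  rownames(out$demo) <- rownames(out$drugs) <- rownames(out$reactions) <- NULL
  out
}

#' Load a drug-synonym table
#'
#' Two-column TSV (`variant`, `ingredient`) mapping uppercase brand/generic
#' spellings to canonical lowercase ingredient names. The default table covers
#' the four ARPIs (brand and generic forms) and common co-medications.
#'
#' @param path Path to a synonym TSV; `NULL` for the packaged default.
#' @return Named character vector: names are normalized variants, values the
#'   canonical ingredient.
#' @export
load_drug_synonyms <- function(path = NULL) {
  path <- path %||% system.file("extdata", "drug_synonyms.tsv",
                                package = "faersignal")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant", "ingredient") %in% names(df))) {
    stop_fmt("synonym table %s must have columns 'variant' and 'ingredient'",
             path)
  }
  stats::setNames(tolower(trimws(df$ingredient)), normalize_key(df$variant))
}

#' Normalize a verbatim drug name to an active ingredient
#'
#' Case- and whitespace-insensitive lookup in a synonym table. Names absent
#' from the table return `"unknown"` — the normalizer never guesses.
#'
#' @param verbatim Character vector of verbatim drug names.
#' @param synonym_table Named vector from [load_drug_synonyms()].
#' @return Character vector of canonical ingredient names or `"unknown"`.
#' @export
#' @examples
#' syn <- stats::setNames(c("enzalutamide", "enzalutamide"),
#'                        c("XTANDI", "ENZALUTAMIDE"))
#' normalize_drug_name(c("XTANDI", " enzalutamide ", "mystery"), syn)
normalize_drug_name <- function(verbatim, synonym_table) {
  hit <- synonym_table[normalize_key(verbatim)]
  out <- unname(hit)
  out[is.na(out)] <- "unknown"
  out
}
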