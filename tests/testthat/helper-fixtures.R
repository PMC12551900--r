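# Shared fixtures, built in code at test time.

DEMO_HEADER <- paste("primaryid", "caseid", "caseversion", "fda_dt", "age",
                     "age_cod", "sex", "occp_cod", "rept_cod",
                     "occr_country", "reporter_country", sep = "$")

# A hand-enumerable quarter: three cases.
#  A (1010101): XTANDI (suspect, prostate cancer) + PREDNISONE; NAUSEA, RASH;
#               serious; US; 72 y.
#  B (1020101): ZYTIGA + ENZALUTAMIDE (both suspect, prostate cancer);
#               FATIGUE; 68 y; US.
#  C (1030101): METFORMIN (diabetes); DIZZINESS; 55 y; US.
write_tiny_quarter <- function(dir,
                               drug_lines = tiny_drug_lines(),
                               reac_lines = tiny_reac_lines()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(
    DEMO_HEADER,
    "1010101$101$1$20200115$72$YR$M$CN$EXP$US$US",
    "1020101$102$1$20210601$68$YR$M$MD$PER$US$US",
    "1030101$103$1$20190310$55$YR$M$MD$DIR$US$US"
  ), file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$drug_seq$role_cod$drugname", drug_lines),
             file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt", reac_lines), file.path(dir, "REAC.txt"))
  writeLines(c(
    "primaryid$indi_drug_seq$indi_pt",
    "1010101$1$PROSTATE CANCER",
    "1020101$1$PROSTATE CANCER",
    "1020101$2$PROSTATE CANCER",
    "1030101$1$DIABETES MELLITUS"
  ), file.path(dir, "INDI.txt"))
  writeLines(c("primaryid$outc_cod", "1010101$HO"),
             file.path(dir, "OUTC.txt"))
  c(demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt"), indi = file.path(dir, "INDI.txt"),
    outc = file.path(dir, "OUTC.txt"))
}

tiny_drug_lines <- function() {
  c("1010101$1$PS$XTANDI",
    "1010101$2$C$PREDNISONE",
    "1020101$1$PS$ZYTIGA",
    "1020101$2$SS$ENZALUTAMIDE",
    "1030101$1$PS$METFORMIN")
}

tiny_reac_lines <- function() {
  c("1010101$NAUSEA",
    "1010101$RASH",
    "1020101$FATIGUE",
    "1030101$DIZZINESS")
}

read_tiny_quarter <- function(dir = withr::local_tempdir(), ...) {
  p <- write_tiny_quarter(dir, ...)
  read_faers_quarter(p["demo"], p["drug"], p["reac"], p["indi"], p["outc"])
}

# Assemble a faers_cases container directly (internal constructor), for
# tests that need precise control over fields.
make_cases <- function(demo, drugs, reactions) {
  faersignal:::new_faers_cases(demo, drugs, reactions)
}

demo_row <- function(primaryid, caseid = substr(primaryid, 1, 3),
                     caseversion = 1L, receipt_date = as.Date("2020-06-01"),
                     age_years = 70, sex = "male", country = "US",
                     reporter_type = "consumer", seriousness = "serious",
                     case_priority = "expedited") {
  data.frame(primaryid = primaryid, caseid = caseid,
             caseversion = as.integer(caseversion),
             receipt_date = as.Date(receipt_date),
             age_years = as.numeric(age_years), sex = sex,
             country = country, reporter_type = reporter_type,
             seriousness = seriousness, case_priority = case_priority,
             stringsAsFactors = FALSE)
}

drug_row <- function(primaryid, verbatim_name, active_ingredient,
                     role = "suspect", indication_pt = "PROSTATE CANCER",
                     drug_seq = 1L) {
  data.frame(primaryid = primaryid, drug_seq = as.integer(drug_seq),
             verbatim_name = verbatim_name,
             active_ingredient = active_ingredient, role = role,
             indication_pt = indication_pt, stringsAsFactors = FALSE)
}

reac_row <- function(primaryid, pt, disease_group = NA_character_) {
  data.frame(primaryid = primaryid, pt = pt, disease_group = disease_group,
             stringsAsFactors = FALSE)
}

# One fully-annotated case with an ARPI and one reaction per supplied PT.
simple_case <- function(primaryid, ingredient = "enzalutamide",
                        pts = "NAUSEA", ...) {
  list(demo = demo_row(primaryid, ...),
       drugs = drug_row(primaryid, toupper(ingredient), ingredient),
       reactions = do.call(rbind, lapply(pts, reac_row,
                                         primaryid = primaryid)))
}

bind_cases <- function(...) {
  parts <- list(...)
  make_cases(do.call(rbind, lapply(parts, `[[`, "demo")),
             do.call(rbind, lapply(parts, `[[`, "drugs")),
             do.call(rbind, lapply(parts, `[[`, "reactions")))
}

tiny_synonyms <- function() {
  load_drug_synonyms()
}
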