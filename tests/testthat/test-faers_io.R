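test_that("a quarter's DEMO/DRUG/REAC/INDI rows join into per-case records", {
  x <- read_tiny_quarter()
  expect_s3_class(x, "faers_cases")
  expect_equal(n_cases(x), 3L)
  drug_counts <- table(x$drugs$primaryid)
  expect_equal(as.integer(drug_counts[c("1010101", "1020101", "1030101")]),
               c(2L, 2L, 1L))
  reac_counts <- table(x$reactions$primaryid)
  expect_equal(as.integer(reac_counts[c("1010101", "1020101", "1030101")]),
               c(2L, 1L, 1L))
  expect_equal(nrow(diagnostics(x)), 0L)
  # field recoding
  a <- x$demo[x$demo$primaryid == "1010101", ]
  expect_equal(a$age_years, 72)
  expect_equal(a$sex, "male")
  expect_equal(a$reporter_type, "consumer")
  expect_equal(a$case_priority, "expedited")
  expect_equal(a$seriousness, "serious")
  expect_equal(x$demo$seriousness[x$demo$primaryid == "1020101"],
               "non_serious")
  # drug normalization happened on ingest
  expect_setequal(
    x$drugs$active_ingredient[x$drugs$primaryid == "1020101"],
    c("abiraterone", "enzalutamide"))
  # indications joined by (primaryid, drug_seq)
  expect_equal(
    x$drugs$indication_pt[x$drugs$primaryid == "1010101" &
                            x$drugs$drug_seq == 1L],
    "PROSTATE CANCER")
  expect_true(is.na(x$drugs$indication_pt[x$drugs$primaryid == "1010101" &
                                            x$drugs$drug_seq == 2L]))
})

test_that("cases without reactions are invalid and diagnosed, not dropped silently", {
  dir <- withr::local_tempdir()
  p <- write_tiny_quarter(dir, reac_lines = character())
  x <- read_faers_quarter(p["demo"], p["drug"], p["reac"], p["indi"],
                          p["outc"])
  expect_equal(n_cases(x), 0L)
  d <- diagnostics(x)
  expect_equal(sum(d$reason == "record invalid: no reactions"), 3L)
})

test_that("an empty drugname drops the entry but keeps the case if drugs remain", {
  dir <- withr::local_tempdir()
  p <- write_tiny_quarter(dir, drug_lines = c(
    "1010101$1$PS$XTANDI",
    "1010101$2$C$",          # dropped entry; case A keeps XTANDI
    "1020101$1$PS$ZYTIGA",
    "1020101$2$SS$ENZALUTAMIDE",
    "1030101$1$PS$"          # case C loses its only drug -> invalid
  ))
  x <- read_faers_quarter(p["demo"], p["drug"], p["reac"], p["indi"],
                          p["outc"])
  expect_equal(sort(unique(x$demo$primaryid)), c("1010101", "1020101"))
  expect_equal(sum(x$drugs$primaryid == "1010101"), 1L)
  d <- diagnostics(x)
  expect_equal(sum(d$reason == "empty drugname; entry dropped"), 2L)
  expect_true(any(d$primaryid == "1030101" &
                    d$reason == "record invalid: no valid drug entries"))
})

test_that("every reaction row is accounted for: attached or diagnosed", {
  dir <- withr::local_tempdir()
  p <- write_tiny_quarter(dir, reac_lines = c(
    tiny_reac_lines(),
    "9999999$HEADACHE",   # orphan: no DEMO row
    "1010101$"            # empty pt
  ))
  x <- read_faers_quarter(p["demo"], p["drug"], p["reac"], p["indi"],
                          p["outc"])
  d <- diagnostics(x)
  attached <- nrow(x$reactions)
  diagnosed <- sum(d$file == "REAC")
  expect_equal(attached + diagnosed, 6L)
})

test_that("FAERS age-unit codes are converted to years before range checks", {
  dir <- withr::local_tempdir()
  dir.create(dir, showWarnings = FALSE)
  writeLines(c(
    DEMO_HEADER,
    "1010101$101$1$20200115$7$DEC$M$CN$EXP$US$US",
    "1020101$102$1$20210601$780$MON$M$MD$EXP$US$US",
    "1030101$103$1$20190310$200$YR$M$MD$EXP$US$US"   # out of range
  ), file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$drug_seq$role_cod$drugname",
               "1010101$1$PS$XTANDI", "1020101$1$PS$XTANDI",
               "1030101$1$PS$XTANDI"), file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt", "1010101$NAUSEA", "1020101$NAUSEA",
               "1030101$NAUSEA"), file.path(dir, "REAC.txt"))
  writeLines("primaryid$indi_drug_seq$indi_pt", file.path(dir, "INDI.txt"))
  x <- read_faers_quarter(file.path(dir, "DEMO.txt"),
                          file.path(dir, "DRUG.txt"),
                          file.path(dir, "REAC.txt"),
                          file.path(dir, "INDI.txt"))
  ages <- setNames(x$demo$age_years, x$demo$primaryid)
  expect_equal(unname(ages["1010101"]), 70)
  expect_equal(unname(ages["1020101"]), 65)
  expect_true(is.na(ages["1030101"]))
  expect_true(any(grepl("age outside", diagnostics(x)$reason)))
})

test_that("missing files and legacy layouts are rejected with clear errors", {
  dir <- withr::local_tempdir()
  p <- write_tiny_quarter(dir)
  expect_error(read_faers_quarter(file.path(dir, "NOPE.txt"), p["drug"],
                                  p["reac"], p["indi"]),
               "DEMO file not found")
  legacy <- file.path(dir, "LEGACY.txt")
  writeLines(c("isr$case$i_f_cod", "1$2$I"), legacy)
  expect_error(read_faers_quarter(legacy, p["drug"], p["reac"], p["indi"]),
               "legacy")
})

test_that("write/read round-trip reproduces the container", {
  x <- read_tiny_quarter()
  dir <- withr::local_tempdir()
  p <- write_faers_quarter(x, dir)
  y <- read_faers_quarter(p["demo"], p["drug"], p["reac"], p["indi"],
                          p["outc"])
  expect_equal(y$demo, x$demo)
  expect_equal(y$drugs, x$drugs)
  expect_equal(y$reactions, x$reactions)
})

test_that("deduplication keeps max version, breaking ties by date then id", {
  x <- bind_cases(
    simple_case("10000101", caseversion = 1, caseid = "100"),
    simple_case("10000102", caseversion = 2, caseid = "100"),
    simple_case("10000201", caseversion = 1, caseid = "101")
  )
  y <- deduplicate_cases(x)
  expect_setequal(y$demo$primaryid, c("10000102", "10000201"))

  # version tie -> latest receipt date wins
  x2 <- bind_cases(
    simple_case("20000103", caseversion = 3, caseid = "200",
                receipt_date = "2020-01-01"),
    simple_case("20000113", caseversion = 3, caseid = "200",
                receipt_date = "2021-01-01")
  )
  y2 <- deduplicate_cases(x2)
  expect_equal(y2$demo$primaryid, "20000113")
  expect_equal(y2$demo$receipt_date, as.Date("2021-01-01"))

  # full tie -> lexically largest primaryid
  x3 <- bind_cases(
    simple_case("30000101", caseversion = 1, caseid = "300"),
    simple_case("30000109", caseversion = 1, caseid = "300")
  )
  expect_equal(deduplicate_cases(x3)$demo$primaryid, "30000109")

  # all-distinct input passes through; idempotence
  x4 <- bind_cases(simple_case("40000101", caseid = "400"),
                   simple_case("40000201", caseid = "401"))
  expect_equal(deduplicate_cases(x4)$demo, x4$demo)
  expect_equal(deduplicate_cases(deduplicate_cases(x))$demo, y$demo)
  # drug/reaction rows follow their retained record
  expect_setequal(unique(y$drugs$primaryid), y$demo$primaryid)
  expect_setequal(unique(y$reactions$primaryid), y$demo$primaryid)
})

test_that("drug-name normalization is case/whitespace-insensitive and never guesses", {
  syn <- tiny_synonyms()
  expect_equal(normalize_drug_name("XTANDI", syn), "enzalutamide")
  expect_equal(normalize_drug_name("  abiraterone   acetate ", syn),
               "abiraterone")
  expect_equal(normalize_drug_name("ASPIRIN-LIKE UNKNOWN SUBSTANCE 3", syn),
               "unknown")
  expect_equal(normalize_drug_name(c("xtandi", "Nubeqa", ""), syn),
               c("enzalutamide", "darolutamide", "unknown"))
})
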