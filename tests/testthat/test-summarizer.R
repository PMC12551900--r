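test_that("characteristics table reproduces hand-computed percentages", {
  x <- bind_cases(
    simple_case("10000101", "enzalutamide", caseid = "100",
                seriousness = "serious", age_years = 72),
    simple_case("10000201", "enzalutamide", caseid = "101",
                seriousness = "serious", age_years = 81),
    simple_case("10000301", "enzalutamide", caseid = "102",
                seriousness = "non_serious", age_years = 55),
    simple_case("10000401", "abiraterone", caseid = "103",
                seriousness = "serious", age_years = 66)
  )
  x <- assign_groups(x)
  suppressWarnings(tab <- characteristics_table(x))
  expect_equal(unname(tab$group_n[c("G1", "G4")]), c(3L, 1L))
  serious <- tab$blocks$Serious
  expect_equal(unname(serious$counts["serious", c("G1", "G4")]), c(2L, 1L))
  expect_equal(unname(serious$pct["serious", "G1"]), 66.7)  # 2/3 half-up
  expect_equal(unname(serious$pct["non_serious", "G1"]), 33.3)
  age <- tab$blocks$Age
  expect_equal(unname(age$counts["70-79", "G1"]), 1L)
  expect_equal(unname(age$pct["70-79", "G1"]), 33.3)
  # tests attach a p-value per block when >1 group
  expect_true(!is.null(serious$test))
  expect_true(serious$test$p_value >= 0 && serious$test$p_value <= 1)
})

test_that("a single-group cohort omits tests with a warning", {
  x <- assign_groups(bind_cases(
    simple_case("10000101", "enzalutamide", caseid = "100"),
    simple_case("10000201", "enzalutamide", caseid = "101")
  ))
  expect_warning(tab <- characteristics_table(x), "single treatment group")
  expect_null(tab$blocks$Serious$test)
})

test_that("events-by-stratum percentages, totals and column sums reconcile", {
  events <- data.frame(
    group = rep(c("G1", "G2"), c(6, 4)),
    age_band = rep(c("60-69", "70-79"), 5),
    category = c("Skin", "Skin", "CNS", "Vascular", "Skin", "CNS",
                 "Skin", "Skin", "Vascular", "CNS")
  )
  tab <- events_by_stratum(events, "group")
  expect_equal(unname(tab$totals), c(6, 4, 0, 0, 0))
  expect_equal(unname(tab$counts["Skin", "G1"]), 3L)
  expect_equal(unname(tab$pct["Skin", "G1"]), 50)
  expect_equal(unname(tab$pct["Skin", "G2"]), 50)
  # each column's category counts sum to the column total
  expect_equal(unname(colSums(tab$counts)), unname(tab$totals))
  # percentages sum to 100 within rounding slack on populated columns
  expect_lt(max(abs(colSums(tab$pct[, tab$totals > 0]) - 100)),
            0.1 * nrow(tab$counts))
  # a stratum with one event is 100% in its category
  one <- events_by_stratum(data.frame(group = "G3", age_band = "60-69",
                                      category = "Skin"), "group")
  expect_equal(unname(one$pct["Skin", "G3"]), 100)
})

test_that("published group characteristics reproduce (serious fraction by group)", {
  t1 <- faers_table_counts("characteristics")
  serious <- t1[t1$block == "Serious", ]
  g5 <- serious[serious$level == "Serious", "G5"]
  n5 <- sum(serious$G5)
  expect_equal(n5, 689)
  expect_equal(faersignal:::round_half_up(100 * g5 / n5, 1), 90.6)
  g1 <- serious[serious$level == "Serious", "G1"]
  expect_equal(faersignal:::round_half_up(100 * g1 / sum(serious$G1), 1),
               67.2)
})

test_that("published event tables reproduce the printed percentages", {
  t3 <- faers_table_counts("events_by_group")
  counts <- as.matrix(t3[, -1])
  rownames(counts) <- t3$category
  totals <- colSums(counts)
  expect_equal(unname(totals),
               c(73139, 6209, 1825, 24476, 1933))
  pct1 <- faersignal:::round_half_up(100 * counts[, "G1"] / totals["G1"], 1)
  expect_equal(unname(pct1["Gastro intestinal"]), 11.4)
  pct2 <- faersignal:::round_half_up(100 * counts[, "G2"] / totals["G2"], 1)
  expect_equal(unname(pct2["Skin"]), 12.5)
  t2 <- faers_table_counts("events_by_age")
  c2 <- as.matrix(t2[, -1])
  rownames(c2) <- t2$category
  expect_equal(faersignal:::round_half_up(
    100 * c2["Lack of efficacy", 1] / sum(c2[, 1]), 2), 16.99)
})

test_that("summary tables render to TSV and Markdown", {
  events <- data.frame(group = rep("G1", 3), age_band = "60-69",
                       category = c("Skin", "Skin", "CNS"))
  tab <- events_by_stratum(events, "group", strata = "G1")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  md <- withr::local_tempfile(fileext = ".md")
  write_summary_table(tab, tsv)
  write_summary_table(tab, md, format = "markdown")
  back <- read.delim(tsv, check.names = FALSE)
  expect_equal(back$category[back$category != ""],
               c(disease_categories(), "Total"))
  expect_true(any(grepl("\\| Skin \\|", readLines(md))))
})

test_that("half-up rounding matches printed-table conventions", {
  expect_equal(faersignal:::round_half_up(12.45, 1), 12.5)
  expect_equal(faersignal:::round_half_up(12.44999, 1), 12.4)
  expect_equal(faersignal:::round_half_up(90.55, 1), 90.6)
  expect_equal(faersignal:::round_half_up(2.5, 0), 3)
  expect_equal(faersignal:::round_half_up(16.985, 2), 16.99)
})
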