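# Independent oracle: naive fraction arithmetic for the PRR.
naive_prr <- function(m, n, M, N) (m / n) / ((M - m) / (N - n))

test_that("contingency quadruples are counted from the event table", {
  # toy database of 20 events, 5 in the group of which 2 are Skin,
  # 6 Skin overall
  events <- data.frame(
    group = c(rep("G2", 5), rep("excluded", 15)),
    category = c("Skin", "Skin", "CNS", "Vascular", "Infection",
                 rep("Skin", 4), rep("CNS", 5), rep("Vascular", 6))
  )
  cc <- build_contingency(events, "G2", "Skin")
  expect_equal(unclass(cc)[c("m", "n", "M", "N")],
               list(m = 2L, n = 5L, M = 6L, N = 20L))
  # category absent from the group
  cc2 <- build_contingency(events, "G2", "Endocrine")
  expect_equal(cc2$m, 0L)
  expect_gt(cc2$n, 0L)
  # the whole database as the stratum is degenerate but countable
  events$group2 <- "ALL"
  names(events)[3] <- "group"
  cc3 <- build_contingency(events[, c(3, 2)], "ALL", "Skin")
  expect_equal(cc3$m, cc3$M)
  expect_equal(cc3$n, cc3$N)
  # empty stratum errors
  expect_error(build_contingency(events, "G9", "Skin"), "empty stratum")
})

test_that("PRR point estimates match direct fraction arithmetic", {
  expect_equal(prr(contingency_counts(10, 100, 20, 200))$prr, 1.0)
  expect_equal(prr(contingency_counts(200, 1000, 400, 11000))$prr, 10.0)
  r <- prr(contingency_counts(50, 500, 150, 3000))
  expect_equal(r$prr, 2.5)
  expect_true(r$is_signal)
  expect_equal(r$se_log, sqrt(1 / 50 - 1 / 500 + 1 / 100 - 1 / 2500))
  expect_equal(r$ci_low, 2.5 * exp(-qnorm(0.975) * r$se_log))
  expect_equal(r$ci_high, 2.5 * exp(qnorm(0.975) * r$se_log))
  expect_lt(r$ci_low, r$prr)
  expect_gt(r$ci_high, r$prr)
})

test_that("PRR agrees with the naive oracle on 1,000 random valid quadruples", {
  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(10:5000, 1)
    m <- sample(1:n, 1)
    Nn <- sample(10:100000, 1)          # N - n
    Mm <- sample(1:Nn, 1)               # M - m
    r <- prr(contingency_counts(m, n, m + Mm, n + Nn))
    worst <- max(worst, abs(r$prr - naive_prr(m, n, m + Mm, n + Nn)) /
                   naive_prr(m, n, m + Mm, n + Nn))
  }
  expect_lt(worst, 1e-12)
})

test_that("PRR is scale-invariant and strictly increasing in m", {
  base <- c(m = 12, n = 120, M = 60, N = 1200)
  p1 <- prr(contingency_counts(base["m"], base["n"], base["M"], base["N"]))$prr
  for (k in c(2, 5, 10)) {
    pk <- prr(contingency_counts(k * base["m"], k * base["n"],
                                 k * base["M"], k * base["N"]))$prr
    expect_equal(pk, p1)
  }
  prev <- -Inf
  for (m in c(1, 5, 10, 20, 40, 59)) {
    cur <- prr(contingency_counts(m, 60, 100, 2000))$prr
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("zero cells get the Haldane correction; doubly-empty cells error", {
  # m = 0 but the event exists elsewhere: finite, defined estimate
  r <- prr(contingency_counts(0, 100, 30, 2000))
  a <- 0.5; b <- 100.5; cc <- 30.5; d <- 1870.5
  expect_equal(r$prr, (a / (a + b)) / (cc / (cc + d)))
  expect_true(is.finite(r$ci_low) && is.finite(r$ci_high))
  # M - m = 0: event only ever seen in the group
  r2 <- prr(contingency_counts(5, 100, 5, 2000))
  expect_true(is.finite(r2$prr))
  # nonzero cells are never perturbed
  r3 <- prr(contingency_counts(3, 100, 30, 2000))
  expect_equal(r3$prr, naive_prr(3, 100, 30, 2000))
  expect_error(prr(contingency_counts(0, 100, 0, 2000)), "nowhere")
  expect_error(prr(contingency_counts(0, 0, 10, 2000)), "n = 0")
  expect_error(prr(contingency_counts(10, 2000, 10, 2000)), "N - n")
})

test_that("invalid count quadruples are rejected", {
  expect_error(contingency_counts(5, 4, 10, 100), "inconsistent")
  expect_error(contingency_counts(5, 10, 4, 100), "inconsistent")
  expect_error(contingency_counts(-1, 10, 4, 100), "non-negative")
  expect_error(contingency_counts(5, 10, 200, 100), "inconsistent")
})

test_that("chi-square without continuity correction matches the closed form", {
  tab <- matrix(c(10, 20, 20, 10), 2)
  res <- contingency_test(tab)
  # closed-form oracle: all expected cells are 15
  oracle <- sum((tab - 15)^2 / 15)
  expect_equal(res$test_used, "chi_square")
  expect_equal(res$statistic, oracle)
  expect_equal(round(res$statistic, 3), 6.667)
  expect_lt(res$p_value, 0.05)
  # homogeneous table
  res0 <- contingency_test(matrix(5, 2, 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("small expected cells switch 2x2 tables to Fisher's exact test", {
  tab <- matrix(c(1, 2, 9, 8), 2)   # [[1,9],[2,8]] rows
  res <- contingency_test(tab)
  expect_equal(res$test_used, "fisher_exact")
  expect_true(res$small_cells)
  # independent hypergeometric enumeration oracle: margins fixed,
  # two-sided p sums probabilities <= that of the observed table
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  probs <- dhyper(0:c1, m1, m2, c1)
  p_oracle <- sum(probs[probs <= dhyper(tab[1, 1], m1, m2, c1) * (1 + 1e-7)])
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  # larger sparse tables stay chi-square but are flagged
  res3 <- contingency_test(matrix(c(1, 2, 3, 1, 2, 3), 2))
  expect_equal(res3$test_used, "chi_square")
  expect_true(res3$small_cells)
  expect_error(contingency_test(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("the panel screens every group x category cell without aborting", {
  set.seed(11)
  events <- data.frame(
    group = sample(c(paste0("G", 1:5), "excluded"), 4000, replace = TRUE,
                   prob = c(rep(0.08, 5), 0.6)),
    category = sample(setdiff(disease_categories(), "Endocrine"), 4000,
                      replace = TRUE)
  )
  pan <- prr_panel(events)
  expect_s3_class(pan, "prr_panel")
  expect_equal(nrow(pan), 65L)
  # cell-by-cell agreement with build_contingency + prr on defined cells
  defined <- which(!is.na(pan$prr))
  for (i in sample(defined, 10)) {
    cc <- build_contingency(events, pan$group[i], pan$category[i])
    expect_equal(pan$prr[i], prr(cc)$prr)
  }
  # category reported nowhere -> undefined cells, noted not fatal
  und <- pan[pan$category == "Endocrine", ]
  expect_true(all(is.na(und$prr)))
  expect_true(all(und$note == "undefined: event reported nowhere"))
  s <- summary(pan)
  expect_true(all(table(s$top$group) <= 3))
})

test_that("panel output renders to the long-format TSV shape", {
  events <- data.frame(
    group = rep(c("G1", "excluded"), c(100, 900)),
    category = sample(disease_categories(), 1000, replace = TRUE)
  )
  pan <- prr_panel(events, groups = "G1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prr_panel(pan, path)
  back <- read.delim(path)
  expect_equal(names(back),
               c("group", "category", "m", "n", "M", "N", "prr", "ci_low",
                 "ci_high", "signal"))
  expect_equal(nrow(back), 13L)
  expect_equal(back$prr, as.data.frame(pan)$prr, tolerance = 1e-9)
})
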