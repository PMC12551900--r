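# Disproportionality analysis: the proportional reporting ratio (PRR) with
# its log-scale Wald interval, stratified contingency tests, and the
# group x category signal panel.
#
# For a target group with m reports of a specific adverse event out of n
# total events, against M and N database-wide,
#
#   PRR = (m / n) / ((M - m) / (N - n))
#
# i.e. the event's reporting proportion in the group relative to its
# proportion in the rest of the database (the group's own events are removed
# from the comparator). PRR >= 2 is the conventional signal threshold.

#' Contingency quadruple for one (group, category) cell
#'
#' Counts the four quantities entering the PRR from a long event table:
#' `m` events of `category` in `group`, `n` all events in `group`, `M` events
#' of `category` database-wide, `N` all events database-wide. The event table
#' must span the full database (background included), not only the treatment
#' groups.
#'
#' @param events Event table from [event_table()] (columns `group`,
#'   `category`), or any data frame with those columns.
#' @param group Target group label.
#' @param category Target adverse-event category label.
#' @return A `contingency_counts` object (named list `m`, `n`, `M`, `N`).
#' @export
build_contingency <- function(events, group, category) {
  stopifnot(all(c("group", "category") %in% names(events)))
  in_g <- events$group == group
  n <- sum(in_g)
  if (n == 0L) stop_fmt("empty stratum: group '%s' has zero events", group)
  contingency_counts(m = sum(in_g & events$category == category), n = n,
                     M = sum(events$category == category), N = nrow(events))
}

#' Construct and validate a contingency quadruple
#'
#' @param m,n,M,N Non-negative counts: specific-event and total-event counts
#'   within the target group (`m`, `n`) and database-wide (`M`, `N`).
#' @return A `contingency_counts` object.
#' @export
contingency_counts <- function(m, n, M, N) {
  for (v in list(m, n, M, N)) {
    if (length(v) != 1L || is.na(v) || v < 0) {
      stop_fmt("contingency counts must be single non-negative numbers")
    }
  }
  if (m > n || M > N || m > M || n > N || (M - m) > (N - n)) {
    stop_fmt(paste0("inconsistent contingency counts ",
                    "(need m<=n, M<=N, m<=M, n<=N, M-m<=N-n): ",
                    "m=%g n=%g M=%g N=%g"), m, n, M, N)
  }
  structure(list(m = m, n = n, M = M, N = N), class = "contingency_counts")
}

#' @export
print.contingency_counts <- function(x, ...) {
  cat(sprintf("contingency counts: m=%g n=%g M=%g N=%g\n", x$m, x$n, x$M, x$N))
  invisible(x)
}

# Vectorized PRR arithmetic shared by prr() and prr_panel(). Zero cells
# (m = 0 or M - m = 0) get the Haldane-Anscombe 0.5 correction applied to all
# four derived 2x2 cells of that comparison only; cells that are undefined
# even then (m = 0 and M - m = 0: the event was never reported anywhere) are
# returned NA.
prr_vec <- function(m, n, M, N, alpha = 0.05, threshold = 2) {
  a <- m
  b <- n - m
  cc <- M - m
  d <- (N - n) - (M - m)
  undef <- (a == 0 & cc == 0)
  adj <- !undef & (a == 0 | cc == 0)
  a <- a + 0.5 * adj
  b <- b + 0.5 * adj
  cc <- cc + 0.5 * adj
  d <- d + 0.5 * adj
  est <- (a / (a + b)) / (cc / (cc + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d))
  z <- stats::qnorm(1 - alpha / 2)
  lo <- est * exp(-z * se)
  hi <- est * exp(z * se)
  est[undef] <- se[undef] <- lo[undef] <- hi[undef] <- NA_real_
  data.frame(prr = est, se_log = se, ci_low = lo, ci_high = hi,
             is_signal = !is.na(est) & est >= threshold)
}

#' Proportional reporting ratio with Wald confidence interval
#'
#' Computes `PRR = (m/n) / ((M-m)/(N-n))` with a log-scale Wald
#' `100 * (1 - alpha)%` interval,
#' `exp(log PRR -/+ z * se)`, `se = sqrt(1/m - 1/n + 1/(M-m) - 1/(N-n))`,
#' and flags a signal when the point estimate reaches `threshold` (default 2,
#' the conventional rule). When `m = 0` or `M - m = 0` the Haldane-Anscombe
#' 0.5 correction is added to all four 2x2 cells; nonzero cells are never
#' perturbed.
#'
#' @param c A `contingency_counts` object (or list with `m`, `n`, `M`, `N`).
#' @param alpha Two-sided interval level; default 0.05 for a 95% CI.
#' @param threshold Signal threshold on the point estimate; default 2.
#' @return A `prr_result` object: list with `prr`, `ci_low`, `ci_high`,
#'   `se_log`, `is_signal`, `counts`, `alpha`, `threshold`.
#' @export
#' @examples
#' prr(contingency_counts(m = 50, n = 500, M = 150, N = 3000))
prr <- function(c, alpha = 0.05, threshold = 2) {
  if (!inherits(c, "contingency_counts")) {
    c <- contingency_counts(c$m, c$n, c$M, c$N)
  }
  if (c$n == 0) stop_fmt("undefined PRR: n = 0 (group has no events)")
  if (c$N - c$n == 0) {
    stop_fmt("undefined PRR: N - n = 0 (empty comparator)")
  }
  if (c$m == 0 && c$M - c$m == 0) {
    stop_fmt("undefined PRR: event reported nowhere (m = 0 and M - m = 0)")
  }
  v <- prr_vec(c$m, c$n, c$M, c$N, alpha = alpha, threshold = threshold)
  structure(list(prr = v$prr, ci_low = v$ci_low, ci_high = v$ci_high,
                 se_log = v$se_log, is_signal = v$is_signal,
                 counts = c, alpha = alpha, threshold = threshold),
            class = "prr_result")
}

#' @export
print.prr_result <- function(x, digits = 3, ...) {
  cat(sprintf("PRR %.*f (%d%% CI %.*f-%.*f)%s\n",
              digits, x$prr, round(100 * (1 - x$alpha)),
              digits, x$ci_low, digits, x$ci_high,
              if (x$is_signal) sprintf("  [signal: PRR >= %g]", x$threshold)
              else ""))
  cat(sprintf("  counts: m=%g n=%g M=%g N=%g\n",
              x$counts$m, x$counts$n, x$counts$M, x$counts$N))
  invisible(x)
}

#' Test for association in a stratified count table
#'
#' Pearson's chi-squared test (without continuity correction) when every
#' expected cell count is at least 5; otherwise Fisher's exact test for 2x2
#' tables, or chi-squared with a small-cell warning flag for larger tables.
#' Two-tailed throughout.
#'
#' @param tab Numeric matrix of non-negative counts (r x c, both >= 2).
#' @return List with `statistic` (NA for Fisher), `p_value`, `test_used`
#'   (`"chi_square"` or `"fisher_exact"`), and `small_cells` (logical:
#'   expected counts below 5 present).
#' @export
#' @examples
#' contingency_test(matrix(c(10, 20, 20, 10), 2))
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(is.na(tab)) || any(tab < 0)) {
    stop_fmt("contingency_test: table cells must be non-negative counts")
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop_fmt("contingency_test: need at least a 2x2 table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  small <- any(expected < 5)
  if (small && nrow(tab) == 2L && ncol(tab) == 2L) {
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    return(list(statistic = NA_real_, p_value = ft$p.value,
                test_used = "fisher_exact", small_cells = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       test_used = "chi_square", small_cells = small)
}

#' PRR signal panel over treatment groups and disease categories
#'
#' Computes one PRR (with CI and signal flag) per (group, category) cell from
#' a database-wide event table. Cells whose PRR is undefined (the category
#' was reported nowhere, or only ever in the group) are retained with `NA`
#' estimates and an explanatory `note` rather than aborting the panel; an
#' entirely empty group likewise yields noted `NA` rows.
#'
#' @param events Event table from [event_table()] spanning the full database.
#' @param groups Group labels to screen; default `G1`-`G5`. Use
#'   `combined = TRUE` to add a pooled stratum of all listed groups.
#' @param categories Adverse-event categories; default the 13 standard ones.
#' @param alpha,threshold Passed to the PRR computation.
#' @param combined Also screen the union of `groups` as one stratum
#'   (labelled `"G1-G5"` style)?
#' @return A `prr_panel` data frame: `group`, `category`, `m`, `n`, `M`, `N`,
#'   `prr`, `ci_low`, `ci_high`, `se_log`, `is_signal`, `note`.
#' @export
prr_panel <- function(events, groups = treatment_groups(),
                      categories = disease_categories(),
                      alpha = 0.05, threshold = 2, combined = FALSE) {
  stopifnot(all(c("group", "category") %in% names(events)))
  ev <- events
  if (combined) {
    pooled <- events[events$group %in% groups, , drop = FALSE]
    pooled$group <- paste(groups[1], groups[length(groups)], sep = "-")
    ev <- rbind(events, pooled)
    groups <- c(groups, pooled$group[1])
  }
  N <- nrow(events)
  Mv <- vapply(categories,
               function(cat) sum(events$category == cat), numeric(1))
  rows <- expand.grid(category = categories, group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("group", "category")]
  nv <- vapply(groups, function(g) sum(ev$group == g), numeric(1))
  rows$n <- nv[rows$group]
  rows$m <- mapply(function(g, cat) {
    sum(ev$group == g & ev$category == cat)
  }, rows$group, rows$category)
  rows$M <- Mv[rows$category]
  rows$N <- N

  out <- cbind(rows[, c("group", "category", "m", "n", "M", "N")],
               prr_vec(rows$m, rows$n, rows$M, rows$N,
                       alpha = alpha, threshold = threshold))
  out$note <- ""
  out$note[out$m == 0 & (out$M - out$m) == 0] <- "undefined: event reported nowhere"
  out$note[out$n == 0] <- "empty stratum"
  bad <- out$n == 0 | out$N - out$n == 0
  out$prr[bad] <- out$se_log[bad] <- out$ci_low[bad] <- out$ci_high[bad] <- NA_real_
  out$is_signal[bad] <- FALSE
  rownames(out) <- NULL
  structure(out, class = c("prr_panel", "data.frame"),
            alpha = alpha, threshold = threshold)
}

#' @export
print.prr_panel <- function(x, digits = 3, ...) {
  cat(sprintf("PRR panel: %d groups x %d categories (N = %g events; signal: PRR >= %g)\n",
              length(unique(x$group)), length(unique(x$category)),
              x$N[1], attr(x, "threshold")))
  df <- as.data.frame(x)
  df$prr <- round(df$prr, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  print.data.frame(df[, c("group", "category", "m", "n", "prr",
                          "ci_low", "ci_high", "is_signal")], row.names = FALSE)
  invisible(x)
}

#' Summarise a PRR panel: signals and top-ranked events per group
#'
#' @param object A `prr_panel`.
#' @param top Number of top-PRR categories to list per group (default 3,
#'   the usual "top 3 high-risk adverse events by group" view).
#' @param ... Unused.
#' @return A `summary.prr_panel` list with the signal subset and the top-`top`
#'   ranking per group.
#' @export
summary.prr_panel <- function(object, top = 3, ...) {
  df <- as.data.frame(object)
  ok <- df[!is.na(df$prr), , drop = FALSE]
  ranked <- do.call(rbind, lapply(split(ok, ok$group), function(g) {
    g <- g[order(-g$prr), , drop = FALSE]
    utils::head(g, top)
  }))
  rownames(ranked) <- NULL
  structure(list(signals = df[df$is_signal %in% TRUE, , drop = FALSE],
                 top = ranked, n_cells = nrow(df),
                 threshold = attr(object, "threshold")),
            class = "summary.prr_panel")
}

#' @export
print.summary.prr_panel <- function(x, digits = 3, ...) {
  cat(sprintf("%d panel cells; %d signals at PRR >= %g\n",
              x$n_cells, nrow(x$signals), x$threshold))
  cat(sprintf("Top %d categories per group by PRR:\n",
              max(table(x$top$group))))
  df <- x$top
  df$prr <- round(df$prr, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  print.data.frame(df[, c("group", "category", "m", "n", "prr",
                          "ci_low", "ci_high", "is_signal")],
                   row.names = FALSE)
  invisible(x)
}

#' Forest plot of a PRR panel
#'
#' Point estimates with CI whiskers per category, one panel row block per
#' group, on a log axis with reference lines at PRR = 1 and at the signal
#' threshold.
#'
#' @param x A `prr_panel`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.prr_panel <- function(x, ...) {
  df <- as.data.frame(x)
  df <- df[!is.na(df$prr), , drop = FALSE]
  if (!nrow(df)) stop_fmt("nothing to plot: all panel cells undefined")
  df$label <- paste(df$group, df$category, sep = ": ")
  df <- df[order(df$group, df$prr), , drop = FALSE]
  y <- seq_len(nrow(df))
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(df$prr, y, log = "x", pch = 16, yaxt = "n",
                 xlab = "PRR (log scale)", ylab = "",
                 xlim = range(c(df$ci_low, df$ci_high), finite = TRUE), ...)
  graphics::segments(df$ci_low, y, df$ci_high, y)
  graphics::abline(v = 1, lty = 3)
  graphics::abline(v = attr(x, "threshold"), lty = 2, col = "red3")
  graphics::axis(2, at = y, labels = df$label, las = 1, cex.axis = 0.6)
  invisible(x)
}

#' Write a PRR panel as long-format TSV
#'
#' Columns `group`, `category`, `m`, `n`, `M`, `N`, `prr`, `ci_low`,
#' `ci_high`, `signal` — the supplementary-table shape.
#'
#' @param x A `prr_panel`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_prr_panel <- function(x, path) {
  df <- as.data.frame(x)
  df$signal <- df$is_signal
  utils::write.table(
    format(df[, c("group", "category", "m", "n", "M", "N", "prr",
                  "ci_low", "ci_high", "signal")],
           digits = 10, trim = TRUE, scientific = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
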