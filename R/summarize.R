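# Stratified summary tables: cohort characteristics by treatment group,
# and event counts by age band or treatment group, with per-block /
# per-category association tests.

#' Cohort characteristics by treatment group
#'
#' Tabulates seriousness, case priority, reporter type, and age band across
#' treatment groups: cell count plus percentage of the group's case total,
#' with a chi-squared (or Fisher) p-value per characteristic block. With a
#' single group present, tests are omitted with a warning (no contrast).
#'
#' @param x A `faers_cases` object with groups assigned ([assign_groups()]).
#' @param groups Columns of the table; default `G1`-`G5`.
#' @param digits Percentage rounding digits (half-up); default 1.
#' @return A `characteristics_table`: list of blocks, each holding `counts`,
#'   `pct`, and `test`, plus the per-group case totals `group_n`.
#' @export
characteristics_table <- function(x, groups = treatment_groups(),
                                  digits = 1) {
  stopifnot(inherits(x, "faers_cases"))
  if (is.null(x$demo$group)) {
    stop_fmt("treatment groups not assigned; call assign_groups() first")
  }
  d <- x$demo[x$demo$group %in% groups, , drop = FALSE]
  groups <- groups[groups %in% unique(d$group)]
  if (!length(groups)) stop_fmt("no cases in any requested group")
  gf <- factor(d$group, levels = groups)
  single <- length(groups) == 1L
  if (single) {
    warning("single treatment group: association tests omitted",
            call. = FALSE)
  }
  specs <- list(
    Serious = factor(d$seriousness, levels = c("serious", "non_serious")),
    `Case priority` = factor(d$case_priority,
                             levels = c("direct", "expedited",
                                        "non_expedited")),
    `Reporter type` = factor(d$reporter_type,
                             levels = c("consumer",
                                        "healthcare_professional",
                                        "not_specified")),
    Age = factor(categorize_age(d$age_years),
                 levels = c(age_bands(), "missing"))
  )
  group_n <- as.integer(table(gf))
  names(group_n) <- groups
  blocks <- lapply(specs, function(f) {
    counts <- unclass(table(f, gf))
    counts <- counts[rowSums(counts) > 0 | rownames(counts) != "missing", ,
                     drop = FALSE]
    pct <- sweep(counts, 2, pmax(group_n, 1L), function(a, b) {
      round_half_up(100 * a / b, digits)
    })
    test <- if (single) NULL else {
      used <- counts[rowSums(counts) > 0, , drop = FALSE]
      if (nrow(used) >= 2L) contingency_test(used) else NULL
    }
    list(counts = counts, pct = pct, test = test)
  })
  structure(list(blocks = blocks, group_n = group_n, digits = digits),
            class = "characteristics_table")
}

#' @export
print.characteristics_table <- function(x, ...) {
  hdr <- paste(sprintf("%s (N=%d)", names(x$group_n), x$group_n),
               collapse = "  ")
  cat("Characteristics by treatment group\n  ", hdr, "\n")
  for (nm in names(x$blocks)) {
    b <- x$blocks[[nm]]
    p <- if (is.null(b$test)) "" else sprintf("  (p %s)",
                                              format_pval(b$test$p_value))
    cat(sprintf("%s%s\n", nm, p))
    cells <- matrix(sprintf("%d (%.*f%%)", b$counts, x$digits, b$pct),
                    nrow = nrow(b$counts),
                    dimnames = dimnames(b$counts))
    print(cells, quote = FALSE)
  }
  invisible(x)
}

format_pval <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.001) "<0.001" else sprintf("%.3f", p)
}

#' Event counts by stratum (age band or treatment group)
#'
#' Counts mapped adverse events per disease category within each stratum,
#' with percentages of the stratum's event total (more than one event per
#' patient is allowed: each reaction entry counts once), a column-total row,
#' and a per-category association test (that category versus all others,
#' across strata).
#'
#' @param events Event table from [event_table()].
#' @param stratum `"age_band"` or `"group"`.
#' @param categories Row labels; default the 13 standard categories.
#' @param strata Column labels; default the five age bands or `G1`-`G5`.
#' @param digits Percentage rounding digits (half-up); default 2, the usual
#'   published precision.
#' @return An `events_table`: list with `counts` (categories x strata),
#'   `pct`, `totals`, per-category `p_values`, and the overall table `test`.
#' @export
events_by_stratum <- function(events, stratum = c("age_band", "group"),
                              categories = disease_categories(),
                              strata = NULL, digits = 2) {
  stratum <- match.arg(stratum)
  stopifnot(all(c("category", stratum) %in% names(events)))
  strata <- strata %||% switch(stratum, age_band = age_bands(),
                               group = treatment_groups())
  ev <- events[events[[stratum]] %in% strata &
                 events$category %in% categories, , drop = FALSE]
  counts <- unclass(table(factor(ev$category, levels = categories),
                          factor(ev[[stratum]], levels = strata)))
  totals <- colSums(counts)
  pct <- sweep(counts, 2, pmax(totals, 1), function(a, b) {
    round_half_up(100 * a / b, digits)
  })
  p_values <- vapply(seq_len(nrow(counts)), function(i) {
    tab <- rbind(counts[i, ], totals - counts[i, ])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2L || all(tab[1, ] == 0)) return(NA_real_)
    contingency_test(tab)$p_value
  }, numeric(1))
  names(p_values) <- categories
  used <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  overall <- if (nrow(used) >= 2L && ncol(used) >= 2L) {
    contingency_test(used)
  } else NULL
  structure(list(counts = counts, pct = pct, totals = totals,
                 p_values = p_values, test = overall, stratum = stratum,
                 digits = digits),
            class = "events_table")
}

#' @export
print.events_table <- function(x, ...) {
  cat(sprintf("Adverse events by %s (%d events)\n", x$stratum,
              sum(x$totals)))
  cells <- matrix(sprintf("%d (%.*f)", x$counts, x$digits, x$pct),
                  nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  cells <- cbind(cells, `p-value` = vapply(x$p_values, format_pval, ""))
  print(cells, quote = FALSE)
  cat("Total:", paste(x$totals, collapse = "  "), "\n")
  invisible(x)
}

# Long data frame of a summary table, used by the TSV/markdown renderers.
table_to_frame <- function(x) {
  UseMethod("table_to_frame")
}

#' @export
table_to_frame.events_table <- function(x) {
  df <- data.frame(category = rownames(x$counts), stringsAsFactors = FALSE)
  for (s in colnames(x$counts)) {
    df[[s]] <- sprintf("%d (%.*f)", x$counts[, s], x$digits, x$pct[, s])
  }
  df$p_value <- vapply(x$p_values, format_pval, "")
  tot <- c("Total", as.character(x$totals), "")
  rbind(df, stats::setNames(as.list(tot), names(df)))
}

#' @export
table_to_frame.characteristics_table <- function(x) {
  rows <- list()
  for (nm in names(x$blocks)) {
    b <- x$blocks[[nm]]
    p <- if (is.null(b$test)) "" else format_pval(b$test$p_value)
    rows[[length(rows) + 1L]] <-
      c(characteristic = nm, level = "",
        stats::setNames(rep("", length(x$group_n)), names(x$group_n)),
        p_value = p)
    for (lv in rownames(b$counts)) {
      cells <- sprintf("%d (%.*f%%)", b$counts[lv, ], x$digits, b$pct[lv, ])
      rows[[length(rows) + 1L]] <-
        c(characteristic = "", level = lv,
          stats::setNames(cells, names(x$group_n)), p_value = "")
    }
  }
  as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
}

#' Write a summary table as TSV or Markdown
#'
#' @param x A `characteristics_table` or `events_table`.
#' @param path Output path.
#' @param format `"tsv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  df <- table_to_frame(x)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
               apply(df, 1, function(r) {
                 paste0("| ", paste(r, collapse = " | "), " |")
               }))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Published aggregate count tables for ARPI adverse-event reports
#'
#' Transcribed aggregate counts from the published US FAERS analysis of the
#' five ARPI treatment groups (2014-2024 window): cohort characteristics by
#' group, and adverse-event counts by age band and by treatment group. These
#' are inputs for reproducing the printed percentages and tests at desk
#' scale; the underlying case-level database is not redistributable.
#'
#' @param which `"characteristics"`, `"events_by_age"`, or
#'   `"events_by_group"`.
#' @return A data frame of counts as printed.
#' @export
faers_table_counts <- function(which = c("characteristics", "events_by_age",
                                         "events_by_group")) {
  which <- match.arg(which)
  f <- c(characteristics = "table1_counts.tsv",
         events_by_age = "table2_counts.tsv",
         events_by_group = "table3_counts.tsv")[which]
  utils::read.delim(system.file("extdata", f, package = "faersignal"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}
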