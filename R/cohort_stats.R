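#' Normality-gated two-group comparison
#'
#' Mirrors the conventional small-cohort workflow: Shapiro-Wilk normality on
#' each group at \code{alpha_norm}; if either group is non-normal and the
#' data are strictly positive, a natural-log transformation is applied and
#' normality retested; if still non-normal (or the data admit no log
#' transform) the Mann-Whitney test is used (exact when both groups have
#' n <= 10 and no ties, normal approximation with continuity/tie correction
#' otherwise), else the unpaired two-sided t-test on the (possibly
#' transformed) data. Group summaries are always reported on the original
#' scale. Constant samples make the normality test undefined and fall
#' through to Mann-Whitney with a warning.
#'
#' @param x,y numeric samples, each n >= 3.
#' @param alpha_norm significance level of the normality gate.
#' @return list of class \code{group_comparison}: \code{test} ("t" or
#'   "mann-whitney"), \code{transformed} (log flag), \code{p} (two-tailed),
#'   \code{mean_x}, \code{sd_x}, \code{mean_y}, \code{sd_y}, \code{n_x},
#'   \code{n_y}.
#' @export
compare_groups <- function(x, y, alpha_norm = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3 || length(y) < 3) stop("each sample needs n >= 3")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")

  shapiro_p <- function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  px <- shapiro_p(x); py <- shapiro_p(y)
  degenerate <- is.na(px) || is.na(py)
  if (degenerate) {
    warning("constant sample: normality undefined, using Mann-Whitney")
  }
  normal <- !degenerate && px >= alpha_norm && py >= alpha_norm
  transformed <- FALSE
  tx <- x; ty <- y
  if (!normal && !degenerate && all(x > 0) && all(y > 0)) {
    tx <- log(x); ty <- log(y)
    transformed <- TRUE
    normal <- shapiro_p(tx) >= alpha_norm && shapiro_p(ty) >= alpha_norm
  }
  if (normal) {
    p <- stats::t.test(tx, ty, var.equal = TRUE)$p.value
    test <- "t"
  } else {
    if (stats::sd(c(x, y)) == 0) {
      # every observation identical: the rank statistic is at its null
      # center, two-sided p is 1 by symmetry
      p <- 1
    } else {
      exact <- length(x) <= 10 && length(y) <= 10 &&
        !any(duplicated(c(x, y)))
      p <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
    }
    test <- "mann-whitney"
    transformed <- FALSE  # rank test is transformation-invariant
  }
  structure(list(test = test, transformed = transformed, p = p,
                 mean_x = mean(x), sd_x = stats::sd(x),
                 mean_y = mean(y), sd_y = stats::sd(y),
                 n_x = length(x), n_y = length(y)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test%s: %.2f +/- %.2f (n=%d) vs %.2f +/- %.2f (n=%d), p = %.4g\n",
              x$test, if (x$transformed) " (log scale)" else "",
              x$mean_x, x$sd_x, x$n_x, x$mean_y, x$sd_y, x$n_y, x$p))
  invisible(x)
}

#' Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value sums the probabilities
#' of all tables with the observed margins whose probability does not exceed
#' that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins must be positive")
  }
  stats::fisher.test(table)$p.value
}

#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation; significance from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors, n >= 3, finite, non-constant.
#' @return list: \code{r}, \code{p}, \code{n}.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for zero-variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# continuous-row helper for cohort_report
.row_cont <- function(label, x, y, digits = 2) {
  cmp <- tryCatch(compare_groups(x, y),
                  warning = function(w) suppressWarnings(compare_groups(x, y)))
  data.frame(
    variable = label,
    group1 = sprintf("%.*f ± %.*f", digits, mean(x), digits, stats::sd(x)),
    group2 = sprintf("%.*f ± %.*f", digits, mean(y), digits, stats::sd(y)),
    p = cmp$p, test = cmp$test)
}

.row_count <- function(label, f1, f2) {
  tab <- rbind(c(sum(f1), sum(!f1)), c(sum(f2), sum(!f2)))
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_ else {
    fisher_exact(tab)
  }
  data.frame(variable = label,
             group1 = sprintf("%d (%.0f%%)", sum(f1), 100 * mean(f1)),
             group2 = sprintf("%d (%.0f%%)", sum(f2), 100 * mean(f2)),
             p = p, test = "fisher")
}

#' Overall cohort outcome rates
#'
#' Re-intervention and death percentages over the whole cohort, rounded to
#' whole percent as conventionally reported.
#'
#' @param records a \code{cohort_records} data.frame.
#' @return list: \code{n}, \code{reintervention_n}, \code{reintervention_pct},
#'   \code{death_n}, \code{death_pct}.
#' @export
outcome_rates <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("reintervention", "death")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(records)
  list(n = n,
       reintervention_n = sum(records$reintervention),
       reintervention_pct = round(100 * sum(records$reintervention) / n),
       death_n = sum(records$death),
       death_pct = round(100 * sum(records$death) / n))
}

#' Cohort summary report
#'
#' Builds the standard two-group summary of a dissection cohort: per-variable
#' group means +/- sd with the gated two-sample test (Fisher exact for sex),
#' a favorable-versus-adverse subgroup table restricted to stable-size
#' patients, a death-versus-survival comparison of FL flow, tortuosity and
#' the tear-margin TAWSS statistic, and the overall outcome rates.
#'
#' @param records a \code{cohort_records} data.frame from
#'   \code{\link{simulate_cohort}} (or read from CSV with the same columns).
#' @return list of class \code{cohort_report}: \code{header},
#'   \code{groups}, \code{subgroups} (NULL if a subgroup has < 3 patients),
#'   \code{mortality}, \code{outcome_rates}.
#' @export
cohort_report <- function(records) {
  need <- c("id", "group", "subgroup", "age", "sex", "initial_diameter_mm",
            "tl_da_ratio", "tear_area_mm2", "n_reentry_tears", "tortuosity",
            "fl_flow_pct", "peak_tawss_pa", "tawss_margins_pamm",
            "reintervention", "death", "surveillance_years")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  vars <- list(
    c("Age [years]", "age", 1),
    c("Initial aortic diameter [mm]", "initial_diameter_mm", 1),
    c("TL/DA area ratio", "tl_da_ratio", 2),
    c("Entry tear size [mm2]", "tear_area_mm2", 1),
    c("Number of re-entry tears", "n_reentry_tears", 1),
    c("Tortuosity", "tortuosity", 2),
    c("FL flow [%]", "fl_flow_pct", 0),
    c("Peak TAWSS (entry tear) [Pa]", "peak_tawss_pa", 1),
    c("TAWSS x margins (entry tear) [Pa mm]", "tawss_margins_pamm", 1))

  two_group_table <- function(a, b) {
    rows <- list(.row_cont("Age [years]", a$age, b$age, 1),
                 .row_count("Male sex", a$sex == "M", b$sex == "M"))
    for (v in vars[-1]) {
      rows[[length(rows) + 1]] <-
        .row_cont(v[1], a[[v[2]]], b[[v[2]]], as.integer(v[3]))
    }
    do.call(rbind, rows)
  }

  st <- records[records$group == "stable", ]
  ra <- records[records$group == "rapid", ]
  groups <- suppressWarnings(two_group_table(st, ra))

  fav <- st[st$subgroup == "favorable", ]
  adv <- st[st$subgroup == "adverse", ]
  subgroups <- if (nrow(fav) >= 3 && nrow(adv) >= 3) {
    suppressWarnings(two_group_table(fav, adv))
  } else NULL

  dead <- records[records$death, ]
  alive <- records[!records$death, ]
  mortality <- if (nrow(dead) >= 3 && nrow(alive) >= 3) {
    suppressWarnings(rbind(
      .row_cont("FL flow [%]", dead$fl_flow_pct, alive$fl_flow_pct, 0),
      .row_cont("Tortuosity", dead$tortuosity, alive$tortuosity, 2),
      .row_cont("TAWSS x margins (entry tear) [Pa mm]",
                dead$tawss_margins_pamm, alive$tawss_margins_pamm, 1)))
  } else NULL

  structure(list(
    header = sprintf("stable n = %d / rapid n = %d", nrow(st), nrow(ra)),
    groups = groups, subgroups = subgroups, mortality = mortality,
    outcome_rates = outcome_rates(records)),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report (", x$header, ")\n\n", sep = "")
  print(x$groups, row.names = FALSE)
  o <- x$outcome_rates
  cat(sprintf("\nRe-intervention %d/%d (%d%%), death %d/%d (%d%%)\n",
              o$reintervention_n, o$n, o$reintervention_pct,
              o$death_n, o$n, o$death_pct))
  invisible(x)
}

#' Write a cohort report as Markdown + CSV tables
#'
#' @param report a \code{\link{cohort_report}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  md <- file.path(dir, "report.md")
  fmt <- function(df) {
    df$p <- signif(df$p, 3)
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(rr) paste0("| ", paste(rr, collapse = " | "), " |")))
  }
  lines <- c(paste("# Cohort report:", report$header), "",
             "## Stable vs rapid growth", fmt(report$groups))
  if (!is.null(report$subgroups)) {
    lines <- c(lines, "", "## Stable-size subgroups (favorable vs adverse)",
               fmt(report$subgroups))
  }
  if (!is.null(report$mortality)) {
    lines <- c(lines, "", "## Death vs survival", fmt(report$mortality))
  }
  o <- report$outcome_rates
  lines <- c(lines, "",
             sprintf("Re-intervention %d/%d (%d%%); death %d/%d (%d%%).",
                     o$reintervention_n, o$n, o$reintervention_pct,
                     o$death_n, o$n, o$death_pct))
  writeLines(lines, md)
  paths <- c(paths, md)
  for (nm in c("groups", "subgroups", "mortality")) {
    if (!is.null(report[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(report[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
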