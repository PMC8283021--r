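# Nonparametric group comparisons and tidy study-level reporting.

pooled_sd <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx + ny < 3L) return(NA_real_)
  sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
}

#' Mann-Whitney U test between two independent samples
#'
#' Two-sided rank-sum comparison. The exact U null distribution is used for
#' `min(n_x, n_y) <= 8` without ties; otherwise the normal approximation
#' with tie correction and continuity correction. Cohen's d (mean
#' difference over pooled SD) accompanies the rank test as the effect size.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_max largest min-group size for which the exact distribution
#'   is used (default 8).
#' @return an object of class `"cr_comparison"`: `statistic` (U), `n`,
#'   `p_value`, `effect_size_d`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= exact_max
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  sp <- pooled_sd(x, y)
  structure(
    list(statistic = unname(ht$statistic), statistic_name = "U",
         n = c(n_x = length(x), n_y = length(y)),
         p_value = min(1, ht$p.value),
         effect_size_d = if (is.na(sp) || sp <= 0) NA_real_ else
           (mean(x) - mean(y)) / sp,
         method = if (exact) "exact" else "normal approximation"),
    class = "cr_comparison")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided within-subject comparison of `before` vs `after`. The exact
#' null is used for up to 12 nonzero differences without ties; otherwise
#' the normal approximation with corrections. The reported statistic W is
#' the smaller of the positive and negative rank sums.
#'
#' @param before,after paired numeric samples of equal length with at least
#'   one nonzero difference.
#' @param exact_max largest number of nonzero differences for the exact
#'   null (default 12).
#' @return a `"cr_comparison"` with `statistic` (W), `n`, `p_value`,
#'   `effect_size_d` (mean difference / SD of differences).
#' @export
wilcoxon_signed_rank <- function(before, after, exact_max = 12) {
  if (length(before) != length(after)) stop("samples must be paired")
  d <- after - before
  d <- d[!is.na(d)]
  if (length(d) == 0L || all(d == 0)) stop("all paired differences are zero")
  nz <- d[d != 0]
  ties <- anyDuplicated(abs(nz)) > 0L
  exact <- !ties && length(nz) <= exact_max && length(nz) == length(d)
  ht <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE,
                                            exact = exact, correct = TRUE))
  v_plus <- unname(ht$statistic)
  n <- length(nz)
  w <- min(v_plus, n * (n + 1) / 2 - v_plus)
  sdd <- stats::sd(d)
  structure(
    list(statistic = w, statistic_name = "W",
         n = c(n_pairs = length(d)),
         p_value = min(1, ht$p.value),
         effect_size_d = if (is.na(sdd) || sdd <= 0) NA_real_ else
           mean(d) / sdd,
         method = if (exact) "exact" else "normal approximation"),
    class = "cr_comparison")
}

#' @export
print.cr_comparison <- function(x, ...) {
  cat(sprintf("<cr_comparison> %s = %g, p = %.4g (%s), d = %s\n",
              x$statistic_name, x$statistic, x$p_value, x$method,
              if (is.na(x$effect_size_d)) "NA" else
                sprintf("%.2f", x$effect_size_d)))
  invisible(x)
}

#' Cohen's d from a mean difference and pooled SD
#'
#' @param mean_diff difference of group means.
#' @param sd_pooled pooled standard deviation (> 0).
#' @return `mean_diff / sd_pooled`.
#' @export
cohens_d <- function(mean_diff, sd_pooled) {
  if (!is.numeric(sd_pooled) || sd_pooled <= 0)
    stop("sd_pooled must be positive")
  mean_diff / sd_pooled
}

#' Assemble a tidy study-level report
#'
#' Takes per-animal outcome tables from the analysis modules (one row per
#' animal, a `group` column plus numeric outcome columns) and produces, per
#' section, group mean +/- SEM for every outcome and a two-sided
#' Mann-Whitney p-value between groups where exactly two groups are
#' present. Sections that are `NULL` are reported as explicit gaps rather
#' than silently dropped.
#'
#' @param sections named list of data.frames (e.g. `bp`, `hrv`, `hvr`,
#'   `sleep_architecture`, `sleep_respiration`); each needs `animal` and
#'   `group` columns.
#' @return an object of class `"cr_report"`: list with `tables` (per
#'   section: `summary` stats and the `per_animal` rows) and `gaps`.
#' @export
study_report <- function(sections) {
  if (is.null(names(sections)) || any(!nzchar(names(sections))))
    stop("sections must be a named list")
  gaps <- names(sections)[vapply(sections, is.null, TRUE)]
  tables <- list()
  for (nm in setdiff(names(sections), gaps)) {
    df <- sections[[nm]]
    if (!all(c("animal", "group") %in% names(df)))
      stop("section '", nm, "' needs 'animal' and 'group' columns")
    metrics <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], "animal")
    groups <- unique(df$group)
    rows <- list()
    for (m in metrics) {
      for (g in groups) {
        v <- df[[m]][df$group == g]
        v <- v[!is.na(v)]
        p <- NA_real_
        if (length(groups) == 2L) {
          other <- df[[m]][df$group == setdiff(groups, g)]
          p <- tryCatch(mann_whitney_u(v, other[!is.na(other)])$p_value,
                        error = function(e) NA_real_)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, group = g, n = length(v), mean = mean(v),
          sem = sem(v), p_between = p)
      }
    }
    tables[[nm]] <- list(summary = do.call(rbind, rows), per_animal = df)
  }
  structure(list(tables = tables, gaps = gaps), class = "cr_report")
}

#' Write a study report to CSV and JSON
#'
#' One `<section>_summary.csv` and `<section>_per_animal.csv` per section,
#' plus a `report.json` with the summary tables and the list of gaps.
#'
#' @param report a [study_report()].
#' @param dir output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables)) {
    utils::write.csv(report$tables[[nm]]$summary,
                     file.path(dir, paste0(nm, "_summary.csv")),
                     row.names = FALSE)
    utils::write.csv(report$tables[[nm]]$per_animal,
                     file.path(dir, paste0(nm, "_per_animal.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(summaries = lapply(report$tables, `[[`, "summary"),
         gaps = report$gaps),
    file.path(dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
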