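# Cohort-level descriptive summaries and between-category comparisons.

q_type7 <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

#' Kruskal-Wallis rank test
#'
#' Rank-based H with the standard tie correction and a chi-square p-value on
#' k-1 degrees of freedom. When every observation is tied the statistic is 0
#' and p is 1. Small-group p-values are approximate (no exact tables); a
#' permutation check covers small instances in the test suite.
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length; at least two non-empty groups.
#' @param alpha Significance threshold for the convenience flag.
#' @return List with `H`, `df`, `p`, `significant`.
#' @export
kruskal_wallis <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(as.factor(groups[ok]))
  k <- nlevels(groups)
  if (k < 2) wq_stop("wq_insufficient_groups",
                     "Kruskal-Wallis requires at least 2 groups, got %d", k)
  N <- length(values)
  r <- rank(values)
  Rj <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {
    H <- 0
    p <- 1
  } else {
    H <- max(H / C, 0)
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  list(H = H, df = k - 1L, p = p, significant = p < alpha)
}

med_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  c(median = q_type7(x, 0.5), q1 = q_type7(x, 0.25), q3 = q_type7(x, 0.75))
}

#' Descriptive summary of a scored corpus
#'
#' Produces the cohort report behind a website-quality study's summary
#' tables: per-category counts and median (IQR) of DISCERN, JAMA, and the
#' weighted quality score; per-category mean (SD) of each content item
#' (SD blank for single-site categories); and corpus-level medians, grade-6
#' compliance, engagement patterns, and dated-page counts. Quartiles use
#' linear interpolation between order statistics (type 7); SDs are sample
#' SDs (n-1).
#'
#' @param site_table Data frame with one row per analyzed website: columns
#'   `id`, `category`, `engagement`, `last_updated`, `discern_total`,
#'   `jama_total`, `content_total`, the six `content_*` item columns,
#'   `smog_grade`, `fk_grade`, `flesch_ease`, `meets_grade6`,
#'   `weighted_score`.
#' @param reference_date Date used for years-since-update.
#' @return List of data frames: `category_summary`, `content_summary`,
#'   `overall`, `engagement`, plus `update_years` (median/IQR of whole years
#'   since update over dated pages).
#' @export
describe_corpus <- function(site_table, reference_date = as.Date("2024-11-21")) {
  if (!nrow(site_table)) wq_stop("wq_empty_corpus", "cannot summarize an empty corpus")
  n <- nrow(site_table)
  cats <- wq_categories()
  present <- cats[cats %in% site_table$category]

  cat_rows <- lapply(present, function(cc) {
    s <- site_table[site_table$category == cc, , drop = FALSE]
    d <- med_iqr(s$discern_total); j <- med_iqr(s$jama_total)
    w <- med_iqr(s$weighted_score)
    data.frame(category = cc, n = nrow(s), pct = 100 * nrow(s) / n,
               discern_median = d[1], discern_q1 = d[2], discern_q3 = d[3],
               jama_median = j[1], jama_q1 = j[2], jama_q3 = j[3],
               weighted_median = w[1], weighted_q1 = w[2], weighted_q3 = w[3],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  category_summary <- do.call(rbind, cat_rows)

  item_cols <- grep("^content_", names(site_table), value = TRUE)
  item_cols <- setdiff(item_cols, "content_total")
  cont_rows <- lapply(present, function(cc) {
    s <- site_table[site_table$category == cc, , drop = FALSE]
    row <- data.frame(category = cc, n = nrow(s), pct = 100 * nrow(s) / n,
                      stringsAsFactors = FALSE)
    for (ic in item_cols) {
      row[[paste0(ic, "_mean")]] <- mean(s[[ic]])
      row[[paste0(ic, "_sd")]] <- if (nrow(s) > 1) stats::sd(s[[ic]]) else NA_real_
    }
    row
  })
  content_summary <- do.call(rbind, cont_rows)

  ov <- function(col) med_iqr(site_table[[col]])
  overall <- do.call(rbind, lapply(
    c("discern_total", "jama_total", "content_total", "smog_grade",
      "fk_grade", "flesch_ease", "weighted_score"),
    function(col) {
      m <- ov(col)
      data.frame(measure = col, median = m[1], q1 = m[2], q3 = m[3],
                 min = min(site_table[[col]]), max = max(site_table[[col]]),
                 row.names = NULL)
    }))

  eng <- table(factor(site_table$engagement))
  engagement <- data.frame(pattern = names(eng), n = as.integer(eng),
                           pct = 100 * as.integer(eng) / n,
                           stringsAsFactors = FALSE)

  dated <- !is.na(site_table$last_updated)
  upd <- if (any(dated)) {
    med_iqr(years_since_update(site_table$last_updated[dated], reference_date))
  } else c(median = NA_real_, q1 = NA_real_, q3 = NA_real_)

  counts <- data.frame(
    measure = c("n_sites", "n_meets_grade6", "n_dated"),
    n = c(n, sum(site_table$meets_grade6), sum(dated)),
    pct = c(100, 100 * sum(site_table$meets_grade6) / n, 100 * sum(dated) / n))

  list(category_summary = category_summary, content_summary = content_summary,
       overall = overall, engagement = engagement, counts = counts,
       update_years = upd)
}

#' Between-category score comparisons
#'
#' Runs [kruskal_wallis()] for each requested score across website
#' categories. No multiple-testing adjustment is applied (single-test
#' reporting, matching standard practice for these cohort tables).
#'
#' @param site_table As in [describe_corpus()].
#' @param scores Character vector of column names to compare.
#' @param alpha Significance threshold.
#' @return Data frame: score, H, df, p, significant.
#' @export
compare_categories <- function(site_table,
                               scores = c("discern_total", "jama_total",
                                          "content_total", "weighted_score"),
                               alpha = 0.05) {
  rows <- lapply(scores, function(sc) {
    kw <- kruskal_wallis(site_table[[sc]], site_table$category, alpha = alpha)
    data.frame(score = sc, H = kw$H, df = kw$df, p = kw$p,
               significant = kw$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
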