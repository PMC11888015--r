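# Shared data model: website records, per-rater instrument ratings, and the
# corpus container tying them together, plus delimited-file I/O.

#' Website category taxonomy
#'
#' The eight source categories used to classify patient-facing health
#' websites. Labels are matched case-insensitively after trimming whitespace.
#'
#' @return Character vector of the eight canonical category labels.
#' @export
wq_categories <- function() {
  c("hospital-affiliated", "commercial", "government", "foundation/advocacy",
    "regional health authority", "academic", "general reference/educational",
    "professional organization")
}

#' Engagement strategy levels
#'
#' @return Character vector: inform, activate, collaborate.
#' @export
wq_engagement_levels <- function() c("inform", "activate", "collaborate")

# Column schemas for the two delimited files.
.records_cols <- c("id", "url", "category", "country", "last_updated",
                   "engagement", "text")
.discern_cols <- paste0("discern_q", 1:16)
.jama_cols <- paste0("jama_", c("authorship", "attribution", "disclosure", "currency"))
.content_cols <- paste0("content_", c("definition", "risk_factors", "outcomes",
                                      "signs_symptoms", "delirium_vs_dementia",
                                      "prevalence"))
.ratings_cols <- c("website_id", "rater_id", .discern_cols, .jama_cols, .content_cols)

canonical_category <- function(x) {
  cats <- wq_categories()
  idx <- match(tolower(trimws(x)), tolower(cats))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    wq_validation_error("unknown website category: %s",
                        paste(sQuote(bad), collapse = ", "))
  }
  cats[idx]
}

# ISO dates, with year-only values completed to July 1 and flagged.
parse_update_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  partial <- rep(FALSE, length(x))
  nonempty <- !is.na(x) & nzchar(x)
  yr_only <- nonempty & grepl("^\\d{4}$", x)
  if (any(yr_only)) out[yr_only] <- as.Date(paste0(x[yr_only], "-07-01"))
  partial[yr_only] <- TRUE
  full <- nonempty & !yr_only
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y-%m-%d")
    if (anyNA(d)) {
      wq_format_error("unparseable last_updated value(s): %s",
                      paste(sQuote(x[full][is.na(d)]), collapse = ", "))
    }
    out[full] <- d
  }
  list(date = out, partial = partial)
}

parse_engagement <- function(x) {
  lv <- wq_engagement_levels()
  vapply(x, function(s) {
    s <- trimws(as.character(s))
    if (is.na(s) || !nzchar(s)) return("")
    parts <- tolower(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
    parts <- parts[nzchar(parts)]
    bad <- setdiff(parts, lv)
    if (length(bad)) {
      wq_validation_error("unknown engagement strategy: %s",
                          paste(sQuote(bad), collapse = ", "))
    }
    paste(lv[lv %in% parts], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a validated corpus
#'
#' Bundles website records with their per-rater instrument ratings and checks
#' every structural invariant: unique ids, known categories, complete in-range
#' item scores, referential integrity, and at least two distinct raters per
#' website (unless the record is flagged single-rated, in which case it is
#' excluded from adjudication outputs).
#'
#' @param records Data frame with columns id, url, category, country,
#'   last_updated (Date), date_partial (logical), engagement
#'   (semicolon-joined subset of [wq_engagement_levels()]), text, and
#'   optionally single_rated (logical).
#' @param ratings Data frame in long form: website_id, rater_id, discern_q1..
#'   discern_q16 (integers 1-5), jama_authorship/attribution/disclosure/
#'   currency (0/1), content_definition/risk_factors/outcomes/signs_symptoms/
#'   delirium_vs_dementia/prevalence (0/1/2).
#' @return Object of class `wq_corpus`: list with elements `records`,
#'   `ratings`.
#' @export
wq_corpus <- function(records, ratings) {
  for (col in setdiff(.records_cols, c("text"))) {
    if (!col %in% names(records)) wq_format_error("records are missing required column '%s'", col)
  }
  n_rec <- nrow(records)
  if (!"text" %in% names(records)) records$text <- rep("", n_rec)
  if (!"date_partial" %in% names(records)) records$date_partial <- rep(FALSE, n_rec)
  if (!"single_rated" %in% names(records)) records$single_rated <- rep(FALSE, n_rec)
  for (col in .ratings_cols) {
    if (!col %in% names(ratings)) wq_format_error("ratings are missing required column '%s'", col)
  }
  records$id <- as.character(records$id)
  if (anyDuplicated(records$id)) {
    wq_validation_error("duplicate website id(s): %s",
                        paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  records$category <- canonical_category(records$category)
  records$engagement <- parse_engagement(records$engagement)
  if (!inherits(records$last_updated, "Date")) {
    p <- parse_update_date(records$last_updated)
    records$last_updated <- p$date
    records$date_partial <- records$date_partial | p$partial
  }
  ratings$website_id <- as.character(ratings$website_id)
  ratings$rater_id <- as.character(ratings$rater_id)

  dangling <- setdiff(ratings$website_id, records$id)
  if (length(dangling)) {
    wq_reference_error("ratings reference unknown website id(s): %s",
                       paste(sQuote(dangling), collapse = ", "))
  }
  check_items <- function(cols, lo, hi, label) {
    for (col in cols) {
      v <- ratings[[col]]
      bad <- which(is.na(v) | v != as.integer(v) | v < lo | v > hi)
      if (length(bad)) {
        i <- bad[1]
        wq_validation_error(
          "%s item out of range: website '%s', rater '%s', item '%s' = %s (allowed %d-%d)",
          label, ratings$website_id[i], ratings$rater_id[i], col,
          as.character(ratings[[col]][i]), lo, hi)
      }
    }
  }
  check_items(.discern_cols, 1L, 5L, "DISCERN")
  check_items(.jama_cols, 0L, 1L, "JAMA")
  check_items(.content_cols, 0L, 2L, "content")

  if (anyDuplicated(ratings[c("website_id", "rater_id")])) {
    wq_validation_error("duplicate (website_id, rater_id) rating rows")
  }
  n_raters <- table(ratings$website_id)
  need2 <- records$id[!records$single_rated]
  short <- need2[!(need2 %in% names(n_raters)) | n_raters[need2] < 2]
  short <- short[!is.na(short)]
  if (length(short)) {
    wq_validation_error("website(s) with fewer than two raters and not flagged single-rated: %s",
                        paste(sQuote(short), collapse = ", "))
  }
  structure(list(records = records, ratings = ratings), class = "wq_corpus")
}

#' @export
print.wq_corpus <- function(x, ...) {
  cat(sprintf("<wq_corpus> %d websites, %d ratings, %d categories\n",
              nrow(x$records), nrow(x$ratings),
              length(unique(x$records$category))))
  invisible(x)
}

#' Load a corpus from records and ratings CSV files
#'
#' Records may carry page text inline in a `text` column or externally via a
#' `text_path` column pointing at a UTF-8 .txt file (resolved relative to the
#' records file). Every structural violation is reported as a classed error
#' naming the offending column, website, rater, or item; nothing is silently
#' coerced.
#'
#' @param records_path,ratings_path CSV file paths.
#' @return A validated [wq_corpus()].
#' @export
load_corpus <- function(records_path, ratings_path) {
  for (p in c(records_path, ratings_path)) {
    if (!file.exists(p)) wq_io_error("file does not exist: %s", p)
  }
  rec <- utils::read.csv(records_path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  rat <- utils::read.csv(ratings_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"text" %in% names(rec) && "text_path" %in% names(rec)) {
    base <- dirname(normalizePath(records_path))
    rec$text <- vapply(rec$text_path, function(tp) {
      fp <- if (grepl("^/", tp)) tp else file.path(base, tp)
      if (!file.exists(fp)) wq_io_error("text_path does not exist: %s", tp)
      paste(readLines(fp, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, character(1), USE.NAMES = FALSE)
  }
  for (col in setdiff(.records_cols, "text")) {
    if (!col %in% names(rec)) wq_format_error("records file is missing required column '%s'", col)
  }
  for (col in .ratings_cols) {
    if (!col %in% names(rat)) wq_format_error("ratings file is missing required column '%s'", col)
  }
  if ("single_rated" %in% names(rec)) {
    rec$single_rated <- tolower(trimws(rec$single_rated)) %in% c("true", "1", "yes")
  }
  for (col in c(.discern_cols, .jama_cols, .content_cols)) {
    v <- suppressWarnings(as.numeric(rat[[col]]))
    if (any(is.na(v) & !is.na(rat[[col]]))) {
      wq_validation_error("non-numeric value in ratings column '%s'", col)
    }
    rat[[col]] <- v
  }
  wq_corpus(rec, rat)
}

#' Write a corpus to records and ratings CSV files
#'
#' Inverse of [load_corpus()]: a written corpus reloads field-for-field equal.
#' Missing dates are written as empty cells and reload as absent.
#'
#' @param corpus A [wq_corpus()].
#' @param records_path,ratings_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_corpus <- function(corpus, records_path, ratings_path) {
  stopifnot(inherits(corpus, "wq_corpus"))
  rec <- corpus$records
  out <- data.frame(
    id = rec$id, url = rec$url, category = rec$category,
    country = ifelse(is.na(rec$country), "", rec$country),
    last_updated = ifelse(is.na(rec$last_updated), "",
                          format(rec$last_updated, "%Y-%m-%d")),
    engagement = rec$engagement, text = rec$text,
    single_rated = rec$single_rated,
    stringsAsFactors = FALSE, check.names = FALSE)
  for (p in c(records_path, ratings_path)) {
    dir <- dirname(p)
    if (!dir.exists(dir)) wq_io_error("directory does not exist: %s", dir)
  }
  utils::write.csv(out, records_path, row.names = FALSE, na = "")
  utils::write.csv(corpus$ratings[, c(.ratings_cols)], ratings_path,
                   row.names = FALSE, na = "")
  invisible(c(records_path, ratings_path))
}

#' Whole calendar years elapsed since a content update
#'
#' Floor of the exact elapsed time in calendar years, the convention behind
#' "time since last update" summaries. Vectorized.
#'
#' @param last_updated,reference Dates (or strings coercible to Date);
#'   `last_updated` must not be after `reference`.
#' @return Non-negative integer vector of whole elapsed years.
#' @export
years_since_update <- function(last_updated, reference) {
  lu <- as.Date(last_updated)
  ref <- as.Date(reference)
  if (any(lu > ref, na.rm = TRUE)) {
    wq_order_error("last_updated (%s) is after the reference date (%s)",
                   format(max(lu, na.rm = TRUE)), format(min(ref)))
  }
  l <- as.POSIXlt(lu); r <- as.POSIXlt(ref)
  yrs <- r$year - l$year
  not_reached <- (r$mon < l$mon) | (r$mon == l$mon & r$mday < l$mday)
  as.integer(yrs - not_reached)
}
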