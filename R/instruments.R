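# Instrument scoring (DISCERN, JAMA benchmark, topic-content rubric) and
# two/three-rater adjudication.

#' DISCERN total score
#'
#' Sum of the 16 DISCERN items (each 1-5, "definite no" to "definite yes"),
#' giving a total in 16-80.
#'
#' @param items Exactly 16 integers, each in 1..5.
#' @return Integer total in \[16, 80\].
#' @export
discern_total <- function(items) {
  if (length(items) != 16) wq_validation_error("DISCERN requires exactly 16 items, got %d", length(items))
  if (any(is.na(items) | items != as.integer(items) | items < 1 | items > 5)) {
    wq_validation_error("DISCERN items must be integers in 1..5")
  }
  as.integer(sum(items))
}

# Quality band lower edges. Published bands stop at 75, but the instrument's
# own usage labels scores up to 80 excellent, so the top band is [63, 80].
.discern_band_breaks <- c(16, 27, 39, 51, 63)
.discern_bands <- c("very poor", "poor", "fair", "good", "excellent")

#' DISCERN quality band
#'
#' Maps a (possibly fractional, from rater means) total to its named quality
#' band: very poor \[16,27), poor \[27,39), fair \[39,51), good \[51,63),
#' excellent \[63,80\].
#'
#' @param total Numeric in \[16, 80\]. Vectorized.
#' @return Character band label(s).
#' @export
classify_discern_band <- function(total) {
  if (any(is.na(total) | total < 16 | total > 80)) {
    wq_range_error("DISCERN total outside [16, 80]: %s",
                   paste(total[is.na(total) | total < 16 | total > 80], collapse = ", "))
  }
  .discern_bands[findInterval(total, .discern_band_breaks)]
}

#' JAMA benchmark total
#'
#' Count of the four credibility standards present (authorship, attribution,
#' disclosure, currency).
#'
#' @param items Exactly 4 logicals (or 0/1).
#' @return Integer in \[0, 4\].
#' @export
jama_total <- function(items) {
  if (length(items) != 4) wq_validation_error("JAMA requires exactly 4 items, got %d", length(items))
  v <- as.integer(items)
  if (any(is.na(v) | !(v %in% c(0L, 1L)))) wq_validation_error("JAMA items must be logical (0/1)")
  sum(v)
}

#' Topic-content rubric total
#'
#' Sum of the six content items (definition, risk factors, outcomes,
#' signs/symptoms, delirium-vs-dementia, prevalence), each scored absent (0),
#' somewhat present (1), or present (2).
#'
#' @param items Exactly 6 integers in 0/1/2.
#' @return Integer in \[0, 12\].
#' @export
content_total <- function(items) {
  if (length(items) != 6) wq_validation_error("content rubric requires exactly 6 items, got %d", length(items))
  if (any(is.na(items) | !(items %in% 0:2))) {
    wq_validation_error("content items must be integers in 0..2")
  }
  as.integer(sum(items))
}

extract_items <- function(rating_row, cols) as.numeric(rating_row[1, cols])

#' Adjudicate DISCERN totals between raters
#'
#' Two raters score independently; totals differing by fewer than 5 points
#' are averaged. A gap of 5 or more requires a third rating, and the final
#' total is the mean of all three (the band follows from
#' [classify_discern_band()]).
#'
#' @param r1,r2 Rating rows (one-row data frames with `discern_q1..q16` and
#'   `website_id`) or plain 16-item vectors.
#' @param r3 Optional third rating in the same form; required iff the two
#'   totals differ by >= 5, ignored (with a note) otherwise.
#' @param website Website label used in diagnostics (taken from `r1` when it
#'   is a rating row).
#' @return Object of class `wq_discern_score`: list with `total`, `band`,
#'   `n_raters_used`.
#' @export
adjudicate_discern <- function(r1, r2, r3 = NULL, website = NULL) {
  as_items <- function(r) if (is.data.frame(r)) extract_items(r, .discern_cols) else r
  site <- if (!is.null(website)) website
          else if (is.data.frame(r1) && "website_id" %in% names(r1)) r1$website_id[1]
          else "<unknown>"
  t1 <- discern_total(as_items(r1))
  t2 <- discern_total(as_items(r2))
  gap <- abs(t1 - t2)
  if (gap >= 5) {
    if (is.null(r3)) {
      wq_stop("wq_adjudication_required",
              "website '%s': DISCERN totals %d and %d differ by %d (>= 5) but no third rating was supplied",
              site, t1, t2, gap)
    }
    t3 <- discern_total(as_items(r3))
    total <- mean(c(t1, t2, t3))
    n <- 3L
  } else {
    if (!is.null(r3)) {
      message(sprintf("website '%s': third rating supplied but totals differ by %d (< 5); ignored",
                      site, gap))
    }
    total <- mean(c(t1, t2))
    n <- 2L
  }
  structure(list(total = total, band = classify_discern_band(total),
                 n_raters_used = n), class = "wq_discern_score")
}

#' Adjudicate item vectors between raters
#'
#' Per-item consensus for JAMA (booleans) and content (0/1/2) items:
#' agreement keeps the value; disagreement is settled by majority with a
#' third rating, or by the third rater's value when all three differ
#' (possible only for three-level items). Disagreement without a third
#' rating is an error listing the unresolved item indices.
#'
#' @param items1,items2 Equal-length item vectors from the two primary raters.
#' @param items3 Optional third rater's vector.
#' @return Adjudicated item vector.
#' @export
adjudicate_items <- function(items1, items2, items3 = NULL) {
  if (length(items1) != length(items2) ||
      (!is.null(items3) && length(items3) != length(items1))) {
    wq_validation_error("item vectors must have equal length")
  }
  disagree <- which(items1 != items2)
  if (!length(disagree)) return(items1)
  if (is.null(items3)) {
    wq_stop("wq_unresolved_disagreement",
            "raters disagree on item(s) %s and no third rating was supplied",
            paste(disagree, collapse = ", "))
  }
  out <- items1
  for (i in disagree) {
    out[i] <- if (items3[i] == items1[i]) items1[i]
              else if (items3[i] == items2[i]) items2[i]
              else items3[i]  # all three differ: third (resolving) rater decides
  }
  out
}

#' Adjudicate every website in a corpus
#'
#' Applies [adjudicate_discern()] and [adjudicate_items()] per website, using
#' the two lowest rater ids as the primary pair and the third (if present) as
#' the resolving rating. Single-rated websites are excluded.
#'
#' @param corpus A [wq_corpus()].
#' @return Data frame with one row per adjudicated website: id, discern_total,
#'   discern_band, discern_raters, jama_total, content_total, the six
#'   adjudicated content items and four JAMA items.
#' @export
adjudicate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "wq_corpus"))
  ids <- corpus$records$id[!corpus$records$single_rated]
  rat <- corpus$ratings[order(corpus$ratings$website_id, corpus$ratings$rater_id), ]
  dm <- as.matrix(rat[.discern_cols])
  jm <- as.matrix(rat[.jama_cols])
  cm <- as.matrix(rat[.content_cols])
  idx <- split(seq_len(nrow(rat)), rat$website_id)

  n <- length(ids)
  discern_tot <- numeric(n); raters <- integer(n)
  jama_mat <- matrix(0, n, 4, dimnames = list(NULL, .jama_cols))
  cont_mat <- matrix(0, n, 6, dimnames = list(NULL, .content_cols))
  for (s in seq_len(n)) {
    id <- ids[s]
    ii <- idx[[id]]
    has3 <- length(ii) >= 3
    ds <- suppressMessages(adjudicate_discern(dm[ii[1], ], dm[ii[2], ],
                                              if (has3) dm[ii[3], ],
                                              website = id))
    item_err <- function(e) {
      wq_stop(class(e)[1], "website '%s': %s", id, conditionMessage(e))
    }
    jama_mat[s, ] <- tryCatch(
      adjudicate_items(jm[ii[1], ], jm[ii[2], ], if (has3) jm[ii[3], ]),
      wq_unresolved_disagreement = item_err)
    cont_mat[s, ] <- tryCatch(
      adjudicate_items(cm[ii[1], ], cm[ii[2], ], if (has3) cm[ii[3], ]),
      wq_unresolved_disagreement = item_err)
    discern_tot[s] <- ds$total
    raters[s] <- ds$n_raters_used
  }
  out <- data.frame(id = ids, discern_total = discern_tot,
                    discern_band = classify_discern_band(discern_tot),
                    discern_raters = raters,
                    jama_total = rowSums(jama_mat),
                    content_total = rowSums(cont_mat),
                    stringsAsFactors = FALSE)
  out[, .jama_cols] <- jama_mat
  out[, .content_cols] <- cont_mat
  out
}
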