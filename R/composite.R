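# Weighted composite quality score: min-max normalization of the four
# component scores and deterministic corpus ranking.

#' Composite score weights
#'
#' Readability, topic content, and DISCERN each carry 30% and the JAMA
#' benchmark 10% by default. Weights must be non-negative and sum to 1.
#'
#' @param readability,content,discern,jama Component weights.
#' @return Object of class `wq_weights` (named numeric vector).
#' @export
composite_weights <- function(readability = 0.30, content = 0.30,
                              discern = 0.30, jama = 0.10) {
  w <- c(readability = readability, content = content,
         discern = discern, jama = jama)
  if (any(w < 0)) wq_validation_error("composite weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-12) {
    wq_validation_error("composite weights must sum to 1 (got %.15f)", sum(w))
  }
  structure(w, class = "wq_weights")
}

#' Min-max normalize a component score
#'
#' `(value - min) / (max - min)`, then reflected to `1 - x` when `reverse` is
#' set (readability grades: lower is better). Instrument components use their
#' possible ranges; readability uses the range observed in the corpus.
#'
#' @param value Numeric vector within \[range_min, range_max\].
#' @param range_min,range_max Range endpoints, `range_min < range_max`.
#' @param reverse Reflect so smaller raw values map to 1.
#' @return Numeric in \[0, 1\].
#' @export
normalize_component <- function(value, range_min, range_max, reverse = FALSE) {
  if (range_min >= range_max) {
    wq_stop("wq_degenerate_range", "degenerate normalization range [%s, %s]",
            format(range_min), format(range_max))
  }
  if (any(value < range_min | value > range_max)) {
    wq_range_error("value outside normalization range [%s, %s]: %s",
                   format(range_min), format(range_max),
                   paste(format(value[value < range_min | value > range_max]), collapse = ", "))
  }
  x <- (value - range_min) / (range_max - range_min)
  if (reverse) 1 - x else x
}

#' Weighted quality score on a 0-100 scale
#'
#' Each component is normalized — DISCERN over its possible range \[16, 80\],
#' content over \[0, 12\], JAMA over \[0, 4\], readability over the range
#' observed in the corpus (reverse-scaled: a lower grade reads easier) — then
#' combined with the weights and scaled to 0-100. Higher is better.
#'
#' @param discern,content,jama Adjudicated instrument totals (vectorized).
#' @param readability Readability metric value(s) for the same websites.
#' @param readability_observed_range Length-2 numeric, min/max of the metric
#'   over the analyzed corpus.
#' @param weights A [composite_weights()].
#' @param reverse_readability `TRUE` for grade metrics (SMOG/FK); use `FALSE`
#'   for Flesch Reading Ease, where higher is better.
#' @return Numeric score(s) in \[0, 100\].
#' @export
weighted_quality_score <- function(discern, content, jama, readability,
                                   readability_observed_range,
                                   weights = composite_weights(),
                                   reverse_readability = TRUE) {
  stopifnot(inherits(weights, "wq_weights"))
  nd <- normalize_component(discern, 16, 80)
  nc <- normalize_component(content, 0, 12)
  nj <- normalize_component(jama, 0, 4)
  nr <- normalize_component(readability, readability_observed_range[1],
                            readability_observed_range[2],
                            reverse = reverse_readability)
  100 * (weights[["readability"]] * nr + weights[["content"]] * nc +
           weights[["discern"]] * nd + weights[["jama"]] * nj)
}

#' Rank a corpus by weighted quality score
#'
#' Computes the readability observed range over the supplied corpus, the
#' weighted score for every website, and a dense 1-based ranking with a
#' deterministic tie-break: weighted score desc, DISCERN desc, content desc,
#' readability asc, id lexicographic. When the corpus has a degenerate
#' readability range (all sites identical) the readability component is
#' substituted with 1.0 for every site and a note is attached.
#'
#' @param scores Data frame with columns `id`, `discern_total`,
#'   `content_total`, `jama_total`, `readability` (the chosen metric's value),
#'   and optionally `url`.
#' @param weights A [composite_weights()].
#' @param reverse_readability As in [weighted_quality_score()].
#' @param top_n Rows for the top-N report.
#' @return List with `ranked` (full data frame, ordered, with `normalized_*`
#'   columns, `weighted_score`, `rank`), `top` (first `top_n` rows with the
#'   score rounded to 1 decimal), and `notes` (character).
#' @export
rank_corpus <- function(scores, weights = composite_weights(),
                        reverse_readability = TRUE, top_n = 10) {
  if (!nrow(scores)) wq_stop("wq_empty_corpus", "cannot rank an empty corpus")
  notes <- character()
  rng <- range(scores$readability)
  if (diff(rng) == 0) {
    nr <- rep(1.0, nrow(scores))
    notes <- c(notes, sprintf(
      "degenerate readability range (all sites at %s); readability component set to 1.0 for all",
      format(rng[1])))
  } else {
    nr <- normalize_component(scores$readability, rng[1], rng[2],
                              reverse = reverse_readability)
  }
  nd <- normalize_component(scores$discern_total, 16, 80)
  nc <- normalize_component(scores$content_total, 0, 12)
  nj <- normalize_component(scores$jama_total, 0, 4)
  ws <- 100 * (weights[["readability"]] * nr + weights[["content"]] * nc +
                 weights[["discern"]] * nd + weights[["jama"]] * nj)
  out <- scores
  out$normalized_readability <- nr
  out$normalized_content <- nc
  out$normalized_discern <- nd
  out$normalized_jama <- nj
  out$weighted_score <- ws
  ord <- order(-out$weighted_score, -out$discern_total, -out$content_total,
               out$readability, out$id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(nrow(out))
  top <- utils::head(out, top_n)
  top$weighted_score <- round(top$weighted_score, 1)  # report-layer rounding only
  list(ranked = out, top = top, notes = notes)
}
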