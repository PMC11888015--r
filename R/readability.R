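# Readability: sentence/word/syllable statistics from raw text and the three
# classic formulas (SMOG, Flesch Reading Ease, Flesch-Kincaid grade level).

.wq_env <- new.env(parent = emptyenv())

# Packaged word -> syllable-count table. Dictionary-first counting keeps the
# pipeline reproducible; the heuristic below only handles words outside it.
syllable_dict <- function() {
  if (is.null(.wq_env$dict)) {
    path <- system.file("extdata", "syllable_dict.csv", package = "webqual")
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    .wq_env$dict <- stats::setNames(as.integer(d$syllables), d$word)
  }
  .wq_env$dict
}

# Abbreviations whose trailing periods never end a sentence.
.wq_abbrev <- c("Dr.", "Mr.", "Mrs.", "Ms.", "Prof.", "St.", "vs.", "etc.",
                "e.g.", "i.e.", "et al.", "Fig.", "No.")

strip_markup <- function(text) {
  text <- gsub("<[^>]*>", " ", text)
  text <- gsub("https?://[^[:space:]]+", " ", text)
  gsub("\\bwww\\.[^[:space:]]+", " ", text)
}

#' Split text into sentences
#'
#' Deterministic rule-based segmentation: sentences end at `.`, `!` or `?`
#' followed by whitespace and a capital letter or digit; a fixed abbreviation
#' stop-list (Dr., e.g., et al., ...) is protected. Markup tags and URLs are
#' stripped first.
#'
#' @param text A UTF-8 string (may be empty).
#' @return Character vector of sentences; `character(0)` for empty input.
#' @export
segment_sentences <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  x <- strip_markup(text)
  # protect abbreviation periods with a one-dot-leader placeholder
  for (ab in .wq_abbrev) {
    pat <- paste0("(?i)\\b", gsub(".", "\\.", ab, fixed = TRUE), "(?=\\s|$)")
    x <- gsub(pat, chartr(".", "․", ab), x, perl = TRUE)
  }
  parts <- strsplit(x, "(?<=[.!?])[[:space:]]+(?=[\"'(“]?[A-Z0-9])",
                    perl = TRUE)[[1]]
  parts <- gsub("․", ".", parts, fixed = TRUE)
  parts <- trimws(gsub("[[:space:]]+", " ", parts))
  parts[vapply(parts, function(s) grepl("[[:alnum:]]", s), logical(1))]
}

tokenize_words <- function(sentence) {
  m <- gregexpr("[A-Za-z0-9]+(?:['’-][A-Za-z0-9]+)*", sentence)
  regmatches(sentence, m)[[1]]
}

# Vowel-group heuristic with silent-e, -le, and -ed adjustments; used only
# for words absent from the packaged dictionary.
syllables_heuristic <- function(w) {
  groups <- lengths(regmatches(w, gregexpr("[aeiouy]+", w)))
  if (groups > 1L && grepl("e$", w) && !grepl("le$", w)) groups <- groups - 1L
  if (groups > 1L && grepl("[^aeiouytd]ed$", w)) groups <- groups - 1L
  max(as.integer(groups), 1L)
}

#' Count syllables in a word
#'
#' Dictionary-first: the packaged hand-counted table is consulted, then a
#' vowel-group heuristic for unknown words. Always at least 1.
#'
#' @param word Character vector; each element must contain at least one letter.
#' @return Integer vector of syllable counts.
#' @export
count_syllables <- function(word) {
  dict <- syllable_dict()
  vapply(word, function(tok) {
    w <- gsub("[^a-z]", "", tolower(tok))
    if (!nzchar(w)) wq_argument_error("word contains no letters: %s", sQuote(tok))
    hit <- dict[w]
    if (!is.na(hit)) return(as.integer(hit))
    syllables_heuristic(w)
  }, integer(1), USE.NAMES = FALSE)
}

# Numerals count as one word and one syllable per digit group; mixed tokens
# ("covid-19") add their digit groups to the letter-part count.
token_syllables <- function(tok) {
  n_digit_groups <- length(regmatches(tok, gregexpr("[0-9]+", tok))[[1]])
  has_letters <- grepl("[A-Za-z]", tok)
  if (!has_letters) {
    if (n_digit_groups == 0) wq_argument_error("token has no letters or digits: %s", sQuote(tok))
    return(n_digit_groups)
  }
  count_syllables(tok) + n_digit_groups
}

#' Sentence, word, syllable, and polysyllable counts for a text
#'
#' @param text A UTF-8 string.
#' @return Object of class `wq_text_stats`: list with `n_sentences`,
#'   `n_words`, `n_syllables`, `n_polysyllables` (words of 3+ syllables).
#' @export
text_stats <- function(text) {
  sents <- segment_sentences(text)
  toks <- unlist(lapply(sents, tokenize_words), use.names = FALSE)
  syl <- if (length(toks)) vapply(toks, token_syllables, numeric(1), USE.NAMES = FALSE) else numeric()
  new_text_stats(length(sents), length(toks), sum(syl), sum(syl >= 3))
}

#' @rdname text_stats
#' @param n_sentences,n_words,n_syllables,n_polysyllables Non-negative counts.
#' @export
new_text_stats <- function(n_sentences, n_words, n_syllables, n_polysyllables) {
  s <- list(n_sentences = as.integer(n_sentences), n_words = as.integer(n_words),
            n_syllables = as.integer(n_syllables),
            n_polysyllables = as.integer(n_polysyllables))
  if (any(unlist(s) < 0)) wq_argument_error("text statistics must be non-negative")
  if (s$n_polysyllables > s$n_words) wq_argument_error("more polysyllables than words")
  if (s$n_words > 0 && s$n_syllables < s$n_words) {
    wq_argument_error("fewer syllables than words")
  }
  structure(s, class = "wq_text_stats")
}

check_defined <- function(stats, need_words = TRUE) {
  if (stats$n_sentences < 1) {
    wq_stop("wq_undefined_statistic", "readability undefined: text has no sentences")
  }
  if (need_words && stats$n_words < 1) {
    wq_stop("wq_undefined_statistic", "readability undefined: text has no words")
  }
}

#' Flesch Reading Ease
#'
#' `206.835 - 1.015 * words/sentence - 84.6 * syllables/word`. Higher is
#' easier; the value is not clamped to \[0, 100\].
#'
#' @param stats A `wq_text_stats` (or a text string, which is tokenized first).
#' @return Numeric score.
#' @export
flesch_reading_ease <- function(stats) {
  if (is.character(stats)) stats <- text_stats(stats)
  check_defined(stats)
  206.835 - 1.015 * (stats$n_words / stats$n_sentences) -
    84.6 * (stats$n_syllables / stats$n_words)
}

#' Flesch-Kincaid grade level
#'
#' `0.39 * words/sentence + 11.8 * syllables/word - 15.59` (US school grade).
#'
#' @inheritParams flesch_reading_ease
#' @return Numeric grade.
#' @export
flesch_kincaid_grade <- function(stats) {
  if (is.character(stats)) stats <- text_stats(stats)
  check_defined(stats)
  0.39 * (stats$n_words / stats$n_sentences) +
    11.8 * (stats$n_syllables / stats$n_words) - 15.59
}

#' SMOG grade
#'
#' `1.0430 * sqrt(polysyllables * 30 / sentences) + 3.1291`. The formula is
#' calibrated for 30-sentence samples; shorter texts are scored anyway and the
#' caller ([readability_profile()]) carries a short-text warning flag.
#'
#' @inheritParams flesch_reading_ease
#' @return Numeric grade.
#' @export
smog_grade <- function(stats) {
  if (is.character(stats)) stats <- text_stats(stats)
  check_defined(stats, need_words = FALSE)
  1.0430 * sqrt(stats$n_polysyllables * 30 / stats$n_sentences) + 3.1291
}

#' Full readability profile of a text
#'
#' Bundles the three scores with the underlying counts and the grade-6
#' compliance flag (`TRUE` when the chosen grade metric is at or below 6.0,
#' the AMA/NIH recommendation for patient materials).
#'
#' @param text A UTF-8 string, non-empty after tokenization.
#' @param grade_metric Which grade drives `meets_grade6`: `"fk"`
#'   (Flesch-Kincaid, default) or `"smog"`.
#' @return Object of class `wq_readability`: list with `stats`, `smog_grade`,
#'   `fk_grade`, `flesch_ease`, `meets_grade6`, `short_text_warning`,
#'   `grade_metric`.
#' @export
readability_profile <- function(text, grade_metric = c("fk", "smog")) {
  grade_metric <- match.arg(grade_metric)
  stats <- if (inherits(text, "wq_text_stats")) text else text_stats(text)
  check_defined(stats)
  smog <- smog_grade(stats)
  fk <- flesch_kincaid_grade(stats)
  fre <- flesch_reading_ease(stats)
  grade <- if (grade_metric == "fk") fk else smog
  structure(list(stats = stats, smog_grade = smog, fk_grade = fk,
                 flesch_ease = fre, meets_grade6 = grade <= 6.0,
                 short_text_warning = stats$n_sentences < 30,
                 grade_metric = grade_metric),
            class = "wq_readability")
}

#' @export
print.wq_readability <- function(x, ...) {
  cat(sprintf("<wq_readability> SMOG %.2f | FK grade %.2f | FRE %.2f%s\n",
              x$smog_grade, x$fk_grade, x$flesch_ease,
              if (x$short_text_warning) " [short text]" else ""))
  invisible(x)
}
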