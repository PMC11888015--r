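# Shared oracles and fixture builders. These deliberately do NOT reuse the
# package's tokenization/statistics code paths: fixtures are constructed from
# the packaged syllable dictionary so their counts are known ground truth,
# and the reference readability implementation below is an independent
# (cruder) tokenizer used for cross-checks.

syl_dict_oracle <- local({
  d <- NULL
  function() {
    if (is.null(d)) {
      path <- system.file("extdata", "syllable_dict.csv", package = "webqual")
      tab <- read.csv(path, stringsAsFactors = FALSE)
      d <<- stats::setNames(as.integer(tab$syllables), tab$word)
    }
    d
  }
})

# Words that could be mistaken for sentence-ending abbreviations ("No.") are
# excluded so the constructed sentence count is exact by design.
fixture_word_pool <- function() {
  d <- syl_dict_oracle()
  d[!(names(d) %in% c("no")) & grepl("^[a-z]+$", names(d))]
}

# Build `n` texts from dictionary words; returns text plus ground-truth
# counts (sentences/words/syllables/polysyllables) established by
# construction, not by running the package tokenizer.
build_fixture_texts <- function(n = 24, seed = 42) {
  pool <- fixture_word_pool()
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    n_s <- sample(2:8, 1)
    wp <- sample(4:12, n_s, replace = TRUE)
    sents <- lapply(wp, function(k) sample(names(pool), k, replace = TRUE))
    text <- paste(vapply(sents, function(ws) {
      ws[1] <- paste0(toupper(substr(ws[1], 1, 1)), substring(ws[1], 2))
      paste0(paste(ws, collapse = " "), ".")
    }, character(1)), collapse = " ")
    all_w <- unlist(sents)
    syl <- unname(pool[all_w])
    list(text = text, n_sentences = n_s, n_words = length(all_w),
         n_syllables = sum(syl), n_polysyllables = sum(syl >= 3))
  })
}

# Independent readability reference: naive sentence split on terminal
# punctuation, naive word split, dictionary lookup with a bare vowel-cluster
# fallback, formulas written out inline.
ref_readability <- function(text) {
  d <- syl_dict_oracle()
  sents <- trimws(strsplit(text, "[.!?]+")[[1]])
  sents <- sents[grepl("[A-Za-z0-9]", sents)]
  words <- unlist(strsplit(tolower(sents), "[^a-z0-9'-]+"))
  words <- words[nzchar(words)]
  syl <- vapply(words, function(w) {
    w2 <- gsub("[^a-z]", "", w)
    if (!nzchar(w2)) return(1L)
    hit <- d[w2]
    if (!is.na(hit)) return(as.integer(hit))
    max(1L, lengths(regmatches(w2, gregexpr("[aeiouy]+", w2))))
  }, integer(1))
  S <- length(sents); W <- length(words)
  list(
    fk = 0.39 * W / S + 11.8 * sum(syl) / W - 15.59,
    fre = 206.835 - 1.015 * W / S - 84.6 * sum(syl) / W,
    smog = 1.0430 * sqrt(sum(syl >= 3) * 30 / S) + 3.1291)
}

# Tie-robust Kruskal-Wallis oracle using the ANOVA-on-ranks identity
# H = (N-1) * sum n_j (rbar_j - rbar)^2 / sum (r_i - rbar)^2,
# algebraically equal to the tie-corrected H but computed differently.
kw_oracle_H <- function(values, groups) {
  r <- rank(values)
  rb <- mean(r)
  num <- sum(tapply(r, groups, function(g) length(g) * (mean(g) - rb)^2))
  den <- sum((r - rb)^2)
  if (den == 0) 0 else (length(values) - 1) * num / den
}

# Exhaustive permutation distribution of H for 9 observations in 3 labeled
# groups of 3 (9! / (3!3!3!) = 1680 assignments).
kw_permutation_9 <- function(values) {
  stopifnot(length(values) == 9)
  out <- numeric(0)
  g1 <- combn(9, 3)
  for (i in seq_len(ncol(g1))) {
    rest <- setdiff(1:9, g1[, i])
    g2 <- combn(rest, 3)
    for (j in seq_len(ncol(g2))) {
      grp <- integer(9)
      grp[g1[, i]] <- 1L
      grp[g2[, j]] <- 2L
      grp[grp == 0L] <- 3L
      out <- c(out, kw_oracle_H(values, grp))
    }
  }
  out
}

# Minimal valid rating row in the corpus ratings schema.
make_rating <- function(website_id, rater_id, discern = rep(3, 16),
                        jama = c(1, 0, 1, 0), content = rep(1, 6)) {
  r <- data.frame(website_id = website_id, rater_id = rater_id,
                  stringsAsFactors = FALSE)
  r[paste0("discern_q", 1:16)] <- as.list(discern)
  r[paste0("jama_", c("authorship", "attribution", "disclosure", "currency"))] <- as.list(jama)
  r[paste0("content_", c("definition", "risk_factors", "outcomes",
                         "signs_symptoms", "delirium_vs_dementia",
                         "prevalence"))] <- as.list(content)
  r
}

# DISCERN item vector with a given total (16..80), deterministic.
discern_items_with_total <- function(total) {
  v <- rep(1L, 16)
  extra <- total - 16
  q <- extra %/% 16
  r <- extra %% 16
  v <- v + q
  if (r > 0) v[seq_len(r)] <- v[seq_len(r)] + 1L
  v
}

make_record <- function(id, category = "academic", last_updated = NA,
                        engagement = "inform", text = "Delirium is common. It can be serious.") {
  data.frame(id = id, url = paste0("https://example.org/", id),
             category = category, country = "Canada",
             last_updated = last_updated, engagement = engagement,
             text = text, stringsAsFactors = FALSE)
}

small_corpus <- function() {
  records <- rbind(make_record("w1", "academic"),
                   make_record("w2", "commercial"),
                   make_record("w3", "government", last_updated = "2021-05-01"))
  ratings <- rbind(
    make_rating("w1", "R1", discern_items_with_total(40)),
    make_rating("w1", "R2", discern_items_with_total(42)),
    make_rating("w2", "R1", discern_items_with_total(60), jama = c(1, 1, 1, 1)),
    make_rating("w2", "R2", discern_items_with_total(62), jama = c(1, 1, 1, 1)),
    make_rating("w3", "R1", discern_items_with_total(30), content = rep(2, 6)),
    make_rating("w3", "R2", discern_items_with_total(33), content = rep(2, 6)))
  wq_corpus(records, ratings)
}
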