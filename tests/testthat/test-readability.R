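test_that("sentence segmentation handles terminators, abbreviations, and empties", {
  expect_length(segment_sentences("Delirium is common. It is serious."), 2)
  expect_length(segment_sentences("Dr. Smith saw the patient."), 1)
  expect_identical(segment_sentences(""), character())
  expect_length(segment_sentences("Is it bad? Yes! It can be."), 3)
  # markup and URLs are stripped before tokenization
  s <- segment_sentences("<p>See https://example.org for care. It helps.</p>")
  expect_length(s, 2)
  expect_false(any(grepl("http", s)))
  # all word characters of the input survive segmentation
  txt <- "The ward was loud. Sleep was poor. Staff helped."
  joined <- gsub("[^[:alnum:]]", "", paste(segment_sentences(txt), collapse = ""))
  expect_identical(joined, gsub("[^[:alnum:]]", "", txt))
})

test_that("syllable counts: dictionary words, heuristic fallback, errors", {
  expect_identical(count_syllables("cat"), 1L)
  expect_identical(count_syllables("delirium"), 4L)
  expect_identical(count_syllables("gobbledygook"), 4L)
  expect_identical(count_syllables("Delirium"), 4L)   # case-insensitive lookup
  # heuristic fallback on words outside the dictionary
  expect_identical(count_syllables("zorblax"), 2L)     # zor-blax
  expect_identical(count_syllables("blate"), 1L)       # silent e
  expect_identical(count_syllables("crumble"), 2L)     # -le keeps its syllable
  expect_true(all(count_syllables(c("strengths", "a", "I")) >= 1L))
  expect_error(count_syllables("123"), class = "wq_argument_error")
})

test_that("text statistics match hand counts", {
  s <- text_stats("The cat sat on the mat.")
  expect_equal(unclass(s)[c("n_sentences", "n_words", "n_syllables", "n_polysyllables")],
               list(n_sentences = 1L, n_words = 6L, n_syllables = 6L,
                    n_polysyllables = 0L))
  # de-lir-i-um (4) + fluc-tu-ates (3), both from the packaged dictionary
  s2 <- text_stats("Delirium fluctuates.")
  expect_equal(s2$n_words, 2L)
  expect_equal(s2$n_syllables, 7L)
  expect_equal(s2$n_polysyllables, 2L)
  s3 <- text_stats("")
  expect_equal(s3$n_sentences + s3$n_words + s3$n_syllables, 0L)
  # numerals: one word, one syllable per digit group
  s4 <- text_stats("It was 2024.")
  expect_equal(s4$n_words, 3L)
  expect_equal(s4$n_syllables, 3L)
})

test_that("formulas evaluate exactly on hand-computed cases", {
  expect_equal(flesch_reading_ease(new_text_stats(1, 6, 6, 0)), 116.145, tolerance = 1e-9)
  expect_equal(flesch_reading_ease(new_text_stats(2, 12, 12, 0)), 116.145, tolerance = 1e-9)
  expect_equal(flesch_reading_ease(new_text_stats(1, 6, 12, 0)), 31.545, tolerance = 1e-9)
  expect_equal(flesch_kincaid_grade(new_text_stats(1, 6, 6, 0)), -1.45, tolerance = 1e-9)
  expect_equal(flesch_kincaid_grade(new_text_stats(1, 20, 40, 0)), 15.81, tolerance = 1e-9)
  expect_equal(smog_grade(new_text_stats(30, 100, 120, 0)), 3.1291, tolerance = 1e-9)
  expect_equal(smog_grade(new_text_stats(30, 100, 190, 30)), 8.84188,
               tolerance = 1e-4)  # 1.0430*sqrt(30) + 3.1291, hand value
  expect_error(flesch_reading_ease(new_text_stats(0, 5, 5, 0)),
               class = "wq_undefined_statistic")
  expect_error(flesch_kincaid_grade(new_text_stats(1, 0, 0, 0)),
               class = "wq_undefined_statistic")
})

test_that("ratio invariance and monotonicity hold on randomized stats", {
  set.seed(101)
  for (i in 1:50) {
    S <- sample(1:40, 1); Wd <- sample(5:400, 1)
    Sy <- Wd + sample(0:(2 * Wd), 1); P <- sample(0:Wd, 1)
    st <- new_text_stats(S, Wd, Sy, P)
    k <- sample(2:5, 1)
    stk <- new_text_stats(k * S, k * Wd, k * Sy, k * P)
    expect_equal(flesch_reading_ease(st), flesch_reading_ease(stk), tolerance = 1e-12)
    expect_equal(flesch_kincaid_grade(st), flesch_kincaid_grade(stk), tolerance = 1e-12)
    expect_equal(smog_grade(st), smog_grade(stk), tolerance = 1e-12)
    # more syllables at fixed words/sentences: FK strictly up, FRE strictly down
    st2 <- new_text_stats(S, Wd, Sy + Wd, P)
    expect_gt(flesch_kincaid_grade(st2), flesch_kincaid_grade(st))
    expect_lt(flesch_reading_ease(st2), flesch_reading_ease(st))
    # more polysyllables never lowers SMOG
    if (P < Wd) expect_gte(smog_grade(new_text_stats(S, Wd, Sy, P + 1)), smog_grade(st))
  }
})

test_that("readability profile applies the grade-6 threshold inclusively", {
  easy <- "The cat sat. The dog ran. He was good."
  p <- readability_profile(easy)
  expect_true(p$meets_grade6)
  expect_true(p$short_text_warning)
  # boundary: the threshold is inclusive ("equal to or lower than grade 6");
  # counts 5/65/91 put FK at 6.0 up to floating point
  st_boundary <- new_text_stats(5, 65, 91, 0)
  pb <- readability_profile(st_boundary)
  expect_equal(pb$fk_grade, 6.0, tolerance = 1e-9)
  expect_identical(pb$meets_grade6, pb$fk_grade <= 6.0)
  hard <- paste(rep("Delirium hallucination university medication prevalence.", 35),
                collapse = " ")
  ph <- readability_profile(hard)
  expect_false(ph$meets_grade6)
  expect_false(ph$short_text_warning)
  expect_gt(ph$fk_grade, 12)
  # smog metric option drives the flag
  expect_identical(readability_profile(easy, grade_metric = "smog")$meets_grade6,
                   readability_profile(easy, grade_metric = "smog")$smog_grade <= 6)
})

test_that("fixture oracle suite: >=20 constructed texts match formula values to 1e-9", {
  fixtures <- build_fixture_texts(n = 24)
  expect_gte(length(fixtures), 20)
  for (fx in fixtures) {
    st <- text_stats(fx$text)
    # tokenizer recovers the constructed ground-truth counts exactly
    expect_identical(st$n_sentences, as.integer(fx$n_sentences))
    expect_identical(st$n_words, as.integer(fx$n_words))
    expect_identical(st$n_syllables, as.integer(fx$n_syllables))
    expect_identical(st$n_polysyllables, as.integer(fx$n_polysyllables))
    ws <- fx$n_words / fx$n_sentences
    sw <- fx$n_syllables / fx$n_words
    expect_equal(flesch_reading_ease(st), 206.835 - 1.015 * ws - 84.6 * sw,
                 tolerance = 1e-9)
    expect_equal(flesch_kincaid_grade(st), 0.39 * ws + 11.8 * sw - 15.59,
                 tolerance = 1e-9)
    expect_equal(smog_grade(st),
                 1.0430 * sqrt(fx$n_polysyllables * 30 / fx$n_sentences) + 3.1291,
                 tolerance = 1e-9)
  }
})

test_that("independent reference implementation agrees within 0.5 grade on fixtures", {
  for (fx in build_fixture_texts(n = 24, seed = 7)) {
    st <- text_stats(fx$text)
    ref <- ref_readability(fx$text)
    expect_lt(abs(flesch_kincaid_grade(st) - ref$fk), 0.5)
    expect_lt(abs(smog_grade(st) - ref$smog), 0.5)
  }
})
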