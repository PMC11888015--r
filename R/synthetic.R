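# Synthetic corpus generator: word-bank texts with controllable reading
# grade and two/three-rater scores with controllable disagreement, so the
# whole pipeline is testable without any download.

#' Synthetic corpus configuration
#'
#' Defaults describe the cohort the generator emulates: 106 sites split
#' across the eight categories in their observed proportions
#' (21/20/19/16/14/6/6/4), per-category latent DISCERN/JAMA/content means at
#' the observed category medians, Flesch-Kincaid grade centered on 10,
#' missing update dates at 23% (82/106 dated), and a 15% forced-disagreement
#' rate driving third-rater adjudication. These defaults are in-distribution
#' smoke settings, never acceptance oracles.
#'
#' @param n_sites Number of websites.
#' @param category_probs Length-8 simplex over [wq_categories()].
#' @param discern_mean,jama_mean,content_mean Length-8 per-category latent
#'   means (or scalars, recycled).
#' @param discern_sd,jama_sd,content_sd Between-site latent SDs.
#' @param grade_mean,grade_sd Target Flesch-Kincaid grade distribution.
#' @param rater_noise_sd Per-rater noise SD on the DISCERN total scale;
#'   scaled by instrument range for JAMA (4/64) and content (12/64) totals.
#' @param disagreement_rate Probability a rater pair is forced to a DISCERN
#'   total gap of at least 5, attaching a third rating; non-forced pairs are
#'   clamped to a gap of at most 4.
#' @param date_range Length-2 Date (or string) range for last_updated.
#' @param missing_date_prob Probability a site reports no date.
#' @param n_sentences Sentences per generated text.
#' @param with_text Generate page text (disable for rating-only simulations).
#' @param seed Integer seed; the whole corpus is reproducible from it.
#' @return Object of class `wq_synth_config`.
#' @export
synthetic_config <- function(n_sites = 106,
                             category_probs = c(21, 20, 19, 16, 14, 6, 6, 4) / 106,
                             discern_mean = c(37.5, 44.5, 42, 46.5, 32.5, 52.5, 40.5, 34),
                             discern_sd = 8,
                             jama_mean = c(1, 3, 1, 1, 1, 1.5, 2.5, 1.5),
                             jama_sd = 1,
                             content_mean = c(6.9, 8.3, 7.9, 8.4, 7.2, 9.6, 7.6, 5.9),
                             content_sd = 2,
                             grade_mean = 10, grade_sd = 2.5,
                             rater_noise_sd = 2,
                             disagreement_rate = 0.15,
                             date_range = c("2014-01-01", "2024-11-21"),
                             missing_date_prob = 0.23,
                             n_sentences = 40,
                             with_text = TRUE,
                             seed = 1L) {
  rec8 <- function(x) if (length(x) == 1) rep(x, 8) else x
  cfg <- list(n_sites = as.integer(n_sites),
              category_probs = category_probs,
              discern_mean = rec8(discern_mean), discern_sd = discern_sd,
              jama_mean = rec8(jama_mean), jama_sd = jama_sd,
              content_mean = rec8(content_mean), content_sd = content_sd,
              grade_mean = rec8(grade_mean), grade_sd = grade_sd,
              rater_noise_sd = rater_noise_sd,
              disagreement_rate = disagreement_rate,
              date_range = as.Date(date_range),
              missing_date_prob = missing_date_prob,
              n_sentences = as.integer(n_sentences),
              with_text = isTRUE(with_text),
              seed = as.integer(seed))
  if (cfg$n_sites < 1) wq_validation_error("n_sites must be >= 1")
  if (length(cfg$category_probs) != 8 || any(cfg$category_probs < 0) ||
      sum(cfg$category_probs) <= 0) {
    wq_validation_error("category_probs must be 8 non-negative weights")
  }
  cfg$category_probs <- cfg$category_probs / sum(cfg$category_probs)
  if (any(c(cfg$discern_sd, cfg$jama_sd, cfg$content_sd, cfg$grade_sd,
            cfg$rater_noise_sd) < 0)) {
    wq_validation_error("standard deviations must be non-negative")
  }
  if (cfg$disagreement_rate < 0 || cfg$disagreement_rate > 1 ||
      cfg$missing_date_prob < 0 || cfg$missing_date_prob > 1) {
    wq_validation_error("probabilities must lie in [0, 1]")
  }
  structure(cfg, class = "wq_synth_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Spread a total across n items bounded by [lo, hi]: every item gets the
# same base amount and the remainder goes to a random subset, one point each.
# Guarantees the exact total (latent totals survive the noiseless path).
allocate_items <- function(total, n, lo, hi) {
  total <- as.integer(round(clamp(total, n * lo, n * hi)))
  extra <- total - n * lo
  q <- extra %/% n
  r <- extra %% n
  v <- rep(lo + q, n)
  if (r > 0) {
    idx <- sample.int(n, r)
    v[idx] <- v[idx] + 1L
  }
  v
}

word_banks <- function() {
  if (is.null(.wq_env$banks)) {
    d <- syllable_dict()
    letters_only <- grepl("^[a-z]+$", names(d)) & nchar(names(d)) >= 2
    .wq_env$banks <- list(mono = names(d)[letters_only & d == 1],
                          poly = names(d)[letters_only & d == 3])
  }
  .wq_env$banks
}

#' Generate text with a target Flesch-Kincaid grade
#'
#' Assembles sentences from dictionary word banks (1-syllable and 3-syllable
#' words), choosing words/sentence and the polysyllable fraction to solve the
#' Flesch-Kincaid formula for the target. Because every bank word carries a
#' packaged syllable count, the generated text's measured statistics are
#' exact, and the achieved grade lands within about +/-1 of the target for
#' 30+ sentences. The prose is word salad by design: only its readability
#' statistics matter.
#'
#' @param target_grade Desired FK grade, in \[1, 22\].
#' @param n_sentences Number of sentences (>= 1).
#' @param seed Optional integer seed (NULL: use the current RNG stream).
#' @return A single text string.
#' @export
generate_text <- function(target_grade, n_sentences, seed = NULL) {
  if (target_grade < 1 || target_grade > 22) {
    wq_argument_error("target_grade must lie in [1, 22], got %s", format(target_grade))
  }
  if (n_sentences < 1) wq_argument_error("n_sentences must be >= 1")
  with_seed(seed, {
    banks <- word_banks()
    spw <- clamp(1.2 + 0.04 * target_grade, 1.1, 2.2)
    wps <- (target_grade + 15.59 - 11.8 * spw) / 0.39
    if (wps < 3 || wps > 35) {
      wps <- clamp(wps, 3, 35)
      spw <- clamp((target_grade + 15.59 - 0.39 * wps) / 11.8, 1.0, 2.6)
    }
    # cumulative rounding: total word count is exactly round(wps * n)
    n_w <- diff(round(wps * (0:n_sentences)))
    n_w <- pmax(n_w, 1)
    W <- sum(n_w)
    p_poly <- clamp((spw - 1) / 2, 0, 1)
    n_poly <- round(p_poly * W)
    spw_ach <- (W - n_poly + 3 * n_poly) / W
    achieved <- 0.39 * (W / n_sentences) + 11.8 * spw_ach - 15.59
    if (abs(achieved - target_grade) > 1) {
      wq_stop("wq_generation_error",
              "target grade %.1f unreachable with available word banks (closest %.1f)",
              target_grade, achieved)
    }
    kinds <- rep(FALSE, W)
    if (n_poly > 0) kinds[sample.int(W, n_poly)] <- TRUE
    words <- character(W)
    words[!kinds] <- sample(banks$mono, W - n_poly, replace = TRUE)
    if (n_poly > 0) words[kinds] <- sample(banks$poly, n_poly, replace = TRUE)
    stops <- cumsum(n_w)
    starts <- c(1, utils::head(stops, -1) + 1)
    sents <- vapply(seq_len(n_sentences), function(i) {
      ws <- words[starts[i]:stops[i]]
      ws[1] <- paste0(toupper(substring(ws[1], 1, 1)), substring(ws[1], 2))
      paste0(paste(ws, collapse = " "), ".")
    }, character(1))
    paste(sents, collapse = " ")
  })
}

#' Generate rater scores around latent instrument totals
#'
#' Draws two independent ratings whose totals sit at the latent totals plus
#' rater noise. With probability `disagreement_rate` the pair is forced to a
#' DISCERN total gap of at least 5 (the adjudication trigger), the second
#' rater's JAMA/content items are perturbed, and a third rating near the
#' latent values is attached; otherwise the pair's gap is clamped below 5 and
#' the JAMA/content vectors agree. Totals are clipped into instrument ranges.
#'
#' @param true_scores List with `discern` (16-80), `content` (0-12),
#'   `jama` (0-4) latent totals.
#' @param noise_sd Rater noise SD on the DISCERN scale.
#' @param disagreement_rate Probability of the forced-disagreement path.
#' @param website_id Website id stamped on the rows.
#' @param seed Optional seed (NULL: current stream).
#' @return Ratings data frame with 2 or 3 rows (rater ids R1, R2, R3).
#' @export
generate_ratings <- function(true_scores, noise_sd, disagreement_rate,
                             website_id = "w1", seed = NULL) {
  with_seed(seed, {
    sm <- gen_site_ratings(true_scores, noise_sd, disagreement_rate)
    out <- data.frame(website_id = rep(website_id, length(sm$raters)),
                      rater_id = sm$raters, stringsAsFactors = FALSE)
    out[, colnames(sm$mat)] <- sm$mat
    out
  })
}

# One site's rater item matrix (rows = raters, cols = the 26 item columns).
# Matrix form so corpus generation avoids per-site data.frame overhead.
gen_site_ratings <- function(true_scores, noise_sd, disagreement_rate) {
  ld <- clamp(true_scores$discern, 16, 80)
  lc <- clamp(true_scores$content, 0, 12)
  lj <- clamp(true_scores$jama, 0, 4)
  sd_c <- noise_sd * 12 / 64
  sd_j <- noise_sd * 4 / 64
  forced <- stats::runif(1) < disagreement_rate
  t1 <- clamp(round(ld + stats::rnorm(1, 0, noise_sd)), 16, 80)
  t2 <- clamp(round(ld + stats::rnorm(1, 0, noise_sd)), 16, 80)
  if (forced) {
    if (abs(t1 - t2) < 5) {
      dir <- if (t1 <= 48) 1 else -1
      t2 <- clamp(t1 + dir * (5 + abs(round(stats::rnorm(1, 0, noise_sd)))), 16, 80)
    }
  } else if (abs(t1 - t2) >= 5) {
    t2 <- clamp(t1 + sign(t2 - t1) * 4, 16, 80)
  }
  c12 <- clamp(round(lc + stats::rnorm(1, 0, sd_c)), 0, 12)
  j12 <- clamp(round(lj + stats::rnorm(1, 0, sd_j)), 0, 4)
  cont1 <- allocate_items(c12, 6, 0, 2)
  jam1 <- allocate_items(j12, 4, 0, 1)
  cont2 <- cont1
  jam2 <- jam1
  if (forced) {
    i <- sample.int(6, 1)
    cont2[i] <- if (cont2[i] < 2) cont2[i] + 1L else cont2[i] - 1L
    i <- sample.int(4, 1)
    jam2[i] <- 1L - jam2[i]
  }
  rows <- list(c(allocate_items(t1, 16, 1, 5), jam1, cont1),
               c(allocate_items(t2, 16, 1, 5), jam2, cont2))
  raters <- c("R1", "R2")
  if (forced) {
    t3 <- clamp(round(ld + stats::rnorm(1, 0, noise_sd)), 16, 80)
    rows <- c(rows, list(c(allocate_items(t3, 16, 1, 5),
                           allocate_items(round(lj), 4, 0, 1),
                           allocate_items(round(lc), 6, 0, 2))))
    raters <- c(raters, "R3")
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- c(.discern_cols, .jama_cols, .content_cols)
  list(raters = raters, mat = mat)
}

#' Generate a complete synthetic corpus with its latent truth
#'
#' Samples categories, metadata (dates, engagement patterns, country),
#' per-site latent instrument totals and target reading grades from the
#' config, renders texts with [generate_text()] and ratings with
#' [generate_ratings()]. Byte-identical output for identical config + seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `corpus` (a [wq_corpus()]), `truth` (data frame of
#'   per-site latent values and the forced-disagreement flag), and `config`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "wq_synth_config"))
  with_seed(config$seed, {
    n <- config$n_sites
    cats <- wq_categories()
    ci <- sample.int(8, n, replace = TRUE, prob = config$category_probs)
    ids <- sprintf("site%03d", seq_len(n))
    lat_d <- clamp(stats::rnorm(n, config$discern_mean[ci], config$discern_sd), 16, 80)
    lat_c <- clamp(stats::rnorm(n, config$content_mean[ci], config$content_sd), 0, 12)
    lat_j <- clamp(stats::rnorm(n, config$jama_mean[ci], config$jama_sd), 0, 4)
    grade <- clamp(stats::rnorm(n, config$grade_mean[ci], config$grade_sd), 1, 22)

    days <- as.integer(config$date_range[2] - config$date_range[1])
    upd <- config$date_range[1] + sample.int(days + 1, n, replace = TRUE) - 1
    upd[stats::runif(n) < config$missing_date_prob] <- NA
    pats <- c("inform;activate;collaborate", "inform;activate", "inform",
              "inform;collaborate")
    engagement <- sample(pats, n, replace = TRUE,
                         prob = c(62, 22, 17, 5) / 106)
    country <- sample(c("Canada", "United States", "United Kingdom",
                        "Australia", NA), n, replace = TRUE,
                      prob = c(0.2, 0.4, 0.15, 0.1, 0.15))

    text <- if (config$with_text) {
      vapply(grade, generate_text, character(1), n_sentences = config$n_sentences)
    } else rep("", n)

    records <- data.frame(
      id = ids, url = paste0("https://example.org/", ids),
      category = cats[ci], country = country,
      last_updated = upd, date_partial = FALSE,
      engagement = engagement, text = text,
      stringsAsFactors = FALSE)

    site_r <- lapply(seq_len(n), function(i) {
      gen_site_ratings(list(discern = lat_d[i], content = lat_c[i], jama = lat_j[i]),
                       noise_sd = config$rater_noise_sd,
                       disagreement_rate = config$disagreement_rate)
    })
    k <- vapply(site_r, function(s) length(s$raters), integer(1))
    mat <- do.call(rbind, lapply(site_r, `[[`, "mat"))
    ratings <- data.frame(website_id = rep(ids, k),
                          rater_id = unlist(lapply(site_r, `[[`, "raters")),
                          stringsAsFactors = FALSE)
    ratings[, colnames(mat)] <- mat

    truth <- data.frame(id = ids, category = cats[ci],
                        discern_latent = lat_d, content_latent = lat_c,
                        jama_latent = lat_j, grade_target = grade,
                        forced_disagreement = ids %in%
                          ratings$website_id[ratings$rater_id == "R3"],
                        stringsAsFactors = FALSE)

    list(corpus = wq_corpus(records, ratings), truth = truth, config = config)
  })
}
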