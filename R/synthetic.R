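# Synthetic readers: parametric texts and simulated scanpaths with
# controllable skill parameters (skip, regression, refixation rates, speed),
# so every pipeline stage and every directional claim can be exercised
# without recorded eye-movement data.

#' Reader profile
#'
#' Bundle of generative parameters for one simulated reader: class-specific
#' word-skipping probabilities, the per-fixation probability of a
#' within-sentence regression (with a span limit), the refixation
#' probability, and the fixation duration distribution (normal, truncated to
#' the 40-1000 ms cleaning window so simulated fixations survive
#' [clean_fixations()] unchanged).
#'
#' @param p_skip_function,p_skip_content Skip probabilities for function and
#'   content words.
#' @param p_skip_topic Skip probability for recurring topic words. Topic
#'   words are informative and unpredictable, so they are rarely skipped at
#'   any skill level; the default is identical in both presets.
#' @param p_regress Per-fixation probability of a backward saccade to a
#'   previously fixated word of the same sentence.
#' @param regress_span Maximum number of words a regression can jump back.
#' @param p_refix Probability of immediately refixating the current word.
#' @param fixation_ms_mean,fixation_ms_sd Fixation duration distribution in
#'   milliseconds.
#' @return Object of class `reader_profile`.
#' @export
reader_profile <- function(p_skip_function = 0.4, p_skip_content = 0.15,
                           p_skip_topic = 0.05, p_regress = 0.15,
                           regress_span = 5L, p_refix = 0.1,
                           fixation_ms_mean = 240, fixation_ms_sd = 60) {
  probs <- c(p_skip_function, p_skip_content, p_skip_topic, p_regress, p_refix)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (fixation_ms_mean <= 0 || fixation_ms_sd <= 0) {
    stop("fixation duration parameters must be positive")
  }
  stopifnot(regress_span >= 1L)
  structure(
    list(p_skip_function = p_skip_function, p_skip_content = p_skip_content,
         p_skip_topic = p_skip_topic,
         p_regress = p_regress, regress_span = as.integer(regress_span),
         p_refix = p_refix, fixation_ms_mean = fixation_ms_mean,
         fixation_ms_sd = fixation_ms_sd),
    class = "reader_profile"
  )
}

#' @export
print.reader_profile <- function(x, ...) {
  cat(sprintf(paste0("Reader profile: skip fn %.2f / content %.2f / topic %.2f, ",
                     "regress %.2f (span %d), refix %.2f, fixation %g±%g ms\n"),
              x$p_skip_function, x$p_skip_content, x$p_skip_topic, x$p_regress,
              x$regress_span, x$p_refix, x$fixation_ms_mean,
              x$fixation_ms_sd))
  invisible(x)
}

#' Skilled and less-skilled reader presets
#'
#' The presets encode the canonical eye-movement contrast between reading
#' skill groups: skilled readers skip more words (especially short
#' closed-class words), regress and refixate less, and fixate more briefly.
#' The rates sit in the ranges typically reported for adult readers of
#' expository text (function-word skip rates around one half for skilled
#' readers, regression rates near one in ten for skilled versus one in four
#' for less skilled).
#'
#' @return A [reader_profile()].
#' @export
skilled_profile <- function() {
  reader_profile(p_skip_function = 0.60, p_skip_content = 0.25,
                 p_skip_topic = 0.05, p_regress = 0.08, regress_span = 5L,
                 p_refix = 0.05, fixation_ms_mean = 210, fixation_ms_sd = 50)
}

#' @rdname skilled_profile
#' @export
less_skilled_profile <- function() {
  reader_profile(p_skip_function = 0.25, p_skip_content = 0.08,
                 p_skip_topic = 0.05, p_regress = 0.25, regress_span = 5L,
                 p_refix = 0.15, fixation_ms_mean = 275, fixation_ms_sd = 70)
}

#' Interpolate between the skill presets
#'
#' Linear blend of every parameter of [less_skilled_profile()] (skill 0) and
#' [skilled_profile()] (skill 1).
#'
#' @param skill Number in \[0, 1\].
#' @return A [reader_profile()].
#' @export
interpolate_profile <- function(skill) {
  stopifnot(is.numeric(skill), length(skill) == 1L, skill >= 0, skill <= 1)
  lo <- less_skilled_profile()
  hi <- skilled_profile()
  mix <- function(f) (1 - skill) * lo[[f]] + skill * hi[[f]]
  reader_profile(p_skip_function = mix("p_skip_function"),
                 p_skip_content = mix("p_skip_content"),
                 p_skip_topic = mix("p_skip_topic"),
                 p_regress = mix("p_regress"),
                 regress_span = round(mix("regress_span")),
                 p_refix = mix("p_refix"),
                 fixation_ms_mean = mix("fixation_ms_mean"),
                 fixation_ms_sd = mix("fixation_ms_sd"))
}

# Pool of pronounceable pseudo content words, deterministic given the RNG
# state; avoids collisions with the function-word lexicon and topic words.
make_content_pool <- function(n_words, reserved) {
  syll <- c("ba", "co", "da", "fe", "gi", "ho", "ju", "ke", "lo", "mi",
            "na", "po", "qu", "ri", "sa", "te", "vu", "we", "xa", "zo")
  pool <- character(0)
  while (length(pool) < n_words) {
    k <- sample(2:3, 1L)
    w <- paste(sample(syll, k, replace = TRUE), collapse = "")
    if (!w %in% reserved && !w %in% pool) pool <- c(pool, w)
  }
  pool
}

#' Generate a synthetic expository text
#'
#' Emulates the structure of a short expository science text: `n_sentences`
#' sentences of around `mean_words` words, closed-class function words
#' recurring from a fixed lexicon, mostly-unique pseudo content words, and
#' `n_topic_words` topic words each planted in a `topic_recurrence` share of
#' the sentences so that a sequential read already produces hub nodes (the
#' role played by recurring topic terms such as "Mars" and "Earth" in real
#' texts, where the topic of an expository passage is named in most
#' sentences).
#'
#' @param n_sentences Number of sentences (default 30).
#' @param mean_words Mean sentence length in words (default 10).
#' @param n_topic_words Number of recurring topic words (default 2).
#' @param topic_recurrence Share of sentences each topic word is planted in
#'   (default 0.8; must be at least 0.5 so topic words are genuine hubs).
#' @param text_id Identifier.
#' @param seed Integer seed; the text is deterministic given the seed.
#' @return A [text_stimulus()] with function-word flags and attribute
#'   `topic_words`.
#' @export
generate_text <- function(n_sentences = 30L, mean_words = 10L,
                          n_topic_words = 2L, topic_recurrence = 0.8,
                          text_id = "synthetic1", seed = NULL) {
  stopifnot(n_sentences >= 1L, mean_words >= 4L, n_topic_words >= 0L,
            topic_recurrence >= 0.5, topic_recurrence <= 1)
  fn_words <- function_word_lexicon()
  topic_pool <- c("mars", "earth", "orbit", "voltage", "satellite", "tanker",
                  "signal", "planet")
  stopifnot(n_topic_words <= length(topic_pool))
  topics <- topic_pool[seq_len(n_topic_words)]
  with_local_seed(seed, {
    lens <- pmax(4L, stats::rpois(n_sentences, mean_words))
    content <- make_content_pool(sum(lens), reserved = c(fn_words, topics))
    ci <- 0L
    sentences <- vector("list", n_sentences)
    for (s in seq_len(n_sentences)) {
      L <- lens[s]
      n_fn <- max(1L, round(0.4 * L))
      fn_pos <- sort(sample(seq_len(L), n_fn))
      toks <- character(L)
      toks[fn_pos] <- sample(fn_words, n_fn, replace = TRUE)
      n_ct <- L - n_fn
      toks[-fn_pos] <- content[ci + seq_len(n_ct)]
      ci <- ci + n_ct
      sentences[[s]] <- toks
    }
    # Plant each topic word into a fixed-size majority of sentences, replacing
    # one content-word slot, so hub structure is guaranteed, not just likely.
    n_hit <- ceiling(topic_recurrence * n_sentences)
    for (tw in topics) {
      hit <- sample(seq_len(n_sentences), n_hit)
      for (s in hit) {
        slots <- which(!sentences[[s]] %in% fn_words &
                         !sentences[[s]] %in% topics)
        if (length(slots) > 0L) {
          pos <- if (length(slots) == 1L) slots else sample(slots, 1L)
          sentences[[s]][pos] <- tw
        }
      }
    }
    flags <- lapply(sentences, function(x) x %in% fn_words)
    out <- text_stimulus(sentences, text_id = text_id, function_flags = flags)
    attr(out, "topic_words") <- topics
    out
  })
}

#' Simulate one reader's scanpath over a text
#'
#' Walks each sentence left to right. Each word is skipped with its
#' class-specific probability; after fixating a word the reader refixates it
#' with probability `p_refix`, and with probability `p_regress` launches a
#' backward saccade to a previously fixated word at most `regress_span`
#' words back in the same sentence, then resumes the forward sweep.
#' Regressions never cross sentence boundaries, matching sentence-by-sentence
#' presentation. Durations are drawn from the profile's truncated normal.
#'
#' @param text A [text_stimulus()].
#' @param profile A [reader_profile()].
#' @param participant_id Identifier.
#' @param seed Integer seed; the scanpath is deterministic given the seed.
#' @return A [scanpath()].
#' @export
simulate_scanpath <- function(text, profile, participant_id = "sim1",
                              seed = NULL) {
  stopifnot(inherits(text, "text_stimulus"), inherits(profile, "reader_profile"))
  with_local_seed(seed, {
    sent_idx <- integer(0)
    word_idx <- integer(0)
    for (s in seq_along(text$sentences)) {
      toks <- text$sentences[[s]]
      flags <- if (!is.null(text$function_flags)) {
        text$function_flags[[s]]
      } else {
        canonicalize_token(toks) %in% function_word_lexicon()
      }
      topics <- attr(text, "topic_words") %||% character(0)
      is_topic <- canonicalize_token(toks) %in% topics
      fixated <- integer(0)
      for (w in seq_along(toks)) {
        p_skip <- if (is_topic[w]) {
          profile$p_skip_topic
        } else if (flags[w]) {
          profile$p_skip_function
        } else {
          profile$p_skip_content
        }
        if (stats::runif(1) < p_skip) next
        fixated <- c(fixated, w)
        sent_idx <- c(sent_idx, s); word_idx <- c(word_idx, w)
        if (stats::runif(1) < profile$p_refix) {
          sent_idx <- c(sent_idx, s); word_idx <- c(word_idx, w)
        }
        if (stats::runif(1) < profile$p_regress) {
          back <- fixated[fixated >= w - profile$regress_span & fixated < w]
          if (length(back) > 0L) {
            tgt <- if (length(back) == 1L) back else sample(back, 1L)
            sent_idx <- c(sent_idx, s); word_idx <- c(word_idx, tgt)
          }
        }
      }
    }
    n_fix <- length(sent_idx)
    if (n_fix == 0L) {
      # pathological all-skip profile: force one fixation on the first word
      sent_idx <- 1L
      word_idx <- 1L
      n_fix <- 1L
    }
    durations <- rtruncnorm(n_fix, profile$fixation_ms_mean,
                            profile$fixation_ms_sd, 40, 1000)
    tokens <- stimulus_token(text, sent_idx, word_idx)
    scanpath(data.frame(node_key = canonicalize_token(tokens),
                        sentence_index = sent_idx, word_index = word_idx,
                        duration_ms = durations, stringsAsFactors = FALSE),
             participant_id = participant_id, text_id = text$text_id)
  })
}

#' Generate a synthetic reader cohort
#'
#' Readers are placed evenly along the skill spectrum from the less-skilled
#' to the skilled preset, each simulated over the given text(s). Behavioral
#' outcome components are monotone functions of skill plus Gaussian noise:
#' assessment accuracy and a standardized reading-test score rise with skill,
#' while total reading time is the reader's actual mean simulated reading
#' time per text (which falls with skill through skipping and shorter
#' fixations). Fully reproducible from `seed`.
#'
#' @param texts A [text_stimulus()] or list of them.
#' @param n_readers Cohort size (default 52).
#' @param skill_range Range of the skill spectrum (default \[0, 1\]).
#' @param assessment_noise_sd,gsrt_noise_sd Noise SDs for the two behavioral
#'   components (accuracy points and standardized-score points).
#' @param seed Integer seed.
#' @return List with `scanpaths` (list per reader of list per text),
#'   `outcomes` (data frame: `participant_id`, `assessment`, `gsrt`,
#'   `total_rt_ms`, `skill`), and `profiles`.
#' @export
generate_cohort <- function(texts, n_readers = 52L, skill_range = c(0, 1),
                            assessment_noise_sd = 0.05, gsrt_noise_sd = 4,
                            seed = NULL) {
  if (inherits(texts, "text_stimulus")) texts <- list(texts)
  stopifnot(length(texts) >= 1L, n_readers >= 2L)
  skills <- seq(skill_range[1], skill_range[2], length.out = n_readers)
  ids <- sprintf("reader%03d", seq_len(n_readers))
  with_local_seed(seed, {
    profiles <- lapply(skills, interpolate_profile)
    scanpaths <- vector("list", n_readers)
    total_rt <- numeric(n_readers)
    for (r in seq_len(n_readers)) {
      sps <- lapply(texts, function(tx) {
        simulate_scanpath(tx, profiles[[r]], participant_id = ids[r])
      })
      names(sps) <- vapply(texts, function(tx) tx$text_id, character(1))
      scanpaths[[r]] <- sps
      total_rt[r] <- mean(vapply(sps, function(sp) sum(sp$entries$duration_ms),
                                 numeric(1)))
    }
    assessment <- pmin(1, pmax(0, 0.45 + 0.45 * skills +
                                 stats::rnorm(n_readers, 0, assessment_noise_sd)))
    gsrt <- 80 + 35 * skills + stats::rnorm(n_readers, 0, gsrt_noise_sd)
    outcomes <- data.frame(participant_id = ids, assessment = assessment,
                           gsrt = gsrt, total_rt_ms = total_rt,
                           skill = skills, stringsAsFactors = FALSE)
    list(scanpaths = scanpaths, outcomes = outcomes, profiles = profiles)
  })
}

#' Write simulated scanpaths as a fixation report
#'
#' Emits the CSV dialect [parse_fixation_report()] consumes with its default
#' column mapping. Onsets are reconstructed by accumulating durations plus a
#' nominal 30 ms saccade gap within each participant-text series.
#'
#' @param scanpaths List (per reader) of lists (per text) of [scanpath()]s,
#'   as produced by [generate_cohort()], or a flat list of scanpaths.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixation_report <- function(scanpaths, path) {
  flat <- list()
  for (el in scanpaths) {
    if (inherits(el, "scanpath")) flat <- c(flat, list(el))
    else flat <- c(flat, unname(el))
  }
  rows <- lapply(flat, function(sp) {
    e <- sp$entries
    onset <- cumsum(c(0, utils::head(e$duration_ms, -1) + 30))
    data.frame(RECORDING_SESSION_LABEL = sp$participant_id,
               text_id = sp$text_id,
               sentence_index = e$sentence_index,
               word_index = e$word_index,
               token = e$node_key,
               CURRENT_FIX_START = onset,
               CURRENT_FIX_DURATION = e$duration_ms,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write behavioral outcomes as CSV
#'
#' @param outcomes Data frame from [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_behavioral_csv <- function(outcomes, path) {
  utils::write.csv(outcomes[c("participant_id", "assessment", "gsrt",
                              "total_rt_ms")], path, row.names = FALSE)
  invisible(path)
}
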