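# Reading, validating and cleaning word-level fixation reports, and turning
# them into per-reader, per-text scanpaths.

#' Default fixation-report column mapping
#'
#' Maps the seven fields a fixation record needs onto column names in the
#' input file. The defaults follow EyeLink Data Viewer fixation-report
#' conventions; override any entry to match your report.
#'
#' @param participant,text,sentence,word,token,onset,duration Column names in
#'   the report for each field.
#' @return Named character vector suitable for `column_map` arguments.
#' @export
fixation_columns <- function(participant = "RECORDING_SESSION_LABEL",
                             text = "text_id",
                             sentence = "sentence_index",
                             word = "word_index",
                             token = "token",
                             onset = "CURRENT_FIX_START",
                             duration = "CURRENT_FIX_DURATION") {
  c(participant = participant, text = text, sentence = sentence,
    word = word, token = token, onset = onset, duration = duration)
}

#' Parse a word-level fixation report
#'
#' Reads a CSV/TSV fixation report into a validated data frame of fixation
#' records. Rows whose numeric fields do not parse are collected in a rejects
#' attribute rather than silently dropped. Extra, unmapped columns are
#' ignored.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector from [fixation_columns()].
#' @param sep Field separator; `","` for CSV (default), `"\t"` for TSV.
#' @return A data frame with columns `participant_id`, `text_id`,
#'   `sentence_index`, `word_index`, `token`, `onset_ms`, `duration_ms`, in
#'   file order, with attribute `"rejects"` holding the skipped rows (with a
#'   `reason` column).
#' @export
parse_fixation_report <- function(path, column_map = fixation_columns(),
                                  sep = ",") {
  needed <- c("participant", "text", "sentence", "word", "token", "onset",
              "duration")
  if (!all(needed %in% names(column_map))) {
    stop("column_map must name all of: ", paste(needed, collapse = ", "))
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0L) {
    warning("fixation report is empty: ", path)
    return(empty_fixation_frame())
  }
  missing_cols <- setdiff(unname(column_map[needed]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("fixation report lacks mapped column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(
    participant_id = raw[[column_map[["participant"]]]],
    text_id = raw[[column_map[["text"]]]],
    sentence_index = suppressWarnings(as.integer(raw[[column_map[["sentence"]]]])),
    word_index = suppressWarnings(as.integer(raw[[column_map[["word"]]]])),
    token = raw[[column_map[["token"]]]],
    onset_ms = suppressWarnings(as.numeric(raw[[column_map[["onset"]]]])),
    duration_ms = suppressWarnings(as.numeric(raw[[column_map[["duration"]]]])),
    stringsAsFactors = FALSE
  )
  bad <- is.na(df$sentence_index) | is.na(df$word_index) |
    is.na(df$onset_ms) | is.na(df$duration_ms) |
    df$duration_ms <= 0 | df$onset_ms < 0 |
    df$sentence_index < 1L | df$word_index < 1L
  rejects <- df[bad, , drop = FALSE]
  if (nrow(rejects) > 0L) {
    rejects$reason <- "unparseable or out-of-range numeric field"
    warning(nrow(rejects), " fixation row(s) rejected; see attr(x, 'rejects')")
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

empty_fixation_frame <- function() {
  out <- data.frame(participant_id = character(0), text_id = character(0),
                    sentence_index = integer(0), word_index = integer(0),
                    token = character(0), onset_ms = numeric(0),
                    duration_ms = numeric(0), stringsAsFactors = FALSE)
  attr(out, "rejects") <- out
  out
}

#' Exclude implausibly short or long fixations
#'
#' Keeps fixations whose duration lies inside the closed interval
#' \[`min_ms`, `max_ms`\]; the standard cleaning window for reading data
#' excludes fixations strictly shorter than 40 ms or strictly longer than
#' 1000 ms, so boundary values survive. Input order is preserved and the call
#' is idempotent.
#'
#' @param records Fixation data frame as from [parse_fixation_report()].
#' @param min_ms,max_ms Duration window in milliseconds.
#' @return A list with elements `kept` and `removed`, partitioning `records`.
#' @export
clean_fixations <- function(records, min_ms = 40, max_ms = 1000) {
  stopifnot(is.data.frame(records))
  if (min_ms >= max_ms) stop("min_ms must be strictly below max_ms")
  keep <- records$duration_ms >= min_ms & records$duration_ms <= max_ms
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Construct a scanpath object
#'
#' A scanpath is the time-ordered sequence of fixated word tokens for one
#' reader over one text, each entry carrying the canonical node key, its
#' sentence/word position, and the fixation duration.
#'
#' @param entries Data frame with columns `node_key`, `sentence_index`,
#'   `word_index`, `duration_ms`, already in fixation onset order.
#' @param participant_id,text_id Identifiers.
#' @return An object of class `scanpath`.
#' @export
scanpath <- function(entries, participant_id, text_id) {
  stopifnot(is.data.frame(entries),
            all(c("node_key", "sentence_index", "word_index",
                  "duration_ms") %in% names(entries)))
  if (nrow(entries) > 0L && any(entries$duration_ms <= 0)) {
    stop("all fixation durations must be positive")
  }
  rownames(entries) <- NULL
  structure(
    list(participant_id = as.character(participant_id),
         text_id = as.character(text_id),
         entries = entries[c("node_key", "sentence_index", "word_index",
                             "duration_ms")]),
    class = "scanpath"
  )
}

#' @export
print.scanpath <- function(x, max_keys = 12L, ...) {
  n <- nrow(x$entries)
  keys <- x$entries$node_key
  shown <- paste(utils::head(keys, max_keys), collapse = " ")
  if (n > max_keys) shown <- paste0(shown, " ...")
  cat(sprintf("Scanpath: participant '%s', text '%s', %d fixations\n",
              x$participant_id, x$text_id, n))
  if (n > 0L) cat("  ", shown, "\n", sep = "")
  invisible(x)
}

#' @export
length.scanpath <- function(x) nrow(x$entries)

#' Extract a scanpath from cleaned fixation records
#'
#' Orders the fixations of one participant on one text by onset time, resolves
#' each (sentence, word) position to its token in the stimulus, and
#' canonicalizes tokens into node keys. For the sentence "Could humans live on
#' Mars some day?" a reader fixating words 1, 2, 3, 5, 7, 1, 2 yields the
#' scanpath \code{could humans live mars day could humans}.
#'
#' Onset ties are broken by input row order with a message; ties indicate a
#' malformed report (a single eye cannot produce simultaneous fixations).
#'
#' @param records Fixation data frame spanning exactly one participant and one
#'   text.
#' @param stimulus The [text_stimulus()] the fixations refer to.
#' @return A [scanpath()].
#' @export
extract_scanpath <- function(records, stimulus) {
  stopifnot(is.data.frame(records), inherits(stimulus, "text_stimulus"))
  if (nrow(records) == 0L) stop("no fixation records to extract a scanpath from")
  if (length(unique(records$participant_id)) != 1L ||
      length(unique(records$text_id)) != 1L) {
    stop("records span multiple participants or texts; group them first")
  }
  if (anyDuplicated(records$onset_ms)) {
    message("onset ties present; broken by input row order")
  }
  ord <- order(records$onset_ms)
  rec <- records[ord, , drop = FALSE]
  tokens <- stimulus_token(stimulus, rec$sentence_index, rec$word_index)
  entries <- data.frame(
    node_key = canonicalize_token(tokens),
    sentence_index = rec$sentence_index,
    word_index = rec$word_index,
    duration_ms = rec$duration_ms,
    stringsAsFactors = FALSE
  )
  scanpath(entries, rec$participant_id[1], rec$text_id[1])
}

#' Write a scanpath to CSV
#'
#' Columns: participant, text, order, node_key, sentence_index, word_index,
#' duration_ms. [read_scanpath()] reproduces the object exactly.
#'
#' @param sp A [scanpath()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scanpath <- function(sp, path) {
  stopifnot(inherits(sp, "scanpath"))
  df <- data.frame(participant = sp$participant_id, text = sp$text_id,
                   order = seq_len(nrow(sp$entries)), sp$entries,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a scanpath written by [write_scanpath()]
#'
#' @param path CSV path.
#' @return A [scanpath()].
#' @export
read_scanpath <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant = "character",
                                       text = "character",
                                       node_key = "character"))
  if (nrow(df) == 0L) stop("scanpath file is empty: ", path)
  df <- df[order(df$order), , drop = FALSE]
  scanpath(df[c("node_key", "sentence_index", "word_index", "duration_ms")],
           participant_id = df$participant[1], text_id = df$text[1])
}
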