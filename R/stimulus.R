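#' Text stimulus
#'
#' A text stimulus is the ordered token content of one reading text: a list of
#' sentences, each an ordered character vector of word tokens, optionally with
#' a parallel logical structure flagging closed-class (function) words. Word
#' and sentence indices throughout the package are 1-based.
#'
#' @param sentences List of non-empty character vectors, one per sentence, in
#'   presentation order.
#' @param text_id Identifier for the text.
#' @param function_flags Optional list of logical vectors parallel to
#'   `sentences`, `TRUE` where the token is a function word.
#' @return An object of class `text_stimulus`.
#' @export
text_stimulus <- function(sentences, text_id = "text1", function_flags = NULL) {
  stopifnot(is.list(sentences), length(sentences) >= 1L)
  for (s in sentences) {
    if (!is.character(s) || length(s) == 0L || any(!nzchar(s))) {
      stop("every sentence must be a non-empty character vector of non-empty tokens")
    }
  }
  if (!is.null(function_flags)) {
    stopifnot(is.list(function_flags), length(function_flags) == length(sentences))
    ok <- mapply(function(f, s) is.logical(f) && length(f) == length(s),
                 function_flags, sentences)
    if (!all(ok)) stop("function_flags must parallel sentences token-for-token")
  }
  structure(
    list(text_id = as.character(text_id), sentences = sentences,
         function_flags = function_flags),
    class = "text_stimulus"
  )
}

#' @export
print.text_stimulus <- function(x, ...) {
  n_tok <- sum(lengths(x$sentences))
  cat(sprintf("Text stimulus '%s': %d sentences, %d tokens%s\n",
              x$text_id, length(x$sentences), n_tok,
              if (is.null(x$function_flags)) "" else " (function words flagged)"))
  invisible(x)
}

# Look up the token at a (sentence, word) position; errors on out-of-range.
stimulus_token <- function(stimulus, sentence_index, word_index) {
  if (any(sentence_index < 1L) || any(sentence_index > length(stimulus$sentences))) {
    stop("sentence_index out of range for text '", stimulus$text_id, "'")
  }
  vapply(seq_along(sentence_index), function(k) {
    s <- stimulus$sentences[[sentence_index[k]]]
    if (word_index[k] < 1L || word_index[k] > length(s)) {
      stop(sprintf("word_index %d out of range in sentence %d of text '%s'",
                   word_index[k], sentence_index[k], stimulus$text_id))
    }
    s[word_index[k]]
  }, character(1))
}

#' Built-in closed-class (function word) lexicon
#'
#' Small English closed-class list used to flag function words when a stimulus
#' file carries no explicit flags, and by the synthetic text generator.
#'
#' @return Character vector of lower-case function words.
#' @export
function_word_lexicon <- function() {
  c("the", "of", "and", "a", "to", "in", "is", "it", "on", "for",
    "with", "as", "at", "by", "from", "that", "this", "be", "are", "or",
    "an", "was", "can", "will", "its", "their", "they", "we", "but", "if")
}

#' Read a text stimulus from disk
#'
#' Two plain-text formats are supported. A `.json` file must contain fields
#' `text_id`, `sentences` (array of token arrays) and optionally
#' `function_words` (parallel boolean arrays). Any other extension is read as
#' one sentence per line, tokenized on whitespace, with function words flagged
#' against `lexicon` applied to canonicalized tokens.
#'
#' @param path File path.
#' @param text_id Identifier used for the plain-text format (default: file
#'   name without extension).
#' @param lexicon Function-word list for the plain-text format; `NULL` leaves
#'   flags unset.
#' @return A [text_stimulus()].
#' @export
read_text_stimulus <- function(path, text_id = NULL,
                               lexicon = function_word_lexicon()) {
  if (!file.exists(path)) stop("stimulus file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    sentences <- lapply(obj$sentences, function(s) unlist(s, use.names = FALSE))
    flags <- NULL
    if (!is.null(obj$function_words)) {
      flags <- lapply(obj$function_words, function(s) as.logical(unlist(s)))
    }
    return(text_stimulus(sentences, text_id = obj$text_id %||% "text1",
                         function_flags = flags))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("stimulus file is empty: ", path)
  sentences <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  flags <- NULL
  if (!is.null(lexicon)) {
    flags <- lapply(sentences, function(s) canonicalize_token(s) %in% lexicon)
  }
  if (is.null(text_id)) text_id <- sub("\\.[^.]*$", "", basename(path))
  text_stimulus(sentences, text_id = text_id, function_flags = flags)
}

#' Write a text stimulus to a JSON file
#'
#' @param stimulus A [text_stimulus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_text_stimulus <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "text_stimulus"))
  obj <- list(text_id = stimulus$text_id, sentences = stimulus$sentences)
  if (!is.null(stimulus$function_flags)) obj$function_words <- stimulus$function_flags
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
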