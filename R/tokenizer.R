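# ---------------------------------------------------------------------------
# Tokenizer: lowercased whitespace+punctuation splitting for the English
# dialect, character-level for Chinese. Ids are dense from 0 with reserved
# specials pad=0, unk=1, cls=2.
# ---------------------------------------------------------------------------

#' Split text into tokens
#'
#' @param text Character vector.
#' @param dialect `"english"` (lowercase, split on any non-alphanumeric run)
#'   or `"chinese"` (character-level).
#' @return For length-1 input, a character vector of tokens; otherwise a list.
#' @export
tokenize <- function(text, dialect = "english") {
  dialect <- match.arg(dialect, c("english", "chinese"))
  out <- lapply(as.character(text), function(x) {
    if (dialect == "chinese") {
      toks <- strsplit(x, "", fixed = FALSE)[[1]]
      toks[!grepl("^[[:space:]]*$", toks)]
    } else {
      toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
      toks[nzchar(toks)]
    }
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Build a tokenizer over a corpus of texts
#'
#' Vocabulary ids are dense integers starting at 0: `pad = 0`, `unk = 1`,
#' `cls = 2`, then corpus tokens in order of first appearance.
#'
#' @param texts Character vector of training texts.
#' @param dialect See [tokenize()].
#' @return Object of class `"birads_tokenizer"`.
#' @export
build_tokenizer <- function(texts, dialect = "english") {
  toks <- tokenize(texts, dialect)
  if (!is.list(toks)) toks <- list(toks)
  vocab_tokens <- unique(unlist(toks))
  ids <- seq_along(vocab_tokens) + 2L          # after pad/unk/cls
  vocab <- c(pad = 0L, unk = 1L, cls = 2L, setNames(ids, vocab_tokens))
  structure(list(vocab = vocab,
                 specials = c(pad = 0L, unk = 1L, cls = 2L),
                 dialect = dialect),
            class = "birads_tokenizer")
}

#' Encode text to token ids / decode ids back to tokens
#'
#' `encode_text()` maps tokens to their integer ids (0-based; out-of-vocab
#' tokens get the `unk` id). `decode_ids()` maps ids back to token strings;
#' the two are inverse on in-vocabulary text.
#'
#' @param tokenizer A [build_tokenizer()] object.
#' @param text A string (or a ready token vector).
#' @param ids Integer ids.
#' @return Integer vector / character vector.
#' @export
encode_text <- function(tokenizer, text) {
  # a character vector of length > 1 is taken as already tokenized
  toks <- if (length(text) > 1L) as.character(text) else {
    tokenize(text, tokenizer$dialect)
  }
  if (length(toks) == 0L) return(integer(0))
  ids <- tokenizer$vocab[toks]
  ids[is.na(ids)] <- tokenizer$specials[["unk"]]
  as.integer(unname(ids))
}

#' @rdname encode_text
#' @export
decode_ids <- function(tokenizer, ids) {
  rev_vocab <- setNames(names(tokenizer$vocab), tokenizer$vocab)
  unname(rev_vocab[as.character(as.integer(ids))])
}

#' @export
print.birads_tokenizer <- function(x, ...) {
  cat(sprintf("<birads_tokenizer> %d tokens (%s dialect)\n",
              length(x$vocab), x$dialect))
  invisible(x)
}

#' Write / read a vocabulary as a two-column text file
#'
#' @param tokenizer A tokenizer.
#' @param path File path (tab-separated `token<TAB>id`).
#' @export
write_vocab <- function(tokenizer, path) {
  writeLines(sprintf("%s\t%d", names(tokenizer$vocab), tokenizer$vocab), path)
  invisible(path)
}

#' @rdname write_vocab
#' @param dialect Dialect recorded on the reloaded tokenizer.
#' @export
read_vocab <- function(path, dialect = "english") {
  lines <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  vocab <- setNames(vapply(lines, function(l) as.integer(l[[2]]), integer(1)),
                    vapply(lines, `[[`, character(1), 1))
  structure(list(vocab = vocab,
                 specials = c(pad = 0L, unk = 1L, cls = 2L),
                 dialect = dialect),
            class = "birads_tokenizer")
}
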