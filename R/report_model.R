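#' Construct a structured report
#'
#' A structured report maps a subset of the ten template categories (see
#' [category_names()]) to free-string descriptor text. Entries with empty
#' descriptor text are treated as absent and dropped. Entries are stored in
#' canonical category order; `complete` is `TRUE` exactly when all ten
#' categories are present (typically after [complete_mci()]).
#'
#' @param entries Named character vector or named list, names being category
#'   identifiers.
#' @return An object of class `"structured_report"`: a list with elements
#'   `entries` (named character) and `complete` (logical).
#' @export
#' @examples
#' structured_report(c(dce_curve_assessment = "washout enhancement curve"))
structured_report <- function(entries = character(0)) {
  entries <- unlist(entries)
  if (is.null(entries)) entries <- character(0)
  entries <- entries[nzchar(entries)]          # empty descriptor => key absent
  storage.mode(entries) <- "character"
  unknown <- setdiff(names(entries), category_names())
  if (length(unknown) > 0L) {
    stop("unknown category key(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(names(entries))) {
    stop("duplicated category key(s) in structured report")
  }
  entries <- entries[intersect(category_names(), names(entries))]
  structure(
    list(entries = entries, complete = length(entries) == 10L),
    class = "structured_report"
  )
}

#' @export
print.structured_report <- function(x, ...) {
  cat(sprintf("<structured_report> %d/10 categories%s\n",
              length(x$entries), if (x$complete) " (complete)" else ""))
  for (cat_name in names(x$entries)) {
    cat(sprintf("  %-36s %s\n", category_display(cat_name), x$entries[[cat_name]]))
  }
  invisible(x)
}

#' Construct a free-text report
#'
#' @param id Record identifier (coerced to character).
#' @param text Narrative text; must be non-empty.
#' @param personal_history Optional personal-history (PH) clause; when given
#'   it must occur verbatim inside `text`.
#' @return An object of class `"free_text_report"`.
#' @export
free_text_report <- function(id, text, personal_history = NULL) {
  text <- as.character(text)
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("free-text report text must be a non-empty string")
  }
  if (!is.null(personal_history)) {
    personal_history <- as.character(personal_history)
    if (!nzchar(personal_history)) personal_history <- NULL
    else if (!grepl(personal_history, text, fixed = TRUE)) {
      stop("personal_history clause is not a substring of the report text")
    }
  }
  structure(
    list(id = as.character(id), text = text, personal_history = personal_history),
    class = "free_text_report"
  )
}

#' @export
print.free_text_report <- function(x, ...) {
  cat(sprintf("<free_text_report> id=%s%s\n", x$id,
              if (!is.null(x$personal_history)) " [PH]" else ""))
  cat(" ", x$text, "\n")
  invisible(x)
}

#' Binary BI-RADS recommendation label
#'
#' Reports are labelled 0 = "Suggestion for Follow-up" (BI-RADS 1-3) or
#' 1 = "Suggestion for Biopsy" (BI-RADS 4A-6).
#'
#' @param value 0 or 1.
#' @return Integer 0/1 with class `"birads_label"`.
#' @export
birads_label <- function(value) {
  value <- as.integer(value)
  if (length(value) != 1L || is.na(value) || !value %in% c(0L, 1L)) {
    stop("BI-RADS label must be 0 (follow-up) or 1 (biopsy)")
  }
  structure(value, class = "birads_label")
}

#' Complete missing category information (MCI)
#'
#' Fills every template category absent from a structured report with the
#' sentinel descriptor [mci_sentinel()] ("not mentioned"), leaving existing
#' descriptors untouched. The operation is idempotent.
#'
#' @param report A [structured_report()] (or named character vector accepted
#'   by its constructor).
#' @param dialect Sentinel language, `"english"` (default) or `"chinese"`.
#' @return A complete `structured_report` with exactly ten entries.
#' @export
#' @examples
#' complete_mci(structured_report(c(prosthesis = "no implant")))
complete_mci <- function(report, dialect = "english") {
  if (!inherits(report, "structured_report")) report <- structured_report(report)
  entries <- report$entries
  absent <- setdiff(category_names(), names(entries))
  entries[absent] <- mci_sentinel(dialect)
  structured_report(entries)
}

default_noise_patterns <- function() {
  pats <- get0(".noise_patterns", envir = .biradsfusion_cache)
  if (is.null(pats)) {
    pats <- yaml::read_yaml(system.file("extdata", "noise_patterns.yaml",
                                        package = "biradsfusion"))
    assign(".noise_patterns", pats, envir = .biradsfusion_cache)
  }
  pats
}

#' Remove noise from narrative text
#'
#' Applies the configured ordered list of regular-expression substitutions
#' (markup tags and characters, non-printing characters, repeated
#' punctuation, duplicated whitespace) until a fixed point is reached, so the
#' operation is idempotent. Alphanumeric content is preserved.
#'
#' @param text Character vector of narratives (empty strings allowed).
#' @param patterns List of `list(pattern, replacement)` entries; defaults to
#'   the pattern file shipped in `inst/extdata/noise_patterns.yaml`.
#' @return Character vector of cleaned text.
#' @export
#' @examples
#' denoise("mass***  seen;;")   # "mass seen;"
denoise <- function(text, patterns = default_noise_patterns()) {
  vapply(as.character(text), function(x) {
    if (is.na(x)) return(NA_character_)
    repeat {
      prev <- x
      for (p in patterns) x <- gsub(p$pattern, p$replacement, x, perl = TRUE)
      if (identical(x, prev)) break
    }
    x
  }, character(1), USE.NAMES = FALSE)
}

# collapse whitespace/punctuation artefacts left after deleting a clause
repair_whitespace <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub(" +([.,;:!?])", "\\1", x)
  x <- gsub("([.,;:!?])\\1+", "\\1", x)
  trimws(x)
}

#' Remove the personal-history clause from a free-text report
#'
#' The ten-category structured template has no personal-history (PH) slot, so
#' PH clauses (e.g. "post-surgery", "follow-up" phrasings) exist only in the
#' narrative. This operation deletes the clause from the text, repairs the
#' surrounding whitespace, and clears the `personal_history` field. Reports
#' without a PH clause pass through unchanged; a report whose text is nothing
#' but the PH clause is rejected (report text must stay non-empty).
#'
#' @param report A [free_text_report()].
#' @return A `free_text_report` without the PH clause.
#' @export
strip_personal_history <- function(report) {
  stopifnot(inherits(report, "free_text_report"))
  if (is.null(report$personal_history)) return(report)
  stripped <- repair_whitespace(
    sub(report$personal_history, "", report$text, fixed = TRUE)
  )
  if (!nzchar(stripped)) {
    stop("report text is exactly the personal-history clause; ",
         "stripping would leave an empty report")
  }
  free_text_report(report$id, stripped, personal_history = NULL)
}

#' Parse a synthetic-dialect narrative into a structured report
#'
#' A deterministic reference structurer for the synthetic report dialect
#' emitted by [generate_corpus()] (it plays the role an LLM backend would
#' play for real clinical narratives). The narrative is split into
#' sentences; within each sentence every lexicon term found as a substring
#' is routed to its category, longest match first, ties broken by canonical
#' category order. Categories never matched are simply absent from the
#' result — MCI completion is a separate step ([complete_mci()]).
#'
#' @param report A [free_text_report()] (or plain string).
#' @param lexicon A [read_lexicon()] object; defaults to the shipped
#'   stand-in lexicon.
#' @param warn_unmatched Emit a warning for non-empty sentences containing no
#'   lexicon term (default `FALSE`; personal-history clauses legitimately
#'   match nothing).
#' @return A (possibly incomplete) `structured_report`.
#' @export
parse_free_text <- function(report, lexicon = default_lexicon(),
                            warn_unmatched = FALSE) {
  text <- if (inherits(report, "free_text_report")) report$text else as.character(report)
  text <- tolower(denoise(text))
  sentences <- trimws(strsplit(text, "[.!?]+")[[1]])
  sentences <- sentences[nzchar(sentences)]
  entries <- character(0)
  for (sentence in sentences) {
    matched <- FALSE
    for (cat_name in category_names()) {
      terms <- lexicon[[cat_name]]$terms
      hits <- terms[vapply(terms, function(t) {
        grepl(tolower(t), sentence, fixed = TRUE)
      }, logical(1))]
      if (length(hits) == 0L) next
      matched <- TRUE
      best <- hits[[which.max(nchar(hits))]]   # longest-match routing
      if (!cat_name %in% names(entries)) entries[[cat_name]] <- best
    }
    if (!matched && warn_unmatched) {
      warning("sentence with no lexicon term ignored: ", sentence, call. = FALSE)
    }
  }
  structured_report(entries)
}

#' Render a structured report as template text
#'
#' One line per category in canonical order: `"category name: descriptor."`.
#' This is the textual form fed to the structured-stream encoder and used in
#' prompt example blocks.
#'
#' @param report A `structured_report`.
#' @param mci If `TRUE` (default) the report is MCI-completed first so all
#'   ten lines appear; if `FALSE`, only present categories are rendered.
#' @return A single string (lines separated by newlines).
#' @export
render_structured_text <- function(report, mci = TRUE) {
  if (!inherits(report, "structured_report")) report <- structured_report(report)
  if (mci) report <- complete_mci(report)
  paste(sprintf("%s: %s.", category_display(names(report$entries)),
                unname(report$entries)),
        collapse = "\n")
}

#' Parse template text back into a structured report
#'
#' Inverse of [render_structured_text()]: lines of the form
#' `"category name: descriptor."` become entries. Used by the mock LLM
#' backend contract and the JSONL round-trip tests.
#'
#' @param text Rendered template text.
#' @return A `structured_report`.
#' @export
parse_structured_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  entries <- character(0)
  display <- category_display(category_names())
  for (line in lines) {
    parts <- regmatches(line, regexec("^([^:]+):\\s*(.*?)\\.?$", line))[[1]]
    if (length(parts) != 3L) {
      cond <- simpleError(paste0("unparseable structured line: ", line))
      cond$raw <- text
      stop(cond)
    }
    idx <- match(trimws(parts[[2]]), display)
    if (is.na(idx)) {
      cond <- simpleError(paste0("unknown category in structured text: ", parts[[2]]))
      cond$raw <- text
      stop(cond)
    }
    entries[[category_names()[idx]]] <- trimws(parts[[3]])
  }
  structured_report(entries)
}

#' Read and write report corpora as JSONL
#'
#' One JSON object per line with fields `id`, `text`, `personal_history`
#' (null when absent), `structured` (object keyed by present category
#' identifiers, in canonical order; null when no structured half exists) and
#' `label` (0/1 or null). The reader and writer are loss-free inverses.
#'
#' @param records A list of records, each a list with elements `free`
#'   ([free_text_report()]), `structured` ([structured_report()] or `NULL`)
#'   and `label` (0/1 or `NULL`); [generate_corpus()] emits this shape.
#' @param path File path.
#' @return `write_reports_jsonl()` returns `path` invisibly;
#'   `read_reports_jsonl()` returns the list of records.
#' @export
write_reports_jsonl <- function(records, path) {
  lines <- vapply(records, function(rec) {
    obj <- list(
      id = rec$free$id,
      text = rec$free$text,
      personal_history = rec$free$personal_history,
      structured = if (!is.null(rec$structured)) as.list(rec$structured$entries),
      label = if (!is.null(rec$label)) as.integer(rec$label)
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_reports_jsonl
#' @export
read_reports_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lapply(lines, function(line) {
    obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    list(
      free = free_text_report(obj$id, obj$text,
                              personal_history = obj$personal_history),
      structured = if (!is.null(obj$structured)) {
        structured_report(unlist(obj$structured))
      },
      label = if (!is.null(obj$label)) as.integer(obj$label)
    )
  })
}
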