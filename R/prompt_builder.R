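# ---------------------------------------------------------------------------
# Knowledge-driven prompt assembly: system description + instruction (task,
# ten-category template with or without lexicon definitions, K worked
# examples) + input. The wording lives in an editable template file; an
# optional LLM backend contract is defined with a shipped mock backend.
# ---------------------------------------------------------------------------

prompt_section_markers <- function() {
  list(task = "### Task", template = "### Template",
       examples = "### Examples", input_marker = "### Input")
}

default_prompt_template_path <- function() {
  system.file("extdata", "prompt_template.txt", package = "biradsfusion")
}

#' Split an instruction string at its section markers
#'
#' Returns the instruction text before the template section, the template
#' section itself, and everything after it (the example blocks, if any).
#' Useful for verifying that prompt variants differ only inside the template
#' section.
#'
#' @param instruction The `instruction` string of a [build_prompt()] bundle.
#' @return List with `before`, `template`, `after` strings.
#' @export
instruction_sections <- function(instruction) {
  m <- prompt_section_markers()
  start <- regexpr(m$template, instruction, fixed = TRUE)
  endm <- regexpr(m$examples, instruction, fixed = TRUE)
  end <- if (endm > 0) endm - 1L else nchar(instruction)
  list(
    before = substr(instruction, 1L, start - 1L),
    template = substr(instruction, start, end),
    after = substr(instruction, end + 1L, nchar(instruction))
  )
}

#' Assemble a structuring prompt
#'
#' Builds the three-part prompt (system description, instruction, input).
#' The instruction holds a task description, the ten-category structured
#' template — with one lexicon definition line per category for the
#' `knowledge_driven` variant, bare category names for `default` — and `k`
#' worked example/response pairs. Assembly is deterministic; the two
#' variants differ only inside the template section.
#'
#' @param variant `"knowledge_driven"` or `"default"`.
#' @param examples List of `list(free =, structured =)` pairs
#'   ([free_text_report()] / [structured_report()]); every structured half
#'   must be MCI-complete.
#' @param input_report The [free_text_report()] to be structured.
#' @param lexicon A lexicon ([read_lexicon()]).
#' @return Object of class `"prompt_bundle"`: list with non-empty `system`,
#'   `instruction`, `input` strings and `k`.
#' @export
build_prompt <- function(variant = c("knowledge_driven", "default"),
                         examples = list(), input_report,
                         lexicon = default_lexicon()) {
  variant <- match.arg(variant)
  stopifnot(inherits(input_report, "free_text_report"))
  for (ex in examples) {
    if (!inherits(ex$structured, "structured_report") ||
        !isTRUE(ex$structured$complete)) {
      stop("every example's structured half must be MCI-complete ",
           "(run complete_mci first)")
    }
  }
  m <- prompt_section_markers()
  template_lines <- if (variant == "knowledge_driven") {
    vapply(names(lexicon), function(cat_name) {
      sprintf("- %s: %s", category_display(cat_name),
              lexicon[[cat_name]]$definition)
    }, character(1))
  } else {
    sprintf("- %s", category_display(names(lexicon)))
  }
  example_blocks <- vapply(seq_along(examples), function(i) {
    paste0("Example ", i, ":\nReport: ", examples[[i]]$free$text,
           "\nResponse:\n", render_structured_text(examples[[i]]$structured))
  }, character(1))
  instruction <- paste(c(
    m$task,
    paste("Extract the content of the radiological description into the",
          "ten-category structured report template below. Assign every",
          "category; write \"not mentioned\" for categories the description",
          "does not cover."),
    m$template, template_lines,
    if (length(example_blocks) > 0) c(m$examples, example_blocks)
  ), collapse = "\n")
  system_text <- paste(
    "You are an experienced breast radiologist structuring breast MRI",
    "reports into a fixed ten-category template.")
  structure(list(system = system_text, instruction = instruction,
                 input = input_report$text, k = length(examples)),
            class = "prompt_bundle")
}

#' @export
print.prompt_bundle <- function(x, ...) {
  cat(sprintf("<prompt_bundle> k=%d examples, %d instruction characters\n",
              x$k, nchar(x$instruction)))
  invisible(x)
}

#' Render a prompt bundle through the prompt-template file
#'
#' Substitutes the instruction into `{ExpertInstruction}` and the input into
#' `{InputData}` of the editable template file; `{OutputImpression}` marks
#' the generation slot and is left for the backend.
#'
#' @param bundle A [build_prompt()] result.
#' @param template_path Path to a template file with the named placeholders.
#' @return A single prompt string.
#' @export
render_prompt <- function(bundle, template_path = default_prompt_template_path()) {
  tpl <- paste(readLines(template_path, warn = FALSE), collapse = "\n")
  tpl <- sub("{ExpertInstruction}", bundle$instruction, tpl, fixed = TRUE)
  sub("{InputData}", bundle$input, tpl, fixed = TRUE)
}

#' Sample worked examples for few-shot prompts
#'
#' Seeded uniform sampling without replacement of `k` distinct pairs.
#'
#' @param pool List of `list(free, structured)` pairs.
#' @param k Number of examples, `0 <= k <= length(pool)`; the reference
#'   setting is `k = 5`, with `0..7` covering the example-count ablation
#'   axis.
#' @param seed RNG seed.
#' @return List of `k` pairs.
#' @export
select_examples <- function(pool, k = 5, seed = 1) {
  k <- as.integer(k)
  if (k < 0L || k > length(pool)) {
    stop("k must satisfy 0 <= k <= pool size (", length(pool), ")")
  }
  if (k == 0L) return(list())
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  pool[sample.int(length(pool), k)]
}

# -- LLM backend contract ----------------------------------------------------

#' Register or query the report-structuring backend
#'
#' The package defines the contract of an LLM structuring backend — a
#' function taking a [build_prompt()] bundle and returning the raw response
#' string — but ships no network client. [mock_llm_backend()] builds a
#' deterministic reference backend for the synthetic dialect from
#' [parse_free_text()] + [complete_mci()].
#'
#' @param backend A function `function(bundle) -> character(1)`, or `NULL` to
#'   clear.
#' @export
register_llm_backend <- function(backend) {
  if (!is.null(backend)) stopifnot(is.function(backend))
  assign(".llm_backend", backend, envir = .biradsfusion_cache)
  invisible(backend)
}

#' @rdname register_llm_backend
#' @param lexicon Lexicon the mock backend parses with.
#' @export
mock_llm_backend <- function(lexicon = default_lexicon()) {
  function(bundle) {
    structured <- complete_mci(parse_free_text(denoise(bundle$input), lexicon))
    render_structured_text(structured)
  }
}

#' Structure a report through the registered backend
#'
#' Sends the prompt to the registered backend and parses the raw response
#' (after [denoise()]) into a [structured_report()]. An unparseable
#' response raises a condition of class `"llm_parse_error"` carrying the raw
#' text in its `raw` field for audit.
#'
#' @param bundle A [build_prompt()] bundle.
#' @return List with `structured` (the parsed report) and `raw` (the raw
#'   response string).
#' @export
llm_structure <- function(bundle) {
  backend <- get0(".llm_backend", envir = .biradsfusion_cache)
  if (is.null(backend)) {
    stop("no backend registered; call register_llm_backend() first")
  }
  raw <- backend(bundle)
  structured <- tryCatch(
    parse_structured_text(denoise(raw)),
    error = function(e) {
      cond <- structure(
        class = c("llm_parse_error", "error", "condition"),
        list(message = paste0("backend response is not parseable: ",
                              conditionMessage(e)),
             call = sys.call(-1), raw = raw))
      stop(cond)
    })
  list(structured = structured, raw = raw)
}

#' Count prompt tokens with the package tokenizer
#'
#' @param bundle A prompt bundle.
#' @param tokenizer A [build_tokenizer()] tokenizer (any vocabulary works;
#'   out-of-vocab tokens map to `unk`).
#' @return Integer token count over system + instruction + input.
#' @export
prompt_token_length <- function(bundle, tokenizer) {
  sum(vapply(c(bundle$system, bundle$instruction, bundle$input),
             function(x) length(encode_text(tokenizer, x)), integer(1)))
}
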