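test_that("complete_mci fills missing categories with the sentinel and is idempotent", {
  nine <- setNames(paste("desc", 1:9), category_names()[1:9])
  out <- complete_mci(structured_report(nine))
  expect_true(out$complete)
  expect_length(out$entries, 10L)
  expect_identical(out$entries[category_names()[1:9]], nine)
  expect_identical(unname(out$entries[["prosthesis"]]), "not mentioned")

  # all ten present: no-op
  full <- complete_mci(structured_report(setNames(paste("d", 1:10),
                                                  category_names())))
  expect_identical(complete_mci(full), full)

  # empty report: all sentinel
  empty <- complete_mci(structured_report())
  expect_true(all(empty$entries == "not mentioned"))

  # idempotence and value preservation over random partial reports
  set.seed(4)
  for (i in 1:20) {
    keep <- sample(category_names(), sample(0:10, 1))
    vals <- if (length(keep)) setNames(paste0("v", seq_along(keep)), keep)
            else character(0)
    rep0 <- structured_report(vals)
    once <- complete_mci(rep0)
    expect_identical(complete_mci(once), once)
    if (length(keep) > 0) {
      expect_identical(once$entries[keep], rep0$entries[keep])
    }
  }
})

test_that("structured reports reject unknown keys and drop empty descriptors", {
  expect_error(structured_report(c(spleen = "x")), "unknown category")
  expect_error(complete_mci(c(prosthesis = "a", bogus = "b")), "bogus")
  rep0 <- structured_report(c(prosthesis = "no implant", skin_lesions = ""))
  expect_identical(names(rep0$entries), "prosthesis")
})

test_that("denoise removes shipped noise patterns, preserves content, idempotent", {
  expect_identical(denoise("mass***  seen;;"), "mass seen;")
  clean <- "An irregular mass with washout enhancement curve."
  expect_identical(denoise(clean), clean)
  expect_identical(denoise(""), "")
  expect_identical(denoise("<b>mass</b>\tseen!!!"), "mass seen!")
  # idempotence over randomly noised strings
  set.seed(11)
  noise <- c("**", "  ", "\t", ";;", "<i>", "~~", "##")
  for (i in 1:25) {
    parts <- sample(c("mass", "washout", "nodes", noise), 8, replace = TRUE)
    x <- paste(parts, collapse = "")
    expect_identical(denoise(denoise(x)), denoise(x))
  }
})

test_that("strip_personal_history removes the clause and repairs whitespace", {
  ph <- "Personal history: post-surgery follow-up"
  rep0 <- free_text_report("a", paste0("The study shows an irregular mass. ",
                                       ph, "."), personal_history = ph)
  out <- strip_personal_history(rep0)
  expect_false(grepl("post-surgery", out$text, fixed = TRUE))
  expect_null(out$personal_history)
  expect_identical(out$text, "The study shows an irregular mass.")
  expect_identical(strip_personal_history(out), out)     # idempotent

  no_ph <- free_text_report("b", "Noted: skin thickening.")
  expect_identical(strip_personal_history(no_ph), no_ph)

  only_ph <- free_text_report("c", ph, personal_history = ph)
  expect_error(strip_personal_history(only_ph), "empty")
})

test_that("free-text reports enforce non-empty text and PH substring", {
  expect_error(free_text_report("x", ""), "non-empty")
  expect_error(free_text_report("x", "some text", personal_history = "absent"),
               "substring")
  expect_error(birads_label(2), "0 .*or 1")
})

test_that("parse_free_text routes lexicon terms to their categories", {
  rec <- free_text_report("r", "Imaging demonstrates washout enhancement curve.")
  parsed <- parse_free_text(rec)
  expect_identical(unname(parsed$entries[["dce_curve_assessment"]]),
                   "washout enhancement curve")

  expect_length(parse_free_text("Nothing relevant here at all.")$entries, 0L)

  # one term per category concatenated -> 10-key report
  lex <- default_lexicon()
  picks <- vapply(lex, function(e) e$terms[[1]], character(1))
  text <- paste0(paste("The study shows", picks, collapse = ". "), ".")
  full <- parse_free_text(text)
  expect_length(full$entries, 10L)
  expect_identical(unname(full$entries), unname(picks))

  # longest-match routing: "irregular mass" wins over "round mass" absent
  p <- parse_free_text("There is irregular mass on the current examination.")
  expect_identical(unname(p$entries[["mass_non_mass"]]), "irregular mass")
})

test_that("parse -> complete_mci round-trips generator ground truth", {
  corpus <- small_corpus(n = 120, seed = 33)
  for (i in seq_along(corpus$records)) {
    truth <- corpus$truth[[i]]
    expected <- complete_mci(
      structured_report(truth$latent[truth$text_present]))
    got <- complete_mci(parse_free_text(corpus$records[[i]]$free))
    expect_identical(got$entries, expected$entries)
  }
})

test_that("JSONL reader and writer are loss-free inverses", {
  corpus <- small_corpus(n = 25, seed = 7)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_reports_jsonl(corpus$records, path)
  back <- read_reports_jsonl(path)
  strip <- function(r) list(r$free$id, r$free$text, r$free$personal_history,
                            if (!is.null(r$structured)) r$structured$entries,
                            as.integer(r$label))
  expect_identical(lapply(back, strip), lapply(corpus$records, strip))
  # byte-identical on rewrite
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_reports_jsonl(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("structured-text rendering parses back exactly", {
  corpus <- small_corpus(n = 15, seed = 9)
  for (r in corpus$records) {
    full <- complete_mci(r$structured)
    expect_identical(parse_structured_text(render_structured_text(full))$entries,
                     full$entries)
  }
  err <- tryCatch(parse_structured_text("no colon line"), error = identity)
  expect_match(conditionMessage(err), "unparseable")
})

test_that("the lexicon has ten categories with definitions and terms", {
  lex <- default_lexicon()
  expect_identical(names(lex), category_names())
  expect_true(all(vapply(lex, function(e) length(e$terms) > 0, logical(1))))
  expect_true(all(vapply(lex, function(e) nzchar(e$definition), logical(1))))
  expect_error(biradsfusion:::validate_lexicon(unclass(lex)[1:9]),
               "missing categories")
})
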