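embedder_fixture <- function(seed = 1, H = 16) {
  corpus <- small_corpus(n = 40, seed = seed)
  tok <- build_tokenizer(vapply(corpus$records, function(r) r$free$text,
                                character(1)))
  cfg <- encoder_config(H = H, n_heads = 4, L = 1, d_ff = 24,
                        vocab_size = length(tok$vocab))
  set.seed(seed)
  list(embedder = encoder_embedder(tok, cfg, init_encoder(cfg)), tok = tok)
}

test_that("bertscore matches self, orthogonal and oracle cases", {
  fx <- embedder_fixture(seed = 2)
  toks <- tokenize("irregular mass with washout enhancement curve")
  self <- bertscore(toks, toks, fx$embedder)
  expect_equal(self$P, 1, tolerance = 1e-9)
  expect_equal(self$R, 1, tolerance = 1e-9)
  expect_equal(self$F, 1, tolerance = 1e-9)

  # mutually orthogonal embeddings give zero scores
  ortho <- function(tokens) {
    if (identical(tokens, c("a", "b"))) rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
    else rbind(c(0, 0, 1, 0), c(0, 0, 0, 1), c(0, 0, 1, 1) / sqrt(2))
  }
  z <- bertscore(c("a", "b"), c("c", "d", "e"), ortho)
  expect_equal(z$P, 0)
  expect_equal(z$R, 0)
  expect_equal(z$F, 0)

  expect_error(bertscore(character(0), toks, fx$embedder), "empty")
  expect_error(bertscore(toks, "", fx$embedder), "empty")
})

test_that("bertscore equals the exhaustive pairwise-max oracle", {
  fx <- embedder_fixture(seed = 3)
  vocab_words <- c("mass", "washout", "nodes", "skin", "cyst", "edema",
                   "implant", "curve", "plateau", "irregular")
  set.seed(31)
  for (i in 1:60) {
    ref <- sample(vocab_words, sample(1:6, 1), replace = TRUE)
    cand <- sample(vocab_words, sample(1:6, 1), replace = TRUE)
    got <- bertscore(ref, cand, fx$embedder)
    want <- bertscore_oracle(fx$embedder(ref), fx$embedder(cand))
    expect_equal(got$P, want$P, tolerance = 1e-12)
    expect_equal(got$R, want$R, tolerance = 1e-12)
    expect_equal(got$F, want$F, tolerance = 1e-12)
    # duality: P(x, xhat) = R(xhat, x)
    swapped <- bertscore(cand, ref, fx$embedder)
    expect_equal(got$P, swapped$R, tolerance = 1e-12)
    expect_equal(got$R, swapped$P, tolerance = 1e-12)
    # harmonic-mean bracketing
    expect_gte(got$F + 1e-12, min(got$P, got$R))
    expect_lte(got$F - 1e-12, max(got$P, got$R))
  }
})

test_that("category-wise bertscore skips doubly-absent categories", {
  fx <- embedder_fixture(seed = 4)
  ref <- structured_report(c(prosthesis = "no implant",
                             skin_lesions = "skin thickening"))
  cand <- structured_report(c(prosthesis = "no implant"))
  out <- bertscore_structured(ref, cand, fx$embedder)
  expect_null(out$mass_non_mass)               # "not mentioned" on both sides
  expect_equal(out$prosthesis$F, 1, tolerance = 1e-9)
  # skin_lesions: reference text vs sentinel -> scored, below self-match
  expect_false(is.null(out$skin_lesions))
  expect_false(is.na(attr(out, "mean_F")))
})

test_that("classification metrics match hand computation and the AUC oracle", {
  perfect <- classification_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  ties <- classification_metrics(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(ties$auc, 0.5)

  # 6-record hand-built instance vs O(n^2) pairwise oracle
  labels <- c(1, 0, 1, 1, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.4, 0.1)
  m <- classification_metrics(labels, scores)
  expect_equal(m$auc, auc_oracle(labels, scores), tolerance = 1e-12)

  # random instances: rank AUC equals pair enumeration; F1 consistent
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2)           # rounding induces ties
    m <- classification_metrics(labels, scores)
    expect_equal(m$auc, auc_oracle(labels, scores), tolerance = 1e-12)
    for (cls in c("class0", "class1")) {
      pr <- m$per_class[cls, ]
      f1 <- if (pr$precision + pr$recall > 0) {
        2 * pr$precision * pr$recall / (pr$precision + pr$recall)
      } else 0
      expect_equal(pr$f1, f1, tolerance = 1e-12)
    }
  }

  expect_message(single <- classification_metrics(rep(1, 4), runif(4)),
                 "one class")
  expect_true(is.na(single$auc))
})

test_that("classification metrics agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  labels <- rbinom(80, 1, 0.6)
  scores <- runif(80)
  ours <- classification_metrics(labels, scores)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("the ablation harness fills every requested cell with bookkeeping", {
  cells <- data.frame(streams = c("free_text", "structured"),
                      fusion = "concatenation", mci = TRUE,
                      ph = c(TRUE, FALSE), stringsAsFactors = FALSE)
  tbl <- run_ablation(cells, generator_config(n = 120, seed = 1),
                      seeds = c(1, 2),
                      encoder = encoder_config(H = 16, n_heads = 2, L = 1,
                                               d_ff = 24),
                      epochs = 1)
  expect_identical(nrow(tbl), 2L)
  expect_true(all(tbl$n_seeds == 2L))
  expect_false(any(tbl$failed))
  expect_true(all(is.finite(tbl$auc_mean)))
  expect_true(all(tbl$auc_sd >= 0))
  runs <- attr(tbl, "runs")
  expect_length(runs, 2L)
  expect_identical(dim(runs[[1]]), c(2L, 4L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ablation_csv(tbl, path)
  expect_identical(nrow(utils::read.csv(path)), 2L)
})

test_that("failing ablation cells are recorded and the run continues", {
  cells <- data.frame(streams = c("bogus_stream", "free_text"),
                      stringsAsFactors = FALSE)
  tbl <- suppressWarnings(
    run_ablation(cells, generator_config(n = 60, seed = 2), seeds = 1,
                 encoder = encoder_config(H = 8, n_heads = 2, L = 1,
                                          d_ff = 12),
                 epochs = 1))
  expect_true(tbl$failed[1])
  expect_match(tbl$reason[1], ".")
  expect_false(tbl$failed[2])
})
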