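# ---------------------------------------------------------------------------
# Evaluation: BERTScore over contextual token embeddings (greedy maximum
# matching), classification metrics (precision/recall/F1/AUC), and the
# seeded ablation harness.
# ---------------------------------------------------------------------------

l2_normalize_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  M / nrm
}

#' BERTScore between a reference and a candidate token sequence
#'
#' Precision is the mean over candidate tokens of the maximum inner product
#' against the reference tokens; recall the mean over reference tokens of
#' the maximum against the candidate tokens; F is their harmonic mean
#' (defined as 0 when P + R = 0). Matching is greedy with no alignment
#' constraint. Embeddings are L2-normalized before matching, so each inner
#' product is a cosine similarity in `[-1, 1]`. No IDF weighting and no
#' baseline rescaling are applied.
#'
#' @param reference,candidate Non-empty token vectors (or strings, tokenized
#'   by the embedder's tokenizer when `embedder` carries one).
#' @param embedder Function mapping a token vector to an `n x H` embedding
#'   matrix (e.g. [encoder_embedder()]).
#' @return Object of class `"bertscore_result"`: list with `P`, `R`, `F`.
#' @export
bertscore <- function(reference, candidate, embedder) {
  if (length(reference) == 0L || !any(nzchar(reference))) {
    stop("bertscore: reference sequence is empty")
  }
  if (length(candidate) == 0L || !any(nzchar(candidate))) {
    stop("bertscore: candidate sequence is empty")
  }
  E_ref <- l2_normalize_rows(as.matrix(embedder(reference)))
  E_cand <- l2_normalize_rows(as.matrix(embedder(candidate)))
  S <- E_ref %*% t(E_cand)               # similarity: ref rows x cand cols
  P <- mean(apply(S, 2, max))
  R <- mean(apply(S, 1, max))
  F <- if (P + R > 0) 2 * P * R / (P + R) else 0
  structure(list(P = P, R = R, F = F), class = "bertscore_result")
}

#' @export
print.bertscore_result <- function(x, ...) {
  cat(sprintf("BERTScore  P = %.4f  R = %.4f  F = %.4f\n", x$P, x$R, x$F))
  invisible(x)
}

#' Contextual token embedder backed by the package encoder
#'
#' Wraps a tokenizer + encoder weights into the embedder function
#' [bertscore()] expects: tokens are encoded as one sequence and the final
#' hidden states returned, so embeddings are contextual.
#'
#' @param tokenizer A [build_tokenizer()] tokenizer.
#' @param config An [encoder_config()].
#' @param weights Encoder weights ([init_encoder()] or a trained model's).
#' @return Function `function(tokens) -> n x H matrix`.
#' @export
encoder_embedder <- function(tokenizer, config, weights) {
  function(tokens) {
    if (length(tokens) == 1L) tokens <- tokenize(tokens, tokenizer$dialect)
    ids <- encode_text(tokenizer, tokens)
    encode(ids, config, weights)
  }
}

#' Category-wise BERTScore between two structured reports
#'
#' Scores each of the ten categories of the candidate against the reference
#' separately, skipping categories where both sides are the "not mentioned"
#' sentinel.
#'
#' @param reference,candidate [structured_report()]s (MCI-completed first).
#' @param embedder As in [bertscore()].
#' @return Named list of `bertscore_result` (skipped categories are `NULL`),
#'   plus attribute `"mean_F"` over scored categories.
#' @export
bertscore_structured <- function(reference, candidate, embedder) {
  ref <- complete_mci(reference)$entries
  cand <- complete_mci(candidate)$entries
  sentinel <- mci_sentinel()
  out <- lapply(category_names(), function(cat_name) {
    if (ref[[cat_name]] == sentinel && cand[[cat_name]] == sentinel) {
      return(NULL)
    }
    bertscore(tokenize(ref[[cat_name]]), tokenize(cand[[cat_name]]), embedder)
  })
  names(out) <- category_names()
  fs <- vapply(Filter(Negate(is.null), out), `[[`, numeric(1), "F")
  attr(out, "mean_F") <- if (length(fs) > 0) mean(fs) else NA_real_
  out
}

#' Binary classification metrics
#'
#' Precision, recall and F1 at threshold 0.5 (per class, plus the requested
#' averaging; default macro), and AUC computed from the Mann-Whitney rank
#' statistic with mid-rank tie correction.
#'
#' @param labels Binary 0/1 labels.
#' @param scores Class-1 probabilities/scores in `[0, 1]`.
#' @param averaging `"macro"` (default), `"micro"` or `"none"`.
#' @param threshold Decision threshold (default 0.5).
#' @return Object of class `"class_metrics"`: list with `precision`,
#'   `recall`, `f1`, `auc`, `per_class` (data frame) and the averaging mode.
#'   With a single observed class, `auc` is `NA` (undefined).
#' @export
classification_metrics <- function(labels, scores,
                                   averaging = c("macro", "micro", "none"),
                                   threshold = 0.5) {
  averaging <- match.arg(averaging)
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  pred <- as.integer(scores >= threshold)
  prf <- function(cls) {
    tp <- sum(pred == cls & labels == cls)
    fp <- sum(pred == cls & labels != cls)
    fn <- sum(pred != cls & labels == cls)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    c(precision = precision, recall = recall, f1 = f1)
  }
  per_class <- rbind(class0 = prf(0L), class1 = prf(1L))
  if (averaging == "macro") {
    precision <- mean(per_class[, "precision"])
    recall <- mean(per_class[, "recall"])
    f1 <- mean(per_class[, "f1"])
  } else if (averaging == "micro") {
    # binary micro-averaged P/R/F all equal accuracy
    precision <- recall <- f1 <- mean(pred == labels)
  } else {
    precision <- per_class["class1", "precision"]
    recall <- per_class["class1", "recall"]
    f1 <- per_class["class1", "f1"]
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- if (n1 == 0 || n0 == 0) {
    message("AUC undefined: only one class present")
    NA_real_
  } else {
    r <- rank(scores)                    # mid-ranks handle ties
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(precision = precision, recall = recall, f1 = f1, auc = auc,
                 per_class = as.data.frame(per_class), averaging = averaging),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("precision %.4f | recall %.4f | F1 %.4f | AUC %s  (%s)\n",
              x$precision, x$recall, x$f1,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
              x$averaging))
  invisible(x)
}

#' Evaluate a fitted classifier on a corpus
#'
#' @param model A [birads_fit()] model.
#' @param corpus Evaluation corpus.
#' @param averaging Passed to [classification_metrics()].
#' @return A `class_metrics` object.
#' @export
evaluate_fit <- function(model, corpus, averaging = "macro") {
  records <- if (inherits(corpus, "report_corpus")) corpus$records else corpus
  labels <- vapply(records, function(r) as.integer(r$label), integer(1))
  scores <- predict(model, corpus, type = "response")
  classification_metrics(labels, scores, averaging)
}

#' Run a seeded ablation grid
#'
#' For every grid cell (a combination of stream selection, fusion strategy,
#' MCI and PH switches) and every seed: regenerate the corpus with that
#' seed, split it 70/20/10, train the classifier on the training split, and
#' evaluate on the test split. Results are aggregated as mean and sd across
#' seeds; a failing cell is recorded with its error message and the run
#' continues.
#'
#' @param cells Data frame with columns `streams`, `fusion`, `mci`, `ph`
#'   (one row per cell; defaults filled for missing columns).
#' @param gen_config A [generator_config()]; its seed is replaced per run.
#' @param seeds Integer vector of seeds (use >= 3 for stochastic summaries).
#' @param encoder An [encoder_config()].
#' @param lr,epochs,batch_size Training hyperparameters.
#' @param ratios Split ratios.
#' @return Data frame, one row per cell: settings, `n_seeds`, mean/sd of
#'   precision, recall, F1 and AUC, and `failed`/`reason` bookkeeping. The
#'   per-run metric values are attached as attribute `"runs"`.
#' @export
run_ablation <- function(cells, gen_config = generator_config(),
                         seeds = 1:3, encoder = encoder_config(),
                         lr = 0.1, epochs = 6, batch_size = 32,
                         ratios = split_ratios()) {
  defaults <- list(streams = "both", fusion = "concatenation",
                   mci = TRUE, ph = TRUE)
  for (col in names(defaults)) {
    if (is.null(cells[[col]])) cells[[col]] <- defaults[[col]]
  }
  runs <- list()
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    cell <- cells[ci, ]
    vals <- matrix(NA_real_, length(seeds), 4,
                   dimnames = list(NULL, c("precision", "recall", "f1", "auc")))
    failed <- FALSE; reason <- ""
    for (si in seq_along(seeds)) {
      res <- tryCatch({
        cfg <- gen_config
        cfg$seed <- as.integer(seeds[si])
        corpus <- generate_corpus(cfg)
        parts <- split_dataset(corpus, ratios, seed = seeds[si])
        model <- birads_fit(parts$train, streams = cell$streams,
                            fusion = cell$fusion, mci = cell$mci,
                            ph = cell$ph, encoder = encoder, lr = lr,
                            epochs = epochs, batch_size = batch_size,
                            seed = seeds[si])
        m <- evaluate_fit(model, parts$test)
        c(m$precision, m$recall, m$f1, m$auc)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- TRUE
        reason <- conditionMessage(res)
      } else {
        vals[si, ] <- res
      }
    }
    runs[[ci]] <<- vals
    ok <- stats::complete.cases(vals)
    data.frame(
      streams = cell$streams, fusion = cell$fusion, mci = cell$mci,
      ph = cell$ph, n_seeds = sum(ok),
      precision_mean = mean(vals[ok, "precision"]),
      precision_sd = sd(vals[ok, "precision"]),
      recall_mean = mean(vals[ok, "recall"]), recall_sd = sd(vals[ok, "recall"]),
      f1_mean = mean(vals[ok, "f1"]), f1_sd = sd(vals[ok, "f1"]),
      auc_mean = mean(vals[ok, "auc"]), auc_sd = sd(vals[ok, "auc"]),
      failed = failed, reason = reason, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  out
}

#' Write an ablation table to CSV
#'
#' @param table Result of [run_ablation()].
#' @param path Output CSV path.
#' @export
write_ablation_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
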