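# ---------------------------------------------------------------------------
# Dual-stream fusion classifier: free-text and structured report encoders,
# five fusion strategies, softmax head. birads_fit() is the fitting front
# end; the heavy lifting happens in src/fusion_net.cpp.
# ---------------------------------------------------------------------------

#' The five stream-fusion strategies
#'
#' Concatenation (the default), addition, average pooling, max pooling and
#' cross-attention; see [fuse()] for their definitions.
#'
#' @return Character vector of strategy names.
#' @export
fusion_strategies <- function() {
  c("concatenation", "addition", "average_pooling", "max_pooling",
    "cross_attention")
}

fusion_code <- function(strategy, concat_axis) {
  if (strategy == "concatenation") {
    if (concat_axis == "feature") 5L else 0L
  } else {
    c(addition = 1L, average_pooling = 2L, max_pooling = 3L,
      cross_attention = 4L)[[strategy]]
  }
}

stream_code <- function(streams) {
  c(free_text = 0L, structured = 1L, both = 2L)[[streams]]
}

#' Fuse two encoded report streams
#'
#' Reference (pure R) implementation of the five fusion strategies applied to
#' the token-feature matrices of the free-text and structured streams:
#'
#' * `concatenation` (default, "ours"): token features of both streams are
#'   stacked along the sequence axis and then pooled (output width `H`); with
#'   `concat_axis = "feature"` each stream is pooled first and the two pooled
#'   vectors concatenated (width `2H`).
#' * `addition` / `average_pooling` / `max_pooling`: each stream is pooled,
#'   then combined elementwise (sum, mean, max); width `H`.
#' * `cross_attention`: scaled dot-product attention with the free-text
#'   features as queries and the structured features as keys and values,
#'   then pooled; width `H`.
#'
#' @param F_free,F_struct Feature matrices (`n1 x H`, `n2 x H`).
#' @param strategy One of [fusion_strategies()].
#' @param pool Sequence-pooling operator, `"mean"` (default) or `"max"`.
#' @param concat_axis `"sequence"` (default) or `"feature"`; only used by the
#'   concatenation strategy.
#' @return Fused numeric vector.
#' @export
fuse <- function(F_free, F_struct,
                 strategy = fusion_strategies(), pool = c("mean", "max"),
                 concat_axis = c("sequence", "feature")) {
  strategy <- match.arg(strategy)
  pool <- match.arg(pool)
  concat_axis <- match.arg(concat_axis)
  F_free <- as.matrix(F_free); F_struct <- as.matrix(F_struct)
  if (ncol(F_free) != ncol(F_struct)) {
    stop("fuse: streams have widths ", ncol(F_free), " and ", ncol(F_struct),
         "; they must share H")
  }
  pool_fn <- if (pool == "max") {
    function(X) apply(X, 2, max)
  } else {
    function(X) colMeans(X)
  }
  switch(strategy,
    concatenation = if (concat_axis == "feature") {
      c(pool_fn(F_free), pool_fn(F_struct))
    } else {
      pool_fn(rbind(F_free, F_struct))
    },
    addition = pool_fn(F_free) + pool_fn(F_struct),
    average_pooling = (pool_fn(F_free) + pool_fn(F_struct)) / 2,
    max_pooling = pmax(pool_fn(F_free), pool_fn(F_struct)),
    cross_attention = pool_fn(attention(F_free, F_struct, F_struct))
  )
}

#' Softmax classification head
#'
#' `softmax(W_fc %*% fused + b_fc)`; class 1 is "Suggestion for Biopsy".
#'
#' @param fused Fused feature vector.
#' @param head List with `W_fc` (`2 x F`) and `b_fc` (length 2).
#' @return Named probability pair `c(follow_up =, biopsy =)` summing to 1.
#' @export
classify <- function(fused, head) {
  if (length(fused) != ncol(head$W_fc)) {
    stop("classify: fused width ", length(fused), " but W_fc expects ",
         ncol(head$W_fc))
  }
  z <- drop(head$W_fc %*% fused + head$b_fc)
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  setNames(p, c("follow_up", "biopsy"))
}

# -- corpus -> token sequences ----------------------------------------------

# prepare per-record stream texts under the MCI / PH switches
prepare_stream_texts <- function(records, use_ph = TRUE, use_mci = TRUE) {
  free <- vapply(records, function(r) {
    ft <- r$free
    if (!use_ph && !is.null(ft$personal_history)) ft <- strip_personal_history(ft)
    denoise(ft$text)
  }, character(1))
  structured <- vapply(records, function(r) {
    if (is.null(r$structured)) return("")
    render_structured_text(r$structured, mci = use_mci)
  }, character(1))
  list(free = free, structured = structured)
}

# token-id sequences: cls-prefixed, truncated to max_len
texts_to_ids <- function(texts, tokenizer, max_len) {
  lapply(texts, function(x) {
    ids <- c(tokenizer$specials[["cls"]], encode_text(tokenizer, x))
    head(ids, max_len)
  })
}

#' Fit the dual-stream BI-RADS report classifier
#'
#' Encodes the free-text and/or structured stream of every record with its
#' own from-scratch transformer encoder (attention projections carry frozen
#' base weights plus trainable LoRA adapters), fuses the streams with the
#' chosen strategy, and trains encoder + head end-to-end by mini-batch
#' gradient descent on the cross-entropy of the binary biopsy/follow-up
#' label. Training is deterministic given `seed`.
#'
#' @param corpus A `report_corpus` (or list of records with `free`,
#'   `structured`, `label`).
#' @param streams `"both"` (default), `"free_text"` or `"structured"`.
#' @param fusion One of [fusion_strategies()] (default `"concatenation"`).
#' @param mci Apply MCI completion to the structured stream (default `TRUE`).
#' @param ph Keep personal-history clauses in the free-text stream (default
#'   `TRUE`).
#' @param encoder An [encoder_config()]; its `vocab_size` is replaced by the
#'   tokenizer's vocabulary size.
#' @param pool `"mean"` or `"max"` sequence pooling.
#' @param concat_axis `"sequence"` or `"feature"` (concatenation strategy
#'   only).
#' @param lr Learning rate of plain mini-batch gradient descent.
#' @param epochs Training epochs (0 returns the untrained model).
#' @param batch_size Mini-batch size.
#' @param clip Global-norm clip applied to the mean mini-batch gradient
#'   (default 1; set 0 to disable). A numerical stabilizer only.
#' @param momentum Classical momentum coefficient of the gradient-descent
#'   update (default 0.9; 0 gives plain gradient descent).
#' @param seed Seed for initialization and batch shuffling.
#' @param val Optional validation corpus; per-epoch loss/accuracy recorded.
#' @return Object of class `"birads_fit"` with `print`, `summary`, `coef`,
#'   `predict`, `plot` and `residuals` methods.
#' @export
birads_fit <- function(corpus, streams = c("both", "free_text", "structured"),
                       fusion = fusion_strategies(), mci = TRUE, ph = TRUE,
                       encoder = encoder_config(), pool = c("mean", "max"),
                       concat_axis = c("sequence", "feature"),
                       lr = 0.2, epochs = 8, batch_size = 32, clip = 1,
                       momentum = 0.9, seed = 1, val = NULL) {
  streams <- match.arg(streams)
  fusion <- match.arg(fusion)
  pool <- match.arg(pool)
  concat_axis <- match.arg(concat_axis)
  records <- if (inherits(corpus, "report_corpus")) corpus$records else corpus
  if (length(records) == 0L) stop("cannot fit on an empty corpus")
  labels <- vapply(records, function(r) as.integer(r$label), integer(1))
  if (length(unique(labels)) < 2L) {
    stop("corpus contains a single class; cannot fit a binary classifier")
  }
  if (lr < 0 || epochs < 0 || batch_size < 1) {
    stop("hyperparameters must be non-negative (batch_size >= 1)")
  }
  if (streams != "free_text" && any(vapply(records, function(r)
        is.null(r$structured), logical(1)))) {
    stop("structured stream requested but records lack structured reports")
  }

  texts <- prepare_stream_texts(records, use_ph = ph, use_mci = mci)
  fit_texts <- switch(streams, both = c(texts$free, texts$structured),
                      free_text = texts$free, structured = texts$structured)
  tokenizer <- build_tokenizer(fit_texts)
  encoder$vocab_size <- length(tokenizer$vocab)

  use_free <- streams != "structured"
  use_struct <- streams != "free_text"
  ids_free <- if (use_free) texts_to_ids(texts$free, tokenizer, encoder$max_len)
  ids_struct <- if (use_struct) texts_to_ids(texts$structured, tokenizer,
                                             encoder$max_len)

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  fused_width <- if (streams == "both" && fusion == "concatenation" &&
                     concat_axis == "feature") 2L * encoder$H else encoder$H
  params <- list(
    free = if (use_free) init_encoder(encoder),
    struct = if (use_struct) init_encoder(encoder),
    W_fc = matrix(rnorm(2 * fused_width, sd = 0.02), 2, fused_width),
    b_fc = rep(0, 2)
  )
  n <- length(records)
  opts <- list(H = encoder$H, n_heads = encoder$n_heads,
               streams = stream_code(streams),
               fusion = fusion_code(fusion, concat_axis),
               pool = if (pool == "max") 1L else 0L)
  pe <- if (encoder$pos_encoding) {
    encoder$pe_scale * positional_encoding(encoder$max_len, encoder$H)
  } else {
    matrix(0, encoder$max_len, encoder$H)
  }

  val_ids_free <- val_ids_struct <- list()
  val_labels <- integer(0)
  if (!is.null(val)) {
    val_records <- if (inherits(val, "report_corpus")) val$records else val
    val_texts <- prepare_stream_texts(val_records, use_ph = ph, use_mci = mci)
    if (use_free) val_ids_free <- texts_to_ids(val_texts$free, tokenizer,
                                               encoder$max_len)
    if (use_struct) val_ids_struct <- texts_to_ids(val_texts$structured,
                                                   tokenizer, encoder$max_len)
    val_labels <- vapply(val_records, function(r) as.integer(r$label),
                         integer(1))
  }

  # the C++ core returns vectors as n x 1 matrices; restore plain vectors so
  # trained and untrained parameter lists share one layout
  normalize_params <- function(p) {
    fix_enc <- function(enc) {
      if (is.null(enc)) return(NULL)
      enc$layers <- lapply(enc$layers, function(l) {
        for (nm in c("g1", "b1", "g2", "b2", "bf1", "bf2")) {
          l[[nm]] <- as.numeric(l[[nm]])
        }
        l
      })
      enc
    }
    p$free <- fix_enc(p$free)
    p$struct <- fix_enc(p$struct)
    p$b_fc <- as.numeric(p$b_fc)
    p[!vapply(p, is.null, logical(1))]
  }

  if (epochs > 0) {
    perms <- vapply(seq_len(epochs), function(e) sample.int(n), integer(n))
    fit <- cpp_fit(if (use_free) ids_free else list(),
                   if (use_struct) ids_struct else list(),
                   labels, params, opts, perms, pe, lr, as.integer(batch_size),
                   clip, momentum, val_ids_free, val_ids_struct, val_labels)
    params <- normalize_params(fit$params)
    loss_history <- fit$train_loss
    val_history <- if (length(val_labels) > 0) {
      data.frame(epoch = seq_len(epochs), loss = fit$val_loss,
                 accuracy = fit$val_acc)
    }
  } else {
    params <- normalize_params(params)
    loss_history <- numeric(0)
    val_history <- NULL
  }

  structure(list(
    params = params, opts = opts, encoder = encoder, tokenizer = tokenizer,
    streams = streams, fusion = fusion, pool = pool,
    concat_axis = concat_axis, mci = mci, ph = ph,
    lr = lr, epochs = epochs, batch_size = batch_size, clip = clip,
    momentum = momentum, seed = seed,
    loss_history = loss_history, val_history = val_history,
    train_labels = labels, pe = pe,
    train_ids_free = ids_free, train_ids_struct = ids_struct,
    trained = epochs > 0, call = match.call()
  ), class = "birads_fit")
}

#' Named training presets
#'
#' The two fine-tuning schedules used as reference settings (initial learning
#' rates 3e-4 and 1e-6 over 5 and 10 epochs); shipped as presets, not
#' defaults.
#'
#' @return Named list of `list(lr, epochs)` presets.
#' @export
fit_presets <- function() {
  list(lora_stage = list(lr = 3e-4, epochs = 5),
       refine_stage = list(lr = 1e-6, epochs = 10))
}

fit_record_ids <- function(object, records) {
  texts <- prepare_stream_texts(records, use_ph = object$ph,
                                use_mci = object$mci)
  list(
    free = if (object$streams != "structured") {
      texts_to_ids(texts$free, object$tokenizer, object$encoder$max_len)
    } else list(),
    struct = if (object$streams != "free_text") {
      texts_to_ids(texts$structured, object$tokenizer, object$encoder$max_len)
    } else list()
  )
}

#' Predict biopsy probabilities from a fitted classifier
#'
#' @param object A [birads_fit()] model.
#' @param newdata A `report_corpus` or list of records; defaults to the
#'   training data.
#' @param type `"prob"` for the `n x 2` probability matrix,
#'   `"response"` for the biopsy-class probability, `"class"` for 0/1 labels.
#' @param ... Unused.
#' @export
predict.birads_fit <- function(object, newdata = NULL,
                               type = c("prob", "response", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    ids <- list(free = if (is.null(object$train_ids_free)) list() else
                  object$train_ids_free,
                struct = if (is.null(object$train_ids_struct)) list() else
                  object$train_ids_struct)
  } else {
    records <- if (inherits(newdata, "report_corpus")) newdata$records else newdata
    ids <- fit_record_ids(object, records)
  }
  probs <- cpp_predict(ids$free, ids$struct, object$params, object$opts,
                       object$pe)
  colnames(probs) <- c("follow_up", "biopsy")
  switch(type,
         prob = probs,
         response = probs[, "biopsy"],
         class = as.integer(probs[, "biopsy"] >= 0.5))
}

#' @export
print.birads_fit <- function(x, ...) {
  cat("BI-RADS dual-stream fusion classifier\n")
  cat(sprintf("  streams: %s | fusion: %s (%s axis, %s pool)\n",
              x$streams, x$fusion, x$concat_axis, x$pool))
  cat(sprintf("  MCI: %s | PH: %s | encoder H=%d heads=%d L=%d lora_r=%d\n",
              x$mci, x$ph, x$encoder$H, x$encoder$n_heads, x$encoder$L,
              x$encoder$lora_rank))
  if (x$trained) {
    cat(sprintf("  trained %d epochs (lr=%g); final loss %.4f\n",
                x$epochs, x$lr, tail(x$loss_history, 1)))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @export
summary.birads_fit <- function(object, ...) {
  p1 <- predict(object, type = "response")
  acc <- mean((p1 >= 0.5) == (object$train_labels == 1))
  out <- list(model = object, train_accuracy = acc,
              loss_history = object$loss_history,
              val_history = object$val_history,
              n = length(object$train_labels))
  class(out) <- "summary.birads_fit"
  out
}

#' @export
print.summary.birads_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  n = %d training records; training accuracy %.3f\n",
              x$n, x$train_accuracy))
  if (!is.null(x$val_history)) {
    last <- x$val_history[nrow(x$val_history), ]
    cat(sprintf("  validation: loss %.4f, accuracy %.3f (epoch %d)\n",
                last$loss, last$accuracy, last$epoch))
  }
  invisible(x)
}

#' @export
coef.birads_fit <- function(object, ...) {
  list(W_fc = object$params$W_fc, b_fc = object$params$b_fc)
}

#' @export
plot.birads_fit <- function(x, ...) {
  if (!x$trained) stop("nothing to plot: model is untrained")
  plot(seq_along(x$loss_history), x$loss_history, type = "b",
       xlab = "epoch", ylab = "training cross-entropy",
       main = "birads_fit loss history", ...)
  if (!is.null(x$val_history)) {
    graphics::lines(x$val_history$epoch, x$val_history$loss, lty = 2)
    graphics::legend("topright", legend = c("train", "validation"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' @export
residuals.birads_fit <- function(object, ...) {
  object$train_labels - predict(object, type = "response")
}

#' Per-token attention importance for a fitted model
#'
#' For each active stream, runs the encoder on the record and reports the
#' attention mass each token receives in the final layer (averaged over
#' queries and heads), normalized to sum to 1 per stream — the quantity
#' rendered as token heat in attention visualizations. The leading `cls`
#' anchor token is included.
#'
#' @param model A [birads_fit()] object.
#' @param record A single record (`list(free, structured, ...)`).
#' @return Named list with one `data.frame(token, weight)` per active stream.
#' @export
attention_weight_map <- function(model, record) {
  stopifnot(inherits(model, "birads_fit"))
  if (!model$trained) {
    warning("model is untrained; attention weights reflect initialization")
  }
  ids <- fit_record_ids(model, list(record))
  cfg <- model$encoder
  out <- list()
  one_stream <- function(id_seq, enc_params) {
    X <- encode(id_seq, cfg, enc_params, return_attention = TRUE)
    attn <- attr(X, "attention")
    if (length(attn) == 0L) {            # L = 0: uniform by construction
      w <- rep(1 / length(id_seq), length(id_seq))
    } else {
      final <- attn[[length(attn)]]
      head_mean <- Reduce(`+`, final) / length(final)
      w <- colMeans(head_mean)
      w <- w / sum(w)
    }
    data.frame(token = decode_ids(model$tokenizer, id_seq), weight = w,
               stringsAsFactors = FALSE)
  }
  if (model$streams != "structured") {
    out$free <- one_stream(ids$free[[1]], model$params$free)
  }
  if (model$streams != "free_text") {
    out$structured <- one_stream(ids$struct[[1]], model$params$struct)
  }
  out
}

#' Export attention maps as JSON
#'
#' @param maps Output of [attention_weight_map()].
#' @param path Output file.
#' @export
write_attention_map <- function(maps, path) {
  jsonlite::write_json(maps, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
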