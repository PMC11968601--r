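# shared tiny fixtures, built in code at test time

tiny_encoder <- function(H = 8, n_heads = 2, L = 1, vocab = 16, seed = 1,
                         d_ff = 12, max_len = 24, lora_rank = 2, ...) {
  cfg <- encoder_config(H = H, n_heads = n_heads, L = L, d_ff = d_ff,
                        max_len = max_len, vocab_size = vocab,
                        lora_rank = lora_rank, ...)
  set.seed(seed)
  list(config = cfg, weights = init_encoder(cfg))
}

small_corpus <- function(n = 60, seed = 1, ...) {
  generate_corpus(generator_config(n = n, seed = seed, ...))
}

example_pool <- function(corpus, k = 9) {
  lapply(corpus$records[seq_len(k)], function(r) {
    list(free = r$free, structured = complete_mci(r$structured))
  })
}

# non-vectorized scaled dot-product attention oracle (scalar loops)
attention_oracle <- function(Q, K, V) {
  n_q <- nrow(Q); n_k <- nrow(K); d_k <- ncol(Q)
  out <- matrix(0, n_q, ncol(V))
  for (i in seq_len(n_q)) {
    logits <- numeric(n_k)
    for (j in seq_len(n_k)) {
      logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    }
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (j in seq_len(n_k)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# exhaustive pairwise-max BERTScore oracle over L2-normalized embeddings
bertscore_oracle <- function(E_ref, E_cand) {
  norm1 <- function(v) { n <- sqrt(sum(v^2)); if (n == 0) v else v / n }
  E_ref <- t(apply(E_ref, 1, norm1))
  E_cand <- t(apply(E_cand, 1, norm1))
  best_for_cand <- numeric(nrow(E_cand))
  for (j in seq_len(nrow(E_cand))) {
    sims <- numeric(nrow(E_ref))
    for (i in seq_len(nrow(E_ref))) sims[i] <- sum(E_ref[i, ] * E_cand[j, ])
    best_for_cand[j] <- max(sims)
  }
  best_for_ref <- numeric(nrow(E_ref))
  for (i in seq_len(nrow(E_ref))) {
    sims <- numeric(nrow(E_cand))
    for (j in seq_len(nrow(E_cand))) sims[j] <- sum(E_ref[i, ] * E_cand[j, ])
    best_for_ref[i] <- max(sims)
  }
  P <- mean(best_for_cand); R <- mean(best_for_ref)
  list(P = P, R = R, F = if (P + R > 0) 2 * P * R / (P + R) else 0)
}

# O(n^2) pairwise AUC oracle (concordant pairs, ties counted half)
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
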