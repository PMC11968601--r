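# ---------------------------------------------------------------------------
# From-scratch transformer encoder primitives (pure R). These are the
# reference implementations of the model's building blocks; the training loop
# in src/ re-implements the forward pass in C++ and is tested against them.
# ---------------------------------------------------------------------------

#' Encoder configuration
#'
#' Desk-scale defaults (`H = 64`, 4 heads, 2 layers) keep every property of
#' the architecture while staying cheap; the BERT-scale setting
#' `H = 768, n_heads = 12, L = 12` is selectable but required nowhere.
#'
#' @param H Hidden width; must equal `n_heads * d_k`.
#' @param n_heads Number of attention heads.
#' @param L Number of encoder layers.
#' @param d_ff Inner width of the position-wise feed-forward network.
#' @param max_len Maximum sequence length (positional-encoding table size).
#' @param vocab_size Vocabulary size (embedding rows).
#' @param pos_encoding Use fixed sinusoidal positional encoding (default
#'   `TRUE`).
#' @param pe_scale Factor applied to the positional encoding before adding it
#'   to the scaled embeddings (default 1).
#' @param emb_init_sd Standard deviation of the embedding initialization
#'   (default 0.02).
#' @param lora_rank Rank of the low-rank adapters attached to the attention
#'   projections (default 8).
#' @return List of class `"encoder_config"` with derived per-head widths
#'   `d_k = d_v = H / n_heads`.
#' @export
encoder_config <- function(H = 64, n_heads = 4, L = 2, d_ff = 128,
                           max_len = 256, vocab_size = 64,
                           pos_encoding = TRUE, pe_scale = 1,
                           emb_init_sd = 0.02, lora_rank = 8) {
  if (H %% n_heads != 0) stop("H must be divisible by n_heads (H = n_heads * d_k)")
  if (any(c(H, n_heads, d_ff, max_len, vocab_size) < 1) || L < 0) {
    stop("encoder dimensions must be positive (L >= 0)")
  }
  structure(list(H = as.integer(H), n_heads = as.integer(n_heads),
                 L = as.integer(L), d_k = as.integer(H / n_heads),
                 d_v = as.integer(H / n_heads), d_ff = as.integer(d_ff),
                 max_len = as.integer(max_len),
                 vocab_size = as.integer(vocab_size),
                 pos_encoding = isTRUE(pos_encoding),
                 pe_scale = as.numeric(pe_scale),
                 emb_init_sd = as.numeric(emb_init_sd),
                 lora_rank = as.integer(lora_rank)),
            class = "encoder_config")
}

# numerically stable row-wise softmax
row_softmax <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V`. Each output row is a
#' convex combination of the rows of `V`.
#'
#' @param Q Query matrix, `n_q x d_k`.
#' @param K Key matrix, `n_k x d_k`.
#' @param V Value matrix, `n_k x d_v`.
#' @return The `n_q x d_v` output matrix, with the row-stochastic attention
#'   weight matrix attached as attribute `"weights"`.
#' @export
attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) {
    stop("attention: Q has width ", ncol(Q), " but K has width ", ncol(K))
  }
  if (nrow(K) != nrow(V)) {
    stop("attention: K has ", nrow(K), " rows but V has ", nrow(V))
  }
  W <- row_softmax(Q %*% t(K) / sqrt(ncol(Q)))
  structure(W %*% V, weights = W)
}

#' Multi-head attention
#'
#' `MultiHead(X) = Concat(head_1, ..., head_h) W_O` with
#' `head_i = Attention(X W_Q_i, X W_K_i, X W_V_i)`.
#'
#' @param X Input matrix, `n x d`.
#' @param params List with elements `W_Q`, `W_K`, `W_V` (each a list of `h`
#'   per-head projection matrices, `d x d_k` / `d x d_k` / `d x d_v`) and
#'   `W_O` (`h*d_v x d`).
#' @return `n x d` output matrix, with per-head attention weights attached as
#'   attribute `"weights"` (list of `h` matrices).
#' @export
multi_head <- function(X, params) {
  X <- as.matrix(X)
  h <- length(params$W_Q)
  if (length(params$W_K) != h || length(params$W_V) != h) {
    stop("multi_head: W_Q, W_K, W_V must list one matrix per head")
  }
  heads <- vector("list", h)
  weights <- vector("list", h)
  for (i in seq_len(h)) {
    if (nrow(params$W_Q[[i]]) != ncol(X)) {
      stop("multi_head: head ", i, " W_Q expects input width ",
           nrow(params$W_Q[[i]]), ", got ", ncol(X))
    }
    out <- attention(X %*% params$W_Q[[i]], X %*% params$W_K[[i]],
                     X %*% params$W_V[[i]])
    heads[[i]] <- out
    weights[[i]] <- attr(out, "weights")
  }
  concat <- do.call(cbind, heads)
  if (ncol(concat) != nrow(params$W_O)) {
    stop("multi_head: W_O expects ", ncol(concat), " rows, has ",
         nrow(params$W_O))
  }
  structure(concat %*% params$W_O, weights = weights)
}

#' Position-wise feed-forward network
#'
#' `FFN(X) = max(0, X W1 + b1) W2 + b2` with elementwise ReLU.
#'
#' @param X Input matrix, `n x d`.
#' @param layer List with `W1` (`d x d_ff`), `b1`, `W2` (`d_ff x d`), `b2`.
#' @return `n x d` matrix.
#' @export
ffn <- function(X, layer) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(layer$W1)) {
    stop("ffn: W1 expects input width ", nrow(layer$W1), ", got ", ncol(X))
  }
  H1 <- pmax(sweep(X %*% layer$W1, 2, layer$b1, "+"), 0)
  sweep(H1 %*% layer$W2, 2, layer$b2, "+")
}

layer_norm <- function(X, gain, bias, eps = 1e-5) {
  mu <- rowMeans(X)
  centered <- X - mu
  sdv <- sqrt(rowMeans(centered^2) + eps)
  sweep(centered / sdv, 2, gain, "*") + rep(bias, each = nrow(X))
}

#' Fixed sinusoidal positional encoding table
#'
#' @param max_len Number of positions.
#' @param H Feature width.
#' @return `max_len x H` matrix.
#' @export
positional_encoding <- function(max_len, H) {
  pos <- seq_len(max_len) - 1
  i <- seq_len(H) - 1
  angle <- outer(pos, 10000^(-(2 * floor(i / 2)) / H))
  PE <- matrix(0, max_len, H)
  even <- which(i %% 2 == 0)
  odd <- which(i %% 2 == 1)
  PE[, even] <- sin(angle[, even, drop = FALSE])
  PE[, odd] <- cos(angle[, odd, drop = FALSE])
  PE
}

# ---------------------------------------------------------------------------
# LoRA adapters
# ---------------------------------------------------------------------------

#' Low-rank adaptation (LoRA) of a frozen weight matrix
#'
#' For a frozen base matrix `W0` (d x k), the adapted weight is
#' `W0 + B %*% A` with trainable `B` (d x r, zero-initialized) and `A`
#' (r x k, Gaussian-initialized, sd 0.02), with rank r far below min(d, k). At
#' construction `B = 0`, so the update `BA` is exactly zero and the adapted
#' model reproduces the base model bitwise. No additional scaling factor is
#' applied to `BA`.
#'
#' @param W0 Frozen base matrix.
#' @param r Adapter rank.
#' @param sd Standard deviation of the Gaussian initialization of `A`.
#' @return Object of class `"lora_adapter"` with fields `W0`, `A`, `B`, `r`.
#' @export
lora_adapter <- function(W0, r = 8, sd = 0.02) {
  W0 <- as.matrix(W0)
  r <- as.integer(r)
  if (r < 1L || r > min(dim(W0))) stop("LoRA rank must satisfy 1 <= r <= min(d, k)")
  structure(list(
    W0 = W0,
    A = matrix(rnorm(r * ncol(W0), sd = sd), r, ncol(W0)),
    B = matrix(0, nrow(W0), r),
    r = r
  ), class = "lora_adapter")
}

#' LoRA forward pass
#'
#' `h = W0 x + B (A x)` — the low-rank path is applied without ever forming
#' the dense product `BA`.
#'
#' @param adapter A [lora_adapter()].
#' @param x Input vector of length `k` (or `k x m` matrix of columns).
#' @return Numeric vector (or matrix) of length `d`.
#' @export
lora_forward <- function(adapter, x) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(x) != ncol(adapter$W0)) {
    stop("lora_forward: x has length ", nrow(x), ", W0 expects ",
         ncol(adapter$W0))
  }
  out <- adapter$W0 %*% x + adapter$B %*% (adapter$A %*% x)
  if (ncol(out) == 1L) drop(out) else out
}

#' Merge a LoRA adapter into a dense matrix
#'
#' `W = W0 + B A`; forward passes with the merged matrix agree with
#' [lora_forward()] up to floating-point roundoff.
#'
#' @param adapter A [lora_adapter()].
#' @return Dense `d x k` matrix.
#' @export
lora_merge <- function(adapter) {
  adapter$W0 + adapter$B %*% adapter$A
}

# ---------------------------------------------------------------------------
# Encoder stack
# ---------------------------------------------------------------------------

#' Initialize encoder weights
#'
#' Embedding and projection entries are drawn N(0, 0.02^2); layer-norm gains
#' start at 1, biases at 0; attention projections are stored as frozen base
#' matrices plus LoRA adapter pairs (`A` Gaussian, `B` zero), so a freshly
#' initialized encoder computes exactly its base forward pass.
#'
#' @param config An [encoder_config()].
#' @return Weight list: `emb` (`vocab_size x H`) and `layers`, a list of `L`
#'   layers each holding `Wq0/Aq/Bq`, `Wk0/Ak/Bk`, `Wv0/Av/Bv`, `Wo0/Ao/Bo`
#'   (combined `H x H` projections; per-head blocks are column slices),
#'   layer-norm parameters `g1/b1/g2/b2` and FFN parameters
#'   `W1/bf1/W2/bf2`.
#' @export
init_encoder <- function(config) {
  H <- config$H; r <- config$lora_rank
  gmat <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, sd = sd), nr, nc)
  emb <- gmat(config$vocab_size, H, sd = config$emb_init_sd)
  layers <- lapply(seq_len(config$L), function(l) {
    list(
      Wq0 = gmat(H, H), Aq = gmat(r, H), Bq = matrix(0, H, r),
      Wk0 = gmat(H, H), Ak = gmat(r, H), Bk = matrix(0, H, r),
      Wv0 = gmat(H, H), Av = gmat(r, H), Bv = matrix(0, H, r),
      Wo0 = gmat(H, H), Ao = gmat(r, H), Bo = matrix(0, H, r),
      g1 = rep(1, H), b1 = rep(0, H), g2 = rep(1, H), b2 = rep(0, H),
      W1 = gmat(H, config$d_ff), bf1 = rep(0, config$d_ff),
      W2 = gmat(config$d_ff, H), bf2 = rep(0, H)
    )
  })
  list(emb = emb, layers = layers)
}

# effective (LoRA-merged) projection matrix of a layer
proj_matrix <- function(layer, which) {
  layer[[paste0("W", which, "0")]] +
    layer[[paste0("B", which)]] %*% layer[[paste0("A", which)]]
}

# split a combined H x H projection into per-head d x d_k blocks
split_heads <- function(W, n_heads) {
  d_k <- ncol(W) / n_heads
  lapply(seq_len(n_heads), function(i) {
    W[, ((i - 1) * d_k + 1):(i * d_k), drop = FALSE]
  })
}

#' Encode a token-id sequence
#'
#' Embedding lookup plus (optional) sinusoidal positional encoding, followed
#' by `L` post-norm encoder layers: multi-head self-attention, residual add,
#' layer norm, FFN, residual add, layer norm. Attention weights of every
#' layer/head are exposed for visualization.
#'
#' @param token_ids Integer ids (0-based, as produced by [encode_text()]).
#' @param config An [encoder_config()].
#' @param weights Weights from [init_encoder()] (or a trained model's).
#' @param return_attention Attach per-layer lists of per-head attention
#'   matrices as attribute `"attention"`.
#' @return `n x H` feature matrix.
#' @export
encode <- function(token_ids, config, weights, return_attention = FALSE) {
  token_ids <- as.integer(token_ids)
  n <- length(token_ids)
  if (n == 0L) stop("encode: empty token sequence")
  if (n > config$max_len) {
    stop("encode: sequence length ", n, " exceeds max_len ", config$max_len)
  }
  if (any(token_ids < 0L | token_ids >= config$vocab_size)) {
    stop("encode: token id out of vocabulary range")
  }
  # embeddings scaled by sqrt(H) before the positional encoding is added,
  # as in the original transformer; this also gives the embedding table an
  # effectively larger learning rate, which the template-alignment signal
  # of MCI-completed structured reports needs
  X <- weights$emb[token_ids + 1L, , drop = FALSE] * sqrt(config$H)
  if (config$pos_encoding) {
    X <- X + config$pe_scale *
      positional_encoding(config$max_len, config$H)[seq_len(n), , drop = FALSE]
  }
  attn_all <- vector("list", length(weights$layers))
  for (l in seq_along(weights$layers)) {
    layer <- weights$layers[[l]]
    mh_params <- list(
      W_Q = split_heads(proj_matrix(layer, "q"), config$n_heads),
      W_K = split_heads(proj_matrix(layer, "k"), config$n_heads),
      W_V = split_heads(proj_matrix(layer, "v"), config$n_heads),
      W_O = proj_matrix(layer, "o")
    )
    A_out <- multi_head(X, mh_params)
    attn_all[[l]] <- attr(A_out, "weights")
    attr(A_out, "weights") <- NULL       # keep the feature matrix attribute-free
    X <- layer_norm(X + A_out, layer$g1, layer$b1)
    F_out <- ffn(X, list(W1 = layer$W1, b1 = layer$bf1,
                         W2 = layer$W2, b2 = layer$bf2))
    X <- layer_norm(X + F_out, layer$g2, layer$b2)
  }
  if (return_attention) attr(X, "attention") <- attn_all
  X
}
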