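test_that("attention matches hand-computed and oracle values", {
  # single key: weight 1, output is V
  expect_equal(unclass(attention(matrix(1), matrix(1), matrix(5)))[1, 1], 5)

  # identical queries over zero keys: uniform weights
  out <- attention(matrix(1, 2, 1), matrix(0, 2, 1), matrix(c(1, 3), 2, 1))
  expect_equal(unname(out[, 1]), c(2, 2))

  # two-term softmax over logits 1/sqrt(2) and 0, computed by the scalar
  # oracle and frozen: sigma = 0.66976157...
  out <- attention(matrix(c(1, 0), 1, 2), rbind(c(1, 0), c(0, 1)),
                   matrix(c(1, 0), 2, 1))
  oracle <- attention_oracle(matrix(c(1, 0), 1, 2), rbind(c(1, 0), c(0, 1)),
                             matrix(c(1, 0), 2, 1))
  expect_equal(out[1, 1], oracle[1, 1], tolerance = 1e-12)
  expect_equal(out[1, 1], 0.6697615, tolerance = 1e-6)

  expect_error(attention(matrix(1, 1, 2), matrix(1, 1, 3), matrix(1)), "width")
  expect_error(attention(matrix(1), matrix(1, 2, 1), matrix(1, 3, 1)), "rows")
})

test_that("attention weights are row-stochastic and outputs lie in conv(V)", {
  set.seed(21)
  for (i in 1:50) {
    n_q <- sample(1:5, 1); n_k <- sample(1:5, 1); d <- sample(1:4, 1)
    Q <- matrix(rnorm(n_q * d), n_q); K <- matrix(rnorm(n_k * d), n_k)
    V <- matrix(rnorm(n_k * 2), n_k)
    out <- attention(Q, K, V)
    W <- attr(out, "weights")
    expect_equal(rowSums(W), rep(1, n_q), tolerance = 1e-6)
    expect_true(all(W >= 0))
    # convex hull containment per output coordinate
    for (j in 1:2) {
      expect_true(all(out[, j] <= max(V[, j]) + 1e-12))
      expect_true(all(out[, j] >= min(V[, j]) - 1e-12))
    }
    # joint permutation of K and V rows leaves output unchanged
    perm <- sample(n_k)
    expect_equal(unclass(attention(Q, K[perm, , drop = FALSE],
                                   V[perm, , drop = FALSE])),
                 unclass(out), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("multi_head reduces, zeroes and matches a brute-force oracle", {
  set.seed(3)
  X <- matrix(rnorm(6), 3, 2)
  W_Q <- matrix(rnorm(4), 2); W_K <- matrix(rnorm(4), 2)
  W_V <- matrix(rnorm(4), 2)
  # h = 1 with identity W_O equals plain attention
  out1 <- multi_head(X, list(W_Q = list(W_Q), W_K = list(W_K),
                             W_V = list(W_V), W_O = diag(2)))
  expect_equal(unclass(out1),
               unclass(attention(X %*% W_Q, X %*% W_K, X %*% W_V)),
               ignore_attr = TRUE)

  # all-zero projections give all-zero output
  zero <- matrix(0, 2, 1)
  out0 <- multi_head(X, list(W_Q = list(zero, zero), W_K = list(zero, zero),
                             W_V = list(zero, zero), W_O = matrix(0, 2, 2)))
  expect_true(all(out0 == 0))

  # h = 2 on a 3-token input vs per-head oracle then concat + project
  heads <- lapply(1:2, function(i) {
    list(Q = matrix(rnorm(2), 2, 1), K = matrix(rnorm(2), 2, 1),
         V = matrix(rnorm(2), 2, 1))
  })
  W_O <- matrix(rnorm(4), 2, 2)
  got <- multi_head(X, list(W_Q = lapply(heads, `[[`, "Q"),
                            W_K = lapply(heads, `[[`, "K"),
                            W_V = lapply(heads, `[[`, "V"), W_O = W_O))
  manual <- do.call(cbind, lapply(heads, function(h) {
    attention_oracle(X %*% h$Q, X %*% h$K, X %*% h$V)
  })) %*% W_O
  expect_equal(unclass(got), manual, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(multi_head(X, list(W_Q = list(W_Q), W_K = list(),
                                  W_V = list(W_V), W_O = diag(2))),
               "one matrix per head")
})

test_that("ffn computes max(0, XW1 + b1)W2 + b2 exactly", {
  X <- matrix(c(0.3, -1.2, 2.0, 0.7), 2, 2)
  # zero weights: every row equals b2
  out <- ffn(X, list(W1 = matrix(0, 2, 3), b1 = rep(0, 3),
                     W2 = matrix(0, 3, 2), b2 = c(5, -1)))
  expect_equal(out, matrix(c(5, 5, -1, -1), 2, 2))
  # all-negative pre-activations: ReLU kills everything
  out <- ffn(X, list(W1 = matrix(0, 2, 3), b1 = rep(-2, 3),
                     W2 = matrix(rnorm(6), 3, 2), b2 = c(1, 2)))
  expect_equal(out, matrix(c(1, 1, 2, 2), 2, 2))
  # random 2x2 instance against scalar arithmetic
  set.seed(5)
  W1 <- matrix(rnorm(4), 2); b1 <- rnorm(2)
  W2 <- matrix(rnorm(4), 2); b2 <- rnorm(2)
  got <- ffn(X, list(W1 = W1, b1 = b1, W2 = W2, b2 = b2))
  for (i in 1:2) for (j in 1:2) {
    h <- pmax(c(sum(X[i, ] * W1[, 1]) + b1[1], sum(X[i, ] * W1[, 2]) + b1[2]), 0)
    expect_equal(got[i, j], sum(h * W2[, j]) + b2[j], tolerance = 1e-12)
  }
  expect_error(ffn(matrix(1, 1, 3), list(W1 = matrix(0, 2, 2))), "width")
})

test_that("LoRA adapters start as the exact base model", {
  set.seed(9)
  W0 <- matrix(rnorm(12), 4, 3)
  ad <- lora_adapter(W0, r = 2)
  expect_true(all(ad$B == 0))
  x <- rnorm(3)
  expect_identical(lora_forward(ad, x), drop(W0 %*% x))  # bitwise
  expect_identical(lora_merge(ad), W0)
})

test_that("LoRA forward, merge and rank behave per the low-rank update", {
  # rank-1 arithmetic: W0 = 0, A = [1 0], B = [2], x = (3, 7) -> 6
  ad <- lora_adapter(matrix(0, 1, 2), r = 1)
  ad$A <- matrix(c(1, 0), 1, 2); ad$B <- matrix(2)
  expect_equal(lora_forward(ad, c(3, 7)), 6)

  set.seed(10)
  ad <- lora_adapter(matrix(rnorm(12), 4, 3), r = 2)
  ad$B <- matrix(rnorm(8), 4, 2)
  x <- rnorm(3)
  expect_lt(max(abs(lora_forward(ad, x) -
                    drop((ad$W0 + ad$B %*% ad$A) %*% x))), 1e-10)

  # merged-minus-base has rank <= r (singular values past r vanish)
  big <- lora_adapter(matrix(rnorm(30), 6, 5), r = 2)
  big$B <- matrix(rnorm(12), 6, 2)
  sv <- svd(lora_merge(big) - big$W0)$d
  expect_lt(sv[3], 1e-10)

  # merge-then-forward vs adapter-forward on 100 random probes
  for (i in 1:100) {
    x <- rnorm(3)
    expect_lt(max(abs(lora_forward(ad, x) - drop(lora_merge(ad) %*% x))), 1e-10)
  }
  expect_error(lora_forward(ad, c(1, 2)), "length")
  expect_error(lora_adapter(matrix(0, 2, 2), r = 5), "rank")
})

test_that("encode applies the documented embedding rule and L layers", {
  enc <- tiny_encoder(L = 0, seed = 2)
  ids <- c(2L, 5L, 9L)
  out <- encode(ids, enc$config, enc$weights)
  pe <- positional_encoding(enc$config$max_len, enc$config$H)
  expect_equal(out,
               enc$weights$emb[ids + 1L, ] * sqrt(enc$config$H) +
                 enc$config$pe_scale * pe[1:3, ],
               tolerance = 1e-12)

  # permutation equivariance without positional encoding
  enc2 <- tiny_encoder(L = 2, seed = 3, pos_encoding = FALSE)
  ids <- c(4L, 7L, 11L, 5L)
  out1 <- encode(ids, enc2$config, enc2$weights)
  out2 <- encode(ids[c(2, 1, 3, 4)], enc2$config, enc2$weights)
  expect_equal(out2, out1[c(2, 1, 3, 4), ], tolerance = 1e-10)

  # attention rows sum to 1 at every layer and head
  att <- attr(encode(ids, enc2$config, enc2$weights, return_attention = TRUE),
              "attention")
  for (layer in att) for (W in layer) {
    expect_equal(rowSums(W), rep(1, length(ids)), tolerance = 1e-6)
  }

  expect_error(encode(integer(0), enc$config, enc$weights), "empty")
  expect_error(encode(rep(0L, 100), enc$config, enc$weights), "max_len")
  expect_error(encode(99L, enc$config, enc$weights), "vocabulary")
})

test_that("the C++ training forward agrees with the R encoder", {
  for (seed in 1:3) {
    enc <- tiny_encoder(H = 12, n_heads = 3, L = 2, seed = seed)
    w <- enc$weights
    # activate the LoRA path so the test covers the adapted projections
    set.seed(seed + 100)
    for (l in seq_along(w$layers)) {
      for (nm in c("Bq", "Bk", "Bv", "Bo")) {
        w$layers[[l]][[nm]][] <- rnorm(length(w$layers[[l]][[nm]]), sd = 0.05)
      }
    }
    ids <- sample(0:15, 6, replace = TRUE)
    # the C++ path receives the pre-scaled positional table
    pe <- enc$config$pe_scale *
      positional_encoding(enc$config$max_len, enc$config$H)
    expect_equal(biradsfusion:::cpp_encode(ids, w, pe, enc$config$n_heads),
                 unclass(encode(ids, enc$config, w)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("analytic gradients match finite differences for every fusion", {
  enc <- tiny_encoder(H = 8, n_heads = 2, L = 1, vocab = 12, seed = 6)
  pe <- positional_encoding(enc$config$max_len, enc$config$H)
  set.seed(6)
  params <- list(free = enc$weights, struct = init_encoder(enc$config),
                 W_fc = matrix(rnorm(16, sd = 0.1), 2, 8), b_fc = c(0, 0))
  for (s in c("free", "struct")) {
    for (nm in c("Bq", "Bk", "Bv", "Bo")) {
      params[[s]]$layers[[1]][[nm]][] <-
        rnorm(length(params[[s]]$layers[[1]][[nm]]), sd = 0.05)
    }
  }
  idf <- c(2L, 4L, 9L); ids <- c(2L, 7L, 5L)
  eps <- 1e-6
  for (fus in 0:5) {
    width <- if (fus == 5) 16 else 8
    params$W_fc <- matrix(rnorm(2 * width, sd = 0.1), 2, width)
    opts <- list(H = 8L, n_heads = 2L, streams = 2L, fusion = fus, pool = 0L)
    g <- biradsfusion:::cpp_loss_grad(idf, ids, 1L, params, opts, pe)
    probe <- function(getter, setter, analytic) {
      v <- getter(params)
      idx <- sample(length(v), 3)
      for (i in idx) {
        up <- v; up[i] <- up[i] + eps
        dn <- v; dn[i] <- dn[i] - eps
        num <- (biradsfusion:::cpp_loss(idf, ids, 1L, setter(params, up),
                                        opts, pe) -
                biradsfusion:::cpp_loss(idf, ids, 1L, setter(params, dn),
                                        opts, pe)) / (2 * eps)
        expect_equal(analytic[i], num, tolerance = 1e-5)
      }
    }
    probe(function(p) p$free$emb,
          function(p, v) { p$free$emb[] <- v; p }, g$free$emb)
    probe(function(p) p$struct$layers[[1]]$Aq,
          function(p, v) { p$struct$layers[[1]]$Aq[] <- v; p },
          g$struct$layers[[1]]$Aq)
    probe(function(p) p$free$layers[[1]]$W1,
          function(p, v) { p$free$layers[[1]]$W1[] <- v; p },
          g$free$layers[[1]]$W1)
    probe(function(p) p$W_fc,
          function(p, v) { p$W_fc[] <- v; p }, g$dW_fc)
  }
})
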