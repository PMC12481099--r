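test_that("self-attention matches a term-by-term dense evaluation", {
  set.seed(1)
  q <- matrix(rnorm(12), 3, 4); k <- matrix(rnorm(12), 3, 4)
  v <- matrix(rnorm(12), 3, 4)
  got <- self_attention(q, k, v, d = 4)$out
  # independent oracle: explicit loops over scores and the softmax sum
  want <- matrix(0, 3, 4)
  for (i in 1:3) {
    s <- numeric(3)
    for (j in 1:3) s[j] <- sum(q[i, ] * k[j, ]) / sqrt(4)
    w <- exp(s) / sum(exp(s))
    for (j in 1:3) want[i, ] <- want[i, ] + w[j] * v[j, ]
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("single-token attention returns the value row; zero queries average", {
  v <- matrix(rnorm(4), 1, 4)
  expect_equal(self_attention(matrix(rnorm(4), 1), matrix(rnorm(4), 1), v)$out,
               v)
  k <- matrix(rnorm(20), 5, 4); v5 <- matrix(rnorm(20), 5, 4)
  got <- self_attention(matrix(0, 5, 4), k, v5)$out
  expect_equal(got, matrix(rep(colMeans(v5), each = 5), 5, 4), tolerance = 1e-12)
})

test_that("attention output stays within the convex hull of the values", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    v <- matrix(runif(n * 4, min = -2, max = 3), n, 4)
    out <- self_attention(matrix(rnorm(n * 4), n), matrix(rnorm(n * 4), n), v)$out
    for (cc in 1:4) {
      expect_gte(min(out[, cc]), min(v[, cc]) - 1e-12)
      expect_lte(max(out[, cc]), max(v[, cc]) + 1e-12)
    }
  }
})

test_that("a query row with zero allowed keys errors", {
  q <- matrix(rnorm(8), 2, 4)
  mask <- rbind(c(TRUE, TRUE), c(FALSE, FALSE))
  expect_error(self_attention(q, q, q, mask = mask), "zero allowed keys")
})

test_that("rotary rotation is identity at position 0 and norm-preserving", {
  set.seed(3)
  x <- matrix(rnorm(40), 5, 8)
  expect_equal(apply_rotary(x, rep(0L, 5)), x)
  rot <- apply_rotary(x, c(0L, 3L, 17L, 100L, 999L))
  expect_equal(sqrt(rowSums(rot^2)), sqrt(rowSums(x^2)), tolerance = 1e-12)
  expect_error(apply_rotary(matrix(rnorm(15), 5, 3), rep(0L, 5)), "even")
})

test_that("rotary dot products depend only on relative position", {
  set.seed(4)
  q <- matrix(rnorm(8), 1, 8); k <- matrix(rnorm(8), 1, 8)
  for (i in 1:20) {
    m <- sample(0:50, 1); n <- sample(0:50, 1); s <- sample(1:200, 1)
    d1 <- sum(apply_rotary(q, m) * apply_rotary(k, n))
    d2 <- sum(apply_rotary(q, m + s) * apply_rotary(k, n + s))
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("a block with zero attention-output and FFN weights is the residual identity", {
  cfg <- model_config(1, 16, 2, norm_style = "pre")
  m <- synth_tiny_model(cfg, seed = 5)
  m$weights[["layers.0.attn.out.weight"]][] <- 0
  m$weights[["layers.0.ffn.fc2.weight"]][] <- 0
  x <- matrix(rnorm(5 * 16), 5, 16)
  expect_equal(transformer_block(x, m), x, tolerance = 1e-12)
})

test_that("gelu and swiglu blocks differ on the same input", {
  x <- matrix(rnorm(4 * 64), 4, 64)
  yg <- transformer_block(x, tiny_model(7))
  ys <- transformer_block(x, tiny_model(7, model_config(2, 64, 4,
                                                        activation = "swiglu")))
  expect_gt(max(abs(yg - ys)), 1e-4)
})

test_that("block outputs are finite across seeds (gelu and swiglu)", {
  for (seed in 1:100) {
    cfg <- if (seed %% 2) tiny_cfg else model_config(2, 64, 4, activation = "swiglu")
    x <- protlm:::with_seed(seed, matrix(rnorm(3 * 64, sd = 2), 3, 64))
    expect_true(all(is.finite(transformer_block(x, tiny_model(3, cfg)))))
  }
})

test_that("forward_logits is deterministic with the contracted shape", {
  m <- tiny_model(1)
  toks <- tokenize(random_aa(30, seed = 8))
  l1 <- forward_logits(toks, m)
  l2 <- forward_logits(toks, m)
  expect_identical(l1, l2)
  expect_identical(dim(l1), c(32L, 33L))
})

test_that("learned-positional models reject over-long sequences explicitly", {
  m <- synth_tiny_model(learned_cfg(16L), seed = 2)
  expect_error(forward_logits(tokenize(random_aa(40, seed = 1)), m),
               "max_positions")
  expect_silent(forward_logits(tokenize(random_aa(14, seed = 1)), m))
})

test_that("packed forward equals per-sequence forward in both positional modes", {
  for (cfg in list(tiny_cfg, learned_cfg(64L))) {
    m <- tiny_model(9, cfg)
    set.seed(20)
    for (rep in 1:5) {
      seqs <- lapply(seq_len(sample(2:5, 1)),
                     function(i) tokenize(random_aa(sample(3:40, 1))))
      pb <- pack(seqs)
      packed <- forward_logits(pb, m)
      solo <- do.call(rbind, lapply(seqs, forward_logits, model = m))
      expect_lt(max(abs(packed - solo)), 1e-4)
    }
  }
})

test_that("mutating one packed sequence leaves the others' logits bitwise unchanged", {
  m <- tiny_model(1)
  s1 <- tokenize(random_aa(12, seed = 31))
  s2 <- tokenize(random_aa(9, seed = 32))
  s3 <- tokenize(random_aa(15, seed = 33))
  base <- forward_logits(pack(list(s1, s2, s3)), m)
  s2mut <- s2
  s2mut[3:5] <- rev(s2mut[3:5]) + 0L
  s2mut[2] <- esm_alphabet()$mask
  mut <- forward_logits(pack(list(s1, s2mut, s3)), m)
  expect_identical(base[1:14, ], mut[1:14, ])          # sequence 1 (rows 1-14)
  expect_identical(base[26:42, ], mut[26:42, ])        # sequence 3 (rows 26-42)
})

test_that("permuting sequences in a packed batch permutes outputs identically", {
  m <- tiny_model(1)
  seqs <- lapply(c(11, 7, 19), function(n) tokenize(random_aa(n, seed = n)))
  out_a <- unpack(pack(seqs), forward_logits(pack(seqs), m))
  perm <- c(3, 1, 2)
  out_b <- unpack(pack(seqs[perm]), forward_logits(pack(seqs[perm]), m))
  # equality to float tolerance: BLAS accumulation order differs with the
  # row layout, so reordered batches agree to the last few ulps, not bitwise
  expect_equal(out_a[perm], out_b, tolerance = 1e-12)
})

test_that("masked-LM loss decreases over 50 steps on a fixed small corpus", {
  cfg <- model_config(1, 32, 2, ffn_dim = 64)
  m <- synth_tiny_model(cfg, seed = 13)
  corpus <- synth_proteins(fixture_spec(20, median_length = 30, sdlog = 0.2,
                                        seed = 14))
  tr <- train_mlm(m, corpus$sequence, steps = 50,
                  config = train_config(lr = 1e-3, minibatch_tokens = 2000,
                                        seed = 15))
  expect_lt(mean(tail(tr$log$loss, 10)), mean(head(tr$log$loss, 10)))
})
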