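test_that("pseudo-perplexity of a uniform-logit model equals the vocab size", {
  expect_equal(pseudo_perplexity(uniform_model(), "MKTAYIAK"), 33, tolerance = 1e-12)
})

test_that("batched pseudo-perplexity equals the one-mask-at-a-time loop", {
  m <- tiny_model(1)
  for (seed in c(41, 42)) {
    s <- random_aa(25, seed = seed)
    naive <- exp(mean(vapply(1:25, function(t) {
      -masked_logprobs(m, s, t)[[substr(s, t, t)]]
    }, numeric(1))))
    expect_equal(pseudo_perplexity(m, s), naive, tolerance = 1e-6)
    # and it does not depend on the batch budget (hence the batch plan)
    expect_equal(pseudo_perplexity(m, s, max_tokens = 60), naive,
                 tolerance = 1e-6)
  }
})

test_that("masked log-probabilities are a normalized distribution", {
  m <- tiny_model(2)
  s <- random_aa(15, seed = 43)
  for (pos in c(1L, 7L, 15L)) {
    expect_equal(sum(exp(masked_logprobs(m, s, pos))), 1, tolerance = 1e-5)
  }
  expect_error(masked_logprobs(m, s, 16L), "outside")
})

test_that("masked-marginal score is zero for ref==alt and for uniform models", {
  s <- random_aa(12, seed = 44)
  r5 <- substr(s, 5, 5)
  v_same <- variant_spec("p", 5, r5, r5)
  expect_identical(masked_margin(tiny_model(1), s, v_same)$score, 0)
  alt <- setdiff(c("A", "C"), r5)[1]
  v_diff <- variant_spec("p", 5, r5, alt)
  expect_equal(masked_margin(uniform_model(), s, v_diff)$score, 0,
               tolerance = 1e-12)
})

test_that("masked-marginal score matches an explicit-loop softmax oracle", {
  m <- tiny_model(3)
  s <- random_aa(18, seed = 45)
  ab <- esm_alphabet()
  pos <- 9L
  ref <- substr(s, pos, pos)
  v <- masked_margin(m, s, variant_spec("p", pos, ref, "W"))$score
  # oracle: raw logits -> probabilities by explicit exponentiation loop
  toks <- tokenize(s)
  toks[pos + 1L] <- ab$mask
  lg <- forward_logits(toks, m)[pos + 1L, ]
  p <- exp(lg) / sum(exp(lg))
  want <- log(p[ab$aa_ids[["W"]] + 1L]) - log(p[ab$aa_ids[[ref]] + 1L])
  expect_equal(v, unname(want), tolerance = 1e-9)
})

test_that("reference mismatches are reported with position and observed residue", {
  s <- "MKTAYIAK"
  wrong <- setdiff(c("A", "C"), substr(s, 3, 3))[1]
  expect_error(masked_margin(tiny_model(1), s, variant_spec("prot1", 3, wrong, "W")),
               "position 3.*prot1|prot1.*position 3")
})

test_that("variant-centered truncation follows the floor-center convention", {
  long <- strrep("A", 3000)
  # short sequences pass through
  tc0 <- truncate_center("MKTAY", 4, 1024)
  expect_identical(tc0$sequence, "MKTAY")
  expect_identical(tc0$position, 4L)
  # both flanks overflow: variant lands at window %/% 2
  tc1 <- truncate_center(long, 1500, 1024)
  expect_identical(nchar(tc1$sequence), 1024L)
  expect_identical(tc1$position, 512L)
  # left edge clips
  tc2 <- truncate_center(long, 5, 1024)
  expect_identical(tc2$offset, 0L)
  expect_identical(tc2$position, 5L)
  # right edge clips
  tc3 <- truncate_center(long, 2999, 1024)
  expect_identical(tc3$offset, 3000L - 1024L)
  expect_identical(tc3$position, 2999L - (3000L - 1024L))
})

test_that("variant tables score identically whatever the batch plan", {
  m <- tiny_model(1)
  set.seed(46)
  recs <- data.frame(id = c("a", "b", "c"),
                     sequence = vapply(c(25, 40, 18), random_aa, character(1)))
  n <- 100
  pid <- sample(recs$id, n, replace = TRUE)
  pos <- vapply(pid, function(p) {
    sample(nchar(recs$sequence[recs$id == p]), 1)
  }, integer(1))
  ref <- vapply(seq_len(n), function(i) {
    substr(recs$sequence[recs$id == pid[i]], pos[i], pos[i])
  }, character(1))
  vt <- data.frame(protein_id = pid, position = pos, ref = ref,
                   alt = sample(c("A", "W", "C", "G"), n, replace = TRUE))
  batched <- score_variant_table(m, recs, vt, max_tokens = 4096)
  tiny_batches <- score_variant_table(m, recs, vt, max_tokens = 50)
  expect_equal(batched$score, tiny_batches$score, tolerance = 1e-5)
  solo <- vapply(seq_len(n), function(i) {
    masked_margin(m, recs$sequence[recs$id == pid[i]],
                  vt[i, , drop = FALSE])$score
  }, numeric(1))
  expect_equal(batched$score, solo, tolerance = 1e-5)
})

test_that("variant-table edge cases: empty input, duplicates, missing proteins", {
  m <- tiny_model(1)
  recs <- data.frame(id = "a", sequence = random_aa(12, seed = 47))
  empty <- score_variant_table(m, recs, data.frame(protein_id = character(0),
                                                  position = integer(0),
                                                  ref = character(0),
                                                  alt = character(0)))
  expect_identical(nrow(empty), 0L)
  r2 <- substr(recs$sequence, 2, 2)
  dup <- data.frame(protein_id = "a", position = c(2L, 2L), ref = r2, alt = "W")
  sc <- score_variant_table(m, recs, dup)
  expect_identical(sc$score[1], sc$score[2])
  expect_error(score_variant_table(m, recs,
                                   data.frame(protein_id = "nope", position = 1L,
                                              ref = "A", alt = "C")),
               "nope")
})

test_that("long proteins are truncated around the variant when capacity demands", {
  m <- synth_tiny_model(learned_cfg(32L), seed = 6)
  s <- random_aa(100, seed = 48)
  pos <- 60L
  vt <- data.frame(protein_id = "a", position = pos,
                   ref = substr(s, pos, pos), alt = "W")
  sc <- score_variant_table(m, data.frame(id = "a", sequence = s), vt)
  tc <- truncate_center(s, pos, 30L)
  want <- masked_margin(m, tc$sequence,
                        variant_spec("a", tc$position, vt$ref, "W"))$score
  expect_equal(sc$score, want, tolerance = 1e-9)
})

test_that("an overfit model prefers its training sequence to a shuffled one", {
  cfg <- model_config(1, 32, 2, ffn_dim = 64)
  m <- synth_tiny_model(cfg, seed = 16)
  s <- random_aa(15, seed = 49)
  tr <- train_mlm(m, rep(s, 4), steps = 500,
                  config = train_config(lr = 1e-3, minibatch_tokens = 200,
                                        seed = 17))
  shuffled <- protlm:::with_seed(50, paste(sample(strsplit(s, "")[[1]]),
                                           collapse = ""))
  expect_lt(pseudo_perplexity(tr$model, s),
            pseudo_perplexity(tr$model, shuffled))
})

test_that("rank and classification metrics behave on known cases", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  y <- c(1, 1, 0, 0)
  expect_equal(auroc(y, c(4, 3, 2, 1)), 1)
  expect_equal(auroc(y, c(1, 2, 3, 4)), 0)
  expect_equal(auprc(y, c(4, 3, 2, 1)), 1)
  # rank-statistic AUROC agrees with an independent ROC integration
  set.seed(51)
  for (i in 1:5) {
    yy <- rbinom(60, 1, 0.4)
    ss <- rnorm(60) + yy
    want <- as.numeric(pROC::auc(pROC::roc(yy, ss, quiet = TRUE,
                                           direction = "<")))
    expect_equal(auroc(yy, ss), want, tolerance = 1e-12)
  }
})
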