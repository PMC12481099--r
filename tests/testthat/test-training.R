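test_that("the step-decay schedule follows the configured constants", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 1), 1e-4)
  expect_equal(lr_at_epoch(cfg, 10), 1e-4)
  expect_equal(lr_at_epoch(cfg, 11), 1e-4 * 0.9)
  expect_equal(lr_at_epoch(cfg, 25), 1e-4 * 0.9^2)
  expect_equal(lr_at_epoch(cfg, 100), 1e-4 * 0.9^9)
  # full audit: the decay sequence over 100 epochs is exactly 0.9^(k)
  lrs <- vapply(1:100, lr_at_epoch, numeric(1), config = cfg)
  expect_equal(unique(lrs), 1e-4 * 0.9^(0:9))
})

test_that("masking hits the configured fraction of residues", {
  m <- tiny_model(1)
  corpus <- synth_proteins(fixture_spec(40, median_length = 260, sdlog = 0.1,
                                        seed = 100))
  toks <- lapply(corpus$sequence, tokenize)
  pb <- pack(toks)
  n_res <- sum(nchar(corpus$sequence))
  expect_gt(n_res, 10000)
  ml <- masked_lm_loss(uniform_model(), pb, mask_rate = 0.15, seed = 101)
  # binomial 99.9% band around 0.15
  band <- 3.3 * sqrt(0.15 * 0.85 / n_res)
  expect_lt(abs(ml$n_masked / n_res - 0.15), band)
  # special tokens are never masked
  ab <- esm_alphabet()
  expect_true(all(pb$tokens[ml$masked_rows] %in% residue_ids(ab)))
})

test_that("uniform-logit models lose exactly log(vocab), independent of context", {
  pb <- pack(list(tokenize(random_aa(30, seed = 102))))
  mu <- uniform_model()
  ml <- masked_lm_loss(mu, pb, mask_rate = 0.3, seed = 103)
  expect_equal(ml$loss, log(33), tolerance = 1e-10)
  # the loss is computed at masked positions only: editing residues outside
  # the masked set cannot change what a context-free model is charged
  pb2 <- pb
  untouched <- setdiff(which(pb$tokens %in% residue_ids()), ml$masked_rows)
  pb2$tokens[untouched[1:5]] <- rev(pb2$tokens[untouched[1:5]]) + 0L
  ml2 <- masked_lm_loss(mu, pb2, mask_rate = 0.3, seed = 103)
  expect_identical(ml2$loss, ml$loss)
  # and the draw is reproducible per seed
  ml3 <- masked_lm_loss(tiny_model(1), pb, mask_rate = 0.2, seed = 104)
  ml4 <- masked_lm_loss(tiny_model(1), pb, mask_rate = 0.2, seed = 104)
  expect_identical(ml3$loss, ml4$loss)
  expect_identical(ml3$masked_rows, ml4$masked_rows)
})

test_that("analytic gradients match finite differences on a micro model", {
  cfg <- model_config(1, 8, 2, ffn_dim = 12)
  m <- synth_tiny_model(cfg, seed = 105)
  pb <- pack(list(tokenize("MKTAY"), tokenize("LVVW")))
  rows <- c(3L, 8L)
  targets <- pb$tokens[rows]
  fwd <- protlm:::plm_forward(m, pb, keep = TRUE)
  ce <- protlm:::masked_ce(fwd$logits, targets, rows)
  g <- protlm:::plm_backward(m, fwd, ce$dlogits)
  loss_of <- function(mm) {
    protlm:::masked_ce(protlm:::plm_forward(mm, pb)$logits, targets, rows)$loss
  }
  eps <- 1e-6
  set.seed(106)
  for (nm in c("layers.0.attn.q.weight", "layers.0.ffn.fc1.weight",
               "layers.0.attn_norm.weight", "embed_tokens.weight",
               "lm_head.bias")) {
    for (i in sample(length(m$weights[[nm]]), 3)) {
      mp <- m; mp$weights[[nm]][i] <- mp$weights[[nm]][i] + eps
      mn <- m; mn$weights[[nm]][i] <- mn$weights[[nm]][i] - eps
      fd <- (loss_of(mp) - loss_of(mn)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("training is bitwise deterministic given config and seed", {
  cfg <- model_config(1, 16, 2, ffn_dim = 32)
  m <- synth_tiny_model(cfg, seed = 107)
  corpus <- synth_proteins(fixture_spec(6, median_length = 20, sdlog = 0.1,
                                        seed = 108))
  tc <- train_config(lr = 1e-3, minibatch_tokens = 300, seed = 109)
  t1 <- train_mlm(m, corpus$sequence, steps = 15, config = tc)
  t2 <- train_mlm(m, corpus$sequence, steps = 15, config = tc)
  expect_identical(t1$model$weights, t2$model$weights)
  expect_identical(t1$log, t2$log)
})

test_that("positional extension reports the closed-form trainable count", {
  # the published ESM-1v-width case: 1280-dim table extended to 4096
  # positions (plus 2 offset rows) trains 5,245,440 parameters
  cfg <- model_config(1, 1280, 2, ffn_dim = 8, vocab_size = 33,
                      positional_mode = "learned", max_positions = 1024)
  m <- synth_tiny_model(cfg, seed = 110)
  ex <- extend_positional(m, 4096)
  expect_identical(ex$report$trainable_params, 5245440)
  expect_identical(nrow(ex$model$weights$embed_positions.weight), 4096L + 2L)
  # old rows are copied verbatim
  expect_identical(ex$model$weights$embed_positions.weight[1:1026, ],
                   m$weights$embed_positions.weight)
  expect_error(extend_positional(tiny_model(1), 4096), "learned positions only")
  expect_error(extend_positional(m, 512), "exceed")
})

test_that("extension training moves only the positional table", {
  m <- synth_tiny_model(learned_cfg(32L, dim = 32L), seed = 111)
  corpus <- synth_proteins(fixture_spec(30, median_length = 50, sdlog = 0.04,
                                        seed = 112))
  ex <- extend_positional(m, 64, corpus = corpus$sequence, steps = 3,
                          config = train_config(lr = 1e-3,
                                                minibatch_tokens = 2000,
                                                seed = 113))
  others <- setdiff(names(m$weights), "embed_positions.weight")
  expect_identical(ex$model$weights[others], m$weights[others])
  expect_false(identical(ex$model$weights$embed_positions.weight[1:34, ],
                         m$weights$embed_positions.weight))
})

test_that("extension retraining reduces masked-LM loss on longer-than-before sequences", {
  m <- synth_tiny_model(learned_cfg(32L, dim = 32L), seed = 114)
  corpus <- synth_proteins(fixture_spec(40, median_length = 54, sdlog = 0.05,
                                        seed = 115))
  expect_true(all(nchar(corpus$sequence) > 30 & nchar(corpus$sequence) <= 62))
  ex <- extend_positional(m, 64, corpus = corpus$sequence, steps = 200,
                          config = train_config(lr = 3e-3,
                                                minibatch_tokens = 2000,
                                                seed = 116))
  expect_lt(mean(tail(ex$log$loss, 20)), mean(head(ex$log$loss, 20)))
  expect_lt(tail(ex$log$val_loss, 1), head(ex$log$loss, 1))
})

test_that("epoch-budget arithmetic reproduces known points", {
  # the published step budget: 500k steps x 2M tokens on 18.7G tokens ~ 53
  tb <- training_time_budget(5e5, 2e6, 18.7e9)
  expect_identical(tb$epochs, 53)
  expect_equal(tb$raw, 5e5 * 2e6 / 18.7e9, tolerance = 1e-12)
  expect_identical(training_time_budget(10, 100, 1000)$epochs, 1)
  expect_equal(training_time_budget(10, 100, 2000)$raw,
               training_time_budget(10, 100, 1000)$raw / 2)
  expect_error(training_time_budget(10, 100, 0), "positive")
})

test_that("gradient accumulation updates every k-th minibatch", {
  m <- tiny_model(1)
  prot <- synth_proteins(fixture_spec(24, median_length = 30, sdlog = 0.1,
                                      seed = 117), model = NULL)
  prot$label <- rnorm(24)
  # one protein per minibatch -> 24 minibatches/epoch, accumulation 8 -> 3 updates
  cfg <- train_config(lr = 1e-3, epochs = 2, minibatch_tokens = 1,
                      grad_accum_steps = 8, seed = 118)
  ft <- finetune(m, prot, task = "regression", pooling = "mean",
                 mode = "head", config = cfg, head_hidden = 8)
  expect_identical(ft$n_updates, 6L)   # 2 epochs x 3 updates, no remainder
})

test_that("head-only fine-tuning keeps every base tensor bitwise frozen", {
  m <- tiny_model(1)
  prot <- synth_proteins(fixture_spec(12, median_length = 25, sdlog = 0.1,
                                      seed = 119))
  prot$label <- rnorm(12)
  cfg <- train_config(lr = 1e-3, epochs = 3, minibatch_tokens = 500,
                      grad_accum_steps = 2, seed = 120)
  ft <- finetune(m, prot, task = "regression", pooling = "attention",
                 mode = "head", config = cfg, head_hidden = 16)
  expect_identical(ft$model$weights, m$weights)
  # and the trained head changed
  expect_false(identical(ft$head$W1, regression_head(64, 16, seed = cfg$seed + 1L)$W1))
})

test_that("LoRA fine-tuning of a pooled head trains adapters, not the base", {
  cfg_m <- model_config(1, 32, 2, ffn_dim = 64)
  m <- lora_attach(synth_tiny_model(cfg_m, seed = 121), rank = 2, seed = 122)
  prot <- synth_proteins(fixture_spec(8, median_length = 20, sdlog = 0.1,
                                      seed = 123))
  prot$label <- rnorm(8)
  cfg <- train_config(lr = 1e-3, epochs = 2, minibatch_tokens = 300,
                      grad_accum_steps = 2, seed = 124)
  ft <- finetune(m, prot, task = "regression", pooling = "mean",
                 mode = "lora", config = cfg, head_hidden = 8)
  expect_identical(ft$model$weights, m$weights)
  expect_gt(max(abs(ft$model$adapters[[1]]$B)), 0)
})

test_that("binary fine-tuning upsamples and reports AUROC", {
  m <- tiny_model(1)
  base <- tiny_model(1)
  prot <- synth_proteins(fixture_spec(30, median_length = 25, sdlog = 0.1,
                                      seed = 125, label = "logistic"),
                         model = base)
  cfg <- train_config(lr = 1e-3, epochs = 2, minibatch_tokens = 2000,
                      grad_accum_steps = 2, seed = 126)
  ft <- finetune(m, prot[1:20, ], val = prot[21:30, ], task = "binary",
                 pooling = "mean", mode = "head", config = cfg,
                 head_hidden = 8)
  expect_true(all(ft$log$val_metric >= 0 & ft$log$val_metric <= 1))
  p <- ft$predict(prot[21:30, ])
  expect_true(all(p > 0 & p < 1))
})
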