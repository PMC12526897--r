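test_that("spectrogram images honour the dB mapping and geometry", {
  set.seed(3)
  w <- train_wave(3)
  cfg <- spectrogram_config(out_size = 96L, stft_window = 256L)
  img <- make_spectrogram(w, cfg)
  expect_equal(dim(img), c(96L, 96L))
  expect_true(all(img >= 0 & img <= 1))

  ## oracle: direct clip-and-map of the same STFT, then bilinear resize
  hop <- max(1L, floor((length(w$samples) - 256L) / 95))
  sg <- signal::specgram(w$samples, n = 256L, Fs = w$fs, overlap = 256L - hop)
  db <- 20 * log10(pmax(Mod(sg$S), .Machine$double.xmin))
  mapped <- (pmin(pmax(db, 60), 120) - 60) / 60
  expect_equal(range(mapped), c(0, 1), tolerance = 0.2)
  expect_equal(img, croaker:::resize_bilinear(mapped, 96L, 96L))

  ## a pure tone lights the row nearest its frequency
  fs <- 48000
  tone <- waveform(10^(100 / 20) * sin(2 * pi * 500 * seq_len(fs / 4) / fs),
                   fs, "uPa")
  ti <- make_spectrogram(tone, cfg)
  bright <- which.max(rowSums(ti))
  expect_lt(abs(bright / 96 * (fs / 2) - 500), 600)

  expect_error(make_spectrogram(waveform(rnorm(100), fs), cfg), "window")
})

test_that("the affine dB mapping sends floor, midpoint and ceiling to 0, 1/2, 1", {
  cfg <- spectrogram_config()
  map_db <- function(db) {
    (pmin(pmax(db, cfg$db_floor), cfg$db_ceil) - cfg$db_floor) /
      (cfg$db_ceil - cfg$db_floor)
  }
  expect_equal(map_db(c(60, 90, 120, 40, 200)), c(0, 0.5, 1, 0, 1))
})

test_that("pair sampling is balanced, labelled and seeded", {
  labels <- rep(c("a", "b", "c"), each = 10)
  set.seed(4)
  pr <- sample_pairs(labels, 100)
  expect_equal(sum(pr$label == 0), 50)
  expect_true(all(labels[pr$i[pr$label == 0]] == labels[pr$j[pr$label == 0]]))
  expect_true(all(labels[pr$i[pr$label == 1]] != labels[pr$j[pr$label == 1]]))
  expect_true(all(pr$i[pr$label == 0] != pr$j[pr$label == 0]))
  set.seed(4)
  expect_identical(sample_pairs(labels, 100), pr)
  expect_error(sample_pairs(rep("a", 10), 10), "2 classes")
})

test_that("contrastive loss matches its closed forms", {
  expect_equal(contrastive_loss(0, 0), 0)
  expect_equal(contrastive_loss(0.5, 1, margin = 0.3), 0)
  expect_equal(contrastive_loss(0.3, 1, margin = 0.3), 0)
  expect_equal(contrastive_loss(0, 1, margin = 0.3), 0.09)
  expect_equal(contrastive_loss(0.2, 0), 0.04)
  expect_true(all(contrastive_loss(runif(20), sample(0:1, 20, TRUE)) >= 0))
})

test_that("cosine similarity is exact on itself and symmetric", {
  set.seed(1)
  a <- rnorm(32)
  b <- rnorm(32)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
  expect_true(abs(cosine_similarity(a, b)) <= 1)
  A <- matrix(rnorm(50 * 8), 50, 8)
  expect_equal(cosine_similarity(A, A), rep(1, 50))
})

test_that("the twin network embeds deterministically at the stated width", {
  net <- siamese_net(seed = 2)
  expect_equal(net$embedding, 512L)
  expect_gt(net$n_parameters, 1e5)
  x <- matrix(runif(2 * (224 / 8)^2), 2)
  e1 <- croaker:::net_forward(net, x)$E
  e2 <- croaker:::net_forward(net, x)$E
  expect_identical(e1, e2)
  expect_equal(ncol(e1), 512L)
})

test_that("zero learning rate freezes training history", {
  set.seed(6)
  waves <- c(lapply(1:6, function(i) train_wave(2)),
             lapply(1:6, function(i) train_wave(5)))
  labels <- rep(c(2, 5), each = 6)
  cfgs <- spectrogram_config(out_size = 64L, stft_window = 256L)
  net <- siamese_net(input_size = 64L, pool = 8L, hidden = 32L,
                     n_blocks = 1L, embedding = 32L, seed = 1)
  tc <- train_config(learning_rate = 0, batch = 8L, eval_every = 5L,
                     max_steps = 15L, n_val_pairs = 10L, seed = 2)
  fit <- train_siamese(waves, labels, net, tc, cfgs)
  expect_true(all(fit$history$val_loss == fit$history$val_loss[1]))
  expect_identical(fit$net$weights$in_W, net$weights$in_W)
})

test_that("training separates chains and degrades monotonically with noise", {
  set.seed(7)
  n_per <- 12
  waves <- c(lapply(seq_len(n_per), function(i) train_wave(2)),
             lapply(seq_len(n_per), function(i) train_wave(9)))
  labels <- rep(c(2, 9), each = n_per)
  cfgs <- spectrogram_config(out_size = 64L, stft_window = 256L)
  net <- siamese_net(input_size = 64L, pool = 4L, hidden = 64L,
                     n_blocks = 1L, embedding = 64L, seed = 1)
  tc <- train_config(learning_rate = 1e-3, batch = 32L, eval_every = 50L,
                     max_steps = 300L, n_val_pairs = 60L, seed = 3)
  fit <- train_siamese(waves, labels, net, tc, cfgs)

  ## held-out positives closer than negatives
  h <- fit$history
  expect_gt(h$val_cos_pos[nrow(h)], h$val_cos_neg[nrow(h)])

  ## same seed, same history
  fit2 <- train_siamese(waves, labels,
                        siamese_net(input_size = 64L, pool = 4L, hidden = 64L,
                                    n_blocks = 1L, embedding = 64L, seed = 1),
                        tc, cfgs)
  expect_identical(fit$history, fit2$history)

  ## identical sets embed identically
  ev <- evaluate_similarity(fit, waves[1:4], waves[1:4], labels[1:4],
                            labels[1:4], cfgs)
  expect_equal(ev$cosine_similarity[ev$chain == "average"], 1,
               tolerance = 1e-12)

  ## monotone degradation with decreasing SNR
  snr15 <- lapply(waves, function(w) add_noise_at_snr(w, noise_spec(15, seed = 1)))
  snr10 <- lapply(waves, function(w) add_noise_at_snr(w, noise_spec(10, seed = 2)))
  av <- function(a, b) {
    e <- evaluate_similarity(fit, a, b, labels, labels, cfgs)
    e$cosine_similarity[e$chain == "average"]
  }
  s_clean <- av(waves, waves)
  s15 <- av(waves, snr15)
  s10 <- av(waves, snr10)
  expect_gte(s_clean, s15)
  expect_gte(s15, s10)
})
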