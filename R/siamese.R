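#' Spectrogram preprocessing configuration
#'
#' Settings for converting a call to the fixed-size dB-magnitude
#' spectrogram image fed to the embedding network: STFT, clipping of the dB
#' range (`db_floor` maps to 0, `db_ceil` to 1) and bilinear resizing to
#' `out_size x out_size`.
#'
#' @param out_size Output image side, pixels.
#' @param db_floor,db_ceil dB levels mapped to 0 and 1.
#' @param stft_window STFT window length, samples.
#' @param stft_hop Hop, samples; `NULL` spreads the frames to roughly fill
#'   `out_size` columns.
#' @return A `croaker_spec_config`.
#' @export
spectrogram_config <- function(out_size = 224L, db_floor = 60, db_ceil = 120,
                               stft_window = 1024L, stft_hop = NULL) {
  if (!(db_floor < db_ceil)) abort("db_floor must be below db_ceil")
  structure(list(out_size = as.integer(out_size), db_floor = db_floor,
                 db_ceil = db_ceil, stft_window = as.integer(stft_window),
                 stft_hop = stft_hop),
            class = "croaker_spec_config")
}

## bilinear resize of a matrix to nr x nc
resize_bilinear <- function(m, nr, nc) {
  sr <- nrow(m); sc <- ncol(m)
  ri <- if (sr == 1L) rep(1, nr) else seq(1, sr, length.out = nr)
  ci <- if (sc == 1L) rep(1, nc) else seq(1, sc, length.out = nc)
  r0 <- pmin(floor(ri), sr - 1L); r1 <- r0 + 1L; wr <- ri - r0
  c0 <- pmin(floor(ci), sc - 1L); c1 <- c0 + 1L; wc <- ci - c0
  if (sr == 1L) { r0 <- r1 <- rep(1L, nr); wr <- rep(0, nr) }
  if (sc == 1L) { c0 <- c1 <- rep(1L, nc); wc <- rep(0, nc) }
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
  d <- m[r1, c0, drop = FALSE]; e <- m[r1, c1, drop = FALSE]
  WR <- matrix(wr, nr, nc); WC <- matrix(wc, nr, nc, byrow = TRUE)
  a * (1 - WR) * (1 - WC) + b * (1 - WR) * WC + d * WR * (1 - WC) + e * WR * WC
}

#' Spectrogram image of a call
#'
#' dB-magnitude short-time Fourier transform, clipped to
#' `[db_floor, db_ceil]`, affinely mapped to `[0, 1]` and bilinearly
#' resized to `out_size x out_size` (rows = frequency, low at row 1).
#'
#' @param w A `croaker_waveform` (pressure in uPa for calibrated dB levels).
#' @param cfg A `croaker_spec_config`.
#' @return Numeric `out_size x out_size` matrix in `[0, 1]`.
#' @export
make_spectrogram <- function(w, cfg = spectrogram_config()) {
  w <- as_waveform(w)
  x <- w$samples
  if (length(x) < cfg$stft_window) {
    abort("input shorter than one STFT window")
  }
  hop <- cfg$stft_hop
  if (is.null(hop)) {
    hop <- max(1L, floor((length(x) - cfg$stft_window) / (cfg$out_size - 1)))
  }
  sg <- signal::specgram(x, n = cfg$stft_window, Fs = w$fs,
                         overlap = cfg$stft_window - hop)
  db <- 20 * log10(pmax(Mod(sg$S), .Machine$double.xmin))
  db <- pmin(pmax(db, cfg$db_floor), cfg$db_ceil)
  img <- (db - cfg$db_floor) / (cfg$db_ceil - cfg$db_floor)
  resize_bilinear(img, cfg$out_size, cfg$out_size)
}

#' Sample positive and negative spectrogram pairs
#'
#' Positive pairs (label 0) draw two distinct examples from one class;
#' negative pairs (label 1) draw one example from each of two distinct
#' classes. Balanced half-and-half by default.
#'
#' @param labels Class label per example (chain id).
#' @param n Number of pairs.
#' @param positive_fraction Fraction of positive pairs.
#' @return A tibble: `i`, `j` (example indices), `label` (0 same-class,
#'   1 different-class).
#' @export
sample_pairs <- function(labels, n, positive_fraction = 0.5) {
  tab <- table(labels)
  classes <- names(tab)
  if (length(classes) < 2L) abort("need at least 2 classes to form negative pairs")
  pos_classes <- classes[tab >= 2L]
  if (length(pos_classes) == 0L) abort("no class has 2 examples for positive pairs")
  n_pos <- round(n * positive_fraction)
  out_i <- integer(n); out_j <- integer(n); lab <- integer(n)
  for (k in seq_len(n)) {
    if (k <= n_pos) {
      cl <- sample(pos_classes, 1L)
      idx <- sample(which(labels == cl), 2L)
      out_i[k] <- idx[1]; out_j[k] <- idx[2]; lab[k] <- 0L
    } else {
      cl2 <- sample(classes, 2L)
      out_i[k] <- sample(which(labels == cl2[1]), 1L)
      out_j[k] <- sample(which(labels == cl2[2]), 1L)
      lab[k] <- 1L
    }
  }
  tibble(i = out_i, j = out_j, label = lab)
}

#' Contrastive loss
#'
#' `L = (1 - y) d^2 + y max(0, margin - d)^2` for distance `d >= 0` and
#' label `y` (0 = same class, 1 = different class). With the cosine
#' distance `d = 1 - cos(e_a, e_b)`.
#'
#' @param d Distances.
#' @param y Labels in `{0, 1}`.
#' @param margin Margin for negative pairs.
#' @return Loss values, `>= 0`.
#' @export
#' @examples
#' contrastive_loss(0, 1, margin = 0.3)  # 0.09
contrastive_loss <- function(d, y, margin = 0.3) {
  stopifnot(all(d >= 0), all(y %in% c(0, 1)))
  (1 - y) * d^2 + y * pmax(0, margin - d)^2
}

#' Cosine similarity between embedding vectors
#'
#' @param a,b Numeric vectors, or matrices with one embedding per row.
#' @return Scalar or per-row cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (is.matrix(a)) {
    num <- rowSums(a * b)
    num / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  } else {
    sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  }
}

#' Twin embedding network
#'
#' A compact residual embedding network applied identically (shared
#' weights) to both members of a pair: the input spectrogram is average
#' pooled by `pool` (224 -> 28 with the defaults), flattened, projected to
#' `hidden` units, passed through `n_blocks` residual fully connected
#' blocks (dense-ReLU-dense plus identity skip), and projected to an
#' `embedding`-dimensional output compared by cosine similarity. He-uniform
#' initialization, seeded.
#'
#' @param input_size Side of the input spectrogram image.
#' @param pool Average-pooling factor applied to the input.
#' @param hidden Width of the trunk.
#' @param n_blocks Number of residual blocks.
#' @param embedding Embedding dimension.
#' @param seed RNG seed for initialization.
#' @return A `croaker_siamese` with weight matrices and an Adam state; the
#'   total parameter count is in `$n_parameters`.
#' @export
siamese_net <- function(input_size = 224L, pool = 8L, hidden = 256L,
                        n_blocks = 2L, embedding = 512L, seed = 1L) {
  stopifnot(input_size %% pool == 0L)
  d_in <- (input_size %/% pool)^2
  set.seed(seed)
  he <- function(nin, nout) {
    matrix(runif(nin * nout, -sqrt(6 / nin), sqrt(6 / nin)), nin, nout)
  }
  W <- list(in_W = he(d_in, hidden), in_b = numeric(hidden))
  for (bl in seq_len(n_blocks)) {
    W[[paste0("blk", bl, "_W1")]] <- he(hidden, hidden)
    W[[paste0("blk", bl, "_b1")]] <- numeric(hidden)
    W[[paste0("blk", bl, "_W2")]] <- he(hidden, hidden)
    W[[paste0("blk", bl, "_b2")]] <- numeric(hidden)
  }
  W$out_W <- he(hidden, embedding)
  W$out_b <- numeric(embedding)
  n_par <- sum(vapply(W, length, integer(1)))
  structure(list(weights = W, input_size = as.integer(input_size),
                 pool = as.integer(pool), hidden = as.integer(hidden),
                 n_blocks = as.integer(n_blocks),
                 embedding = as.integer(embedding),
                 n_parameters = n_par,
                 adam = NULL),
            class = "croaker_siamese")
}

#' @export
print.croaker_siamese <- function(x, ...) {
  cat("<croaker_siamese>", x$n_blocks, "residual blocks, hidden", x$hidden,
      "-> embedding", x$embedding, " (", x$n_parameters, "parameters )\n")
  invisible(x)
}

## average pool a square image by integer factor, then flatten row vector
pool_flatten <- function(img, pool) {
  n <- nrow(img)
  m <- n %/% pool
  ## block means via index-sum trick
  grp <- rep(seq_len(m), each = pool)
  pooled <- rowsum(img, grp) # sums rows
  pooled <- t(rowsum(t(pooled), grp)) / pool^2
  as.numeric(pooled)
}

net_forward <- function(net, X) {
  W <- net$weights
  cache <- list(X = X)
  h <- X %*% W$in_W
  h <- sweep(h, 2, W$in_b, "+")
  h <- pmax(h, 0)
  cache$h0 <- h
  for (bl in seq_len(net$n_blocks)) {
    z1 <- sweep(h %*% W[[paste0("blk", bl, "_W1")]], 2,
                W[[paste0("blk", bl, "_b1")]], "+")
    a1 <- pmax(z1, 0)
    z2 <- sweep(a1 %*% W[[paste0("blk", bl, "_W2")]], 2,
                W[[paste0("blk", bl, "_b2")]], "+")
    out <- pmax(h + z2, 0)
    cache[[paste0("b", bl)]] <- list(hin = h, z1 = z1, a1 = a1, z2 = z2,
                                     out = out)
    h <- out
  }
  E <- sweep(h %*% W$out_W, 2, W$out_b, "+")
  cache$htop <- h
  cache$E <- E
  cache
}

## backprop dL/dE -> gradients for all weights
net_backward <- function(net, cache, dE) {
  W <- net$weights
  g <- list()
  g$out_W <- t(cache$htop) %*% dE
  g$out_b <- colSums(dE)
  dh <- dE %*% t(W$out_W)
  for (bl in rev(seq_len(net$n_blocks))) {
    cb <- cache[[paste0("b", bl)]]
    dout <- dh * (cb$out > 0)
    dz2 <- dout
    g[[paste0("blk", bl, "_W2")]] <- t(cb$a1) %*% dz2
    g[[paste0("blk", bl, "_b2")]] <- colSums(dz2)
    da1 <- dz2 %*% t(W[[paste0("blk", bl, "_W2")]])
    dz1 <- da1 * (cb$z1 > 0)
    g[[paste0("blk", bl, "_W1")]] <- t(cb$hin) %*% dz1
    g[[paste0("blk", bl, "_b1")]] <- colSums(dz1)
    dh <- dout + dz1 %*% t(W[[paste0("blk", bl, "_W1")]])
  }
  dh0 <- dh * (cache$h0 > 0)
  g$in_W <- t(cache$X) %*% dh0
  g$in_b <- colSums(dh0)
  g
}

adam_step <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(net$adam)) {
    net$adam <- list(t = 0L,
                     m = lapply(net$weights, function(w) w * 0),
                     v = lapply(net$weights, function(w) w * 0))
  }
  st <- net$adam
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    net$weights[[nm]] <- net$weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  net$adam <- st
  net
}

#' Embed waveforms or spectrograms
#'
#' @param net A `croaker_siamese`.
#' @param x List of `croaker_waveform`s or of spectrogram matrices, or a
#'   matrix of pre-flattened pooled inputs.
#' @param spec_cfg A `croaker_spec_config` used when `x` holds waveforms.
#' @return Matrix of embeddings, one row per input.
#' @export
embed_calls <- function(net, x, spec_cfg = spectrogram_config(net$input_size)) {
  X <- inputs_to_matrix(net, x, spec_cfg)
  net_forward(net, X)$E
}

inputs_to_matrix <- function(net, x, spec_cfg) {
  if (is.matrix(x) && !is.list(x)) return(x)
  rows <- lapply(x, function(el) {
    img <- if (inherits(el, "croaker_waveform")) make_spectrogram(el, spec_cfg) else el
    pool_flatten(img, net$pool)
  })
  do.call(rbind, rows)
}

#' Training configuration for the twin network
#'
#' Defaults mirror the reference training protocol: Adam with learning rate
#' 1e-5, contrastive margin 0.3, mini-batches of 64 pairs, evaluation every
#' 100 steps with early stopping after 5 non-improving evaluations, and a
#' disjoint 7:3 train/validation split.
#'
#' @param learning_rate Adam step size.
#' @param margin Contrastive margin.
#' @param batch Pairs per step.
#' @param eval_every Steps between evaluations.
#' @param early_stop_patience Non-improving evaluations tolerated.
#' @param split Training fraction.
#' @param max_steps Hard step cap.
#' @param n_val_pairs Validation pairs per evaluation.
#' @param seed RNG seed.
#' @return A `croaker_train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, margin = 0.3, batch = 64L,
                         eval_every = 100L, early_stop_patience = 5L,
                         split = 0.7, max_steps = 2000L,
                         n_val_pairs = 200L, seed = 1L) {
  stopifnot(split > 0, split < 1, margin > 0)
  structure(list(learning_rate = learning_rate, margin = margin,
                 batch = as.integer(batch), eval_every = as.integer(eval_every),
                 early_stop_patience = as.integer(early_stop_patience),
                 split = split, max_steps = as.integer(max_steps),
                 n_val_pairs = as.integer(n_val_pairs),
                 seed = as.integer(seed)),
            class = "croaker_train_config")
}

#' Train the twin network with contrastive loss
#'
#' Splits the examples into disjoint train/validation sets, then repeatedly
#' samples balanced positive/negative pairs, runs both pair members through
#' the shared-weight network, and minimizes the contrastive loss on the
#' cosine distance with Adam. Every `eval_every` steps the validation loss
#' is computed on a fixed seeded pair sample; training stops early after
#' `early_stop_patience` non-improving evaluations. Seeded and
#' single-threaded: the same seed reproduces the history exactly.
#'
#' @param x List of waveforms or spectrogram matrices.
#' @param labels Class (chain) label per example.
#' @param net A `croaker_siamese`; a default one is built if omitted.
#' @param cfg A `croaker_train_config`.
#' @param spec_cfg A `croaker_spec_config` for waveform inputs.
#' @return A `croaker_siamese_fit`: list with `net`, `history` (tibble:
#'   step, train_loss, val_loss, val_cos_pos, val_cos_neg), and the split
#'   indices.
#' @export
train_siamese <- function(x, labels, net = NULL, cfg = train_config(),
                          spec_cfg = NULL) {
  if (is.null(net)) net <- siamese_net(seed = cfg$seed)
  if (is.null(spec_cfg)) spec_cfg <- spectrogram_config(net$input_size)
  labels <- as.character(labels)
  X <- inputs_to_matrix(net, x, spec_cfg)
  n <- nrow(X)
  set.seed(cfg$seed)
  idx_train <- sort(sample(n, round(cfg$split * n)))
  idx_val <- setdiff(seq_len(n), idx_train)
  val_pairs <- sample_pairs(labels[idx_val], cfg$n_val_pairs)

  eval_val <- function(net) {
    ca <- net_forward(net, X[idx_val[val_pairs$i], , drop = FALSE])
    cb <- net_forward(net, X[idx_val[val_pairs$j], , drop = FALSE])
    cs <- cosine_similarity(ca$E, cb$E)
    d <- 1 - cs
    loss <- mean(contrastive_loss(d, val_pairs$label, cfg$margin))
    list(loss = loss,
         cos_pos = mean(cs[val_pairs$label == 0]),
         cos_neg = mean(cs[val_pairs$label == 1]))
  }

  hist <- list()
  best_val <- Inf
  patience <- 0L
  for (step in seq_len(cfg$max_steps)) {
    pr <- sample_pairs(labels[idx_train], cfg$batch)
    ca <- net_forward(net, X[idx_train[pr$i], , drop = FALSE])
    cb <- net_forward(net, X[idx_train[pr$j], , drop = FALSE])
    A <- ca$E; B <- cb$E
    na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
    cs <- rowSums(A * B) / (na * nb)
    d <- 1 - cs
    loss <- mean(contrastive_loss(d, pr$label, cfg$margin))
    if (!is.finite(loss)) {
      abort(paste0("training diverged at step ", step, " (non-finite loss)"))
    }
    ## dL/dd per pair, then dd/dE = -dcos/dE
    dLdd <- ifelse(pr$label == 0, 2 * d,
                   -2 * pmax(0, cfg$margin - d)) / cfg$batch
    dcs_dA <- B / (na * nb) - A * (cs / na^2)
    dcs_dB <- A / (na * nb) - B * (cs / nb^2)
    dA <- -dLdd * dcs_dA
    dB <- -dLdd * dcs_dB
    gA <- net_backward(net, ca, dA)
    gB <- net_backward(net, cb, dB)
    g <- Map(`+`, gA, gB)
    net <- adam_step(net, g, cfg$learning_rate)
    if (step %% cfg$eval_every == 0L || step == cfg$max_steps) {
      ev <- eval_val(net)
      hist[[length(hist) + 1L]] <- tibble(step = step, train_loss = loss,
                                          val_loss = ev$loss,
                                          val_cos_pos = ev$cos_pos,
                                          val_cos_neg = ev$cos_neg)
      if (ev$loss < best_val - 1e-12) {
        best_val <- ev$loss
        patience <- 0L
      } else {
        patience <- patience + 1L
        if (patience >= cfg$early_stop_patience) break
      }
    }
  }
  structure(list(net = net, history = dplyr::bind_rows(hist),
                 idx_train = idx_train, idx_val = idx_val,
                 config = cfg),
            class = "croaker_siamese_fit")
}

#' @export
print.croaker_siamese_fit <- function(x, ...) {
  h <- x$history
  cat("<croaker_siamese_fit>", if (nrow(h)) max(h$step) else 0, "steps;",
      "final val loss", if (nrow(h)) signif(h$val_loss[nrow(h)], 4) else NA, "\n")
  invisible(x)
}

#' @export
glance.croaker_siamese_fit <- function(x, ...) {
  h <- x$history
  tibble(steps = if (nrow(h)) max(h$step) else 0L,
         val_loss = if (nrow(h)) h$val_loss[nrow(h)] else NA_real_,
         val_cos_pos = if (nrow(h)) h$val_cos_pos[nrow(h)] else NA_real_,
         val_cos_neg = if (nrow(h)) h$val_cos_neg[nrow(h)] else NA_real_,
         n_parameters = x$net$n_parameters)
}

#' Chain-wise cosine similarity between two signal sets
#'
#' Embeds both sets with the trained network and reports, per chain, the
#' mean cosine similarity over matched pairs (the i-th member of each set
#' within a chain, recycling the shorter set), plus the overall average.
#' Empty chains are dropped with a warning.
#'
#' @param fit A `croaker_siamese_fit` (or a bare `croaker_siamese`).
#' @param set_a,set_b Lists of waveforms or spectrograms.
#' @param chains_a,chains_b Chain label per element.
#' @param spec_cfg A `croaker_spec_config` for waveform inputs.
#' @return A tibble: `chain` (including `"average"`), `n_pairs`,
#'   `cosine_similarity`.
#' @export
evaluate_similarity <- function(fit, set_a, set_b, chains_a, chains_b,
                                spec_cfg = NULL) {
  net <- if (inherits(fit, "croaker_siamese_fit")) fit$net else fit
  if (is.null(spec_cfg)) spec_cfg <- spectrogram_config(net$input_size)
  Ea <- embed_calls(net, set_a, spec_cfg)
  Eb <- embed_calls(net, set_b, spec_cfg)
  chains <- sort(unique(as.character(chains_a)))
  rows <- list()
  allcs <- numeric(0)
  for (ch in chains) {
    ia <- which(as.character(chains_a) == ch)
    ib <- which(as.character(chains_b) == ch)
    if (length(ia) == 0L || length(ib) == 0L) {
      warn(paste0("chain ", ch, " empty in one set; omitted"))
      next
    }
    m <- max(length(ia), length(ib))
    ia <- rep_len(ia, m); ib <- rep_len(ib, m)
    cs <- cosine_similarity(Ea[ia, , drop = FALSE], Eb[ib, , drop = FALSE])
    rows[[length(rows) + 1L]] <- tibble(chain = ch, n_pairs = m,
                                        cosine_similarity = mean(cs))
    allcs <- c(allcs, cs)
  }
  out <- dplyr::bind_rows(rows)
  dplyr::bind_rows(out, tibble(chain = "average", n_pairs = length(allcs),
                               cosine_similarity = mean(allcs)))
}
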