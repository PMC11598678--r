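# BYOL self-supervised pretraining of the ResNet18 encoder.
#
# Two independently augmented views of each image are fed to an online
# network (encoder + projector + predictor) and a target network (EMA copy
# of encoder + projector). The loss for one ordering is
# 2 - 2 cos(predictor(online(v1)), stopgrad(target(v2))); the symmetrised
# loss averages both orderings, so each pair contributes a value in
# [0, 4]. Only the online network receives gradients; the target follows
# by exponential moving average. Batch normalisation in the projector
# keeps the representation from collapsing.

#' BYOL pretraining configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Images per optimisation step.
#' @param lr Adam learning rate.
#' @param ema_momentum Base target-network EMA momentum in (0, 1); with
#'   `cosine_schedule = TRUE` the momentum is annealed from this value
#'   towards 1 over training (the standard BYOL schedule).
#' @param cosine_schedule Anneal the learning rate to zero and the EMA
#'   momentum to 1 with a cosine schedule over the run (default TRUE);
#'   stabilises the final epochs at small batch sizes.
#' @param pred_lr_mult Learning-rate multiplier for the predictor. The
#'   asymmetric predictor must track its optimum faster than the encoder
#'   for the online/target dynamics to align the two views; a 10x
#'   predictor rate is the usual small-batch stabilisation.
#' @param proj_dim,hidden_dim Projector output / hidden widths (the
#'   predictor mirrors the projector).
#' @param crop_scale Length-2 range of the area fraction kept by the
#'   random crop (resized back to the input size).
#' @param p_flip,p_jitter,p_blur Probabilities of horizontal flip,
#'   brightness/contrast jitter and Gaussian blur.
#' @param jitter_strength Maximum relative brightness/contrast change.
#' @param blur_sigma Length-2 range of the blur scale in pixels.
#' @param seed RNG seed for augmentation and initialisation.
#' @return Object of class `byol_config`.
#' @export
byol_config <- function(epochs = 50, batch_size = 5, lr = 3e-3,
                        ema_momentum = 0.99, cosine_schedule = TRUE,
                        pred_lr_mult = 10, proj_dim = 64,
                        hidden_dim = 256, crop_scale = c(0.6, 1),
                        p_flip = 0.5, p_jitter = 0.8, p_blur = 0.5,
                        jitter_strength = 0.4, blur_sigma = c(0.1, 1.5),
                        seed = 1) {
  if (ema_momentum <= 0 || ema_momentum >= 1)
    stop("ema_momentum must lie in (0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "byol_config")
}

#' Random augmentation of one grayscale image
#'
#' Random crop-resize, horizontal flip, brightness/contrast jitter and
#' Gaussian blur, each applied with its configured probability. Two calls
#' on the same image generally produce different views.
#'
#' @param img Matrix in \[0,1\].
#' @param cfg A [byol_config()].
#' @return Augmented matrix of the same size.
#' @export
augment_image <- function(img, cfg = byol_config()) {
  H <- nrow(img); W <- ncol(img)
  area <- runif(1, cfg$crop_scale[1], cfg$crop_scale[2])
  side <- sqrt(area)
  ch <- max(8L, round(H * side)); cw <- max(8L, round(W * side))
  i0 <- sample.int(H - ch + 1L, 1L); j0 <- sample.int(W - cw + 1L, 1L)
  out <- img[i0:(i0 + ch - 1L), j0:(j0 + cw - 1L)]
  out <- cpp_bilinear_resize(out, H, W)
  if (runif(1) < cfg$p_flip) out <- out[, rev(seq_len(ncol(out)))]
  if (runif(1) < cfg$p_jitter) {
    s <- cfg$jitter_strength
    ct <- runif(1, 1 - s, 1 + s)
    br <- runif(1, -s / 2, s / 2)
    out <- clamp01(ct * (out - 0.5) + 0.5 + br)
  }
  if (runif(1) < cfg$p_blur)
    out <- gaussian_blur(out, runif(1, cfg$blur_sigma[1], cfg$blur_sigma[2]))
  out
}

make_mlp <- function(cin, hidden, cout) {
  list(lin1 = layer_linear(cin, hidden), bn = layer_bn1d(hidden),
       relu = layer_relu(), lin2 = layer_linear(hidden, cout))
}

mlp_fwd <- function(m, X, train) {
  h <- relu_fwd(m$relu, bn1d_fwd(m$bn, linear_fwd(m$lin1, X), train))
  linear_fwd(m$lin2, h)
}

mlp_bwd <- function(m, dY) {
  dh <- linear_bwd(m$lin2, dY)
  dh <- bn1d_bwd(m$bn, relu_bwd(m$relu, dh))
  linear_bwd(m$lin1, dh)
}

mlp_layers <- function(m, prefix) {
  out <- list(m$lin1, m$bn, m$lin2)
  names(out) <- paste0(prefix, c(".lin1", ".bn", ".lin2"))
  out
}

row_normalize <- function(X) X / pmax(sqrt(rowSums(X * X)), 1e-12)

# loss and gradient of sum over rows of 2 - 2 cos(q_i, t_i); t is treated
# as constant (stop-gradient).
cosine_loss <- function(q, t) {
  qn <- row_normalize(q)
  tn <- row_normalize(t)
  s <- rowSums(qn * tn)
  nq <- pmax(sqrt(rowSums(q * q)), 1e-12)
  dq <- -2 * (tn - s * qn) / nq
  list(loss = 2 - 2 * s, dq = dq)
}

#' BYOL pretraining of the ResNet18 encoder on unlabeled images
#'
#' @param images List of grayscale matrices (all the same size, a multiple
#'   of 32); at least 2.
#' @param cfg A [byol_config()].
#' @param net_cfg A [net_config()] fixing encoder width and input size.
#' @param verbose Print the per-epoch mean loss.
#' @return List with `encoder_state` (named parameter list for
#'   [transfer_and_finetune()]), `loss_trace` (per-epoch mean symmetrised
#'   loss) and `encoder` (the trained encoder object).
#' @export
byol_pretrain <- function(images, cfg = byol_config(),
                          net_cfg = net_config(), verbose = FALSE) {
  if (length(images) < 2)
    stop("BYOL needs at least 2 images", call. = FALSE)
  set.seed(cfg$seed)
  enc <- resnet_encoder(net_cfg$in_channels, net_cfg$width_multiplier)
  feat_dim <- enc$channels[5]
  proj <- make_mlp(feat_dim, cfg$hidden_dim, cfg$proj_dim)
  pred <- make_mlp(cfg$proj_dim, cfg$hidden_dim, cfg$proj_dim)
  gap_on <- new_layer("gap", params = character(0))
  gap_tg <- new_layer("gap", params = character(0))
  # target = EMA copies of encoder and projector
  enc_t <- resnet_encoder(net_cfg$in_channels, net_cfg$width_multiplier)
  proj_t <- make_mlp(feat_dim, cfg$hidden_dim, cfg$proj_dim)
  base_layers <- c(enc_layers(enc), mlp_layers(proj, "proj"))
  pred_layers <- mlp_layers(pred, "pred")
  on_layers <- c(base_layers, pred_layers)
  tg_layers <- c(enc_layers(enc_t), mlp_layers(proj_t, "proj"))
  on_ema_layers <- c(enc_layers(enc), mlp_layers(proj, "proj"))
  load_layers_state(tg_layers, layers_state(on_ema_layers))

  online_branch <- function(X, t_const) {
    s <- enc_fwd(enc, X, TRUE)
    z <- mlp_fwd(proj, gap_fwd_nc(gap_on, s$s4), TRUE)
    q <- mlp_fwd(pred, z, TRUE)
    cl <- cosine_loss(q, t_const)
    # mean over batch, halved for the two-view symmetrisation
    scale <- 0.5 / nrow(q)
    dz <- mlp_bwd(pred, cl$dq * scale)
    ds4 <- gap_bwd_nc(gap_on, mlp_bwd(proj, dz))
    enc_bwd(enc, list(s0 = NULL, s1 = NULL, s2 = NULL, s3 = NULL, s4 = ds4))
    mean(cl$loss)
  }
  # The target runs on its EMA-tracked running statistics rather than the
  # current batch's: at batch size 5, batch statistics make the regression
  # target itself noisy, raising the attainable loss floor.
  target_proj <- function(X) {
    s <- enc_fwd(enc_t, X, FALSE)
    mlp_fwd(proj_t, gap_fwd_nc(gap_tg, s$s4), FALSE)
  }

  n <- length(images)
  steps_per_epoch <- length(seq(1, n, cfg$batch_size))
  total_steps <- max(1L, cfg$epochs * steps_per_epoch)
  step <- 0L
  loss_trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_losses <- c()
    for (start in seq(1, n, cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      if (length(idx) < 2) next    # BN needs more than one sample
      v1 <- as_batch(lapply(images[idx], augment_image, cfg = cfg))
      v2 <- as_batch(lapply(images[idx], augment_image, cfg = cfg))
      t1 <- target_proj(v1)
      t2 <- target_proj(v2)
      zero_grads(on_layers)
      l_a <- online_branch(v1, t2)
      l_b <- online_branch(v2, t1)
      step <- step + 1L
      frac <- if (cfg$cosine_schedule) {
        0.5 * (1 + cos(pi * (step - 1L) / total_steps))
      } else 1
      adam_step(base_layers, lr = cfg$lr * frac, t = step)
      adam_step(pred_layers, lr = cfg$lr * cfg$pred_lr_mult * frac,
                t = step)
      # EMA target update; momentum annealed towards 1 under the schedule
      tau <- 1 - (1 - cfg$ema_momentum) * frac
      for (nm in names(tg_layers)) {
        lt <- tg_layers[[nm]]; lo <- on_ema_layers[[nm]]
        for (p in c(lt$params, "rm", "rv"))
          if (!is.null(lt[[p]]))
            lt[[p]] <- tau * lt[[p]] + (1 - tau) * lo[[p]]
      }
      ep_losses <- c(ep_losses, (l_a + l_b) / 2)
    }
    loss_trace[ep] <- mean(ep_losses)
    if (verbose)
      message(sprintf("epoch %3d  byol loss %.4f", ep, loss_trace[ep]))
  }
  list(encoder_state = layers_state(enc_layers(enc)),
       loss_trace = loss_trace, encoder = enc)
}
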