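# Supervised training of the U-Net+ResNet18 on labeled vein images, with
# optional transfer of a BYOL-pretrained encoder, plus inference.

#' Fine-tuning configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Images per optimisation step.
#' @param lr Adam learning rate.
#' @param val_fraction Fraction of the labeled set held out for the
#'   per-epoch metric traces (0 disables validation).
#' @param seed RNG seed (shuffling, augmentation-free here).
#' @param record_hd Also compute the Hausdorff distance per epoch (the
#'   most expensive metric; off by default).
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 60, batch_size = 5, lr = 1e-3,
                         val_fraction = 0.2, seed = 1, record_hd = FALSE) {
  structure(as.list(environment()), class = "train_config")
}

bce_grad <- function(prob, labels) {
  # gradient of mean BCE w.r.t. the logits of a sigmoid output
  (prob - labels) / length(prob)
}

#' Transfer a pretrained encoder and fine-tune the segmentation network
#'
#' Loads the encoder parameters (shape-checked per layer) into a freshly
#' built U-Net+ResNet18 and trains all layers on the labeled images with
#' mean binary cross-entropy. Per-epoch BCE/IoU/Dice (optionally HD) are
#' recorded on a held-out split and the parameters with the best
#' validation Dice are kept. `encoder_state = NULL` trains from random
#' initialisation.
#'
#' @param encoder_state Named parameter list from [byol_pretrain()], or
#'   `NULL`.
#' @param labeled List of `list(image = <matrix>, mask = <binary matrix>)`.
#' @param cfg A [train_config()].
#' @param net_cfg A [net_config()].
#' @return List with `net` (best-Dice parameters restored), `state`
#'   (per-epoch traces: `train_bce`, `train_bce_batch_sum`, and on the
#'   validation split `bce`, `iou`, `dice`, `hd`), `best_epoch`.
#' @export
transfer_and_finetune <- function(encoder_state, labeled,
                                  cfg = train_config(),
                                  net_cfg = net_config()) {
  set.seed(cfg$seed)
  net <- build_network(net_cfg)
  if (!is.null(encoder_state))
    load_layers_state(enc_layers(net$enc), encoder_state)
  layers <- unet_layers(net)
  n <- length(labeled)
  n_val <- if (cfg$val_fraction > 0 && n >= 5)
    max(1L, round(cfg$val_fraction * n)) else 0L
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  traces <- list(train_bce = numeric(0), train_bce_batch_sum = numeric(0),
                 bce = numeric(0), iou = numeric(0), dice = numeric(0),
                 hd = numeric(0))
  best <- list(dice = -Inf, state = NULL, epoch = 0L)
  step <- 0L
  for (ep in seq_len(max(cfg$epochs, 0))) {
    ord <- sample(tr_idx)
    batch_bces <- c()
    for (start in seq(1, length(ord), cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      X <- as_batch(lapply(labeled[idx], `[[`, "image"))
      Y <- as_batch(lapply(labeled[idx], function(s)
        matrix(as.numeric(s$mask > 0), nrow(s$mask), ncol(s$mask))))
      zero_grads(layers)
      prob <- unet_fwd(net, X, train = TRUE)
      batch_bces <- c(batch_bces, bce(prob, Y))
      unet_bwd(net, bce_grad(prob, Y))
      step <- step + 1L
      adam_step(layers, lr = cfg$lr, t = step)
    }
    traces$train_bce <- c(traces$train_bce, mean(batch_bces))
    # reporting convention: per-epoch sum of the batch-average BCEs
    traces$train_bce_batch_sum <- c(traces$train_bce_batch_sum,
                                    sum(batch_bces))
    if (n_val > 0) {
      vm <- evaluate_net(net, labeled[val_idx], record_hd = cfg$record_hd)
      traces$bce <- c(traces$bce, vm$bce)
      traces$iou <- c(traces$iou, vm$iou)
      traces$dice <- c(traces$dice, vm$dice)
      traces$hd <- c(traces$hd, vm$hd)
      if (vm$dice > best$dice)
        best <- list(dice = vm$dice, state = layers_state(layers),
                     epoch = ep)
    }
  }
  if (!is.null(best$state)) load_layers_state(layers, best$state)
  list(net = net, state = traces,
       best_epoch = if (n_val > 0) best$epoch else cfg$epochs)
}

# mean metrics of a network over a labeled set (eval mode)
evaluate_net <- function(net, labeled, record_hd = FALSE) {
  ms <- lapply(labeled, function(s) {
    p <- segment(net, s$image)$prob
    cc <- confusion(matrix(as.integer(p >= 0.5), nrow(p), ncol(p)),
                    matrix(as.integer(s$mask > 0), nrow(p), ncol(p)))
    hd <- NA_real_
    if (record_hd) {
      bp <- boundary_points(p >= 0.5); bl <- boundary_points(s$mask)
      if (nrow(bp) > 0 && nrow(bl) > 0) hd <- hausdorff(bp, bl)
    }
    c(bce = bce(p, s$mask > 0), iou = iou(cc), dice = dice(cc), hd = hd)
  })
  m <- do.call(rbind, ms)
  list(bce = mean(m[, "bce"]), iou = mean(m[, "iou"]),
       dice = mean(m[, "dice"]),
       hd = if (record_hd) mean(m[, "hd"], na.rm = TRUE) else NA_real_)
}

#' Segment a vein image with a trained network
#'
#' The image is reflection-padded to the next multiple of 32, passed
#' through the network in inference mode (batch-norm running statistics),
#' un-padded, and thresholded at probability 0.5 (`>= 0.5` is foreground).
#'
#' @param net A trained [build_network()] object.
#' @param img Grayscale matrix in \[0,1\].
#' @param threshold Probability threshold (foreground at `prob >=
#'   threshold`).
#' @return List with `prob` (probability map) and `mask` (binary matrix).
#' @export
segment <- function(net, img, threshold = 0.5) {
  assert_gray(img)
  H <- nrow(img); W <- ncol(img)
  Hp <- 32 * ceiling(H / 32); Wp <- 32 * ceiling(W / 32)
  pad <- img
  if (Hp > H) pad <- rbind(pad, pad[H:(2 * H - Hp + 1), , drop = FALSE])
  if (Wp > W) pad <- cbind(pad, pad[, W:(2 * W - Wp + 1), drop = FALSE])
  X <- array(pad, c(Hp, Wp, 1, 1))
  prob <- unet_fwd(net, X, train = FALSE)[seq_len(H), seq_len(W), 1, 1]
  prob <- matrix(prob, H, W)
  list(prob = prob,
       mask = matrix(as.integer(prob >= threshold), H, W))
}

#' Save / load a network checkpoint
#'
#' Single-file RDS holding the configuration and all parameters with
#' batch-norm running statistics.
#'
#' @param net Network object.
#' @param path Destination file.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(cfg = net$cfg, state = layers_state(unet_layers(net))), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$cfg)
  load_layers_state(unet_layers(net), ck$state)
  net
}
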