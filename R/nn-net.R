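# ResNet18 encoder and U-Net decoder assembly.
#
# The encoder is the standard ResNet18 layout (7x7 stem, 3x3 max-pool,
# four stages of two basic residual blocks, channels 64/64/128/256/512
# scaled by a width multiplier). The U-Net keeps its decoder and skip
# connections: each decoder stage 2x-upsamples, concatenates the matching
# encoder stage and applies two 3x3 conv+BN+ReLU blocks; a final 1x1
# convolution and sigmoid yield per-pixel vein probabilities at the input
# resolution.

scaled_ch <- function(base, width) max(4L, as.integer(round(base * width)))

make_basic_block <- function(cin, cout, stride) {
  blk <- list(
    conv1 = layer_conv(cin, cout, 3, stride),
    bn1 = layer_bn2d(cout),
    relu1 = layer_relu(),
    conv2 = layer_conv(cout, cout, 3, 1),
    bn2 = layer_bn2d(cout),
    relu2 = layer_relu())
  if (stride != 1 || cin != cout) {
    blk$convd <- layer_conv(cin, cout, 1, stride, pad = 0)
    blk$bnd <- layer_bn2d(cout)
  }
  blk
}

block_fwd <- function(blk, X, train) {
  h <- conv_fwd(blk$conv1, X)
  h <- bn2d_fwd(blk$bn1, h, train)
  h <- relu_fwd(blk$relu1, h)
  h <- conv_fwd(blk$conv2, h)
  h <- bn2d_fwd(blk$bn2, h, train)
  sc <- if (!is.null(blk$convd))
    bn2d_fwd(blk$bnd, conv_fwd(blk$convd, X), train) else X
  relu_fwd(blk$relu2, h + sc)
}

block_bwd <- function(blk, dY) {
  dy <- relu_bwd(blk$relu2, dY)
  dh <- bn2d_bwd(blk$bn2, dy)
  dh <- conv_bwd(blk$conv2, dh)
  dh <- relu_bwd(blk$relu1, dh)
  dh <- bn2d_bwd(blk$bn1, dh)
  dX <- conv_bwd(blk$conv1, dh)
  dsc <- if (!is.null(blk$convd))
    conv_bwd(blk$convd, bn2d_bwd(blk$bnd, dy)) else dy
  dX + dsc
}

#' @noRd
resnet_encoder <- function(in_channels = 1, width = 0.25) {
  ch <- vapply(c(64, 64, 128, 256, 512), scaled_ch, 1L, width = width)
  enc <- new.env(parent = emptyenv())
  enc$width <- width
  enc$in_channels <- in_channels
  enc$channels <- ch
  enc$stem_conv <- layer_conv(in_channels, ch[1], 7, 2, 3)
  enc$stem_bn <- layer_bn2d(ch[1])
  enc$stem_relu <- layer_relu()
  enc$pool <- layer_maxpool(3, 2, 1)
  strides <- c(1, 2, 2, 2)
  enc$stages <- lapply(1:4, function(s) {
    cin <- if (s == 1) ch[1] else ch[s]
    cout <- ch[s + 1]
    list(make_basic_block(cin, cout, strides[s]),
         make_basic_block(cout, cout, 1))
  })
  enc
}

enc_layers <- function(enc) {
  out <- list(stem_conv = enc$stem_conv, stem_bn = enc$stem_bn)
  for (s in 1:4) for (b in 1:2) {
    blk <- enc$stages[[s]][[b]]
    for (nm in names(blk))
      if (!is.null(blk[[nm]]$params) && length(blk[[nm]]$params))
        out[[sprintf("stage%d.block%d.%s", s, b, nm)]] <- blk[[nm]]
  }
  out
}

enc_fwd <- function(enc, X, train = TRUE) {
  s0 <- relu_fwd(enc$stem_relu, bn2d_fwd(enc$stem_bn,
                                         conv_fwd(enc$stem_conv, X), train))
  h <- maxpool_fwd(enc$pool, s0)
  outs <- vector("list", 4)
  for (s in 1:4) {
    for (b in 1:2) h <- block_fwd(enc$stages[[s]][[b]], h, train)
    outs[[s]] <- h
  }
  list(s0 = s0, s1 = outs[[1]], s2 = outs[[2]], s3 = outs[[3]],
       s4 = outs[[4]])
}

# ds: list of gradients for s0..s4 (NULL entries are zero)
enc_bwd <- function(enc, ds) {
  g <- ds$s4
  for (s in 4:1) {
    for (b in 2:1) g <- block_bwd(enc$stages[[s]][[b]], g)
    if (s > 1 && !is.null(ds[[paste0("s", s - 1)]]))
      g <- g + ds[[paste0("s", s - 1)]]
  }
  g <- maxpool_bwd(enc$pool, g)
  if (!is.null(ds$s0)) g <- g + ds$s0
  g <- relu_bwd(enc$stem_relu, g)
  g <- bn2d_bwd(enc$stem_bn, g)
  conv_bwd(enc$stem_conv, g)
}

make_dec_block <- function(cin, cout) {
  list(conv1 = layer_conv(cin, cout, 3, 1), bn1 = layer_bn2d(cout),
       relu1 = layer_relu(),
       conv2 = layer_conv(cout, cout, 3, 1), bn2 = layer_bn2d(cout),
       relu2 = layer_relu())
}

dec_block_fwd <- function(blk, X, train) {
  h <- relu_fwd(blk$relu1, bn2d_fwd(blk$bn1, conv_fwd(blk$conv1, X), train))
  relu_fwd(blk$relu2, bn2d_fwd(blk$bn2, conv_fwd(blk$conv2, h), train))
}

dec_block_bwd <- function(blk, dY) {
  dh <- conv_bwd(blk$conv2, bn2d_bwd(blk$bn2, relu_bwd(blk$relu2, dY)))
  conv_bwd(blk$conv1, bn2d_bwd(blk$bn1, relu_bwd(blk$relu1, dh)))
}

#' Network configuration for the U-Net with ResNet18 encoder
#'
#' @param in_channels Input channels (1 for NIR grayscale).
#' @param input_size Nominal square input size in pixels; must be a
#'   multiple of 32 (five 2x downsamplings). The network itself is fully
#'   convolutional and accepts any multiple-of-32 size.
#' @param width_multiplier Channel scaling of the whole network; 1 is the
#'   full ResNet18 width (64/64/128/256/512), 0.25 the reduced desk-scale
#'   profile used throughout the tests.
#' @return Object of class `net_config`.
#' @export
net_config <- function(in_channels = 1, input_size = 96,
                       width_multiplier = 0.25) {
  if (input_size %% 32 != 0)
    stop("input_size must be a multiple of 32", call. = FALSE)
  structure(list(in_channels = in_channels, input_size = input_size,
                 width_multiplier = width_multiplier), class = "net_config")
}

#' Build the U-Net+ResNet18 segmentation network
#'
#' Forward maps an (H, W, 1, N) batch to per-pixel vein probabilities of
#' the same spatial size. With all residual-branch weights zero each
#' encoder block reduces to the identity (plus the 1x1 projection on
#' downsampling blocks).
#'
#' @param cfg A [net_config()].
#' @return Network object (class `unet_resnet18`).
#' @export
build_network <- function(cfg = net_config()) {
  w <- cfg$width_multiplier
  enc <- resnet_encoder(cfg$in_channels, w)
  ch <- enc$channels
  dec_out <- c(ch[4], ch[3], ch[2], ch[2])
  skip_ch <- c(ch[4], ch[3], ch[2], ch[1])
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$enc <- enc
  net$up <- lapply(1:5, function(i) new_layer("up2", params = character(0)))
  cin_prev <- ch[5]
  net$dec <- vector("list", 4)
  for (i in 1:4) {
    net$dec[[i]] <- make_dec_block(cin_prev + skip_ch[i], dec_out[i])
    cin_prev <- dec_out[i]
  }
  fch <- scaled_ch(32, w)
  net$fconv <- layer_conv(cin_prev, fch, 3, 1)
  net$fbn <- layer_bn2d(fch)
  net$frelu <- layer_relu()
  net$head <- layer_conv(fch, 1, 1, 1, pad = 0, bias = TRUE)
  class(net) <- "unet_resnet18"
  net
}

unet_layers <- function(net) {
  out <- enc_layers(net$enc)
  names(out) <- paste0("enc.", names(out))
  for (i in 1:4) {
    blk <- net$dec[[i]]
    for (nm in names(blk))
      if (length(blk[[nm]]$params))
        out[[sprintf("dec%d.%s", i, nm)]] <- blk[[nm]]
  }
  out$fconv <- net$fconv
  out$fbn <- net$fbn
  out$head <- net$head
  out
}

unet_fwd <- function(net, X, train = TRUE) {
  s <- enc_fwd(net$enc, X, train)
  skips <- list(s$s3, s$s2, s$s1, s$s0)
  d <- s$s4
  net$cat_ch <- integer(4)
  for (i in 1:4) {
    d <- up2_fwd(net$up[[i]], d)
    net$cat_ch[i] <- dim(d)[3]
    d <- abind4(d, skips[[i]])
    d <- dec_block_fwd(net$dec[[i]], d, train)
  }
  d <- up2_fwd(net$up[[5]], d)
  d <- relu_fwd(net$frelu, bn2d_fwd(net$fbn, conv_fwd(net$fconv, d), train))
  logits <- conv_fwd(net$head, d)
  1 / (1 + exp(-logits))
}

# gradient w.r.t. logits in, full backward pass
unet_bwd <- function(net, dlogits) {
  dd <- conv_bwd(net$head, dlogits)
  dd <- conv_bwd(net$fconv, bn2d_bwd(net$fbn, relu_bwd(net$frelu, dd)))
  dd <- up2_bwd(net$up[[5]], dd)
  ds <- list(s0 = NULL, s1 = NULL, s2 = NULL, s3 = NULL, s4 = NULL)
  skip_names <- c("s3", "s2", "s1", "s0")
  for (i in 4:1) {
    dcat <- dec_block_bwd(net$dec[[i]], dd)
    cu <- net$cat_ch[i]
    dup <- dcat[, , seq_len(cu), , drop = FALSE]
    ds[[skip_names[i]]] <- dcat[, , -seq_len(cu), , drop = FALSE]
    dd <- up2_bwd(net$up[[i]], dup)
  }
  ds$s4 <- dd
  enc_bwd(net$enc, ds)
}

# concatenate two (H, W, C, N) arrays along channels
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2], da[4] == db[4])
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# batch a list of matrices into an (H, W, 1, N) array
as_batch <- function(imgs) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  array(unlist(imgs), c(H, W, 1, length(imgs)))
}

#' Number of trainable parameters of a network
#' @param net A [build_network()] result or an encoder.
#' @export
count_params <- function(net) {
  layers <- if (inherits(net, "unet_resnet18")) unet_layers(net)
            else enc_layers(net)
  sum(vapply(layers, function(l)
    sum(vapply(l$params, function(p) length(l[[p]]), 1)), 1))
}
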