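# Convolutional backbone registry.
#
# Each builder returns list(layers, feature_dim): a layer sequence mapping a
# 224 x 224 x 3 image to a spatial feature tensor, and the channel count
# after global average pooling. Topologies follow the canonical published
# designs; weights are randomly initialized (He scaling) unless loaded from a
# checkpoint. The "tiny" backbone is a compact 3-stage CNN provided for fast
# desk-scale experiments and tests.

bb_conv_bn_relu <- function(prefix, in_ch, out_ch, k, stride = 1L, pad = NULL) {
  list(layer_conv(paste0(prefix, "_conv"), in_ch, out_ch, k = k,
                  stride = stride, pad = pad, init = "he"),
       layer_bn(paste0(prefix, "_bn"), out_ch, spatial = TRUE),
       layer_act(paste0(prefix, "_relu"), "relu"))
}

# basic residual block (3x3 + 3x3), used by ResNet-18
bb_basic_block <- function(prefix, in_ch, out_ch, stride) {
  body <- c(
    bb_conv_bn_relu(paste0(prefix, "_a"), in_ch, out_ch, 3L, stride),
    list(layer_conv(paste0(prefix, "_b_conv"), out_ch, out_ch, 3L, init = "he"),
         layer_bn(paste0(prefix, "_b_bn"), out_ch, spatial = TRUE))
  )
  shortcut <- if (stride != 1L || in_ch != out_ch)
    list(layer_conv(paste0(prefix, "_sc_conv"), in_ch, out_ch, 1L,
                    stride = stride, pad = 0L, init = "he"),
         layer_bn(paste0(prefix, "_sc_bn"), out_ch, spatial = TRUE))
  else list()
  layer_residual(prefix, body, shortcut)
}

# bottleneck residual block (1x1 reduce, 3x3, 1x1 expand), ResNet-50/101
bb_bottleneck_block <- function(prefix, in_ch, mid_ch, out_ch, stride) {
  body <- c(
    bb_conv_bn_relu(paste0(prefix, "_a"), in_ch, mid_ch, 1L, stride, pad = 0L),
    bb_conv_bn_relu(paste0(prefix, "_b"), mid_ch, mid_ch, 3L),
    list(layer_conv(paste0(prefix, "_c_conv"), mid_ch, out_ch, 1L, pad = 0L,
                    init = "he"),
         layer_bn(paste0(prefix, "_c_bn"), out_ch, spatial = TRUE))
  )
  shortcut <- if (stride != 1L || in_ch != out_ch)
    list(layer_conv(paste0(prefix, "_sc_conv"), in_ch, out_ch, 1L,
                    stride = stride, pad = 0L, init = "he"),
         layer_bn(paste0(prefix, "_sc_bn"), out_ch, spatial = TRUE))
  else list()
  layer_residual(prefix, body, shortcut)
}

bb_resnet <- function(depth) {
  stem <- c(bb_conv_bn_relu("stem", 3L, 64L, 7L, stride = 2L, pad = 3L),
            list(layer_maxpool("stem_pool", 3L, 2L, 1L)))
  if (depth == 18L) {
    counts <- c(2L, 2L, 2L, 2L)
    chans <- c(64L, 128L, 256L, 512L)
    layers <- stem
    in_ch <- 64L
    for (s in 1:4) {
      for (b in seq_len(counts[s])) {
        stride <- if (s > 1L && b == 1L) 2L else 1L
        layers <- c(layers, list(bb_basic_block(
          sprintf("s%db%d", s, b), in_ch, chans[s], stride)))
        in_ch <- chans[s]
      }
    }
    return(list(layers = layers, feature_dim = 512L))
  }
  counts <- if (depth == 50L) c(3L, 4L, 6L, 3L) else c(3L, 4L, 23L, 3L)
  mids <- c(64L, 128L, 256L, 512L)
  outs <- mids * 4L
  layers <- stem
  in_ch <- 64L
  for (s in 1:4) {
    for (b in seq_len(counts[s])) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      layers <- c(layers, list(bb_bottleneck_block(
        sprintf("s%db%d", s, b), in_ch, mids[s], outs[s], stride)))
      in_ch <- outs[s]
    }
  }
  list(layers = layers, feature_dim = 2048L)
}

bb_vgg <- function(depth) {
  cfg <- if (depth == 16L)
    list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
         c(512L, 512L, 512L), c(512L, 512L, 512L))
  else
    list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L, 256L),
         c(512L, 512L, 512L, 512L), c(512L, 512L, 512L, 512L))
  layers <- list()
  in_ch <- 3L
  for (s in seq_along(cfg)) {
    for (b in seq_along(cfg[[s]])) {
      layers <- c(layers,
                  list(layer_conv(sprintf("s%db%d_conv", s, b), in_ch,
                                  cfg[[s]][b], 3L, init = "he"),
                       layer_act(sprintf("s%db%d_relu", s, b), "relu")))
      in_ch <- cfg[[s]][b]
    }
    layers <- c(layers, list(layer_maxpool(sprintf("s%d_pool", s), 2L, 2L)))
  }
  list(layers = layers, feature_dim = 512L)
}

# Inception branch helper: a chain of conv-bn-relu units described by
# (out_ch, k, stride, pad) rows
bb_inc_chain <- function(prefix, in_ch, spec) {
  layers <- list()
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    layers <- c(layers, bb_conv_bn_relu(sprintf("%s_%d", prefix, i), in_ch,
                                        s[1], s[2], s[3], s[4]))
    in_ch <- s[1]
  }
  layers
}

bb_inception_a <- function(prefix, in_ch, pool_ch) {
  layer_branch_concat(prefix, list(
    bb_inc_chain(paste0(prefix, "_b1"), in_ch, list(c(64L, 1L, 1L, 0L))),
    bb_inc_chain(paste0(prefix, "_b2"), in_ch,
                 list(c(48L, 1L, 1L, 0L), c(64L, 5L, 1L, 2L))),
    bb_inc_chain(paste0(prefix, "_b3"), in_ch,
                 list(c(64L, 1L, 1L, 0L), c(96L, 3L, 1L, 1L), c(96L, 3L, 1L, 1L))),
    c(list(layer_avgpool(paste0(prefix, "_b4_pool"), 3L, 1L, 1L)),
      bb_inc_chain(paste0(prefix, "_b4"), in_ch, list(c(pool_ch, 1L, 1L, 0L))))
  ))
}

bb_reduction_a <- function(prefix, in_ch) {
  layer_branch_concat(prefix, list(
    bb_inc_chain(paste0(prefix, "_b1"), in_ch, list(c(384L, 3L, 2L, 0L))),
    bb_inc_chain(paste0(prefix, "_b2"), in_ch,
                 list(c(64L, 1L, 1L, 0L), c(96L, 3L, 1L, 1L), c(96L, 3L, 2L, 0L))),
    list(layer_maxpool(paste0(prefix, "_b3_pool"), 3L, 2L, 0L))
  ))
}

# 7x7 factorized module; the 1x7/7x1 pair is approximated by a same-padded
# square kernel of width 7 to keep the engine's kernel model simple
bb_inception_b <- function(prefix, in_ch, mid) {
  layer_branch_concat(prefix, list(
    bb_inc_chain(paste0(prefix, "_b1"), in_ch, list(c(192L, 1L, 1L, 0L))),
    bb_inc_chain(paste0(prefix, "_b2"), in_ch,
                 list(c(mid, 1L, 1L, 0L), c(192L, 7L, 1L, 3L))),
    bb_inc_chain(paste0(prefix, "_b3"), in_ch,
                 list(c(mid, 1L, 1L, 0L), c(mid, 7L, 1L, 3L), c(192L, 7L, 1L, 3L))),
    c(list(layer_avgpool(paste0(prefix, "_b4_pool"), 3L, 1L, 1L)),
      bb_inc_chain(paste0(prefix, "_b4"), in_ch, list(c(192L, 1L, 1L, 0L))))
  ))
}

bb_reduction_b <- function(prefix, in_ch) {
  layer_branch_concat(prefix, list(
    bb_inc_chain(paste0(prefix, "_b1"), in_ch,
                 list(c(192L, 1L, 1L, 0L), c(320L, 3L, 2L, 0L))),
    bb_inc_chain(paste0(prefix, "_b2"), in_ch,
                 list(c(192L, 1L, 1L, 0L), c(192L, 7L, 1L, 3L), c(192L, 3L, 2L, 0L))),
    list(layer_maxpool(paste0(prefix, "_b3_pool"), 3L, 2L, 0L))
  ))
}

bb_inception_c <- function(prefix, in_ch) {
  layer_branch_concat(prefix, list(
    bb_inc_chain(paste0(prefix, "_b1"), in_ch, list(c(320L, 1L, 1L, 0L))),
    bb_inc_chain(paste0(prefix, "_b2"), in_ch,
                 list(c(384L, 1L, 1L, 0L), c(768L, 3L, 1L, 1L))),
    bb_inc_chain(paste0(prefix, "_b3"), in_ch,
                 list(c(448L, 1L, 1L, 0L), c(384L, 3L, 1L, 1L), c(768L, 3L, 1L, 1L))),
    c(list(layer_avgpool(paste0(prefix, "_b4_pool"), 3L, 1L, 1L)),
      bb_inc_chain(paste0(prefix, "_b4"), in_ch, list(c(192L, 1L, 1L, 0L))))
  ))
}

bb_inception_v3 <- function() {
  layers <- c(
    bb_conv_bn_relu("stem1", 3L, 32L, 3L, 2L, 0L),
    bb_conv_bn_relu("stem2", 32L, 32L, 3L, 1L, 0L),
    bb_conv_bn_relu("stem3", 32L, 64L, 3L, 1L, 1L),
    list(layer_maxpool("stem_pool1", 3L, 2L, 0L)),
    bb_conv_bn_relu("stem4", 64L, 80L, 1L, 1L, 0L),
    bb_conv_bn_relu("stem5", 80L, 192L, 3L, 1L, 0L),
    list(layer_maxpool("stem_pool2", 3L, 2L, 0L)),
    list(bb_inception_a("incA1", 192L, 32L),
         bb_inception_a("incA2", 256L, 64L),
         bb_inception_a("incA3", 288L, 64L),
         bb_reduction_a("redA", 288L),
         bb_inception_b("incB1", 768L, 128L),
         bb_inception_b("incB2", 768L, 160L),
         bb_inception_b("incB3", 768L, 160L),
         bb_inception_b("incB4", 768L, 192L),
         bb_reduction_b("redB", 768L),
         bb_inception_c("incC1", 1280L),
         bb_inception_c("incC2", 2048L))
  )
  list(layers = layers, feature_dim = 2048L)
}

bb_tiny <- function() {
  layers <- list()
  chans <- c(8L, 16L, 32L)
  in_ch <- 3L
  for (s in seq_along(chans)) {
    layers <- c(layers,
                list(layer_conv(sprintf("t%d_conv", s), in_ch, chans[s], 3L,
                                stride = 2L, init = "he"),
                     layer_bn(sprintf("t%d_bn", s), chans[s], spatial = TRUE),
                     layer_act(sprintf("t%d_relu", s), "relu"),
                     layer_maxpool(sprintf("t%d_pool", s), 2L, 2L)))
    in_ch <- chans[s]
  }
  list(layers = layers, feature_dim = 32L)
}

#' Available classification backbones
#'
#' @return character vector of registered backbone names.
#' @export
backbone_names <- function() {
  c("RESNET50", "VGG16", "INCEPTIONV3", "RESNET101", "VGG19", "RESNET18",
    "TINY")
}

#' Build a convolutional backbone
#'
#' Constructs the convolutional stack of a registered topology with randomly
#' initialized (He-scaled) weights. `TINY` is a compact 3-stage CNN intended
#' for fast CPU experiments.
#'
#' @param name backbone name, one of [backbone_names()] (case-insensitive).
#' @param seed integer seed for weight initialization.
#' @return a list with `layers` (the layer sequence), `feature_dim` (channel
#'   count after global average pooling) and `name`.
#' @export
build_backbone <- function(name, seed = 0L) {
  key <- toupper(name)
  if (!key %in% backbone_names())
    stop("configuration error: unknown backbone '", name, "'; available: ",
         paste(backbone_names(), collapse = ", "))
  old <- local_rng(seed)
  on.exit(restore_rng(old), add = TRUE)
  bb <- switch(key,
    RESNET18 = bb_resnet(18L),
    RESNET50 = bb_resnet(50L),
    RESNET101 = bb_resnet(101L),
    VGG16 = bb_vgg(16L),
    VGG19 = bb_vgg(19L),
    INCEPTIONV3 = bb_inception_v3(),
    TINY = bb_tiny())
  bb$name <- key
  bb
}

# forward an image through a backbone to the pooled feature vector
backbone_features <- function(backbone, px) {
  out <- seq_fwd(backbone$layers, px, training = FALSE, need_cache = FALSE)$out
  d <- dim(out)
  colMeans(matrix(out, d[1] * d[2], d[3]))
}
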