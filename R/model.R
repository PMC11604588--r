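#' FusionNet architecture configuration
#'
#' Hyperparameters of the dual-decoder fusion network: a shared VGG16-style
#' 3D convolutional encoder feeding both a skip-connection (U-Net-style)
#' decoder and a pooling-index (SegNet-style) decoder, whose full-resolution
#' feature maps are joined by the fusion head before a shared 1x1x1 voxelwise
#' classifier.
#'
#' @param in_channels Number of input MRI modalities (1-4 typical).
#' @param num_classes Number of output labels (default 4: background,
#'   necrotic core, peritumoral edema, enhancing tumor).
#' @param base_width Channels in the first encoder block (default 8).
#'   Subsequent blocks double the width, capped at `max_width`.
#' @param num_blocks Number of encoder blocks, each ending in a 2x max-pooling
#'   (default 5, the VGG16 depth with 13 convolutional layers).
#' @param fusion_mode How the two decoders' outputs are joined: `"A"`
#'   (elementwise addition), `"M"` (elementwise multiplication) or `"C"`
#'   (channel concatenation).
#' @param input_edge Cubic input edge length in voxels; must be divisible by
#'   `2^num_blocks`. Default 256; desk-scale runs use 32 or 64.
#' @param max_width Cap on per-block channel width (default unbounded).
#' @return An object of class `fusionnet_config`.
#' @export
fusionnet_config <- function(in_channels,
                             num_classes = 4L,
                             base_width = 8L,
                             num_blocks = 5L,
                             fusion_mode = c("A", "M", "C"),
                             input_edge = 256L,
                             max_width = Inf) {
  fusion_mode <- match.arg(fusion_mode)
  in_channels <- as.integer(in_channels)
  num_classes <- as.integer(num_classes)
  base_width <- as.integer(base_width)
  num_blocks <- as.integer(num_blocks)
  input_edge <- as.integer(input_edge)
  if (in_channels < 1L) stop("in_channels must be >= 1")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (base_width < 1L) stop("base_width must be >= 1")
  if (num_blocks < 1L) stop("num_blocks must be >= 1")
  if (input_edge %% 2L^num_blocks != 0L)
    stop(sprintf("input_edge (%d) must be divisible by 2^num_blocks (%d)",
                 input_edge, 2L^num_blocks))
  widths <- pmin(base_width * 2L^(seq_len(num_blocks) - 1L), max_width)
  # VGG16 convolutional layout: (2, 2, 3, 3, 3) convs per block = 13 layers
  vgg <- c(2L, 2L, 3L, 3L, 3L)
  n_convs <- if (num_blocks <= 5L) vgg[seq_len(num_blocks)] else
    c(vgg, rep(3L, num_blocks - 5L))
  structure(
    list(in_channels = in_channels, num_classes = num_classes,
         base_width = base_width, num_blocks = num_blocks,
         fusion_mode = fusion_mode, input_edge = input_edge,
         widths = as.integer(widths), convs_per_block = n_convs),
    class = "fusionnet_config")
}

#' @export
print.fusionnet_config <- function(x, ...) {
  cat(sprintf(
    "FusionNet-%s config: %d modalities -> %d classes, edge %d, %d blocks, widths %s, %d conv layers\n",
    x$fusion_mode, x$in_channels, x$num_classes, x$input_edge, x$num_blocks,
    paste(x$widths, collapse = "/"), sum(x$convs_per_block)))
  invisible(x)
}

#' Build a FusionNet model
#'
#' Instantiates all trainable parameters (He-initialized convolution weights,
#' batch-norm scale/shift, classifier) for the configuration.
#'
#' @param config A [fusionnet_config()].
#' @param seed Optional integer; when given, parameter initialization is
#'   seed-deterministic.
#' @return An object of class `fusionnet` holding `config` and `params`.
#' @export
build_fusionnet <- function(config, seed = NULL) {
  stopifnot(inherits(config, "fusionnet_config"))
  if (!is.null(seed)) set.seed(seed)
  nb <- config$num_blocks
  w <- config$widths

  enc <- vector("list", nb)
  for (i in seq_len(nb)) {
    cin <- if (i == 1L) config$in_channels else w[i - 1L]
    ncv <- config$convs_per_block[i]
    convs <- vector("list", ncv)
    bns <- vector("list", ncv)
    for (l in seq_len(ncv)) {
      convs[[l]] <- conv3d_init(3L, if (l == 1L) cin else w[i], w[i])
      bns[[l]] <- bn_init(w[i])
    }
    enc[[i]] <- list(convs = convs, bns = bns)
  }

  dec_stage <- function(cin, cout) {
    list(conv = conv3d_init(3L, cin, cout), bn = bn_init(cout))
  }
  dskip <- vector("list", nb)
  dindex <- vector("list", nb)
  # stage j works at the resolution of encoder block i = nb - j + 1; its
  # input must carry w[i] channels (the unpool indices were recorded at that
  # width), and it convolves down to the next block's width, ending at
  # base_width for the full-resolution output
  prev <- w[nb]
  for (j in seq_len(nb)) {
    i <- nb - j + 1L
    cout <- w[max(i - 1L, 1L)]
    dskip[[j]] <- dec_stage(prev + w[i], cout)  # upsampled prev ++ skip
    dindex[[j]] <- dec_stage(prev, cout)        # unpooled prev, no skip
    prev <- cout
  }

  head_cin <- if (config$fusion_mode == "C") 2L * config$base_width else
    config$base_width
  head <- conv3d_init(1L, head_cin, config$num_classes)

  structure(list(config = config,
                 params = list(enc = enc, dskip = dskip, dindex = dindex,
                               head = head)),
            class = "fusionnet")
}

#' @export
print.fusionnet <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, numeric(1)))
  print(x$config)
  cat(sprintf("  %d trainable values\n", as.integer(np)))
  invisible(x)
}

check_stack_shape <- function(config, x) {
  d <- tensor_dims(x)
  e <- config$input_edge
  for (ax in 1:3)
    if (d[ax] != e)
      stop(sprintf("input axis %d has length %d, expected input_edge %d",
                   ax, d[ax], e))
  if (d[4L] != config$in_channels)
    stop(sprintf("input has %d channels, config expects in_channels = %d",
                 d[4L], config$in_channels))
  d
}

as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) dim(x) <- c(d, 1L)
  x
}

# --- encoder -----------------------------------------------------------------

enc_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params$enc
  nb <- cfg$num_blocks
  skips <- vector("list", nb)
  inds <- vector("list", nb)
  caches <- if (keep_cache) vector("list", nb) else NULL
  cur <- x
  for (i in seq_len(nb)) {
    blk <- p[[i]]
    bc <- list(conv_in = list(), bn = list(), relu = list(), pool_in_dim = NULL)
    for (l in seq_along(blk$convs)) {
      if (keep_cache) bc$conv_in[[l]] <- cur
      cur <- conv3d_fwd(cur, blk$convs[[l]]$W, blk$convs[[l]]$b)
      bf <- bn_fwd(cur, blk$bns[[l]], training)
      model$params$enc[[i]]$bns[[l]] <- bf$bn
      if (keep_cache) bc$bn[[l]] <- bf$cache
      cur <- relu_fwd(bf$y)
      if (keep_cache) bc$relu[[l]] <- cur
    }
    skips[[i]] <- cur
    bc$pool_in_dim <- dim(cur)
    pool <- maxpool2_fwd(cur)
    cur <- pool$y
    inds[[i]] <- pool$ind
    if (keep_cache) caches[[i]] <- bc
  }
  state <- structure(list(bottleneck = cur, skip_features = skips,
                          pool_indices = inds, config = cfg),
                     class = "encoder_state")
  list(state = state, model = model, caches = caches)
}

enc_backward <- function(model, caches, g_bottleneck, g_skips) {
  p <- model$params$enc
  nb <- model$config$num_blocks
  grads <- vector("list", nb)
  gcur <- g_bottleneck
  for (i in rev(seq_len(nb))) {
    blk <- p[[i]]
    bc <- caches[[i]]
    # through the pooling, then add the skip-path gradient
    gcur <- maxpool2_bwd(gcur, model$params$enc[[i]]$ind_cache, bc$pool_in_dim)
    if (!is.null(g_skips[[i]])) gcur <- gcur + g_skips[[i]]
    nl <- length(blk$convs)
    bg <- list(convs = vector("list", nl), bns = vector("list", nl))
    for (l in rev(seq_len(nl))) {
      gcur <- relu_bwd(bc$relu[[l]], gcur)
      bb <- bn_bwd(bc$bn[[l]], gcur)
      cb <- conv3d_bwd(bc$conv_in[[l]], blk$convs[[l]]$W, bb$gx)
      bg$convs[[l]] <- list(W = cb$gw, b = cb$gb)
      bg$bns[[l]] <- list(gamma = bb$ggamma, beta = bb$gbeta)
      gcur <- cb$gx
    }
    grads[[i]] <- bg
  }
  list(grads = grads, gx = gcur)
}

# --- decoders ----------------------------------------------------------------

dec_forward <- function(model, state, kind = c("skip", "index"),
                        training = FALSE, keep_cache = FALSE) {
  kind <- match.arg(kind)
  cfg <- model$config
  nb <- cfg$num_blocks
  pkey <- if (kind == "skip") "dskip" else "dindex"
  p <- model$params[[pkey]]
  caches <- if (keep_cache) vector("list", nb) else NULL
  cur <- state$bottleneck
  for (j in seq_len(nb)) {
    i <- nb - j + 1L  # matching encoder block
    sc <- list(in_dim = dim(cur))
    if (kind == "skip") {
      up <- upsample2_fwd(cur)
      skip <- state$skip_features[[i]]
      if (!all(dim(up)[c(1:3, 5L)] == dim(skip)[c(1:3, 5L)]))
        stop("skip feature shape does not match upsampled decoder feature")
      cur <- concat_channels(up, skip)
      sc$up_channels <- dim(up)[4L]
    } else {
      cur <- unpool2_fwd(cur, state$pool_indices[[i]])
    }
    if (keep_cache) sc$conv_in <- cur
    cur <- conv3d_fwd(cur, p[[j]]$conv$W, p[[j]]$conv$b)
    bf <- bn_fwd(cur, p[[j]]$bn, training)
    model$params[[pkey]][[j]]$bn <- bf$bn
    if (keep_cache) sc$bn <- bf$cache
    cur <- relu_fwd(bf$y)
    if (keep_cache) { sc$relu <- cur; caches[[j]] <- sc }
  }
  list(out = cur, model = model, caches = caches)
}

dec_backward <- function(model, state, caches, gout,
                         kind = c("skip", "index")) {
  kind <- match.arg(kind)
  cfg <- model$config
  nb <- cfg$num_blocks
  pkey <- if (kind == "skip") "dskip" else "dindex"
  p <- model$params[[pkey]]
  grads <- vector("list", nb)
  g_skips <- vector("list", nb)
  gcur <- gout
  for (j in rev(seq_len(nb))) {
    i <- nb - j + 1L
    sc <- caches[[j]]
    gcur <- relu_bwd(sc$relu, gcur)
    bb <- bn_bwd(sc$bn, gcur)
    cb <- conv3d_bwd(sc$conv_in, p[[j]]$conv$W, bb$gx)
    grads[[j]] <- list(conv = list(W = cb$gw, b = cb$gb),
                       bn = list(gamma = bb$ggamma, beta = bb$gbeta))
    if (kind == "skip") {
      sp <- split_channels(cb$gx, sc$up_channels)
      g_skips[[i]] <- sp$b
      gcur <- upsample2_bwd(sp$a, sc$in_dim)
    } else {
      gcur <- unpool2_bwd(cb$gx, state$pool_indices[[i]], sc$in_dim)
    }
  }
  list(grads = grads, g_bottleneck = gcur, g_skips = g_skips)
}

# --- fusion head -------------------------------------------------------------

#' Fuse two decoder feature maps
#'
#' Joint output operation combining the skip-connection and pooling-index
#' decoder features: `"A"` sums them, `"M"` multiplies elementwise, `"C"`
#' concatenates along the channel axis.
#'
#' @param a,b Feature arrays with layout (X, Y, Z, C) or (X, Y, Z, C, N) and
#'   identical spatial/batch shape; `"A"` and `"M"` also require equal
#'   channel counts.
#' @param mode `"A"`, `"M"` or `"C"`.
#' @return The fused feature array.
#' @export
fuse <- function(a, b, mode = c("A", "M", "C")) {
  mode <- match.arg(mode)
  squeeze <- FALSE
  if (length(dim(a)) == 4L && length(dim(b)) == 4L) {
    a <- as_batch(a); b <- as_batch(b); squeeze <- TRUE
  }
  da <- tensor_dims(a); db <- tensor_dims(b)
  if (!all(da[-4L] == db[-4L]))
    stop("fuse: spatial/batch shapes differ")
  out <- switch(mode,
    A = { if (da[4L] != db[4L]) stop("fuse A: channel counts differ"); a + b },
    M = { if (da[4L] != db[4L]) stop("fuse M: channel counts differ"); a * b },
    C = concat_channels(a, b))
  if (squeeze) { d <- dim(out); dim(out) <- d[1:4] }
  out
}

head_forward <- function(model, fused) {
  logits <- conv3d_fwd(fused, model$params$head$W, model$params$head$b)
  list(logits = logits, prob = softmax_channels(logits))
}

# --- full forward / backward -------------------------------------------------

net_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  ef <- enc_forward(model, x, training, keep_cache)
  model <- ef$model
  ds <- dec_forward(model, ef$state, "skip", training, keep_cache)
  model <- ds$model
  di <- dec_forward(model, ef$state, "index", training, keep_cache)
  model <- di$model
  fused <- fuse_batch(ds$out, di$out, model$config$fusion_mode)
  hd <- head_forward(model, fused)
  list(model = model, state = ef$state, prob = hd$prob, logits = hd$logits,
       cache = if (keep_cache) list(enc = ef$caches, dskip = ds$caches,
                                    dindex = di$caches, a = ds$out,
                                    b = di$out, fused = fused) else NULL)
}

fuse_batch <- function(a, b, mode) {
  switch(mode, A = a + b, M = a * b, C = concat_channels(a, b))
}

net_backward <- function(model, state, cache, g_logits) {
  hb <- conv3d_bwd(cache$fused, model$params$head$W, g_logits)
  head_grad <- list(W = hb$gw, b = hb$gb)
  gf <- hb$gx
  mode <- model$config$fusion_mode
  if (mode == "A") {
    ga <- gf; gb <- gf
  } else if (mode == "M") {
    ga <- gf * cache$b; gb <- gf * cache$a
  } else {
    sp <- split_channels(gf, dim(cache$a)[4L])
    ga <- sp$a; gb <- sp$b
  }
  dsb <- dec_backward(model, state, cache$dskip, ga, "skip")
  dib <- dec_backward(model, state, cache$dindex, gb, "index")
  g_bottleneck <- dsb$g_bottleneck + dib$g_bottleneck

  # stash pooling indices where enc_backward expects them
  for (i in seq_len(model$config$num_blocks))
    model$params$enc[[i]]$ind_cache <- state$pool_indices[[i]]
  eb <- enc_backward(model, cache$enc, g_bottleneck, dsb$g_skips)
  list(enc = eb$grads, dskip = dsb$grads, dindex = dib$grads,
       head = head_grad, gx = eb$gx)
}

sgd_apply <- function(model, grads, lr) {
  nb <- model$config$num_blocks
  for (i in seq_len(nb)) {
    for (l in seq_along(model$params$enc[[i]]$convs)) {
      model$params$enc[[i]]$convs[[l]]$W <-
        model$params$enc[[i]]$convs[[l]]$W - lr * grads$enc[[i]]$convs[[l]]$W
      model$params$enc[[i]]$convs[[l]]$b <-
        model$params$enc[[i]]$convs[[l]]$b - lr * grads$enc[[i]]$convs[[l]]$b
      model$params$enc[[i]]$bns[[l]]$gamma <-
        model$params$enc[[i]]$bns[[l]]$gamma - lr * grads$enc[[i]]$bns[[l]]$gamma
      model$params$enc[[i]]$bns[[l]]$beta <-
        model$params$enc[[i]]$bns[[l]]$beta - lr * grads$enc[[i]]$bns[[l]]$beta
    }
    for (key in c("dskip", "dindex")) {
      model$params[[key]][[i]]$conv$W <-
        model$params[[key]][[i]]$conv$W - lr * grads[[key]][[i]]$conv$W
      model$params[[key]][[i]]$conv$b <-
        model$params[[key]][[i]]$conv$b - lr * grads[[key]][[i]]$conv$b
      model$params[[key]][[i]]$bn$gamma <-
        model$params[[key]][[i]]$bn$gamma - lr * grads[[key]][[i]]$bn$gamma
      model$params[[key]][[i]]$bn$beta <-
        model$params[[key]][[i]]$bn$beta - lr * grads[[key]][[i]]$bn$beta
    }
  }
  model$params$head$W <- model$params$head$W - lr * grads$head$W
  model$params$head$b <- model$params$head$b - lr * grads$head$b
  model
}

# One SGD step on a batch: forward in training mode, softmax cross-entropy,
# backprop, parameter update. y_onehot layout (X, Y, Z, num_classes, N).
train_step <- function(model, x, y_onehot, lr) {
  fw <- net_forward(model, x, training = TRUE, keep_cache = TRUE)
  model <- fw$model
  d <- tensor_dims(fw$prob)
  nvox <- prod(d[c(1:3, 5L)])
  loss <- -sum(y_onehot * log(pmax(fw$prob, 1e-12))) / nvox
  g_logits <- (fw$prob - y_onehot) / nvox
  grads <- net_backward(model, fw$state, fw$cache, g_logits)
  model <- sgd_apply(model, grads, lr)
  list(model = model, loss = loss)
}

# --- user-facing encoder / decoder / predict --------------------------------

#' Run the shared encoder
#'
#' @param model A [build_fusionnet()] model.
#' @param stack Array (X, Y, Z, C) or (X, Y, Z, C, N): one or more cubic
#'   multimodal volumes matching the config's `input_edge` and `in_channels`.
#' @return An `encoder_state` with `bottleneck`, `skip_features` (one per
#'   block, saved before each downsampling) and `pool_indices` (the argmax
#'   positions of each 2x max-pooling).
#' @export
encode <- function(model, stack) {
  stopifnot(inherits(model, "fusionnet"))
  stack <- as_batch(stack)
  check_stack_shape(model$config, stack)
  enc_forward(model, stack, training = FALSE)$state
}

#' Run the skip-connection (U-Net-style) decoder
#'
#' Repeated trilinear 2x upsampling, concatenation with the matching encoder
#' skip feature, and convolution, back to full resolution.
#'
#' @param model A `fusionnet` model.
#' @param state An `encoder_state` from [encode()] with matching config.
#' @return Full-resolution feature array (X, Y, Z, base_width, N).
#' @export
decode_skip <- function(model, state) {
  stopifnot(inherits(model, "fusionnet"), inherits(state, "encoder_state"))
  dec_forward(model, state, "skip", training = FALSE)$out
}

#' Run the pooling-index (SegNet-style) decoder
#'
#' Max-unpooling with the recorded argmax indices (zeros elsewhere) followed
#' by convolution at each stage; no skip-feature concatenation anywhere.
#'
#' @inheritParams decode_skip
#' @return Full-resolution feature array (X, Y, Z, base_width, N).
#' @export
decode_index <- function(model, state) {
  stopifnot(inherits(model, "fusionnet"), inherits(state, "encoder_state"))
  dec_forward(model, state, "index", training = FALSE)$out
}

#' Segment a modality stack
#'
#' Full forward pass: shared encoder, both decoders, fusion head, voxelwise
#' softmax classifier, and argmax labeling (ties broken toward the lowest
#' class index).
#'
#' @param model A `fusionnet` model.
#' @param stack Array (X, Y, Z, C) matching the config.
#' @return List with `prob` (X, Y, Z, num_classes; voxel probabilities
#'   summing to 1) and `labels` (X, Y, Z integer array with values in
#'   `0:(num_classes-1)`).
#' @export
predict_segmentation <- function(model, stack) {
  stopifnot(inherits(model, "fusionnet"))
  stack <- as_batch(stack)
  check_stack_shape(model$config, stack)
  if (tensor_dims(stack)[5L] != 1L)
    stop("predict_segmentation takes a single volume; loop for batches")
  fw <- net_forward(model, stack, training = FALSE)
  prob <- fw$prob
  d <- dim(prob)
  dim(prob) <- d[1:4]
  labels <- argmax_channels(prob)
  list(prob = prob, labels = labels)
}

# per-voxel argmax over the 4th axis; ties -> lowest class index; 0-based
argmax_channels <- function(prob) {
  d <- dim(prob)
  m <- matrix(prob, nrow = prod(d[1:3]), ncol = d[4L])
  lab <- max.col(m, ties.method = "first") - 1L
  array(lab, dim = d[1:3])
}

# --- checkpoints -------------------------------------------------------------

#' Save / load a self-describing model checkpoint
#'
#' The configuration is embedded alongside the weights, so a checkpoint can
#' be restored without external context.
#'
#' @param model A `fusionnet` model.
#' @param path File path (`.rds`).
#' @param extra Optional list stored verbatim (e.g. training log).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `model` and `extra`.
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  stopifnot(inherits(model, "fusionnet"))
  saveRDS(list(config = unclass(model$config), params = model$params,
               extra = extra, format = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- structure(ck$config, class = "fusionnet_config")
  model <- structure(list(config = cfg, params = ck$params),
                     class = "fusionnet")
  list(model = model, extra = ck$extra)
}
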