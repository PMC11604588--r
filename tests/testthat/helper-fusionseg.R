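# Shared fixtures and independent oracles for the test suite.

# small 2-modality phantom on a 32-voxel grid, cached per session
desk_phantom <- local({
  cache <- NULL
  function(seed = 7) {
    if (is.null(cache) || attr(cache, "seed") != seed) {
      s <- generate_phantom(phantom_spec(
        edge = 32, modalities = c("FLAIR", "ceT1"),
        radii = c(10, 6.5, 3.5), center_jitter = 2, seed = seed))
      attr(s, "seed") <- seed
      cache <<- s
    }
    cache
  }
})

tiny_config <- function(fusion_mode = "A", in_channels = 1L,
                        num_classes = 3L, base_width = 2L,
                        num_blocks = 2L, input_edge = 8L) {
  fusionnet_config(in_channels = in_channels, num_classes = num_classes,
                   base_width = base_width, num_blocks = num_blocks,
                   fusion_mode = fusion_mode, input_edge = input_edge)
}

random_labels <- function(edge, num_classes = 4L, seed = 1) {
  set.seed(seed)
  array(sample(0:(num_classes - 1L), edge^3, replace = TRUE),
        dim = rep(edge, 3L))
}

random_mask <- function(edge, p = 0.3, seed = 1) {
  set.seed(seed)
  array(stats::runif(edge^3) < p, dim = rep(edge, 3L))
}

# --- independent oracles -----------------------------------------------------

# per-voxel loop for confusion counts
oracle_confusion <- function(pred, truth, class_id) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == class_id
    t <- truth[i] == class_id
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && !t) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# all-pairs brute-force average symmetric surface distance
oracle_assd <- function(pred_mask, true_mask, spacing = c(1, 1, 1)) {
  P <- surface_points(pred_mask, spacing)
  G <- surface_points(true_mask, spacing)
  if (nrow(P) == 0L || nrow(G) == 0L) return(NaN)
  dmat <- outer(seq_len(nrow(P)), seq_len(nrow(G)), Vectorize(function(i, j)
    sqrt(sum((P[i, ] - G[j, ])^2))))
  (mean(apply(dmat, 1L, min)) + mean(apply(dmat, 2L, min))) / 2
}

# naive quadruple-loop cross-entropy (h, w, d, c)
oracle_cross_entropy <- function(y_true, y_pred) {
  d <- dim(y_true)
  acc <- 0
  for (h in seq_len(d[1])) for (w in seq_len(d[2]))
    for (dd in seq_len(d[3])) for (c in seq_len(d[4]))
      acc <- acc + y_true[h, w, dd, c] * log(max(y_pred[h, w, dd, c], 1e-12))
  -acc / prod(d[1:3])
}

# random one-hot / probability pair on a small grid
random_loss_inputs <- function(edge = 4L, num_classes = 3L, seed = 1) {
  set.seed(seed)
  d <- c(rep(edge, 3L), num_classes)
  cls <- sample(seq_len(num_classes), edge^3, replace = TRUE)
  y <- array(0, d)
  for (c in seq_len(num_classes))
    y[, , , c][cls == c] <- 1
  raw <- array(stats::runif(prod(d), 0.05, 1), d)
  norm <- array(rep(apply(raw, c(1, 2, 3), sum), num_classes), d)
  list(y_true = y, y_pred = raw / norm)
}
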