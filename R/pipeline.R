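# Training / prediction / evaluation orchestration: the SGD recipe with an
# exponentially decaying learning rate, seed-deterministic cohort splitting,
# modality-subset selection, and slice-overlay rendering.

#' Training configuration
#'
#' Defaults follow the published recipe: plain SGD, initial learning rate
#' 0.01 decayed by a factor of 0.8 per epoch, 20 epochs, batch size 5.
#'
#' @param lr0 Initial learning rate.
#' @param decay Per-epoch exponential decay factor in (0, 1].
#' @param epochs Number of epochs.
#' @param batch_size Samples per SGD step.
#' @param seed Integer seed controlling shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 0.01, decay = 0.8, epochs = 20L,
                         batch_size = 5L, seed = 1L) {
  if (lr0 <= 0) stop("lr0 must be > 0")
  if (decay <= 0 || decay > 1) stop("decay must be in (0, 1]")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(lr0 = lr0, decay = decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Exponential decay: `lr0 * decay^epoch` with `epoch` counted from 0.
#'
#' @param lr0 Initial learning rate.
#' @param decay Decay factor.
#' @param epoch Zero-based epoch index.
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(lr0, decay, epoch) {
  stopifnot(all(epoch >= 0))
  lr0 * decay^epoch
}

#' Split a cohort into train / validation / test sets
#'
#' Seed-deterministic disjoint exhaustive partition, e.g. 611 subjects into
#' 500 training (82%), 31 validation (5%) and 80 test (13%).
#'
#' @param subject_ids Unique subject identifiers.
#' @param split Integer vector `c(train, val, test)` summing to
#'   `length(subject_ids)`.
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test` id vectors.
#' @export
split_cohort <- function(subject_ids, split, seed = 1L) {
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  split <- as.integer(split)
  if (length(split) != 3L || sum(split) != length(subject_ids))
    stop(sprintf("split counts (%s) must sum to the cohort size (%d)",
                 paste(split, collapse = ", "), length(subject_ids)))
  set.seed(seed)
  perm <- sample(subject_ids)
  list(train = perm[seq_len(split[1])],
       val = perm[split[1] + seq_len(split[2])],
       test = perm[split[1] + split[2] + seq_len(split[3])])
}

#' Select a modality subset from a sample or stack
#'
#' Channels are emitted in canonical order (FLAIR, T1, ceT1, T2) regardless
#' of the order requested.
#'
#' @param x An `mri_sample` or a (X, Y, Z, C) array with a `modalities`
#'   attribute.
#' @param subset Nonempty character vector of modality names.
#' @return The same kind of object restricted to the subset.
#' @export
select_modalities <- function(x, subset) {
  if (length(subset) == 0L) stop("subset must be nonempty")
  bad <- setdiff(subset, MODALITIES)
  if (length(bad))
    stop("unknown modality name(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(MODALITIES, collapse = ", "))
  canon <- MODALITIES[MODALITIES %in% subset]
  if (inherits(x, "mri_sample")) {
    missing <- setdiff(canon, x$modalities)
    if (length(missing))
      stop("sample lacks modality: ", paste(missing, collapse = ", "))
    idx <- match(canon, x$modalities)
    mri_sample(x$stack[, , , idx, drop = FALSE], x$labels, canon,
               x$subject_id, x$spacing, x$transform_tag)
  } else {
    stop("select_modalities expects an mri_sample")
  }
}

#' All nonempty modality combinations
#'
#' The 15 nonempty subsets of FLAIR/T1/ceT1/T2, in canonical order, for
#' modality-ablation sweeps.
#'
#' @return A list of character vectors.
#' @export
modality_combinations <- function() {
  out <- list()
  for (k in 4:1) {
    cmb <- utils::combn(MODALITIES, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# one-hot encode labels (X, Y, Z) -> (X, Y, Z, C, 1)
onehot_labels <- function(labels, num_classes) {
  d <- dim(labels)
  y <- array(0, c(d, num_classes, 1L))
  for (c in seq_len(num_classes) - 1L) {
    m <- array(0, d)
    m[labels == c] <- 1
    y[, , , c + 1L, 1L] <- m
  }
  y
}

# stack a list of samples into a batch tensor pair
batch_tensors <- function(samples, num_classes) {
  n <- length(samples)
  d <- dim(samples[[1]]$stack)
  x <- array(0, c(d, n))
  y <- array(0, c(d[1:3], num_classes, n))
  for (i in seq_len(n)) {
    x[, , , , i] <- samples[[i]]$stack
    y[, , , , i] <- onehot_labels(samples[[i]]$labels, num_classes)[, , , , 1L]
  }
  list(x = x, y = y)
}

# BraTS-style label maps use {0, 1, 2, 4}; remap 4 -> 3 at load time
remap_brats_labels <- function(labels) {
  if (any(labels == 4L)) labels[labels == 4L] <- 3L
  labels
}

unmap_brats_labels <- function(labels) {
  labels[labels == 3L] <- 4L
  labels
}

#' Train a FusionNet model
#'
#' Minimizes voxelwise cross-entropy with plain SGD, learning rate
#' `lr0 * decay^epoch`, shuffled mini-batches. Logs per-epoch mean training
#' loss and (when a validation set is given) per-subregion validation Dice;
#' tracks the best epoch by mean validation Dice over the three tumor
#' subregions.
#'
#' @param model A [build_fusionnet()] model.
#' @param train_samples List of `mri_sample`s matching the model config.
#' @param config A [train_config()].
#' @param val_samples Optional validation list.
#' @param checkpoint_dir Optional directory; when given, `best.rds` and
#'   `final.rds` checkpoints (config embedded) are written there.
#' @param verbose Print per-epoch progress.
#' @return List: trained `model`, `best_model`, `log` (data.frame with
#'   epoch, lr, train_loss, val dice columns), `best_epoch`.
#' @export
train_fusionnet <- function(model, train_samples, config = train_config(),
                            val_samples = NULL, checkpoint_dir = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(model, "fusionnet"), inherits(config, "train_config"))
  nc <- model$config$num_classes
  set.seed(config$seed)
  log_rows <- list()
  best <- list(dice = -Inf, model = model, epoch = NA_integer_)
  for (ep in seq_len(config$epochs)) {
    lr <- lr_schedule(config$lr0, config$decay, ep - 1L)
    ord <- sample(seq_along(train_samples))
    losses <- c()
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      bt <- batch_tensors(train_samples[idx], nc)
      st <- train_step(model, bt$x, bt$y, lr)
      model <- st$model
      if (!is.finite(st$loss))
        stop(sprintf("non-finite training loss at epoch %d (lr %.4g)", ep, lr))
      losses <- c(losses, st$loss)
    }
    row <- data.frame(epoch = ep, lr = lr, train_loss = mean(losses))
    if (!is.null(val_samples)) {
      vd <- validation_dice(model, val_samples)
      row$dice_NC <- vd["NC"]; row$dice_ED <- vd["ED"]; row$dice_ET <- vd["ET"]
      mean_dice <- mean(vd, na.rm = TRUE)
      row$mean_dice <- mean_dice
      if (is.finite(mean_dice) && mean_dice > best$dice)
        best <- list(dice = mean_dice, model = model, epoch = ep)
    }
    log_rows[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %d: lr %.4g, train loss %.4f%s", ep, lr,
                      mean(losses),
                      if (!is.null(val_samples))
                        sprintf(", val mean dice %.3f", row$mean_dice) else ""))
  }
  log <- do.call(rbind, log_rows)
  if (is.null(val_samples)) { best$model <- model; best$epoch <- config$epochs }
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    save_checkpoint(best$model, file.path(checkpoint_dir, "best.rds"),
                    extra = list(log = log, epoch = best$epoch))
    save_checkpoint(model, file.path(checkpoint_dir, "final.rds"),
                    extra = list(log = log))
  }
  list(model = model, best_model = best$model, log = log,
       best_epoch = best$epoch)
}

# mean per-subregion Dice over a sample list (NaN-excluding mean)
validation_dice <- function(model, samples, classes = c(NC = 1, ED = 2, ET = 3)) {
  per <- sapply(samples, function(s) {
    pred <- predict_segmentation(model, s$stack)$labels
    vapply(classes, function(cl) dice(confusion(pred, s$labels, cl)),
           numeric(1))
  })
  if (is.null(dim(per))) per <- matrix(per, nrow = length(classes))
  out <- apply(per, 1L, function(v) if (all(is.nan(v))) NaN else
    mean(v[is.finite(v)]))
  names(out) <- names(classes)
  out
}

#' Evaluate a model over a test cohort
#'
#' Predicts every sample and aggregates the six metrics per subregion.
#'
#' @param model A trained `fusionnet`.
#' @param samples Test `mri_sample` list.
#' @param method Label for the report rows.
#' @return A [evaluate_cohort()] `metric_report`.
#' @export
evaluate_model <- function(model, samples, method = NULL) {
  if (is.null(method))
    method <- paste0("FusionNet-", model$config$fusion_mode)
  reports <- lapply(samples, function(s) {
    pred <- predict_segmentation(model, s$stack)$labels
    evaluate_subject(pred, s$labels, spacing = s$spacing)
  })
  evaluate_cohort(reports, method = method)
}

#' Modality-ablation sweep
#'
#' Trains one model per modality subset (all 15 nonempty combinations by
#' default) on the given cohort split and evaluates each on the test set,
#' producing a long report: one row per (modality combination, subregion).
#'
#' @param samples Cohort list of 4-modality `mri_sample`s.
#' @param split `c(train, val, test)` counts.
#' @param model_args List of [fusionnet_config()] arguments other than
#'   `in_channels` (e.g. `input_edge`, `base_width`, `num_blocks`,
#'   `fusion_mode`).
#' @param config A [train_config()].
#' @param combinations Subset list (default all 15).
#' @param augment Expand the training set sixfold by flips/rotations first.
#' @param seed Master seed for split and weight init.
#' @param verbose Print progress.
#' @return A `metric_report` data.frame with a `modalities` column.
#' @export
sweep_modalities <- function(samples, split,
                             model_args = list(),
                             config = train_config(),
                             combinations = modality_combinations(),
                             augment = FALSE, seed = 1L, verbose = FALSE) {
  ids <- vapply(samples, `[[`, character(1), "subject_id")
  sp <- split_cohort(ids, split, seed)
  pick <- function(set) samples[match(set, ids)]
  out <- list()
  for (cmb in combinations) {
    if (verbose) message("modalities: ", paste(cmb, collapse = "/"))
    tr <- lapply(pick(sp$train), select_modalities, subset = cmb)
    if (augment) tr <- expand_training_set(tr)
    va <- lapply(pick(sp$val), select_modalities, subset = cmb)
    te <- lapply(pick(sp$test), select_modalities, subset = cmb)
    cfg <- do.call(fusionnet_config, c(list(in_channels = length(cmb)),
                                       model_args))
    model <- build_fusionnet(cfg, seed = seed)
    fit <- train_fusionnet(model, tr, config, val_samples = va)
    rep <- evaluate_model(fit$best_model, te,
                          method = paste0("FusionNet-", cfg$fusion_mode))
    rep$modalities <- paste(cmb, collapse = "/")
    out[[length(out) + 1L]] <- rep
  }
  res <- do.call(rbind, out)
  structure(res, class = c("metric_report", "data.frame"))
}

#' Render a segmentation overlay slice
#'
#' Grayscale background with the standard color code: necrotic core red,
#' enhancing tumor yellow, peritumoral edema green, blended at fixed alpha.
#'
#' @param sample An `mri_sample` (the first channel is displayed) or a 3D
#'   intensity array.
#' @param labels Optional label array when `sample` is a plain array.
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param slice Slice index along the plane's axis.
#' @param path Output PNG path.
#' @param alpha Overlay opacity in (0, 1].
#' @return `path`, invisibly; the written image is a (rows x cols x 3) PNG.
#' @export
render_overlay <- function(sample, labels = NULL,
                           plane = c("axial", "coronal", "sagittal"),
                           slice, path, alpha = 0.5) {
  plane <- match.arg(plane)
  if (inherits(sample, "mri_sample")) {
    vol <- sample$stack[, , , 1L, drop = TRUE]
    labels <- sample$labels
  } else {
    vol <- sample
    if (is.null(labels)) stop("labels required when passing a plain array")
  }
  axis <- switch(plane, axial = 3L, coronal = 2L, sagittal = 1L)
  if (slice < 1L || slice > dim(vol)[axis])
    stop(sprintf("slice %d out of range 1..%d for the %s plane",
                 slice, dim(vol)[axis], plane))
  take <- function(v) switch(axis,
                             v[slice, , , drop = TRUE],
                             v[, slice, , drop = TRUE],
                             v[, , slice, drop = TRUE])
  img <- take(vol)
  lab <- take(labels)
  rng <- range(img)
  g <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  rgb <- array(rep(g, 3L), dim = c(dim(g), 3L))
  # NC = red, ED = green, ET = yellow
  col <- rbind("1" = c(1, 0, 0), "2" = c(0, 1, 0), "3" = c(1, 1, 0))
  for (cl in c(1L, 2L, 3L)) {
    m <- lab == cl
    if (!any(m)) next
    for (ch in 1:3)
      rgb[, , ch][m] <- (1 - alpha) * rgb[, , ch][m] + alpha * col[as.character(cl), ch]
  }
  png::writePNG(aperm(rgb, c(2L, 1L, 3L))[dim(rgb)[2]:1, , , drop = FALSE],
                path)
  invisible(path)
}
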