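# Zero-padding to the network's cubic input size and the five-transform
# augmentation scheme (axial-plane flips and 90/180/270-degree rotations),
# applied jointly to every modality channel and the label map.

TRANSFORM_TAGS <- c("original", "hflip", "vflip", "rot90", "rot180", "rot270")

#' Construct a multimodal sample
#'
#' Bundles a modality stack and its label map on one voxel grid.
#'
#' @param stack Array (X, Y, Z, C): one channel per MRI modality.
#' @param labels Integer array (X, Y, Z): 0 background, 1 necrotic core,
#'   2 peritumoral edema, 3 enhancing tumor.
#' @param modalities Character vector naming the channels (canonical order
#'   FLAIR, T1, ceT1, T2).
#' @param subject_id Subject identifier.
#' @param spacing Voxel spacing in mm.
#' @param transform_tag Provenance tag, one of
#'   original/hflip/vflip/rot90/rot180/rot270.
#' @return An `mri_sample` list.
#' @export
mri_sample <- function(stack, labels, modalities, subject_id,
                       spacing = c(1, 1, 1), transform_tag = "original") {
  if (length(dim(stack)) == 3L) dim(stack) <- c(dim(stack), 1L)
  if (length(dim(stack)) != 4L) stop("stack must be (X, Y, Z, C)")
  if (!all(dim(stack)[1:3] == dim(labels)))
    stop("stack and labels must share one grid")
  if (dim(stack)[4L] != length(modalities))
    stop("one modality name per channel required")
  if (!transform_tag %in% TRANSFORM_TAGS)
    stop("transform_tag must be one of: ", paste(TRANSFORM_TAGS, collapse = ", "))
  structure(list(stack = stack, labels = labels,
                 modalities = as.character(modalities),
                 subject_id = as.character(subject_id),
                 spacing = rep_len(as.numeric(spacing), 3L),
                 transform_tag = transform_tag),
            class = "mri_sample")
}

#' @export
print.mri_sample <- function(x, ...) {
  cat(sprintf("mri_sample %s [%s]: %s voxels, modalities %s\n",
              x$subject_id, x$transform_tag,
              paste(dim(x$labels), collapse = "x"),
              paste(x$modalities, collapse = "/")))
  invisible(x)
}

pad_margins <- function(len, target) {
  if (len > target)
    stop(sprintf("axis length %d exceeds target edge %d", len, target))
  m <- target - len
  c(lo = m %/% 2L, hi = m - m %/% 2L)  # extra voxel on the high side
}

#' Zero-pad a sample to a cube
#'
#' Centers the original content in a `target_edge`-cubed grid: intensities
#' are zero-padded, labels background-padded, and odd margins put the extra
#' voxel on the high side (so 240x240x155 -> 256 cubed gets margins
#' (8,8)/(8,8)/(50,51)). The margins are recorded so padding is reversible.
#'
#' @param sample An [mri_sample()].
#' @param target_edge Cubic edge length; every axis must already be <= it.
#' @return The padded `mri_sample`, with `attr(, "pad_margins")` a 3x2
#'   matrix of (lo, hi) margins.
#' @export
pad_to_cube <- function(sample, target_edge) {
  stopifnot(inherits(sample, "mri_sample"))
  target_edge <- as.integer(target_edge)
  d <- dim(sample$labels)
  mg <- vapply(d, pad_margins, integer(2), target = target_edge)  # 2 x 3
  nc <- dim(sample$stack)[4L]
  stack <- array(0, c(rep(target_edge, 3L), nc))
  labels <- array(0L, rep(target_edge, 3L))
  ix <- lapply(1:3, function(a) mg[1L, a] + seq_len(d[a]))
  stack[ix[[1]], ix[[2]], ix[[3]], ] <- sample$stack
  labels[ix[[1]], ix[[2]], ix[[3]]] <- sample$labels
  out <- mri_sample(stack, labels, sample$modalities, sample$subject_id,
                    sample$spacing, sample$transform_tag)
  attr(out, "pad_margins") <- t(mg)
  out
}

#' Undo [pad_to_cube()]
#'
#' @param sample A padded `mri_sample` carrying a `pad_margins` attribute
#'   (or pass `margins` explicitly as a 3x2 (lo, hi) matrix).
#' @param margins Optional explicit margins.
#' @return The cropped `mri_sample`.
#' @export
crop_to_margins <- function(sample, margins = attr(sample, "pad_margins")) {
  if (is.null(margins)) stop("no pad margins recorded on this sample")
  d <- dim(sample$labels)
  ix <- lapply(1:3, function(a) (margins[a, 1L] + 1L):(d[a] - margins[a, 2L]))
  mri_sample(sample$stack[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE],
             sample$labels[ix[[1]], ix[[2]], ix[[3]]],
             sample$modalities, sample$subject_id, sample$spacing,
             sample$transform_tag)
}

# index permutation of one 3D volume; flips and rotations act in the axial
# (X, Y) plane, the slice axis Z is never touched
permute_volume <- function(v, tag) {
  d <- dim(v)
  switch(tag,
    original = v,
    hflip = v[d[1]:1, , , drop = FALSE],
    vflip = v[, d[2]:1, , drop = FALSE],
    rot90 = {
      if (d[1] != d[2]) stop("90/270-degree rotation needs a square axial plane")
      aperm(v, c(2L, 1L, 3L))[d[2]:1, , , drop = FALSE]
    },
    rot180 = v[d[1]:1, d[2]:1, , drop = FALSE],
    rot270 = {
      if (d[1] != d[2]) stop("90/270-degree rotation needs a square axial plane")
      aperm(v, c(2L, 1L, 3L))[, d[1]:1, , drop = FALSE]
    },
    stop("unknown transform tag: ", tag))
}

#' Apply one augmentation transform
#'
#' Applies the identical in-plane (axial) index permutation to every
#' modality channel and to the label map; labels are permuted, never
#' interpolated.
#'
#' @param sample An `mri_sample`.
#' @param tag One of `"hflip"`, `"vflip"`, `"rot90"`, `"rot180"`,
#'   `"rot270"` (or `"original"`, the identity).
#' @return The transformed `mri_sample`, tagged with `tag`.
#' @export
apply_transform <- function(sample, tag) {
  stopifnot(inherits(sample, "mri_sample"))
  if (!tag %in% TRANSFORM_TAGS)
    stop("unknown transform tag: ", tag)
  nc <- dim(sample$stack)[4L]
  stack <- sample$stack
  for (c in seq_len(nc))
    stack[, , , c] <- permute_volume(sample$stack[, , , c, drop = TRUE], tag)
  labels <- permute_volume(sample$labels, tag)
  mri_sample(stack, labels, sample$modalities, sample$subject_id,
             sample$spacing, tag)
}

#' Expand a training set by flip/rotation augmentation
#'
#' Each tagged-original sample is kept and joined by its five transforms
#' (horizontal flip, vertical flip, 90/180/270-degree rotations), a sixfold
#' expansion — e.g. 500 originals become 3,000 training samples.
#'
#' @param samples List of cubic `mri_sample`s, all tagged `"original"`.
#' @return List of `6 * length(samples)` samples with correct provenance
#'   tags.
#' @export
expand_training_set <- function(samples) {
  if (length(samples) == 0L) return(list())
  tags <- vapply(samples, `[[`, character(1), "transform_tag")
  if (!all(tags == "original"))
    stop("expand_training_set expects samples tagged 'original'")
  out <- list()
  seen <- character(0)
  for (s in samples) {
    for (tag in TRANSFORM_TAGS) {
      key <- paste(s$subject_id, tag, sep = "#")
      if (key %in% seen)
        stop("duplicate subject_id + transform pair: ", key)
      seen <- c(seen, key)
      out[[length(out) + 1L]] <-
        if (tag == "original") s else apply_transform(s, tag)
    }
  }
  out
}
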