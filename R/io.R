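# NIfTI input/output. Each sample is written as one image per modality plus
# a label map, with a sidecar JSON recording provenance (subject id,
# transform tag, modalities, spacing, pad margins).

#' Write a sample as NIfTI volumes
#'
#' Writes `<prefix>_<modality>.nii.gz` per channel, `<prefix>_seg.nii.gz`
#' for the labels, and `<prefix>.json` with provenance.
#'
#' @param sample An [mri_sample()].
#' @param prefix Output path prefix (directories are created).
#' @return The sidecar JSON path, invisibly.
#' @export
write_sample_nifti <- function(sample, prefix) {
  stopifnot(inherits(sample, "mri_sample"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  for (m in seq_along(sample$modalities)) {
    img <- RNifti::asNifti(sample$stack[, , , m, drop = TRUE],
                           pixdim = sample$spacing)
    RNifti::writeNifti(img, sprintf("%s_%s.nii.gz", prefix,
                                    sample$modalities[m]))
  }
  seg <- RNifti::asNifti(array(as.integer(sample$labels),
                               dim = dim(sample$labels)),
                         pixdim = sample$spacing)
  RNifti::writeNifti(seg, sprintf("%s_seg.nii.gz", prefix))
  meta <- list(subject_id = sample$subject_id,
               transform_tag = sample$transform_tag,
               modalities = sample$modalities,
               spacing = sample$spacing)
  mg <- attr(sample, "pad_margins")
  if (!is.null(mg)) meta$pad_margins <- unname(apply(mg, 1L, identity,
                                                     simplify = FALSE))
  sidecar <- sprintf("%s.json", prefix)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a sample written by [write_sample_nifti()]
#'
#' @param prefix The path prefix used when writing.
#' @return An [mri_sample()]; BraTS-style label values `{0,1,2,4}` are
#'   remapped to contiguous `{0,1,2,3}` at load time.
#' @export
read_sample_nifti <- function(prefix) {
  meta <- jsonlite::read_json(sprintf("%s.json", prefix),
                              simplifyVector = TRUE)
  mods <- meta$modalities
  vols <- lapply(mods, function(m) {
    as.array(RNifti::readNifti(sprintf("%s_%s.nii.gz", prefix, m)))
  })
  d <- dim(vols[[1]])
  stack <- array(0, c(d, length(mods)))
  for (m in seq_along(mods)) stack[, , , m] <- vols[[m]]
  labels <- as.array(RNifti::readNifti(sprintf("%s_seg.nii.gz", prefix)))
  labels <- remap_brats_labels(array(as.integer(round(labels)), dim = d))
  out <- mri_sample(stack, labels, mods, meta$subject_id,
                    as.numeric(meta$spacing), meta$transform_tag)
  if (!is.null(meta$pad_margins))
    attr(out, "pad_margins") <- do.call(rbind, lapply(meta$pad_margins,
                                                      as.integer))
  out
}

#' Write a cohort with a manifest
#'
#' Writes every sample under `dir/<subject_id>` and a `manifest.csv` with
#' subject id, transform tag and modalities.
#'
#' @param samples List of `mri_sample`s.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_cohort_nifti <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    write_sample_nifti(s, file.path(dir, s$subject_id))
    data.frame(subject_id = s$subject_id, transform_tag = s$transform_tag,
               modalities = paste(s$modalities, collapse = "/"),
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
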