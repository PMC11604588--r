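#' Voxelwise multi-class cross-entropy
#'
#' The training objective: mean over all voxels of the negative log predicted
#' probability of the true class,
#' \deqn{L = -\frac{1}{HWD} \sum_{h,w,d}\sum_c y_{h,w,d,c} \log \hat y_{h,w,d,c}.}
#' Predicted probabilities are clamped below at `1e-12` before the log so a
#' degenerate zero probability yields a large finite loss rather than `Inf`.
#'
#' @param y_true One-hot label array; the last axis indexes classes and must
#'   sum to 1 at every voxel.
#' @param y_pred Predicted probability array of identical shape.
#' @return A single non-negative finite number.
#' @examples
#' y <- array(0, c(2, 2, 2, 2)); y[, , , 1] <- 1
#' p <- array(0.5, c(2, 2, 2, 2))
#' cross_entropy(y, p)  # log(2)
#' @export
cross_entropy <- function(y_true, y_pred) {
  dt <- dim(y_true)
  dp <- dim(y_pred)
  if (is.null(dt) || is.null(dp) || length(dt) != length(dp) || !all(dt == dp))
    stop("cross_entropy: y_true and y_pred must be arrays of identical shape")
  nc <- dt[length(dt)]
  nvox <- prod(dt[-length(dt)])
  if (any(y_pred < -1e-5) || any(y_pred > 1 + 1e-5))
    stop("cross_entropy: predicted probabilities outside [0, 1]")
  if (!all(y_true %in% c(0, 1)))
    stop("cross_entropy: y_true must be one-hot (entries 0 or 1)")
  sums <- rowSums(matrix(y_true, nrow = nvox, ncol = nc))
  if (any(sums != 1))
    stop("cross_entropy: y_true rows must one-hot encode exactly one class")
  p <- pmax(y_pred, 1e-12)
  -sum(y_true * log(p)) / nvox
}
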