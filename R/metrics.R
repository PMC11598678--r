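# Evaluation metrics: binary cross-entropy, IoU, Dice, Hausdorff distance,
# disparity error rates, illuminance uniformity and percent-change
# reporting arithmetic.

#' Binary cross-entropy between a probability map and a binary label
#'
#' Mean over all pixels of `-(y ln p + (1-y) ln(1-p))` in nats, with
#' predictions clipped to \[1e-7, 1 - 1e-7\].
#'
#' @param pred Probability matrix/array in \[0,1\].
#' @param label Binary matrix/array of the same shape.
#' @return BCE in nats.
#' @export
bce <- function(pred, label) {
  if (!identical(dim(pred), dim(label)) || length(pred) != length(label))
    stop("pred and label must have the same shape", call. = FALSE)
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  y <- as.numeric(label)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Pixelwise confusion counts between a predicted and a reference mask
#'
#' @param pred_mask,label Binary matrices of the same shape.
#' @return List with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred_mask, label) {
  if (!identical(dim(pred_mask), dim(label)))
    stop("masks must have the same shape", call. = FALSE)
  if (!is_binary(pred_mask) || !is_binary(label))
    stop("confusion() expects binary masks", call. = FALSE)
  p <- as.logical(pred_mask); y <- as.logical(label)
  list(TP = sum(p & y), FP = sum(p & !y), FN = sum(!p & y), TN = sum(!p & !y))
}

#' Intersection over union from confusion counts
#'
#' `IoU = TP / (FP + FN + TP)`; when both masks are empty the overlap is
#' defined as 1.
#' @param counts Output of [confusion()].
#' @export
iou <- function(counts) {
  den <- counts$FP + counts$FN + counts$TP
  if (den == 0) 1 else counts$TP / den
}

#' Dice coefficient from confusion counts
#'
#' `Dice = 2 TP / (FP + FN + 2 TP)`; both-empty convention is 1. Related to
#' IoU by `Dice = 2 IoU / (1 + IoU)`.
#' @param counts Output of [confusion()].
#' @export
dice <- function(counts) {
  den <- counts$FP + counts$FN + 2 * counts$TP
  if (den == 0) 1 else 2 * counts$TP / den
}

#' Boundary pixels of a binary mask
#'
#' Foreground pixels 4-adjacent to background (or to the image border).
#' @param mask Binary matrix.
#' @return (row, col) integer matrix.
#' @export
boundary_points <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  p <- matrix(0L, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- as.integer(mask > 0)
  inner <- p[2:(H + 1), 2:(W + 1)]
  nb4 <- p[1:H, 2:(W + 1)] + p[3:(H + 2), 2:(W + 1)] +
         p[2:(H + 1), 1:W] + p[2:(H + 1), 3:(W + 2)]
  which(inner == 1L & nb4 < 4L, arr.ind = TRUE)
}

#' Hausdorff distance between two point sets
#'
#' `HD = max(h(A,B), h(B,A))` with the directed distance
#' `h(A,B) = max_a min_b ||a-b||`. For integer pixel coordinates a Euclidean
#' distance-transform fast path is used; `method = "brute"` forces the
#' O(|A||B|) evaluation. Segmentation masks are compared on their
#' [boundary_points()] (edge emphasis).
#'
#' @param A,B Nonempty two-column (row, col) coordinate matrices.
#' @param method "auto", "grid" (distance transform) or "brute".
#' @return Distance in pixels.
#' @export
hausdorff <- function(A, B, method = c("auto", "grid", "brute")) {
  method <- match.arg(method)
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0)
    stop("Hausdorff distance is undefined for empty sets", call. = FALSE)
  integer_coords <- all(A == round(A)) && all(B == round(B))
  if (method == "auto") method <- if (integer_coords) "grid" else "brute"
  if (method == "grid" && !integer_coords)
    stop("grid method requires integer pixel coordinates", call. = FALSE)
  if (method == "brute") {
    h_ab <- max(vapply(seq_len(nrow(A)), function(i)
      min(sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2)), 0))
    h_ba <- max(vapply(seq_len(nrow(B)), function(i)
      min(sqrt((A[, 1] - B[i, 1])^2 + (A[, 2] - B[i, 2])^2)), 0))
    return(max(h_ab, h_ba))
  }
  off <- c(min(A[, 1], B[, 1]) - 1, min(A[, 2], B[, 2]) - 1)
  H <- max(A[, 1], B[, 1]) - off[1]
  W <- max(A[, 2], B[, 2]) - off[2]
  shift <- function(P) cbind(P[, 1] - off[1], P[, 2] - off[2])
  dist_at <- function(P, Q) {       # distances from points P to set Q
    m <- matrix(1, H, W)
    m[shift(Q)] <- 0
    D <- as.matrix(EBImage::distmap(m, metric = "euclidean"))
    max(D[shift(P)])
  }
  max(dist_at(A, B), dist_at(B, A))
}

#' Full segmentation metric panel
#'
#' @param pred Probability map (or binary mask) predicted by a model.
#' @param label Binary reference mask.
#' @param threshold Probability threshold for the mask-based metrics.
#' @return List with `bce`, `iou`, `dice`, `hd`.
#' @export
seg_metrics <- function(pred, label, threshold = 0.5) {
  m <- matrix(as.integer(pred >= threshold), nrow(pred), ncol(pred))
  cc <- confusion(m, label)
  hd <- if (cc$TP + cc$FP == 0 || cc$TP + cc$FN == 0) NA_real_
        else hausdorff(boundary_points(m), boundary_points(label))
  list(bce = bce(pred, label), iou = iou(cc), dice = dice(cc), hd = hd)
}

#' Illuminance uniformity of a light-receiving plane
#'
#' `U = E_min / E_mean` over the (masked) region; 1 for perfectly uniform
#' illumination.
#'
#' @param E Nonnegative illuminance matrix.
#' @param region Optional binary mask restricting the evaluation region.
#' @return Uniformity in \[0, 1\].
#' @export
uniformity <- function(E, region = NULL) {
  v <- if (is.null(region)) as.numeric(E) else E[region > 0]
  if (length(v) == 0) stop("empty evaluation region", call. = FALSE)
  if (any(v < 0)) stop("illuminance must be nonnegative", call. = FALSE)
  m <- mean(v)
  if (m == 0) stop("mean illuminance is zero", call. = FALSE)
  min(v) / m
}

#' Disparity error statistics against ground truth
#'
#' @param est Estimated disparity map (invalid pixels as `NA`).
#' @param gt Ground-truth disparity map (invalid as `NA`).
#' @param valid Optional binary mask of evaluable pixels.
#' @param bad_threshold Error (pixels) above which a pixel counts as bad.
#' @return List with `mae` (mean absolute error, pixels) and `bad_percent`
#'   (percentage of evaluated pixels with error > threshold).
#' @export
disparity_error <- function(est, gt, valid = NULL, bad_threshold = 2) {
  if (!identical(dim(est), dim(gt)))
    stop("disparity maps must have the same shape", call. = FALSE)
  ok <- is.finite(est) & is.finite(gt)
  if (!is.null(valid)) ok <- ok & (valid > 0)
  if (!any(ok)) stop("no valid pixels to evaluate", call. = FALSE)
  err <- abs(est[ok] - gt[ok])
  list(mae = mean(err), bad_percent = 100 * mean(err > bad_threshold))
}

#' Percent change between two reported metric values
#'
#' `100 (old - new) / old` for a reduction, `100 (new - old) / old` for an
#' increase; reported rounded to two decimals.
#'
#' @param old,new Metric values; `old` must be nonzero.
#' @param direction "reduction" or "increase".
#' @param digits Rounding for reporting (default 2).
#' @return Signed percentage.
#' @export
percent_change <- function(old, new, direction = c("reduction", "increase"),
                           digits = 2) {
  direction <- match.arg(direction)
  if (old == 0) stop("old value must be nonzero", call. = FALSE)
  pc <- if (direction == "reduction") 100 * (old - new) / old
        else 100 * (new - old) / old
  round(pc, digits)
}
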