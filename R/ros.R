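# Reactive-oxygen-species quantification: mitochondrial superoxide
# normalized by mitochondrial mass (MitoSOX / MitoTracker ratio) and
# cytosolic ROS reporter intensity (CellROX RFU).

#' Mitochondrial ROS level: MitoSOX / MitoTracker intensity ratio
#'
#' The mitochondrial ROS level is the mean in-mask superoxide-channel
#' intensity normalized by the mean in-mask mitochondrial-mass-channel
#' intensity, optionally after per-channel background subtraction. The
#' ratio is invariant to a common gain applied to both channels.
#'
#' @param sox_image,tracker_image numeric matrices of identical shape.
#' @param mask logical matrix (nonempty) restricting the measurement.
#' @param bg_sox,bg_tracker channel backgrounds subtracted before
#'   averaging.
#' @return a `ros_result` list: `mito_ros_ratio`, `sox_mean`,
#'   `tracker_mean`, `n_pixels`.
#' @export
mito_ros_ratio <- function(sox_image, tracker_image, mask = NULL,
                           bg_sox = 0, bg_tracker = 0) {
  if (!all(dim(sox_image) == dim(tracker_image))) {
    stop("channel images differ in shape", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(sox_image), ncol(sox_image))
  mask <- mask != 0
  if (!any(mask)) stop("`mask` is empty", call. = FALSE)
  sox_mean <- mean(sox_image[mask]) - bg_sox
  tracker_mean <- mean(tracker_image[mask]) - bg_tracker
  if (tracker_mean <= 0) {
    stop("background-corrected tracker mean <= 0; cannot normalize",
         call. = FALSE)
  }
  structure(list(mito_ros_ratio = sox_mean / tracker_mean,
                 sox_mean = sox_mean, tracker_mean = tracker_mean,
                 n_pixels = sum(mask)),
            class = "ros_result")
}

#' Cytosolic ROS level: mean CellROX intensity (RFU)
#'
#' @param cellrox_image numeric matrix.
#' @param cell_mask logical matrix (nonempty); default whole image.
#' @param bg background intensity subtracted from the mean.
#' @return a `ros_result` list: `cyto_ros_rfu`, `n_pixels`.
#' @export
cyto_ros_rfu <- function(cellrox_image, cell_mask = NULL, bg = 0) {
  if (is.null(cell_mask)) {
    cell_mask <- matrix(TRUE, nrow(cellrox_image), ncol(cellrox_image))
  }
  cell_mask <- cell_mask != 0
  if (!any(cell_mask)) stop("`cell_mask` is empty", call. = FALSE)
  structure(list(cyto_ros_rfu = mean(cellrox_image[cell_mask]) - bg,
                 n_pixels = sum(cell_mask)),
            class = "ros_result")
}

#' @export
print.ros_result <- function(x, ...) {
  if (!is.null(x$mito_ros_ratio)) {
    cat(sprintf("Mitochondrial ROS: sox/tracker ratio %.4g over %d px\n",
                x$mito_ros_ratio, x$n_pixels))
  } else {
    cat(sprintf("Cytosolic ROS: %.4g RFU over %d px\n",
                x$cyto_ros_rfu, x$n_pixels))
  }
  invisible(x)
}
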