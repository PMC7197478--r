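#' Detect nuclei in a DAPI image
#'
#' Segmentation pipeline: rescale intensities to `[0, 1]`, median filter,
#' local adaptive threshold, fill holes in the binary mask, smooth borders
#' with a single round of erosion and dilation, then label connected
#' components and take their centroids. Components smaller than `min_area`
#' pixels are dropped.
#'
#' @param dapi Numeric matrix of nonnegative pixel intensities (rows by
#'   columns).
#' @param median_radius Median-filter radius in pixels (default 10).
#' @param thresh_window Side of the moving-average window for the adaptive
#'   threshold, in pixels (default 25).
#' @param thresh_offset Intensity offset above the local mean required to
#'   call foreground (default 0.02, on the rescaled `[0, 1]` scale).
#' @param min_area Minimum connected-component area in pixels (default 50).
#' @param brush_size Diameter of the disc brush used for the
#'   erosion/dilation round (default 5).
#' @return A list of class `"nucleus_set"`: `centroids` (matrix with columns
#'   `row`, `col`) and `count`. A blank image yields `count = 0`.
#' @export
detect_nuclei <- function(dapi, median_radius = 10, thresh_window = 25,
                          thresh_offset = 0.02, min_area = 50,
                          brush_size = 5) {
  if (!is.matrix(dapi)) stop("dapi must be a matrix of pixel intensities")
  if (min(dim(dapi)) < 2 * median_radius + 1)
    stop("image too small for the median filter radius")
  rng <- range(dapi)
  empty <- function() structure(list(
    centroids = matrix(numeric(0), 0, 2,
                       dimnames = list(NULL, c("row", "col"))),
    count = 0L), class = "nucleus_set")
  if (rng[2] <= rng[1]) return(empty())  # constant image: nothing to find
  img <- EBImage::Image((dapi - rng[1]) / (rng[2] - rng[1]))
  img <- EBImage::medianFilter(img, size = median_radius)
  mask <- EBImage::thresh(img, w = thresh_window, h = thresh_window,
                          offset = thresh_offset)
  mask <- EBImage::fillHull(mask)
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  mask <- EBImage::dilate(EBImage::erode(mask, brush), brush)
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(empty())
  areas <- tabulate(as.integer(lab[lab > 0]), nbins = max(lab))
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(empty())
  mom <- EBImage::computeFeatures.moment(lab)
  # EBImage's first image dimension is the matrix row dimension
  centroids <- cbind(row = mom[keep, "m.cx"], col = mom[keep, "m.cy"])
  rownames(centroids) <- NULL
  structure(list(centroids = centroids, count = length(keep)),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat("nucleus_set:", x$count, "nuclei\n")
  if (x$count > 0) print(round(x$centroids, 1))
  invisible(x)
}

#' Background-corrected log-sum fluorescence score for one channel
#'
#' Places a square cell area of side `side` pixels centered on the nucleus
#' centroid (clipped at the image edges), estimates the channel background
#' as the median intensity of all pixels outside the square, subtracts that
#' background from every in-square pixel, sums the corrected values, and
#' returns the log10 of the sum. A nonpositive corrected sum has no defined
#' log score and yields `NA` (such cells fail downstream QC).
#'
#' @param image Numeric matrix of pixel intensities.
#' @param centroid Numeric `(row, col)` position inside the image.
#' @param side Side of the square cell area in pixels (default 100).
#' @return Scalar score, or `NA` when the corrected sum is nonpositive.
#' @export
score_channel <- function(image, centroid, side = 100) {
  if (!is.matrix(image)) stop("image must be a matrix")
  nr <- nrow(image); nc <- ncol(image)
  r <- round(centroid[1]); cc <- round(centroid[2])
  half <- side %/% 2
  r0 <- r - half + 1; r1 <- r0 + side - 1
  c0 <- cc - half + 1; c1 <- c0 + side - 1
  if (r1 < 1 || r0 > nr || c1 < 1 || c0 > nc)
    stop("cell area lies fully outside the image")
  rows <- max(1, r0):min(nr, r1)
  cols <- max(1, c0):min(nc, c1)
  inside <- matrix(FALSE, nr, nc)
  inside[rows, cols] <- TRUE
  if (all(inside))
    stop("cell area covers the whole image; no background pixels remain")
  bg <- stats::median(image[!inside])
  s <- sum(image[inside] - bg)
  if (s <= 0) return(NA_real_)
  log10(s)
}

#' Score one cell across the DAPI, EGFP and mCherry channels
#'
#' Applies [score_channel()] to each channel at the shared nucleus centroid
#' derived from the DAPI image, so the EGFP and mCherry cell areas are
#' aligned to the nucleus location.
#'
#' @param images Named list with numeric matrices `dapi`, `egfp`, and
#'   `mcherry`, all of the same dimensions.
#' @param centroid `(row, col)` nucleus centroid from the DAPI channel.
#' @param side Cell-area side in pixels (default 100).
#' @return One-row data frame with `dapi_score`, `egfp_score`,
#'   `mcherry_score`; any `NA` score flags the cell as unusable.
#' @export
score_cell <- function(images, centroid, side = 100) {
  need <- c("dapi", "egfp", "mcherry")
  missing_ch <- setdiff(need, names(images))
  if (length(missing_ch))
    stop("missing channel image(s): ", paste(missing_ch, collapse = ", "))
  dims <- vapply(images[need], dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("channel images must share dimensions")
  data.frame(
    dapi_score = score_channel(images$dapi, centroid, side),
    egfp_score = score_channel(images$egfp, centroid, side),
    mcherry_score = score_channel(images$mcherry, centroid, side))
}

#' Score all wells of an imaging run
#'
#' For each well, detects nuclei on the DAPI image and scores all three
#' channels at the centroid of each detected nucleus. Wells whose DAPI
#' image yields no nucleus, or more than one, are reported with the nucleus
#' count so that downstream QC can require exactly one cell per well.
#'
#' @param wells Named list; each element is a per-well named list of
#'   channel matrices (`dapi`, `egfp`, `mcherry`).
#' @param side Cell-area side in pixels (default 100).
#' @param ... Passed to [detect_nuclei()].
#' @return Data frame with one row per detected nucleus: `well_id`,
#'   `cells_in_well`, the three scores, and the centroid.
#' @export
score_wells <- function(wells, side = 100, ...) {
  rows <- lapply(names(wells), function(w) {
    imgs <- wells[[w]]
    ns <- detect_nuclei(imgs$dapi, ...)
    if (ns$count == 0)
      return(data.frame(well_id = w, cells_in_well = 0L,
                        dapi_score = NA_real_, egfp_score = NA_real_,
                        mcherry_score = NA_real_, centroid_row = NA_real_,
                        centroid_col = NA_real_))
    do.call(rbind, lapply(seq_len(ns$count), function(i) {
      sc <- score_cell(imgs, ns$centroids[i, ], side = side)
      cbind(data.frame(well_id = w, cells_in_well = ns$count), sc,
            data.frame(centroid_row = ns$centroids[i, "row"],
                       centroid_col = ns$centroids[i, "col"]))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a grayscale channel image from TIFF or PNG
#'
#' @param path Image file; 16-bit grayscale TIFF and PNG are supported
#'   through EBImage.
#' @return Numeric intensity matrix.
#' @export
read_channel_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) dat <- dat[, , 1]  # collapse gray-as-RGB
  as.matrix(dat)
}
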