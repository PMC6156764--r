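#' Difference-of-Gaussian filter parameters
#'
#' The DoG band-pass is the first stage of the nucleus detector: the image
#' is blurred with a narrow Gaussian (suppressing pixel noise) and a wide
#' Gaussian (estimating smooth background), and the wide blur is subtracted
#' from the narrow one. Output is signed.
#'
#' @param sigma_low SD (pixels) of the narrow Gaussian; default 1.
#' @param sigma_high SD (pixels) of the wide Gaussian; default 15.
#' @return An object of class `dog_params`.
#' @export
dog_params <- function(sigma_low = 1, sigma_high = 15) {
  if (!(sigma_low > 0)) stop("sigma_low must be positive")
  if (sigma_low >= sigma_high)
    stop("sigma_low must be strictly smaller than sigma_high")
  structure(list(sigma_low = sigma_low, sigma_high = sigma_high),
            class = "dog_params")
}

#' Nucleus acceptance parameters
#'
#' Post-segmentation filter: candidate regions are accepted as nuclei only
#' if their mean intensity on the source image reaches
#' `min_mean_intensity` (the minimum-average-intensity criterion) and their
#' area reaches `min_region_area` (suppresses single-pixel noise regions).
#'
#' @param k_clusters number of intensity clusters for the adaptive
#'   threshold (default 2: foreground/background).
#' @param min_mean_intensity minimum mean source-image intensity of an
#'   accepted nucleus, on the \[0, 1\] scale; default 0.2.
#' @param min_region_area minimum region area in pixels; default 40.
#' @param clear_border drop regions touching the image border
#'   (default `FALSE`).
#' @param watershed_tolerance minimum height (in distance-transform units,
#'   i.e. pixels) of a local maximum to seed its own object; the h-maxima
#'   depth of the marker detection. Default 0.3, calibrated on the
#'   synthetic generator so deliberately fused nucleus pairs are split
#'   without over-segmenting single nuclei.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(k_clusters = 2L,
                                min_mean_intensity = 0.2,
                                min_region_area = 40L,
                                clear_border = FALSE,
                                watershed_tolerance = 0.3) {
  if (k_clusters < 2L) stop("k_clusters must be >= 2")
  if (min_mean_intensity < 0) stop("min_mean_intensity must be >= 0")
  if (min_region_area < 1L) stop("min_region_area must be >= 1")
  structure(list(k_clusters = as.integer(k_clusters),
                 min_mean_intensity = min_mean_intensity,
                 min_region_area = as.integer(min_region_area),
                 clear_border = isTRUE(clear_border),
                 watershed_tolerance = watershed_tolerance),
            class = "segmentation_params")
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- EBImage::makeBrush(2L * r + 1L, shape = "gaussian", sigma = sigma)
  k / sum(k)
}

#' Apply a difference-of-Gaussian band-pass filter
#'
#' Computes `blur(image, sigma_low) - blur(image, sigma_high)` with
#' normalized Gaussian kernels truncated at 3 sigma and replicated borders.
#' The result is signed: flat regions map to ~0, compact bright structures
#' to positive values.
#'
#' @param image numeric matrix.
#' @param params a [dog_params()].
#' @return signed numeric matrix, same shape as `image`.
#' @export
dog_filter <- function(image, params = dog_params()) {
  stopifnot(inherits(params, "dog_params"), is.matrix(image))
  if (!all(is.finite(image))) stop("image must be finite")
  k_lo <- gaussian_kernel(params$sigma_low)
  k_hi <- gaussian_kernel(params$sigma_high)
  # replicate-pad so wide kernels also work on images smaller than the
  # kernel support; padding by the kernel radius leaves border semantics
  # identical to plain replicate-boundary filtering
  pad <- (nrow(k_hi) - 1L) %/% 2L
  h <- nrow(image); w <- ncol(image)
  ri <- c(rep(1L, pad), seq_len(h), rep(h, pad))
  ci <- c(rep(1L, pad), seq_len(w), rep(w, pad))
  padded <- image[ri, ci, drop = FALSE]
  lo <- EBImage::filter2(padded, k_lo, boundary = "replicate")
  hi <- EBImage::filter2(padded, k_hi, boundary = "replicate")
  out <- matrix(as.numeric(lo - hi), nrow = nrow(padded))
  out[pad + seq_len(h), pad + seq_len(w), drop = FALSE]
}

# Exact 1-D 2-means on a weighted set of unique values: scan every ordered
# split point, minimizing total within-cluster SSE via prefix sums.
# Returns the index s such that values[1..s] form the lower cluster.
best_split_index <- function(values, weights) {
  cw <- cumsum(weights)
  cwx <- cumsum(weights * values)
  cwx2 <- cumsum(weights * values^2)
  n <- length(values)
  tot_w <- cw[n]; tot_x <- cwx[n]; tot_x2 <- cwx2[n]
  s <- seq_len(n - 1L)
  sse_lo <- cwx2[s] - cwx[s]^2 / cw[s]
  w_hi <- tot_w - cw[s]; x_hi <- tot_x - cwx[s]
  sse_hi <- (tot_x2 - cwx2[s]) - x_hi^2 / w_hi
  which.min(sse_lo + sse_hi)
}

#' Adaptive threshold by k-means clustering of pixel intensities
#'
#' Partitions the pixel intensities into `k` clusters minimizing the
#' within-cluster squared error and returns the binary foreground mask of
#' the brightest cluster, together with the threshold (midpoint between
#' the brightest cluster's lower edge and its neighbour). For `k = 2` the
#' 1-D k-means objective is solved exactly and deterministically by
#' exhaustive split-point search on the intensity histogram; for `k > 2`
#' Lloyd iterations are run from quantile-spaced centers.
#'
#' @param image numeric matrix.
#' @param k_clusters number of clusters (>= 2).
#' @return list with elements `threshold` (numeric) and `mask` (logical
#'   matrix: pixels in the brightest cluster).
#' @export
kmeans_threshold <- function(image, k_clusters = 2L) {
  stopifnot(is.matrix(image))
  if (k_clusters < 2L) stop("k_clusters must be >= 2")
  v <- as.numeric(image)
  ux <- sort(unique(v))
  if (length(ux) < 2L)
    stop("degenerate input: constant image has no k-means threshold")
  if (k_clusters == 2L) {
    w <- tabulate(match(v, ux), nbins = length(ux))
    s <- best_split_index(ux, w)
    thr <- (ux[s] + ux[s + 1L]) / 2
  } else {
    centers <- stats::quantile(v, probs = seq(0, 1, length.out = k_clusters),
                               names = FALSE)
    centers <- unique(centers)
    km <- suppressWarnings(
      stats::kmeans(v, centers = matrix(centers, ncol = 1), iter.max = 100L))
    ord <- order(km$centers)
    top <- ord[length(ord)]                 # brightest cluster is foreground
    lo_edge <- min(v[km$cluster == top])
    below <- v[km$cluster != top]
    thr <- (max(below) + lo_edge) / 2
  }
  list(threshold = thr,
       mask = matrix(v > thr, nrow = nrow(image)))
}

#' Split a foreground mask into nuclei with a hybrid watershed
#'
#' The "hybrid" delineation combines the binary threshold mask with
#' watershed flooding: the Euclidean distance transform of the mask is
#' computed, its regional maxima (subject to an h-maxima depth
#' `tolerance`) seed the objects, and the inverted distance map is flooded
#' so fused nuclei are split along the watershed lines. The source image
#' accompanies the mask through the pipeline but intensities enter only in
#' the subsequent minimum-average-intensity filter, not in the flooding.
#' Flooding ties are resolved deterministically in raster-scan order.
#'
#' @param source_image numeric matrix (shape reference; carried for the
#'   downstream intensity filter).
#' @param mask logical or 0/1 matrix of foreground pixels.
#' @param tolerance h-maxima depth in pixels; default 1 for the bare
#'   operation ([segmentation_params()] carries the pipeline default).
#' @return integer label matrix (0 = background, labels 1..n contiguous).
#' @export
hybrid_watershed <- function(source_image, mask, tolerance = 1) {
  stopifnot(is.matrix(mask))
  if (!is.null(source_image) &&
      !identical(dim(source_image), dim(mask)))
    stop("source_image and mask must have the same shape")
  m <- matrix(as.numeric(mask), nrow = nrow(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(m)
  w <- EBImage::watershed(dm, tolerance = tolerance, ext = 1L)
  lab <- matrix(as.integer(round(EBImage::imageData(w))), nrow = nrow(mask))
  relabel_contiguous(lab)
}

relabel_contiguous <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(labels)
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  out <- labels
  out[out > 0L] <- map[out[out > 0L]]
  out
}

#' Accept candidate regions as nuclei by mean intensity and area
#'
#' Implements the post-processing acceptance criterion: a candidate region
#' is kept only if its mean intensity on `intensity_image` reaches
#' `min_mean_intensity` and its pixel area reaches `min_region_area`
#' (optionally also discarding border-touching regions). Survivors are
#' relabeled contiguously (1..n).
#'
#' @param labels integer label matrix.
#' @param intensity_image numeric matrix, same shape.
#' @param params a [segmentation_params()].
#' @return filtered integer label matrix.
#' @export
filter_regions <- function(labels, intensity_image,
                           params = segmentation_params()) {
  stopifnot(identical(dim(labels), dim(intensity_image)),
            inherits(params, "segmentation_params"))
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(labels)
  fg <- labels > 0L
  lab_fg <- labels[fg]
  area <- tabulate(lab_fg, nbins = max(ids))[ids]
  total <- unname(tapply(intensity_image[fg], lab_fg, sum))[match(ids, sort(unique(lab_fg)))]
  mean_int <- total / area
  keep <- area >= params$min_region_area & mean_int >= params$min_mean_intensity
  if (params$clear_border) {
    border_ids <- unique(c(labels[1, ], labels[nrow(labels), ],
                           labels[, 1], labels[, ncol(labels)]))
    keep <- keep & !(ids %in% border_ids)
  }
  drop <- ids[!keep]
  out <- labels
  if (length(drop)) out[out %in% drop] <- 0L
  relabel_contiguous(out)
}

#' Segment nuclei from a DAPI image
#'
#' The full nucleus detector: DoG band-pass, adaptive k-means threshold on
#' the preprocessed image, hybrid watershed of the threshold mask, then the
#' minimum-average-intensity / minimum-area acceptance filter evaluated on
#' the original image.
#'
#' @param image numeric matrix, the DAPI channel in \[0, 1\].
#' @param dog a [dog_params()].
#' @param seg a [segmentation_params()].
#' @return integer label matrix of accepted nuclei.
#' @export
#' @examples
#' field <- simulate_field(simulation_config(n_cells = 30, seed = 2))
#' nuclei <- segment_nuclei(field$channels$dapi)
#' max(nuclei)  # detected nucleus count
segment_nuclei <- function(image, dog = dog_params(),
                           seg = segmentation_params()) {
  d <- dog_filter(image, dog)
  th <- kmeans_threshold(d, seg$k_clusters)
  lab <- hybrid_watershed(d, th$mask, tolerance = seg$watershed_tolerance)
  filter_regions(lab, image, seg)
}

#' Per-region property table of a label map
#'
#' @param labels integer label matrix.
#' @param intensity_image optional numeric matrix for per-region mean
#'   intensity.
#' @param pixel_size pixel size in micrometres per pixel (for `area_um2`).
#' @return data frame with one row per region: `label`, `centroid_row`,
#'   `centroid_col` (0-based), `area_px`, `area_um2`, `mean_intensity`.
#' @export
region_table <- function(labels, intensity_image = NULL, pixel_size = 1) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids))
    return(data.frame(label = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area_px = integer(),
                      area_um2 = numeric(), mean_intensity = numeric()))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels)       # 0-based coordinates
  cols <- (idx - 1L) %/% nrow(labels)
  area <- as.integer(tabulate(lab, nbins = max(ids))[ids])
  f <- factor(lab, levels = ids)
  cr <- as.numeric(tapply(rows, f, mean))
  cc <- as.numeric(tapply(cols, f, mean))
  mi <- if (is.null(intensity_image)) rep(NA_real_, length(ids))
        else as.numeric(tapply(intensity_image[idx], f, mean))
  data.frame(label = ids, centroid_row = cr, centroid_col = cc,
             area_px = area, area_um2 = area * pixel_size^2,
             mean_intensity = mi)
}
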