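#' Classification parameters for transfection and proliferation calls
#'
#' @param flag_threshold transfection threshold on the per-cell mean Flag
#'   (DoG-preprocessed) intensity, or `"auto"` to select it from the
#'   intensity distribution with [select_transfection_threshold()].
#' @param edu_min_intensity minimum per-cell mean EdU intensity for an
#'   EdU-positive (proliferating) call; inclusive (>=). Default 0.25 on
#'   the \[0, 1\] scale.
#' @param flag_min_intensity additional absolute floor a transfected
#'   cell's mean Flag signal must reach (inclusive); default 0.
#' @param fallback_quantile quantile of the Flag intensities used as
#'   threshold when no bimodality is detected; default 0.75.
#' @param strict_flag logical; transfection comparison strict (`>`,
#'   default) or inclusive (`>=`).
#' @return An object of class `classify_params`.
#' @export
classify_params <- function(flag_threshold = "auto",
                            edu_min_intensity = 0.25,
                            flag_min_intensity = 0,
                            fallback_quantile = 0.75,
                            strict_flag = TRUE) {
  if (!identical(flag_threshold, "auto")) {
    if (!is.numeric(flag_threshold) || flag_threshold < 0)
      stop("flag_threshold must be \"auto\" or a non-negative number")
  }
  if (edu_min_intensity < 0 || flag_min_intensity < 0)
    stop("intensity thresholds must be >= 0")
  structure(list(flag_threshold = flag_threshold,
                 edu_min_intensity = edu_min_intensity,
                 flag_min_intensity = flag_min_intensity,
                 fallback_quantile = fallback_quantile,
                 strict_flag = isTRUE(strict_flag)),
            class = "classify_params")
}

#' Measure per-nucleus channel signals
#'
#' Builds one record per segmented nucleus. The Flag channel is
#' preprocessed with the identical DoG filter used for the DAPI channel
#' and its mean is taken over the nucleus positions; the nuclear EdU
#' marker is averaged directly over the nucleus regions. An optional
#' dilation grows the measurement region beyond the nucleus outline.
#'
#' @param nuclei integer label matrix from [segment_nuclei()].
#' @param flag_image,edu_image numeric matrices, same shape as `nuclei`.
#' @param dog [dog_params()] applied to the Flag channel.
#' @param dapi_image optional DAPI matrix for `mean_dapi`.
#' @param dilate_radius optional radius (pixels) by which the measurement
#'   region is dilated; 0 (default) measures on the nucleus mask only.
#' @param pixel_size micrometres per pixel, for `area_um2`.
#' @return data frame with one row per nucleus: `cell_id`, `centroid_row`,
#'   `centroid_col` (0-based), `area_px`, `area_um2`, `mean_dapi`,
#'   `mean_flag`, `mean_edu`.
#' @export
measure_channels <- function(nuclei, flag_image, edu_image,
                             dog = dog_params(), dapi_image = NULL,
                             dilate_radius = 0, pixel_size = 1) {
  stopifnot(is.matrix(nuclei))
  if (!identical(dim(nuclei), dim(flag_image)) ||
      !identical(dim(nuclei), dim(edu_image)))
    stop("channel images must share the label map's shape")
  if (!is.null(dapi_image) && !identical(dim(nuclei), dim(dapi_image)))
    stop("dapi_image must share the label map's shape")
  meas <- nuclei
  if (dilate_radius > 0) {
    brush <- EBImage::makeBrush(2L * ceiling(dilate_radius) + 1L,
                                shape = "disc")
    meas <- matrix(as.integer(EBImage::imageData(
      EBImage::dilate(EBImage::Image(nuclei), brush))), nrow = nrow(nuclei))
  }
  flag_dog <- dog_filter(flag_image, dog)
  base <- region_table(meas, NULL, pixel_size)
  if (!nrow(base))
    return(data.frame(cell_id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area_px = integer(),
                      area_um2 = numeric(), mean_dapi = numeric(),
                      mean_flag = numeric(), mean_edu = numeric()))
  idx <- which(meas > 0L)
  f <- factor(meas[idx], levels = base$label)
  out <- data.frame(
    cell_id = base$label,
    centroid_row = base$centroid_row,
    centroid_col = base$centroid_col,
    area_px = base$area_px,
    area_um2 = base$area_um2,
    mean_dapi = if (is.null(dapi_image)) NA_real_
                else as.numeric(tapply(dapi_image[idx], f, mean)),
    mean_flag = as.numeric(tapply(flag_dog[idx], f, mean)),
    mean_edu = as.numeric(tapply(edu_image[idx], f, mean))
  )
  rownames(out) <- NULL
  out
}

#' Select the transfection-intensity threshold from the Flag distribution
#'
#' Automates the manual threshold choice of the assay: the per-cell Flag
#' intensities are split into two components by the exact
#' within-class-variance-minimizing split and the threshold is the
#' midpoint between the components. All-positive (raw) intensities are
#' split on the log scale, where fluorescence modes are roughly
#' symmetric; signed DoG-scale measurements are split linearly. If the two components are
#' not separated (Ashman's D, the standardized mode distance, below
#' `min_separation`), the
#' distribution is treated as unimodal: a warning is emitted and the
#' configured fallback quantile is returned instead.
#'
#' @param flag_intensities numeric vector of per-cell mean Flag
#'   intensities (>= 10 values).
#' @param fallback_quantile quantile used when no bimodality is found.
#' @param min_separation minimum Ashman's D
#'   (|mu2 - mu1| / sqrt(2 (s1^2 + s2^2))) of the two components, on the
#'   original intensity scale, to accept the split; default 2.
#' @return numeric threshold on the original intensity scale, with
#'   attribute `method` (`"split"` or `"fallback"`).
#' @export
select_transfection_threshold <- function(flag_intensities,
                                          fallback_quantile = 0.75,
                                          min_separation = 2) {
  x <- flag_intensities[is.finite(flag_intensities)]
  if (length(x) < 10L)
    stop("need at least 10 intensity values to select a threshold")
  fallback <- function(msg) {
    warning(msg, call. = FALSE)
    structure(unname(stats::quantile(x, fallback_quantile)),
              method = "fallback")
  }
  if (length(unique(x)) < 2L)
    return(fallback("all Flag intensities identical; using fallback quantile"))
  # raw (all-positive) intensities are split on the log scale; signed
  # DoG-scale measurements are split linearly, where the band-passed
  # background mode is approximately symmetric around zero
  use_log <- min(x) > 0
  lx <- if (use_log) log(x) else x
  ux <- sort(unique(lx))
  w <- tabulate(match(lx, ux), nbins = length(ux))
  s <- best_split_index(ux, w)
  lo <- x[lx <= ux[s]]; hi <- x[lx > ux[s]]
  if (length(lo) < 2L || length(hi) < 2L)
    return(fallback("degenerate Flag split; using fallback quantile"))
  # Ashman's D of the two components on the original intensity scale;
  # D > 2 indicates a clean two-component structure
  sep <- abs(mean(hi) - mean(lo)) /
    sqrt(2 * (stats::var(lo) + stats::var(hi)) + 1e-12)
  if (!is.finite(sep) || sep < min_separation)
    return(fallback(sprintf(
      "no bimodality detected in Flag intensities (separation %.2f < %.2f); using fallback quantile",
      sep, min_separation)))
  mid <- (ux[s] + ux[s + 1L]) / 2
  structure(if (use_log) exp(mid) else mid, method = "split")
}

#' Flag each cell transfected / proliferating
#'
#' Applies the resolved thresholds: a cell is transfected iff its mean
#' Flag signal exceeds the transfection threshold (strictly, by default)
#' and reaches the absolute Flag floor; it is proliferating iff its mean
#' EdU signal reaches `edu_min_intensity` (inclusive).
#'
#' @param records data frame from [measure_channels()].
#' @param params a [classify_params()]; `flag_threshold = "auto"` resolves
#'   the threshold from `records$mean_flag`.
#' @param condition optional condition label stored with every record.
#' @return `records` with logical columns `transfected` and
#'   `proliferating` plus a `condition` column; the resolved threshold is
#'   attached as attribute `flag_threshold`.
#' @export
classify_cells <- function(records, params = classify_params(),
                           condition = NA_character_) {
  stopifnot(is.data.frame(records),
            all(c("mean_flag", "mean_edu") %in% names(records)))
  thr <- params$flag_threshold
  if (identical(thr, "auto"))
    thr <- as.numeric(select_transfection_threshold(
      records$mean_flag, params$fallback_quantile))
  above <- if (params$strict_flag) records$mean_flag > thr
           else records$mean_flag >= thr
  records$transfected <- above & records$mean_flag >= params$flag_min_intensity
  records$proliferating <- records$mean_edu >= params$edu_min_intensity
  records$condition <- condition
  attr(records, "flag_threshold") <- thr
  records
}

#' Render a classification overlay image
#'
#' Writes (or returns) an RGB overlay of the automatic cell detection:
#' nucleus outlines on the DAPI channel with transfected cells in green,
#' EdU-positive cells in red, and double-positive (transfected
#' proliferating) cells appearing yellow.
#'
#' @param nuclei integer label matrix.
#' @param cells classified cell table from [classify_cells()].
#' @param dapi_image numeric DAPI matrix used as the grayscale backdrop.
#' @param path optional PNG path; if `NULL` the EBImage object is
#'   returned.
#' @return Invisibly the overlay `Image` (and writes `path` if given).
#' @export
overlay_image <- function(nuclei, cells, dapi_image, path = NULL) {
  stopifnot(identical(dim(nuclei), dim(dapi_image)))
  base <- dapi_image / max(dapi_image, 1e-9) * 0.6
  r <- base; g <- base; b <- base
  tr_ids <- cells$cell_id[cells$transfected]
  ed_ids <- cells$cell_id[cells$proliferating]
  g[nuclei %in% tr_ids] <- 1
  r[nuclei %in% ed_ids] <- 1
  img <- EBImage::rgbImage(red = r, green = g, blue = b)
  if (!is.null(path)) EBImage::writeImage(img, path, type = "png")
  invisible(img)
}
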