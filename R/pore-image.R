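# Pore quantification from electron micrographs: threshold -> morphological
# opening -> connected-component labelling -> area filter -> size histogram
# and a coverage-based porosity estimate
#   phi = <A_p> * N_p / A_s
# which is identically total segmented pore area over sample area.

#' Calibrated grayscale image
#'
#' @param pixels Numeric matrix of intensities in [0, 1] (rows = y,
#'   columns = x, as returned by the PNG/TIFF readers).
#' @param nm_per_px Pixel size calibration, nanometres per pixel.
#' @param roi Optional analysis region `c(width_nm, height_nm)` cropped from
#'   the top-left corner of the image (e.g. `c(750, 500)`).
#' @return Object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, nm_per_px, roi = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!is.numeric(nm_per_px) || nm_per_px <= 0) stop("nm_per_px must be > 0")
  if (!is.null(roi)) {
    if (length(roi) != 2 || any(roi <= 0)) stop("roi must be c(width_nm, height_nm) > 0")
    if (roi[1] / nm_per_px > ncol(pixels) || roi[2] / nm_per_px > nrow(pixels))
      stop("roi exceeds image bounds")
  }
  structure(list(pixels = pixels, nm_per_px = nm_per_px, roi = roi),
            class = "calibrated_image")
}

#' Crop a calibrated image to its region of interest
#'
#' @param image A [calibrated_image()].
#' @return The image restricted to its ROI (a no-op when no ROI is set).
#' @export
apply_roi <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  if (is.null(image$roi)) return(image)
  nx <- round(image$roi[1] / image$nm_per_px)
  ny <- round(image$roi[2] / image$nm_per_px)
  calibrated_image(image$pixels[seq_len(ny), seq_len(nx), drop = FALSE],
                   image$nm_per_px, roi = NULL)
}

#' Threshold an image into pore and non-pore regions
#'
#' Applies the ROI crop, then a global threshold. The default method is
#' Otsu's automatic threshold; `method = "manual"` uses `manual_level`
#' directly. Pores are the darker phase by default (secondary-electron
#' micrographs show voids dark); set `polarity = "bright"` to invert.
#'
#' @param image A [calibrated_image()].
#' @param method `"otsu"` (default) or `"manual"`.
#' @param manual_level Threshold level in [0, 1] for the manual method.
#' @param polarity `"dark"` (pore pixels below threshold) or `"bright"`.
#' @return Logical matrix, `TRUE` = pore.
#' @export
threshold_pores <- function(image, method = c("otsu", "manual"),
                            manual_level = NULL,
                            polarity = c("dark", "bright")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  image <- apply_roi(image)
  px <- image$pixels
  if (length(px) == 0) stop("image is empty")
  if (method == "otsu") {
    if (diff(range(px)) == 0)
      stop("cannot auto-threshold a constant image; supply manual_level")
    level <- EBImage::otsu(EBImage::Image(t(px)), range = c(0, 1))
  } else {
    if (is.null(manual_level)) stop("manual method requires manual_level")
    level <- manual_level
  }
  if (polarity == "dark") px < level else px > level
}

#' Morphological filtering of a pore mask
#'
#' Erosion(s) followed by dilation(s) with a square structuring element;
#' the default (one of each, 3x3) is a morphological opening that removes
#' sub-element specks while preserving large pores to within a one-pixel
#' boundary band.
#'
#' @param mask Logical matrix from [threshold_pores()].
#' @param erode_iters,dilate_iters Non-negative iteration counts.
#' @param element Side of the square structuring element (odd integer).
#' @return Filtered logical matrix.
#' @export
morph_filter <- function(mask, erode_iters = 1, dilate_iters = 1, element = 3) {
  stopifnot(is.matrix(mask))
  if (erode_iters < 0 || dilate_iters < 0) stop("iteration counts must be >= 0")
  if (element < 1 || element %% 2 == 0) stop("element must be an odd positive integer")
  brush <- EBImage::makeBrush(element, shape = "box")
  m <- EBImage::Image(t(mask * 1))
  for (i in seq_len(erode_iters)) m <- EBImage::erode(m, brush)
  for (i in seq_len(dilate_iters)) m <- EBImage::dilate(m, brush)
  t(EBImage::imageData(m)) > 0.5
}

# Connected-component labels; EBImage::bwlabel is 4-connected, so for the
# 8-connected default diagonal-touching labels are merged afterwards.
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
  nlab <- max(lab)
  if (connectivity == 8 && nlab > 1) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal
    a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]    # up-right diagonal
    keep1 <- a1 > 0 & b1 > 0 & a1 != b1
    keep2 <- a2 > 0 & b2 > 0 & a2 != b2
    edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
    if (nrow(edges) > 0) {
      g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                       directed = FALSE)
      g <- igraph::add_vertices(
        g, length(setdiff(as.character(seq_len(nlab)),
                          igraph::V(g)$name)),
        name = setdiff(as.character(seq_len(nlab)), igraph::V(g)$name))
      comp <- igraph::components(g)$membership
      remap <- integer(nlab)
      remap[as.integer(names(comp))] <- comp
      lab[lab > 0] <- remap[lab[lab > 0]]
    }
  }
  lab
}

#' Label pores and measure their areas
#'
#' Connected components of the mask (8-connectivity by default) become pore
#' records with pixel counts converted to nm^2 via the calibration.
#'
#' @param mask Logical matrix, `TRUE` = pore.
#' @param image The [calibrated_image()] the mask came from (for
#'   `nm_per_px`); a bare numeric calibration is also accepted.
#' @param connectivity 8 (default) or 4.
#' @return `data.frame` with columns `label_id`, `pixel_count`, `area_nm2`,
#'   `centroid_row`, `centroid_col`.
#' @export
label_pores <- function(mask, image, connectivity = 8) {
  nm_per_px <- if (inherits(image, "calibrated_image")) image$nm_per_px else image
  if (!is.numeric(nm_per_px) || nm_per_px <= 0) stop("calibration nm_per_px must be > 0")
  lab <- label_components(mask, connectivity)
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) {
    return(data.frame(label_id = integer(0), pixel_count = integer(0),
                      area_nm2 = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0)))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  vals <- lab[lab > 0]
  counts <- as.integer(table(factor(vals, levels = ids)))
  crow <- tapply(idx[, 1], factor(vals, levels = ids), mean)
  ccol <- tapply(idx[, 2], factor(vals, levels = ids), mean)
  data.frame(
    label_id = seq_along(ids),
    pixel_count = counts,
    area_nm2 = counts * nm_per_px^2,
    centroid_row = as.numeric(crow),
    centroid_col = as.numeric(ccol)
  )
}

#' Filter pore records to an area range
#'
#' Keeps pores whose area lies in the inclusive range `[min_nm2, max_nm2]`
#' (default 5-300 nm^2); pores outside the range are excluded from all
#' downstream statistics.
#'
#' @param records Pore record `data.frame` from [label_pores()].
#' @param min_nm2,max_nm2 Inclusive area bounds in nm^2.
#' @return The filtered records, original order preserved.
#' @export
filter_pores <- function(records, min_nm2 = 5, max_nm2 = 300) {
  if (min_nm2 > max_nm2) stop("min_nm2 must not exceed max_nm2")
  records[records$area_nm2 >= min_nm2 & records$area_nm2 <= max_nm2, , drop = FALSE]
}

#' Pore-size frequency distribution
#'
#' Bins pore areas into fixed-width bins over `[lo, hi]` (default width 15
#' over 5-305 nm^2, i.e. 20 bins `[5,20), [20,35), ..., [290,305]`; the
#' last bin is closed).
#'
#' @param records Filtered pore records.
#' @param bin_width Bin width in nm^2.
#' @param lo,hi Histogram range in nm^2; `hi - lo` must be a multiple of
#'   `bin_width`.
#' @return Object of class `pore_size_distribution`: list with `bin_edges`,
#'   `counts`, `freq`.
#' @export
size_histogram <- function(records, bin_width = 15, lo = 5, hi = 305) {
  if ((hi - lo) %% bin_width != 0)
    stop("(hi - lo) must be divisible by bin_width")
  edges <- seq(lo, hi, by = bin_width)
  a <- records$area_nm2
  if (any(a < lo | a > hi)) stop("records contain areas outside [lo, hi]; filter first")
  bin <- pmin(floor((a - lo) / bin_width) + 1, length(edges) - 1)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  freq <- if (sum(counts) > 0) counts / sum(counts) else rep(0, length(counts))
  structure(list(bin_edges = edges, counts = counts, freq = freq),
            class = "pore_size_distribution")
}

#' Porosity estimate from segmented pores
#'
#' `phi = <A_p> * N_p / A_s`, the mean pore area times the pore count over
#' the sample area -- identically the total segmented pore area divided by
#' the sample area. Zero pores give `phi = 0`.
#'
#' @param records Pore records (usually filtered).
#' @param sample_area_nm2 Total analysed area `A_s` in nm^2.
#' @return List with `mean_pore_area`, `n_pores`, `sample_area_nm2`, `phi`.
#' @export
porosity_estimate <- function(records, sample_area_nm2) {
  if (sample_area_nm2 <= 0) stop("sample_area_nm2 must be > 0")
  n <- nrow(records)
  mean_area <- if (n > 0) mean(records$area_nm2) else 0
  list(
    mean_pore_area = mean_area,
    n_pores = n,
    sample_area_nm2 = sample_area_nm2,
    phi = mean_area * n / sample_area_nm2
  )
}

#' Compare two pore-size distributions
#'
#' Per-bin relative-frequency differences (`b - a`) and, when the sign of
#' the difference flips exactly once along the bins, the area at which the
#' balance crosses over (e.g. one genotype richer in small pores, the other
#' in large pores).
#'
#' @param dist_a,dist_b Two [size_histogram()] results on identical bins.
#' @return List with `table` (bin_lo, bin_hi, freq_a, freq_b, diff) and
#'   `crossover_nm2` (the shared bin edge at the unique sign flip, or NA).
#' @export
compare_distributions <- function(dist_a, dist_b) {
  stopifnot(inherits(dist_a, "pore_size_distribution"),
            inherits(dist_b, "pore_size_distribution"))
  if (!identical(dist_a$bin_edges, dist_b$bin_edges))
    stop("distributions must share identical bin edges")
  edges <- dist_a$bin_edges
  d <- dist_b$freq - dist_a$freq
  tab <- data.frame(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    freq_a = dist_a$freq,
    freq_b = dist_b$freq,
    diff = d
  )
  s <- sign(d)
  nz <- which(s != 0)
  crossover <- NA_real_
  if (length(nz) >= 2) {
    flips <- which(diff(s[nz]) != 0)
    if (length(flips) == 1) {
      # edge between the last bin of one sign and the first of the other
      crossover <- edges[nz[flips + 1]]
    }
  }
  list(table = tab, crossover_nm2 = crossover)
}
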