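#' Configuration of the synthetic stained-section renderer
#'
#' Describes a nickel-DAB-like image: dark nuclear disks on a light
#' background, restricted to a horizontal band standing for the pyramidal
#' cell layer, partitioned into consecutive 200 um-wide ROI boxes.
#'
#' Placement guarantees every pair of nucleus centers is separated by more
#' than twice the maximum radius (plus a small guard gap), every disk lies
#' fully inside the band, and centers keep a lateral margin from ROI box
#' edges so a detected centroid cannot fall into the wrong box.
#'
#' @param scale_px_per_um pixels per micrometre.
#' @param roi_width_um ROI box width in micrometres.
#' @param band_height_um pyramidal-layer band height in micrometres.
#' @param radius_px_range min and max nucleus radius in pixels.
#' @param background,foreground 8-bit gray levels of background and nuclei.
#' @param noise_sd Gaussian pixel noise standard deviation (gray levels).
#' @param edge_margin_px minimum lateral distance of a center from an ROI box
#'   edge.
#' @return list of class `fos_image_config`.
#' @export
image_config <- function(scale_px_per_um = 1, roi_width_um = 200,
                         band_height_um = 100, radius_px_range = c(4, 6),
                         background = 200, foreground = 60, noise_sd = 8,
                         edge_margin_px = 3) {
  stopifnot(scale_px_per_um > 0, roi_width_um > 0, band_height_um > 0,
            length(radius_px_range) == 2, all(radius_px_range > 0),
            diff(radius_px_range) >= 0, noise_sd >= 0,
            background > foreground)
  structure(as.list(environment()), class = "fos_image_config")
}

#' Render a synthetic stained section for one row of ROIs
#'
#' Draws one ROI box per count, places exactly `counts[i]` non-overlapping
#' dark disks in box `i` by rejection sampling, and adds Gaussian noise.
#' Uses the current RNG state.
#'
#' @param counts integer vector of per-ROI nucleus counts (distal to
#'   proximal), or a single animal's count rows (as from
#'   [generate_animal()]) together with `section`/`hemisphere` selecting one
#'   section.
#' @param config a `fos_image_config`.
#' @param section,hemisphere used only when `counts` is a data frame.
#' @return list with `image` (numeric matrix, rows = y, gray levels 0-255),
#'   `truth` (data frame `x`, `y`, `r`, `roi` of true nucleus centers),
#'   `boxes` (the ROI boxes used) and `counts`.
#' @export
render_section_image <- function(counts, config = image_config(),
                                 section = NULL, hemisphere = "H1") {
  if (is.data.frame(counts)) {
    if (is.null(section)) stop("give `section` when `counts` is a data frame")
    rows <- counts[counts$section == section &
                     counts$hemisphere == hemisphere, ]
    counts <- rows$count[order(rows$roi)]
  }
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  w_box <- round(config$roi_width_um * config$scale_px_per_um)
  height <- round(config$band_height_um * config$scale_px_per_um)
  width <- w_box * length(counts)
  boxes <- place_roi_boxes(list(x0 = 0, y0 = 0, width = width,
                                height = height),
                           scale = config$scale_px_per_um,
                           width_um = config$roi_width_um)
  r_max <- config$radius_px_range[2]
  min_sep <- 2 * r_max + 4          # guard gap: components can never touch
  placed_x <- numeric(0); placed_y <- numeric(0)
  truth <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    n <- counts[i]
    if (n == 0L) { truth[[i]] <- NULL; next }
    lo_x <- boxes$xmin[i] + config$edge_margin_px
    hi_x <- boxes$xmax[i] - config$edge_margin_px
    lo_y <- r_max + 1; hi_y <- height - r_max - 1
    if (hi_x <= lo_x || hi_y <= lo_y) {
      stop("ROI box too small for requested nuclei; enlarge the band or ",
           "shrink the radii")
    }
    got <- 0L; tries <- 0L
    while (got < n) {
      tries <- tries + 1L
      if (tries > 400L * n) {
        stop("could not place ", n, " non-overlapping nuclei in ROI box ", i,
             "; enlarge the band or shrink the radii")
      }
      x <- stats::runif(1, lo_x, hi_x); y <- stats::runif(1, lo_y, hi_y)
      if (length(placed_x) &&
          min((placed_x - x)^2 + (placed_y - y)^2) < min_sep^2) next
      placed_x <- c(placed_x, x); placed_y <- c(placed_y, y)
      got <- got + 1L
    }
    k <- seq.int(length(placed_x) - n + 1L, length(placed_x))
    truth[[i]] <- data.frame(
      x = placed_x[k], y = placed_y[k],
      r = stats::runif(n, config$radius_px_range[1], config$radius_px_range[2]),
      roi = i)
  }
  truth <- if (length(placed_x)) do.call(rbind, truth) else
    data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
               roi = integer(0))
  img <- matrix(config$background, nrow = height, ncol = width)
  for (j in seq_len(nrow(truth))) {
    cx <- truth$x[j]; cy <- truth$y[j]; r <- truth$r[j]
    xs <- max(1, floor(cx - r)):min(width, ceiling(cx + r))
    ys <- max(1, floor(cy - r)):min(height, ceiling(cy + r))
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    sub <- img[ys, xs, drop = FALSE]
    sub[d2 <= r^2] <- config$foreground
    img[ys, xs] <- sub
  }
  if (config$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), sd = config$noise_sd),
                        nrow = height)
  }
  img <- pmin(pmax(img, 0), 255)
  rownames(truth) <- NULL
  list(image = img, truth = truth, boxes = boxes, counts = counts)
}

#' Nucleus detection parameters
#'
#' Detection is threshold-based: pixels darker than the robust background
#' estimate by more than `threshold_k` robust standard deviations (MAD) form
#' a mask; connected components within the area window are nuclei.
#'
#' @param background_estimator "global_median" or "percentile".
#' @param percentile background percentile when `background_estimator =
#'   "percentile"`.
#' @param threshold_k contrast threshold in robust-SD units.
#' @param min_area_px,max_area_px accepted component area range (pixels).
#' @param connectivity pixel connectivity, 4 or 8.
#' @param dark_on_light if `FALSE`, detect bright objects on dark background.
#' @return list of class `fos_detection_params`.
#' @export
detection_params <- function(background_estimator = c("global_median",
                                                      "percentile"),
                             percentile = 0.5, threshold_k = 3,
                             min_area_px = 20L, max_area_px = 250L,
                             connectivity = 8L, dark_on_light = TRUE) {
  background_estimator <- match.arg(background_estimator)
  stopifnot(threshold_k > 0, min_area_px >= 1,
            min_area_px <= max_area_px, connectivity %in% c(4L, 8L))
  structure(list(background_estimator = background_estimator,
                 percentile = percentile, threshold_k = threshold_k,
                 min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px),
                 connectivity = as.integer(connectivity),
                 dark_on_light = isTRUE(dark_on_light)),
            class = "fos_detection_params")
}

#' Robust background intensity of a grayscale image
#'
#' @param image numeric matrix of pixel intensities.
#' @param params a `fos_detection_params`.
#' @return scalar intensity (median, or the configured percentile).
#' @export
estimate_background <- function(image, params = detection_params()) {
  if (length(image) == 0) stop("empty image")
  if (params$background_estimator == "global_median") {
    stats::median(image)
  } else {
    unname(stats::quantile(image, params$percentile))
  }
}

# internal: label foreground mask pixels into connected components.
# Builds neighbor-pair edges between foreground pixels and takes graph
# components; supports 4- and 8-connectivity.
label_components <- function(mask_idx, nrow_img, connectivity) {
  n <- length(mask_idx)
  if (n == 0) return(integer(0))
  row <- (mask_idx - 1L) %% nrow_img + 1L
  col <- (mask_idx - 1L) %/% nrow_img + 1L
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  pos <- nrow_img * (col - 1L) + row      # == mask_idx, sorted lookup key
  edges <- integer(0)
  for (off in offsets) {
    nb <- nrow_img * (col + off[2] - 1L) + (row + off[1])
    valid <- row + off[1] >= 1L & row + off[1] <= nrow_img
    j <- match(nb, pos)
    ok <- which(valid & !is.na(j))
    if (length(ok)) edges <- c(edges, rbind(ok, j[ok]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  as.integer(igraph::components(g)$membership)
}

#' Detect stained nuclei in a grayscale section image
#'
#' Pixels darker than `background - threshold_k * MAD` (dark-on-light
#' polarity) are masked; connected components with area inside
#' `[min_area_px, max_area_px]` are returned. Deterministic; adding a
#' constant to all pixels leaves the result unchanged because the background
#' and spread are re-estimated.
#'
#' @param image numeric matrix.
#' @param params a `fos_detection_params`.
#' @return data frame with one row per nucleus: `x`, `y` (centroid, pixel
#'   coordinates, x = column), `area`, `mean_intensity`.
#' @export
detect_nuclei <- function(image, params = detection_params()) {
  bg <- estimate_background(image, params)
  spread <- stats::mad(image)
  if (spread == 0) spread <- 1e-8
  mask <- if (params$dark_on_light) {
    image < bg - params$threshold_k * spread
  } else {
    image > bg + params$threshold_k * spread
  }
  idx <- which(mask)
  comp <- label_components(idx, nrow(image), params$connectivity)
  empty <- data.frame(x = numeric(0), y = numeric(0), area = integer(0),
                      mean_intensity = numeric(0))
  if (!length(idx)) return(empty)
  row <- (idx - 1L) %% nrow(image) + 1L
  col <- (idx - 1L) %/% nrow(image) + 1L
  area <- tabulate(comp)
  keep <- which(area >= params$min_area_px & area <= params$max_area_px)
  if (!length(keep)) return(empty)
  sel <- comp %in% keep
  out <- data.frame(
    x = tapply(col[sel], comp[sel], mean),
    y = tapply(row[sel], comp[sel], mean),
    area = as.integer(area[keep][order(keep)]),
    mean_intensity = tapply(image[idx][sel], comp[sel], mean))
  out <- out[order(out$x, out$y), ]
  rownames(out) <- NULL
  out
}

#' Partition a layer band into consecutive ROI boxes
#'
#' Boxes of width `width_um * scale` pixels are laid left (distal) to right
#' (proximal) across the band; a final partial box is dropped.
#'
#' @param layer_band list with `x0`, `y0`, `width`, `height` in pixels.
#' @param scale pixels per micrometre.
#' @param width_um ROI width in micrometres.
#' @return data frame `roi`, `xmin`, `xmax`, `ymin`, `ymax` (boxes share
#'   edges; a point on a shared edge belongs to the lower-index box).
#' @export
place_roi_boxes <- function(layer_band, scale, width_um = 200) {
  if (scale <= 0) stop("`scale` must be positive")
  w <- width_um * scale
  n <- floor(layer_band$width / w + 1e-9)
  if (n < 1) stop("band narrower than one ROI")
  data.frame(roi = seq_len(n),
             xmin = layer_band$x0 + (seq_len(n) - 1) * w,
             xmax = layer_band$x0 + seq_len(n) * w,
             ymin = layer_band$y0, ymax = layer_band$y0 + layer_band$height)
}

#' Tally detections per ROI box
#'
#' A detection is assigned to the box containing its centroid; a centroid
#' exactly on a shared edge goes to the lower-index box; detections outside
#' all boxes are ignored.
#'
#' @param detections data frame with centroid columns `x`, `y`.
#' @param roi_boxes as returned by [place_roi_boxes()]; must be disjoint.
#' @return integer vector of counts, one per box.
#' @export
count_in_rois <- function(detections, roi_boxes) {
  b <- roi_boxes[order(roi_boxes$xmin), ]
  if (nrow(b) > 1 && any(b$xmax[-nrow(b)] > b$xmin[-1] + 1e-9)) {
    stop("ROI boxes overlap")
  }
  counts <- integer(nrow(roi_boxes))
  if (!nrow(detections)) return(counts)
  for (i in seq_len(nrow(roi_boxes))) {
    lo_open <- roi_boxes$xmin[i] != min(roi_boxes$xmin)
    in_x <- if (lo_open) detections$x > roi_boxes$xmin[i] &
                         detections$x <= roi_boxes$xmax[i]
            else detections$x >= roi_boxes$xmin[i] &
                 detections$x <= roi_boxes$xmax[i]
    in_y <- detections$y >= roi_boxes$ymin[i] &
            detections$y <= roi_boxes$ymax[i]
    counts[i] <- sum(in_x & in_y)
  }
  counts
}

#' Write a rendered section image as 8-bit grayscale PNG
#'
#' @param image numeric matrix, gray levels 0-255.
#' @param path output file.
#' @export
write_section_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}
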