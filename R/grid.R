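#' Canonical dorsal CA1 ROI grid
#'
#' Builds the grid of counting ROIs covering the dorsal CA1 pyramidal layer:
#' ordered coronal sections along the antero-posterior axis, each carrying a
#' row of contiguous 200 um ROIs along the proximo-distal axis. By default 12
#' sections span bregma -1.22 to -1.92 mm, with 8 ROIs per hemisphere in the
#' four most anterior sections, 10 in the four medial ones and 12 in the four
#' most posterior ones.
#'
#' ROI index 1 is the most distal position (nearest the subiculum, anchored at
#' the ventricle midline); indices increase toward proximal CA1 (toward
#' CA2/dentate gyrus).
#'
#' @param n_sections number of coronal sections (antero-posterior axis).
#' @param roi_counts named integer vector giving the per-hemisphere ROI count
#'   for each antero-posterior band, in band order.
#' @param ap_bands named list of integer vectors assigning section indices to
#'   the bands named in `roi_counts`; must partition `1:n_sections`.
#' @param bregma numeric vector of bregma coordinates (mm), one per section.
#' @return An object of class `fos_grid`: a list with a `sections` data frame
#'   (`section`, `bregma`, `n_roi`, `ap_band`) and the two hemisphere labels.
#' @examples
#' grid <- build_canonical_grid()
#' grid$sections$n_roi   # 8 8 8 8 10 10 10 10 12 12 12 12
#' @export
build_canonical_grid <- function(n_sections = 12L,
                                 roi_counts = c(anterior = 8L, medial = 10L,
                                                posterior = 12L),
                                 ap_bands = list(anterior = 1:4, medial = 5:8,
                                                 posterior = 9:12),
                                 bregma = seq(-1.22, -1.92,
                                              length.out = n_sections)) {
  n_sections <- as.integer(n_sections)
  if (n_sections < 1L) stop("`n_sections` must be >= 1")
  if (is.null(names(roi_counts)) || is.null(names(ap_bands)) ||
      !setequal(names(roi_counts), names(ap_bands))) {
    stop("`roi_counts` and `ap_bands` must share the same band names")
  }
  covered <- sort(unlist(ap_bands, use.names = FALSE))
  if (!identical(as.integer(covered), seq_len(n_sections))) {
    stop("`ap_bands` must partition sections 1..", n_sections,
         " (each section in exactly one band)")
  }
  if (length(bregma) != n_sections) {
    stop("`bregma` must have one coordinate per section")
  }
  band_of <- character(n_sections)
  for (b in names(ap_bands)) band_of[ap_bands[[b]]] <- b
  n_roi <- as.integer(roi_counts[band_of])
  if (any(n_roi < 1L)) stop("every band must carry at least one ROI")
  sections <- data.frame(section = seq_len(n_sections), bregma = bregma,
                         n_roi = n_roi, ap_band = band_of,
                         stringsAsFactors = FALSE)
  structure(list(sections = sections, hemispheres = c("H1", "H2")),
            class = "fos_grid")
}

#' @export
print.fos_grid <- function(x, ...) {
  cat("dCA1 ROI grid:", nrow(x$sections), "sections x",
      paste(range(x$sections$n_roi), collapse = "-"),
      "ROIs x 2 hemispheres (",
      sum(x$sections$n_roi), "nominal positions per hemisphere )\n")
  invisible(x)
}

#' Enumerate all grid coordinates
#'
#' @param grid a `fos_grid`.
#' @param hemispheres hemisphere labels to include.
#' @return data frame with columns `hemisphere`, `section`, `roi`, one row per
#'   nominal ROI position.
#' @export
grid_coordinates <- function(grid, hemispheres = grid$hemispheres) {
  per_hemi <- do.call(rbind, lapply(seq_len(nrow(grid$sections)), function(i) {
    data.frame(section = grid$sections$section[i],
               roi = seq_len(grid$sections$n_roi[i]))
  }))
  out <- do.call(rbind, lapply(hemispheres, function(h) {
    cbind(data.frame(hemisphere = h, stringsAsFactors = FALSE), per_hemi)
  }))
  rownames(out) <- NULL
  out
}

#' Default eight-subregion scheme for dorsal CA1
#'
#' Crosses the grid's antero-posterior bands (anterior/medial/posterior) with
#' proximo-distal bands of the ROI index to yield the eight named subregions
#' AD, AC, MD, MC, MP, PD, PC, PP. Under the defaults the distal band is ROI
#' 1-4, central 5-8 and proximal 9 and above, so anterior sections (8 ROIs)
#' have no proximal band and no antero-proximal subregion exists.
#'
#' @param pd_breaks two increasing integers: the last ROI index of the distal
#'   band and of the central band; larger indices are proximal.
#' @param flip_pd if `TRUE`, reverse the proximo-distal orientation (ROI 1
#'   proximal instead of distal) before banding.
#' @return An object of class `fos_scheme`.
#' @export
default_subregion_scheme <- function(pd_breaks = c(4L, 8L), flip_pd = FALSE) {
  pd_breaks <- as.integer(pd_breaks)
  if (length(pd_breaks) != 2L || any(pd_breaks < 1L) || diff(pd_breaks) <= 0L) {
    stop("`pd_breaks` must be two increasing positive integers")
  }
  structure(list(pd_breaks = pd_breaks, flip_pd = isTRUE(flip_pd),
                 ap_letters = c(anterior = "A", medial = "M", posterior = "P"),
                 pd_letters = c(distal = "D", central = "C", proximal = "P")),
            class = "fos_scheme")
}

#' @export
print.fos_scheme <- function(x, ...) {
  cat("dCA1 subregion scheme: distal = ROI 1-", x$pd_breaks[1],
      ", central = ", x$pd_breaks[1] + 1L, "-", x$pd_breaks[2],
      ", proximal = ", x$pd_breaks[2] + 1L, "+",
      if (x$flip_pd) " (orientation flipped)", "\n", sep = "")
  invisible(x)
}

# internal: stop unless every (hemisphere, section, roi) row is on the grid
validate_coords <- function(coords, grid, what = "coordinate") {
  bad_h <- !(coords$hemisphere %in% grid$hemispheres)
  bad_s <- !(coords$section %in% grid$sections$section)
  if (any(bad_h)) stop("invalid hemisphere in ", what, ": ",
                       paste(unique(coords$hemisphere[bad_h]), collapse = ", "))
  if (any(bad_s)) stop("invalid section in ", what, ": ",
                       paste(unique(coords$section[bad_s]), collapse = ", "))
  n_roi <- grid$sections$n_roi[match(coords$section, grid$sections$section)]
  bad_r <- coords$roi < 1L | coords$roi > n_roi
  if (any(bad_r)) {
    i <- which(bad_r)[1]
    stop("ROI index ", coords$roi[i], " is outside the grid at section ",
         coords$section[i], " (", n_roi[i], " ROIs available)")
  }
  invisible(TRUE)
}

#' Assign grid coordinates to subregions
#'
#' @param coords data frame with columns `hemisphere`, `section`, `roi` (a
#'   single coordinate may also be given as a list with those names).
#' @param grid a `fos_grid`.
#' @param scheme a `fos_scheme`.
#' @return character vector of subregion labels ("AD", "PC", ...), one per
#'   coordinate. Coordinates off the grid raise an error.
#' @examples
#' grid <- build_canonical_grid(); scheme <- default_subregion_scheme()
#' assign_subregion(data.frame(hemisphere = "H1", section = 10, roi = 2),
#'                  grid, scheme)  # "PD"
#' @export
assign_subregion <- function(coords, grid, scheme) {
  coords <- as.data.frame(coords)
  validate_coords(coords, grid)
  ap <- grid$sections$ap_band[match(coords$section, grid$sections$section)]
  roi <- coords$roi
  if (scheme$flip_pd) {
    n_roi <- grid$sections$n_roi[match(coords$section, grid$sections$section)]
    roi <- n_roi - roi + 1L
  }
  pd <- ifelse(roi <= scheme$pd_breaks[1], "distal",
               ifelse(roi <= scheme$pd_breaks[2], "central", "proximal"))
  unname(paste0(scheme$ap_letters[ap], scheme$pd_letters[pd]))
}

#' Subregion sizes per hemisphere
#'
#' @inheritParams assign_subregion
#' @return named integer vector: number of nominal ROI positions per
#'   subregion in one hemisphere.
#' @export
subregion_sizes <- function(grid, scheme) {
  coords <- grid_coordinates(grid, hemispheres = grid$hemispheres[1])
  labs <- assign_subregion(coords, grid, scheme)
  tab <- table(labs)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Euclidean distance between grid coordinates
#'
#' Distances are measured in grid-index units on the (section, roi) lattice:
#' `sqrt((section_a - section_b)^2 + (roi_a - roi_b)^2)`. Coordinates on
#' different hemispheres have no defined distance; neighborhoods are always
#' within a hemisphere.
#'
#' @param a,b coordinates as data frames (or lists) with `hemisphere`,
#'   `section`, `roi`; recycled elementwise like arithmetic.
#' @return numeric vector of distances.
#' @export
grid_distance <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  if (any(a$hemisphere != b$hemisphere)) {
    stop("grid_distance is undefined across hemispheres")
  }
  sqrt((a$section - b$section)^2 + (a$roi - b$roi)^2)
}

# internal: full pairwise distance matrix for one hemisphere's coordinates
pairwise_grid_distance <- function(coords) {
  as.matrix(stats::dist(cbind(coords$section, coords$roi)))
}
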