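# Preprocessing: eye (illuminated-field) mask, optic-disc mask from manual
# endpoint annotations, and analysis-channel selection.

#' Construct a fundus image object
#'
#' @param pixels H x W x 3 numeric array, 8-bit intensities in [0, 255].
#' @param id identifier string.
#' @param path source path, if the image was read from disk.
#' @return an object of class \code{fundus_image}.
#' @export
fundus_image <- function(pixels, id = "image", path = NA_character_) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3L] == 3L,
            dim(pixels)[1L] >= 64L, dim(pixels)[2L] >= 64L,
            min(pixels) >= 0, max(pixels) <= 255)
  structure(list(pixels = pixels, id = id, path = path),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Fundus image '%s': %d x %d px, 3 channels\n", x$id,
              d[1L], d[2L]))
  invisible(x)
}

#' Optic-disc geometry from annotated major-axis endpoints
#'
#' The optic disc is annotated manually by its two major-axis endpoints; the
#' disc is modelled as the circle whose center is their midpoint and whose
#' radius is half their distance. All diagnostic regions are anchored to
#' this geometry.
#'
#' @param endpoint_a,endpoint_b numeric \code{c(row, col)} pixel coordinates.
#' @return an object of class \code{od_geometry} with fields
#'   \code{endpoint_a}, \code{endpoint_b}, \code{centroid}, \code{radius}.
#' @export
od_geometry <- function(endpoint_a, endpoint_b) {
  endpoint_a <- as.numeric(endpoint_a); endpoint_b <- as.numeric(endpoint_b)
  stopifnot(length(endpoint_a) == 2L, length(endpoint_b) == 2L)
  radius <- sqrt(sum((endpoint_a - endpoint_b)^2)) / 2
  if (radius <= 0)
    stop("optic-disc endpoints coincide: zero radius", call. = FALSE)
  structure(list(endpoint_a = endpoint_a, endpoint_b = endpoint_b,
                 centroid = (endpoint_a + endpoint_b) / 2, radius = radius),
            class = "od_geometry")
}

#' @export
print.od_geometry <- function(x, ...) {
  cat(sprintf("Optic disc: centroid (%.1f, %.1f), radius %.1f px\n",
              x$centroid[1L], x$centroid[2L], x$radius))
  invisible(x)
}

#' Mask of the illuminated field, excluding the saturated ring
#'
#' Fundus images carry a border ring of saturated pixels where illumination
#' falls off. The channel-mean intensity image is contrast-stretched between
#' its 1st and 99th percentiles, thresholded globally (Otsu by default, with
#' an override), pixels at the saturated top of the stretched range are
#' dropped, holes are filled, the largest connected component is kept, and
#' the result is eroded by a safety margin.
#'
#' @param image a [fundus_image()].
#' @param margin erosion margin in pixels (default 5).
#' @param threshold optional global threshold on the stretched 0-255 scale;
#'   default is Otsu's value.
#' @return logical H x W mask of usable field pixels.
#' @export
compute_eye_mask <- function(image, margin = 5L, threshold = NULL) {
  stopifnot(inherits(image, "fundus_image"))
  inten <- (image$pixels[, , 1L] + image$pixels[, , 2L] +
            image$pixels[, , 3L]) / 3
  q <- stats::quantile(inten, c(0.01, 0.99), names = FALSE)
  if (q[2L] <= q[1L])
    stop("degenerate input: no intensity contrast to stretch", call. = FALSE)
  st <- rescale255(inten, q[1L], q[2L])
  # Saturated pixels sit at the clipped top of the stretched range; the
  # cutoff is below 255 so sensor noise cannot pull ring pixels under it.
  sat <- st >= 250
  thr <- threshold %||% otsu_threshold(st[!sat])
  fg <- st > thr & !sat
  if (!any(fg))
    stop("degenerate input: empty eye mask after thresholding",
         call. = FALSE)
  fg <- as.matrix(EBImage::fillHull(matrix(as.numeric(fg), nrow(fg)))) > 0
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(fg), nrow(fg))))
  keep <- which.max(tabulate(lab[lab > 0]))
  fg <- lab == keep
  if (margin > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(margin) + 1L, shape = "disc")
    fg <- as.matrix(EBImage::erode(matrix(as.numeric(fg), nrow(fg)),
                                   brush)) > 0
  }
  if (!any(fg))
    stop("degenerate input: eye mask empty after erosion", call. = FALSE)
  fg
}

#' Circular optic-disc mask
#'
#' Pixels within \code{od$radius} of the OD centroid, clipped to the image
#' bounds. The disc interior is excluded from every downstream feature
#' computation.
#'
#' @param od an [od_geometry()].
#' @param shape integer \code{c(H, W)}.
#' @param margin extra radius in pixels. The pipeline masks the disc plus a
#'   margin because the bright disc rim leaves a ring artifact in the
#'   vesselness image; the disc boundary must not contribute to features.
#' @return logical H x W mask.
#' @export
compute_od_mask <- function(od, shape, margin = 0) {
  stopifnot(inherits(od, "od_geometry"), length(shape) >= 2L)
  dist2_grid(shape[1:2], od$centroid) <= (od$radius + margin)^2
}

#' Select the analysis channel
#'
#' Channel statistics are computed over the eye mask only. Channels whose
#' mean intensity is at or below \code{mean_cutoff} (default 64, the 25th
#' percentile of the 8-bit range) are excluded; among the survivors the
#' channel with the least variance is chosen. If no channel survives, the
#' channel with the greatest mean is used as a fallback (with a warning).
#' Ties break in the order green, blue, red.
#'
#' @param image a [fundus_image()].
#' @param eye_mask logical mask from [compute_eye_mask()].
#' @param mean_cutoff exclusion cutoff on the channel mean.
#' @return the selected channel as an H x W matrix with attributes
#'   \code{channel} (name) and \code{stats} (per-channel mean/variance).
#' @export
select_channel <- function(image, eye_mask, mean_cutoff = 64) {
  stopifnot(inherits(image, "fundus_image"), any(eye_mask))
  order_pref <- c(green = 2L, blue = 3L, red = 1L)  # tie-break order
  mu <- vapply(order_pref, function(k) mean(image$pixels[, , k][eye_mask]),
               numeric(1))
  va <- vapply(order_pref, function(k)
    stats::var(image$pixels[, , k][eye_mask]), numeric(1))
  surv <- mu > mean_cutoff
  if (any(surv)) {
    pick <- names(which.min(va[surv]))
  } else {
    warning("no channel exceeds the mean cutoff; falling back to the ",
            "brightest channel", call. = FALSE)
    pick <- names(which.max(mu))
  }
  out <- image$pixels[, , order_pref[[pick]]]
  attr(out, "channel") <- pick
  attr(out, "stats") <- data.frame(channel = names(order_pref),
                                   mean = unname(mu), variance = unname(va))
  out
}
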