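# Vessel network segmentation. Three interchangeable backends:
#  - morphology: oriented line blurring + background subtraction, then a
#    gray-level co-occurrence (GLCM) second-order entropy threshold;
#  - matched_filter: oriented Gaussian-profile line detectors, max response,
#    Otsu threshold;
#  - scale_space: multiscale Gaussian/Laplacian responses with per-scale
#    Otsu thresholds and a >= 3-of-5 voting rule.

#' Construct a vessel network object
#' @param pixels logical H x W vessel map.
#' @param method segmentation backend tag.
#' @param threshold threshold(s) used.
#' @param ... further diagnostic fields stored in the object.
#' @return object of class \code{vessel_network}.
#' @keywords internal
vessel_network <- function(pixels, method, threshold = NA_real_, ...) {
  structure(list(pixels = pixels, method = method, threshold = threshold,
                 ...), class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("Vessel network (%s): %d foreground px (%.2f%%)",
              x$method, sum(x$pixels), 100 * mean(x$pixels)))
  if (!all(is.na(x$threshold)))
    cat(sprintf(", threshold %s",
                paste(signif(x$threshold, 4), collapse = "/")))
  cat("\n")
  invisible(x)
}

# Uniform line kernel of `len` pixels at angle `theta` (radians, 0 = along
# rows), weights summing to 1. Coincident rounded pixels accumulate weight.
.line_kernel <- function(len, theta) {
  half <- (len - 1) / 2
  off <- seq(-half, half, by = 1)
  rr <- round(off * cos(theta)); cc <- round(off * sin(theta))
  g <- as.integer(max(abs(c(rr, cc))))
  k <- matrix(0, 2L * g + 1L, 2L * g + 1L)
  for (i in seq_along(off))
    k[rr[i] + g + 1L, cc[i] + g + 1L] <- k[rr[i] + g + 1L, cc[i] + g + 1L] +
      1 / len
  k
}

#' Oriented blurring and background subtraction
#'
#' Blurs the selected channel with the mean of 12 uniform line kernels
#' (default length 9 px, orientations 0-165 degrees at 15-degree steps) and
#' subtracts the original channel from the blur. Vessels are darker than
#' their surround, so the difference is bright exactly on vessels; negative
#' values are clipped to 0 and the result is rescaled to [0, 255] and
#' rounded to integer gray levels.
#'
#' @param channel H x W gray matrix from [select_channel()].
#' @param eye_mask optional logical mask; when given, the rescaling maximum
#'   is taken over mask pixels so that ring artifacts outside the field do
#'   not compress the vessel contrast.
#' @param len line-kernel length in pixels.
#' @param n_orient number of orientations over 180 degrees.
#' @return H x W integer gray matrix in [0, 255] (the "vesselness" image).
#' @export
blur_subtract <- function(channel, eye_mask = NULL, len = 9L,
                          n_orient = 12L) {
  thetas <- pi * (seq_len(n_orient) - 1L) / n_orient
  # mean of convolutions = convolution with the mean kernel
  ks <- lapply(thetas, .line_kernel, len = len)
  g <- max(vapply(ks, nrow, integer(1)))
  mean_k <- Reduce(`+`, lapply(ks, function(k) {
    pad <- (g - nrow(k)) %/% 2L
    out <- matrix(0, g, g)
    out[pad + seq_len(nrow(k)), pad + seq_len(ncol(k))] <- k
    out
  })) / n_orient
  blurred <- as.matrix(EBImage::filter2(channel, mean_k,
                                        boundary = "replicate"))
  v <- pmax(blurred - channel, 0)
  hi <- if (is.null(eye_mask)) max(v) else max(v[eye_mask], 0)
  if (hi < 1e-6) return(matrix(0, nrow(channel), ncol(channel)))
  round(rescale255(v, 0, hi))
}

# 256x256 symmetric gray-level co-occurrence matrix over unit horizontal and
# vertical offsets; only pixel pairs with both members inside `mask` count.
.glcm <- function(g, mask = NULL) {
  g <- matrix(as.integer(pmin(pmax(round(g), 0), 255)), nrow(g))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(g), ncol(g))
  counts <- numeric(65536L)
  h <- nrow(g); w <- ncol(g)
  pair <- function(a, b, ma, mb) {
    ok <- ma & mb
    if (!any(ok)) return(invisible(NULL))
    idx <- a[ok] * 256L + b[ok] + 1L
    t <- tabulate(idx, nbins = 65536L)
    counts <<- counts + t
    invisible(NULL)
  }
  pair(g[, -w], g[, -1L], mask[, -w], mask[, -1L])       # offset (0, 1)
  pair(g[-h, ], g[-1L, ], mask[-h, ], mask[-1L, ])       # offset (1, 0)
  C <- matrix(counts, 256L, 256L, byrow = TRUE)          # row = first pixel
  C + t(C)
}

#' GLCM second-order entropy threshold
#'
#' Builds the symmetric gray-level co-occurrence matrix C of the image
#' (unit horizontal + vertical offsets, restricted to the eye mask), and for
#' every candidate threshold t normalizes the background quadrant
#' C[0..t, 0..t] and the foreground quadrant C[t+1.., t+1..] separately into
#' probability tables. The second-order entropies
#' H = -sum p log2 p of the two quadrants are summed, and the threshold
#' maximizing the sum is returned; vessel pixels are those strictly above
#' it.
#'
#' @param gray H x W integer gray matrix in [0, 255] (typically the output
#'   of [blur_subtract()]).
#' @param mask optional logical support mask; pairs outside it are ignored.
#' @return list with elements \code{threshold} (gray level t*) and
#'   \code{pixels} (logical vessel map, restricted to \code{mask} if given).
#' @export
glcm_entropy_threshold <- function(gray, mask = NULL) {
  support <- if (is.null(mask)) gray else gray[mask]
  if (length(unique(as.vector(round(support)))) < 2L)
    stop("degenerate input: image is constant over its support",
         call. = FALSE)
  C <- .glcm(gray, mask)
  # 2-d cumulative sums give O(1) quadrant sums for every candidate t
  CM <- apply(apply(C, 2L, cumsum), 1L, cumsum)           # CM[a,b] transposed
  CM <- t(CM)                                             # CM[a,b]=sum C[1:a,1:b]
  L <- C * 0
  nz <- C > 0
  L[nz] <- C[nz] * log2(C[nz])
  LM <- t(apply(apply(L, 2L, cumsum), 1L, cumsum))
  tot <- CM[256L, 256L]; ltot <- LM[256L, 256L]
  t_cand <- 0:254
  i <- t_cand + 1L                                        # bg block 1..i
  s_bg <- diag(CM)[i]
  l_bg <- diag(LM)[i]
  s_fg <- tot - CM[cbind(i, 256L)] - CM[cbind(256L, i)] + diag(CM)[i]
  l_fg <- ltot - LM[cbind(i, 256L)] - LM[cbind(256L, i)] + diag(LM)[i]
  valid <- s_bg > 0 & s_fg > 0
  if (!any(valid))
    stop("degenerate input: no threshold splits the co-occurrence matrix",
         call. = FALSE)
  H <- rep(-Inf, length(t_cand))
  H[valid] <- (log2(s_bg[valid]) - l_bg[valid] / s_bg[valid]) +
              (log2(s_fg[valid]) - l_fg[valid] / s_fg[valid])
  tstar <- t_cand[which.max(H)]
  px <- gray > tstar
  if (!is.null(mask)) px <- px & mask
  list(threshold = tstar, pixels = px)
}

#' Morphological segmentation with local-entropy thresholding
#'
#' The proposed backend: oriented blurring and subtraction
#' ([blur_subtract()]) followed by the GLCM entropy threshold
#' ([glcm_entropy_threshold()]). Out-of-focus, low-contrast structures fall
#' below the entropy threshold and are absent from the network. The result
#' is restricted to the eye mask minus the optic-disc mask.
#'
#' @param channel H x W gray matrix (selected channel).
#' @param eye_mask,od_mask logical masks from the preprocessing stage.
#' @param blur_len line-kernel length for [blur_subtract()].
#' @param n_orient orientations for [blur_subtract()].
#' @return a \code{vessel_network} with \code{method = "morphology"}.
#' @export
segment_morphology <- function(channel, eye_mask, od_mask = NULL,
                               blur_len = 9L, n_orient = 12L) {
  v <- blur_subtract(channel, eye_mask, len = blur_len, n_orient = n_orient)
  th <- glcm_entropy_threshold(v, eye_mask)
  px <- th$pixels & eye_mask
  if (!is.null(od_mask)) px <- px & !od_mask
  vessel_network(px, "morphology", threshold = th$threshold)
}

#' Oriented Gaussian matched-filter kernel bank
#'
#' Twelve zero-mean kernels at 15-degree spacing. The base kernel has the
#' profile \code{-exp(-v^2 / (2 sigma^2))} across the vessel (so a dark line
#' on a bright background yields a positive response) and is constant along
#' its axis over \code{length} pixels; each kernel is mean-subtracted over
#' its support. Angle 0 detects lines running along image rows (vertical in
#' the usual display); kernels are generated analytically in rotated
#' coordinates, so the 0- and 90-degree kernels are exact transposes.
#'
#' @param sigma Gaussian cross-profile scale in pixels.
#' @param length kernel extent along the vessel axis in pixels.
#' @param n_orient number of orientations over 180 degrees (default 12).
#' @return object of class \code{kernel_bank}: list of kernels plus
#'   \code{angles} (degrees), \code{sigma}, \code{length}.
#' @export
build_kernel_bank <- function(sigma = 2, length = 9L, n_orient = 12L) {
  stopifnot(sigma > 0, length >= 3)
  g <- as.integer(ceiling(max(length / 2, 3 * sigma)))
  dr <- matrix(rep(-g:g, 2L * g + 1L), 2L * g + 1L)
  dc <- t(dr)
  angles <- 180 * (seq_len(n_orient) - 1L) / n_orient
  kernels <- lapply(angles * pi / 180, function(th) {
    u <- dr * cos(th) + dc * sin(th)    # along the vessel axis
    v <- -dr * sin(th) + dc * cos(th)   # across the vessel
    supp <- abs(u) <= length / 2 & abs(v) <= 3 * sigma
    k <- matrix(0, 2L * g + 1L, 2L * g + 1L)
    k[supp] <- -exp(-v[supp]^2 / (2 * sigma^2))
    k[supp] <- k[supp] - mean(k[supp])
    k
  })
  structure(list(kernels = kernels, angles = angles, sigma = sigma,
                 length = length), class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("Matched-filter bank: %d kernels (%.0f-degree spacing), ",
              length(x$kernels), diff(x$angles[1:2])))
  cat(sprintf("sigma %.1f px, length %d px\n", x$sigma, x$length))
  invisible(x)
}

#' Matched-filter segmentation
#'
#' Convolves the channel with every kernel of the bank, keeps the per-pixel
#' maximum response, thresholds the response image by Otsu's method over the
#' eye mask, and intersects with the field masks. A constant response image
#' yields an empty network with a warning (not an error).
#'
#' @param channel H x W gray matrix (selected channel; vessels dark).
#' @param eye_mask,od_mask logical masks.
#' @param bank a [build_kernel_bank()] object.
#' @return a \code{vessel_network} with \code{method = "matched_filter"};
#'   the element \code{orientation} holds the per-pixel index of the winning
#'   kernel for diagnostic use.
#' @export
segment_matched_filter <- function(channel, eye_mask, od_mask = NULL,
                                   bank = build_kernel_bank()) {
  stopifnot(inherits(bank, "kernel_bank"))
  best <- matrix(-Inf, nrow(channel), ncol(channel))
  wins <- matrix(1L, nrow(channel), ncol(channel))
  for (k in seq_along(bank$kernels)) {
    r <- as.matrix(EBImage::filter2(channel, bank$kernels[[k]],
                                    boundary = "replicate"))
    upd <- r > best
    best[upd] <- r[upd]
    wins[upd] <- k
  }
  rng <- range(best[eye_mask])
  if (diff(rng) <= 1e-6) {
    warning("constant matched-filter response; returning an empty network",
            call. = FALSE)
    return(vessel_network(matrix(FALSE, nrow(channel), ncol(channel)),
                          "matched_filter", orientation = wins))
  }
  scaled <- rescale255(best, rng[1L], rng[2L])
  thr <- otsu_threshold(scaled[eye_mask])
  px <- scaled > thr & eye_mask
  if (!is.null(od_mask)) px <- px & !od_mask
  vessel_network(px, "matched_filter", threshold = thr, orientation = wins)
}

# Normalized s x s Gaussian kernel with the given sigma.
.gaussian_kernel <- function(s, sigma) {
  g <- (s - 1L) / 2
  d <- outer((-g:g)^2, (-g:g)^2, `+`)
  k <- exp(-d / (2 * sigma^2))
  k / sum(k)
}

# Replace impulse pixels (strict local 3x3 extrema) by the local median.
.adaptive_median <- function(m) {
  lo <- hi <- NULL
  for (k in seq_len(8L)) {
    s <- mat_shift(m, .nbr_offsets[k, 1L], .nbr_offsets[k, 2L], fill = NA)
    lo <- if (is.null(lo)) s else pmin(lo, s, na.rm = TRUE)
    hi <- if (is.null(hi)) s else pmax(hi, s, na.rm = TRUE)
  }
  impulse <- m > hi | m < lo
  if (!any(impulse)) return(m)
  med <- median3x3(m)
  m[impulse] <- med[impulse]
  m
}

#' Scale-space segmentation with multiscale voting
#'
#' For each scale s in \code{scales} (default 3, 5, 7, 9, 11): blur with an
#' s x s Gaussian kernel (sigma = s/6), convolve with a 3 x 3 Laplacian
#' (dark vessels give positive responses), apply an adaptive 3 x 3 median
#' filter where impulse noise is detected, threshold by Otsu over the eye
#' mask, and remove connected components smaller than \code{island_min}
#' pixels. A pixel enters the final network only if it is foreground in at
#' least \code{votes} of the per-scale maps; isolated impulses and
#' large-scale choroidal structure fail the vote.
#'
#' @param channel H x W gray matrix (selected channel).
#' @param eye_mask,od_mask logical masks.
#' @param scales odd kernel sizes.
#' @param island_min minimum component size (px) kept in each scale map.
#' @param votes minimum number of scales that must agree.
#' @return a \code{vessel_network} with \code{method = "scale_space"}; the
#'   element \code{scale_maps} holds the per-scale binary maps.
#' @export
segment_scale_space <- function(channel, eye_mask, od_mask = NULL,
                                scales = c(3L, 5L, 7L, 9L, 11L),
                                island_min = 20L, votes = 3L) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L)
  maps <- lapply(scales, function(s) {
    b <- as.matrix(EBImage::filter2(channel, .gaussian_kernel(s, s / 6),
                                    boundary = "replicate"))
    resp <- as.matrix(EBImage::filter2(b, lap, boundary = "replicate"))
    resp <- .adaptive_median(resp)
    rng <- range(resp[eye_mask])
    if (diff(rng) <= 1e-6 * max(abs(rng), 1))
      return(matrix(FALSE, nrow(channel), ncol(channel)))
    scaled <- rescale255(resp, rng[1L], rng[2L])
    thr <- otsu_threshold(scaled[eye_mask])
    bin <- scaled > thr & eye_mask
    if (island_min > 0L && any(bin)) {
      lab <- label8(bin)
      sizes <- tabulate(lab[lab > 0L])
      bin[lab > 0L & sizes[pmax(lab, 1L)] < island_min] <- FALSE
    }
    bin
  })
  votes_map <- Reduce(`+`, maps)
  px <- votes_map >= votes & eye_mask
  if (!is.null(od_mask)) px <- px & !od_mask
  vessel_network(px, "scale_space",
                 threshold = NA_real_, scale_maps = maps,
                 scales = scales)
}
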