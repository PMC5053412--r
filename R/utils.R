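# Low-level raster helpers shared across modules. All rasters use the
# (row, col) convention with 1-based indices; masks are logical matrices.

#' Shift a matrix by a fixed offset
#'
#' Returns a matrix of the same shape whose entry \code{[i, j]} holds
#' \code{m[i + dr, j + dc]}; positions falling outside the input are filled
#' with \code{fill}. Used to read the 8-neighborhood of every pixel at once.
#'
#' @param m matrix (numeric or logical).
#' @param dr,dc integer row/column offset.
#' @param fill value used outside the input (default 0; use \code{FALSE} for
#'   logical masks).
#' @return matrix of the same dimensions as \code{m}.
#' @keywords internal
mat_shift <- function(m, dr, dc, fill = if (is.logical(m)) FALSE else 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L - dr):min(h, h - dr)
  cs <- max(1L, 1L - dc):min(w, w - dc)
  if (length(rs) > 0L && length(cs) > 0L)
    out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

# Offsets of the 8-neighborhood in Zhang-Suen order P2..P9:
# N, NE, E, SE, S, SW, W, NW.
.nbr_offsets <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                      dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))

#' Count true 8-neighbors of every pixel
#' @param mask logical matrix.
#' @return integer matrix of per-pixel neighbor counts.
#' @keywords internal
neighbor_count <- function(mask) {
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(8L))
    acc <- acc + mat_shift(mask, .nbr_offsets[k, 1L], .nbr_offsets[k, 2L])
  acc
}

#' Label 8-connected components of a binary mask
#'
#' EBImage's \code{bwlabel} uses 4-connectivity, which splits diagonal pixel
#' chains; skeletons and thin vessel maps need 8-connectivity, so components
#' are taken from the pixel adjacency graph instead.
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 for background, 1..k component labels.
#' @keywords internal
label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  id <- integer(h * w)
  id[idx] <- seq_along(idx)
  # Edges along 4 of the 8 directions cover every adjacent pair once.
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r <- ((idx - 1L) %% h) + 1L
    c <- ((idx - 1L) %/% h) + 1L
    r2 <- r + off[1L]; c2 <- c + off[2L]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    j <- (c2[ok] - 1L) * h + r2[ok]
    keep <- mask[j]
    if (any(keep))
      edges <- rbind(edges, cbind(id[idx[ok][keep]], id[j[keep]]))
  }
  if (is.null(edges)) {
    memb <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  }
  lab[idx] <- as.integer(memb)
  lab
}

#' Otsu threshold on a vector of gray values
#'
#' Maximizes between-class variance over a 256-bin histogram. Unlike
#' \code{EBImage::otsu} this operates on an arbitrary pixel subset, so
#' statistics can be restricted to the illuminated field.
#'
#' @param v numeric vector of intensities.
#' @param range numeric length-2, histogram range (default \code{c(0, 255)}).
#' @param levels number of histogram bins.
#' @return threshold on the input scale; pixels strictly above it are
#'   foreground. \code{NA} if \code{v} is constant.
#' @keywords internal
otsu_threshold <- function(v, range = c(0, 255), levels = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L || max(v) == min(v)) return(NA_real_)
  br <- seq(range[1L], range[2L], length.out = levels + 1L)
  v <- pmin(pmax(v, range[1L]), range[2L])
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[levels]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-levels])
  br[k + 1L]  # upper edge of bin k: foreground = v > threshold
}

#' Rescale a matrix linearly to [0, 255]
#' @keywords internal
rescale255 <- function(m, lo = min(m), hi = max(m)) {
  if (hi <= lo) return(matrix(0, nrow(m), ncol(m)))
  pmin(pmax((m - lo) / (hi - lo) * 255, 0), 255)
}

#' Squared distance of every pixel to a point
#' @keywords internal
dist2_grid <- function(shape, center) {
  outer((seq_len(shape[1L]) - center[1L])^2,
        (seq_len(shape[2L]) - center[2L])^2, `+`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Vectorized 3x3 median filter
#'
#' Median of each pixel's 3x3 neighborhood via a 19-exchange sorting
#' network, all in whole-matrix operations. Border neighborhoods are padded
#' with the center value.
#'
#' @param m numeric matrix.
#' @return filtered matrix of the same shape.
#' @keywords internal
median3x3 <- function(m) {
  v <- vector("list", 9L)
  v[[5L]] <- m
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    if (dr == 0L && dc == 0L) next
    s <- mat_shift(m, dr, dc, fill = NA)
    s[is.na(s)] <- m[is.na(s)]
    v[[k]] <- s
  }
  swap <- function(a, b) {
    lo <- pmin(v[[a]], v[[b]]); hi <- pmax(v[[a]], v[[b]])
    v[[a]] <<- lo; v[[b]] <<- hi
  }
  # Paeth's median-of-9 network (indices shifted to 1-based)
  net <- list(c(2,3), c(5,6), c(8,9), c(1,2), c(4,5), c(7,8), c(2,3),
              c(5,6), c(8,9), c(1,4), c(6,9), c(5,8), c(4,7), c(2,5),
              c(3,6), c(5,8), c(5,3), c(7,5), c(5,3))
  for (p in net) swap(p[1L], p[2L])
  v[[5L]]
}
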