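# Skeleton analysis: thinning to unit width, branch/end point detection,
# splitting into ordered segments, spur pruning, and the segment-length
# (area) threshold. 8-connectivity throughout.

# Number of 0->1 transitions in the circular neighbor sequence P2..P9,P2
# (Zhang-Suen A(p)), computed for every pixel at once.
.transition_count <- function(mask) {
  nb <- lapply(seq_len(8L), function(k)
    mat_shift(mask, .nbr_offsets[k, 1L], .nbr_offsets[k, 2L]))
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(8L)) {
    nxt <- nb[[if (k == 8L) 1L else k + 1L]]
    acc <- acc + (!nb[[k]] & nxt)
  }
  acc
}

#' Thin a binary vessel network to a unit-width skeleton
#'
#' Zhang-Suen iterative thinning (homotopy preserving), followed by a
#' cleanup pass that deletes redundant pixels of any remaining 2 x 2 block
#' whose removal does not alter local connectivity. The result contains no
#' 2 x 2 all-true block.
#'
#' @param network a \code{vessel_network} or a logical matrix.
#' @return logical H x W skeleton matrix.
#' @export
skeletonize <- function(network) {
  m <- if (inherits(network, "vessel_network")) network$pixels else network
  stopifnot(is.logical(m))
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- lapply(seq_len(8L), function(k)
        mat_shift(m, .nbr_offsets[k, 1L], .nbr_offsets[k, 2L]))
      B <- Reduce(`+`, nb)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in seq_len(8L))
        A <- A + (!nb[[k]] & nb[[if (k == 8L) 1L else k + 1L]])
      # P2 = N, P4 = E, P6 = S, P8 = W
      if (pass == 1L) {
        cond <- !(nb[[1L]] & nb[[3L]] & nb[[5L]]) &
                !(nb[[3L]] & nb[[5L]] & nb[[7L]])
      } else {
        cond <- !(nb[[1L]] & nb[[3L]] & nb[[7L]]) &
                !(nb[[1L]] & nb[[5L]] & nb[[7L]])
      }
      del <- m & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # remove leftover 2x2 thickenings while preserving connectivity; pixels
  # are deleted one at a time with a local simplicity test (A(p) = 1,
  # B(p) > 1 in the current skeleton)
  h <- nrow(m); w <- ncol(m)
  local_AB <- function(r, c) {
    rr <- r + .nbr_offsets[, 1L]; cc <- c + .nbr_offsets[, 2L]
    nb <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    v <- logical(8L)
    v[nb] <- m[cbind(rr[nb], cc[nb])]
    list(A = sum(!v & v[c(2:8, 1L)]), B = sum(v))
  }
  repeat {
    blk <- m & mat_shift(m, 0L, 1L) & mat_shift(m, 1L, 0L) &
      mat_shift(m, 1L, 1L)
    if (!any(blk)) break
    cand <- which(blk | mat_shift(blk, 0L, -1L) | mat_shift(blk, -1L, 0L) |
                  mat_shift(blk, -1L, -1L))
    deleted <- FALSE
    for (i in cand) {
      if (!m[i]) next
      r <- ((i - 1L) %% h) + 1L; c <- ((i - 1L) %/% h) + 1L
      # still part of a 2x2 block?
      in_blk <- FALSE
      for (dr in c(-1L, 0L)) for (dc in c(-1L, 0L)) {
        if (r + dr >= 1L && c + dc >= 1L && r + dr + 1L <= h &&
            c + dc + 1L <= w &&
            m[r + dr, c + dc] && m[r + dr + 1L, c + dc] &&
            m[r + dr, c + dc + 1L] && m[r + dr + 1L, c + dc + 1L])
          in_blk <- TRUE
      }
      if (!in_blk) next
      ab <- local_AB(r, c)
      if (ab$A == 1L && ab$B > 1L) {
        m[i] <- FALSE
        deleted <- TRUE
      }
    }
    if (!deleted) break
  }
  # staircase removal: Zhang-Suen keeps orthogonal detour pixels on
  # 8-connected curves (corners where the path could take the diagonal),
  # which inflates chain arc lengths by up to 25% at 45 degrees. A pixel
  # with exactly two arms (A = 2) is redundant when its foreground
  # neighbors stay mutually 8-connected without it; terminal corners
  # (A = 1) and junctions (A >= 3) are untouched.
  repeat {
    B <- neighbor_count(m)
    A <- .transition_count(m)
    cand <- which(m & B >= 2L & A == 2L)
    deleted <- FALSE
    for (i in cand) {
      r <- ((i - 1L) %% h) + 1L; c <- ((i - 1L) %/% h) + 1L
      rr <- r + .nbr_offsets[, 1L]; cc <- c + .nbr_offsets[, 2L]
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      nb <- which(ok)[m[cbind(rr[ok], cc[ok])]]
      if (length(nb) < 2L) next
      # recheck A locally (the matrix has changed since the batch was cut)
      v <- logical(8L); v[nb] <- TRUE
      if (sum(!v & v[c(2:8, 1L)]) != 2L) next
      # are the neighbors one 8-connected cluster without p?
      off <- .nbr_offsets[nb, , drop = FALSE]
      grp <- seq_along(nb)
      for (a in seq_along(nb)) for (b in seq_along(nb)) {
        if (a < b && max(abs(off[a, ] - off[b, ])) == 1L)
          grp[grp == grp[b]] <- grp[a]
      }
      if (length(unique(grp)) == 1L) {
        m[i] <- FALSE
        deleted <- TRUE
      }
    }
    if (!deleted) break
  }
  m
}

#' Locate branch points and end points of a skeleton
#'
#' An end point has exactly one true 8-neighbor. A branch point is a pixel
#' with more than one route to take, operationalized by the crossing number:
#' the count of distinct arms entering the pixel, i.e. the number of
#' 0-to-1 transitions around its 8-neighborhood, must be at least 3. (A raw
#' neighbor-count rule misclassifies staircase corners of 8-connected
#' curves, where a diagonal and an orthogonal neighbor are mutually
#' adjacent, as junctions.)
#'
#' @param skel logical skeleton matrix.
#' @return list with integer matrices \code{branch_points} and
#'   \code{end_points} (n x 2, (row, col)).
#' @export
find_critical_points <- function(skel) {
  B <- neighbor_count(skel)
  A <- .transition_count(skel)
  list(branch_points = which(skel & A >= 3L, arr.ind = TRUE),
       end_points = which(skel & B == 1L, arr.ind = TRUE))
}

# Trace the ordered pixel chain of one path-or-cycle component.
# `comp_idx` = linear indices; degree computed within the component.
.trace_chain <- function(idx, h, w, member) {
  nbrs_of <- function(i) {
    r <- ((i - 1L) %% h) + 1L
    c <- ((i - 1L) %/% h) + 1L
    rr <- r + .nbr_offsets[, 1L]; cc <- c + .nbr_offsets[, 2L]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    j <- (cc[ok] - 1L) * h + rr[ok]
    j[member[j]]
  }
  deg <- vapply(idx, function(i) length(nbrs_of(i)), integer(1))
  closed <- all(deg >= 2L)
  start <- if (closed) idx[1L] else idx[which(deg <= 1L)[1L]]
  visited <- logical(length(member))
  chain <- integer(length(idx))
  cur <- start
  for (n in seq_along(idx)) {
    chain[n] <- cur
    visited[cur] <- TRUE
    nxt <- nbrs_of(cur)
    nxt <- nxt[!visited[nxt]]
    if (length(nxt) == 0L) {
      chain <- chain[seq_len(n)]
      break
    }
    # prefer orthogonal steps so diagonal shortcuts do not skip chain pixels
    if (length(nxt) > 1L) {
      r <- ((cur - 1L) %% h) + 1L; c <- ((cur - 1L) %/% h) + 1L
      rr <- ((nxt - 1L) %% h) + 1L; cc <- ((nxt - 1L) %/% h) + 1L
      d <- (rr - r)^2 + (cc - c)^2
      nxt <- nxt[order(d)]
    }
    cur <- nxt[1L]
  }
  list(chain = chain, closed = closed)
}

#' Split a skeleton into vessel segments at its branch points
#'
#' Branch points (and adjacent branch pixels forming thick junction cliques)
#' are deleted; every remaining 8-connected component is a simple path or a
#' closed loop and becomes one vessel segment with an ordered pixel chain.
#' Single-pixel junction debris is discarded. Closed loops (vessel loops)
#' are traversed as one segment with coincident endpoints and flagged
#' \code{closed}.
#'
#' @param skel logical skeleton matrix.
#' @return object of class \code{segment_set}: list with \code{segments}
#'   (each a list with \code{chain} n x 2, \code{eps1}, \code{eps2},
#'   \code{lambda} pixel count, \code{arc_len}, \code{chord_len},
#'   \code{closed}, \code{n_free_ends}), \code{branch_points},
#'   \code{end_points}, and the source \code{shape}.
#' @export
split_segments <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  cp <- find_critical_points(skel)
  A <- .transition_count(skel)
  # Overlaying a branch point deletes its full 3x3 neighborhood: without
  # this, diagonally adjacent arm tips stay 8-connected around the deleted
  # junction pixel and the arms do not separate.
  branch <- skel & A >= 3L
  blocked <- branch
  for (k in seq_len(8L))
    blocked <- blocked | mat_shift(branch, .nbr_offsets[k, 1L],
                                   .nbr_offsets[k, 2L])
  body <- skel & !blocked
  endpt <- matrix(FALSE, h, w)
  if (nrow(cp$end_points) > 0L) endpt[cp$end_points] <- TRUE
  lab <- label8(body)
  segs <- list()
  if (any(body)) {
    fg <- which(lab > 0L)
    comp_idx <- split(fg, lab[fg])
    for (idx in comp_idx) {
      if (length(idx) < 2L) next     # junction debris
      memb_comp <- logical(h * w)
      memb_comp[idx] <- TRUE
      tr <- .trace_chain(idx, h, w, memb_comp)
      chain <- cbind(((tr$chain - 1L) %% h) + 1L,
                     ((tr$chain - 1L) %/% h) + 1L)
      lam <- nrow(chain)
      arc <- chain_arc_length(chain)
      if (tr$closed) {
        e1 <- e2 <- chain[1L, ]
        # close the traversal: add the step back to the start
        arc <- arc + sqrt(sum((chain[lam, ] - chain[1L, ])^2))
        chord <- 0
      } else {
        e1 <- chain[1L, ]; e2 <- chain[lam, ]
        chord <- sqrt(sum((e1 - e2)^2))
      }
      segs[[length(segs) + 1L]] <- list(
        chain = chain, eps1 = e1, eps2 = e2, lambda = lam,
        arc_len = arc, chord_len = chord, closed = tr$closed,
        n_free_ends = sum(endpt[chain[c(1L, lam), , drop = FALSE]]))
    }
  }
  structure(list(segments = segs, branch_points = cp$branch_points,
                 end_points = cp$end_points, shape = c(h, w)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  lam <- vapply(x$segments, `[[`, numeric(1), "lambda")
  cat(sprintf("Segment set: %d segments, %d branch points, %d end points\n",
              length(x$segments), nrow(x$branch_points),
              nrow(x$end_points)))
  if (length(lam) > 0L)
    cat(sprintf("  lambda: median %.0f px, range %d-%d px\n",
                stats::median(lam), min(lam), max(lam)))
  invisible(x)
}

#' Prune terminal spurs from a skeleton
#'
#' Removes every terminal branch (a segment with exactly one free end)
#' shorter than \code{spur_len} pixels, re-thins the remainder (which fuses
#' the L- and T-shaped junction artifacts left by spur removal), and
#' recomputes critical points and segments. Isolated short components, which
#' are whole vessels rather than branches off a junction, are kept and left
#' to [area_threshold()]. By default pruning repeats until no spur remains
#' (a re-thin can expose a new short terminal), bounded by \code{passes};
#' set \code{passes = 1} for a single prune-and-rethin cycle.
#'
#' @param skel logical skeleton matrix.
#' @param spur_len minimum terminal-branch length in pixels (default 10:
#'   branches shorter than this are removed).
#' @param passes maximum number of prune-and-rethin passes.
#' @return list with elements \code{skeleton} (logical matrix) and
#'   \code{segments} (a [split_segments()] result on the pruned skeleton).
#' @export
prune <- function(skel, spur_len = 10, passes = 8L) {
  for (p in seq_len(passes)) {
    segs <- split_segments(skel)
    drop <- vapply(segs$segments, function(s)
      !s$closed && s$n_free_ends == 1L && s$lambda < spur_len, logical(1))
    if (!any(drop)) break
    for (s in segs$segments[drop]) skel[s$chain] <- FALSE
    skel <- skeletonize(skel)
  }
  list(skeleton = skel, segments = split_segments(skel))
}

#' Remove short segments below a minimum length
#'
#' The area threshold drops every segment whose pixel count is below
#' \code{min_len}, so short fragments do not enter the feature vector: tiny
#' chains carry no usable tortuosity signal (their arc/chord ratio is pure
#' raster quantization) and mostly arise from sensor noise and junction
#' debris. The pipeline applies it to all three backends by default, at the
#' same 10-px scale as the spur-pruning rule.
#'
#' @param segments a \code{segment_set}.
#' @param min_len minimum pixel count; 0 is the identity.
#' @return the filtered \code{segment_set}.
#' @export
area_threshold <- function(segments, min_len) {
  stopifnot(inherits(segments, "segment_set"))
  keep <- vapply(segments$segments, function(s) s$lambda >= min_len,
                 logical(1))
  segments$segments <- segments$segments[keep]
  segments
}
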