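# Diagnostic regions anchored to the optic disc, per-segment tortuosity,
# and the per-region feature vector (T, S).

#' Diagnostic region specification
#'
#' The three regions are concentric annuli in units of the optic-disc
#' radius r: DR1 is the disk of 4r around the OD centroid, EDR1 extends it
#' to 6r so that vessel arching at the DR1 boundary does not inflate the
#' tortuosity estimate, and DR2 is the 4r-8r annulus of the peripheral
#' fundus. EDR1 and DR2 overlap in the 4r-6r annulus by design.
#'
#' @param name \code{"DR1"}, \code{"EDR1"} or \code{"DR2"}.
#' @return list with \code{name}, \code{inner_mult}, \code{outer_mult}.
#' @export
region_spec <- function(name = c("DR1", "EDR1", "DR2")) {
  name <- match.arg(name)
  mult <- switch(name, DR1 = c(0, 4), EDR1 = c(0, 6), DR2 = c(4, 8))
  list(name = name, inner_mult = mult[1L], outer_mult = mult[2L])
}

#' Rasterize a diagnostic region mask
#'
#' Annulus \code{inner_mult * r <= dist < outer_mult * r} around the OD
#' centroid, intersected with the eye mask and with the OD disc removed.
#'
#' @param spec a [region_spec()] (or a region name).
#' @param od an [od_geometry()].
#' @param shape \code{c(H, W)}; taken from \code{eye_mask} if missing.
#' @param eye_mask,od_mask optional logical masks.
#' @return logical H x W mask.
#' @export
region_mask <- function(spec, od, shape = NULL, eye_mask = NULL,
                        od_mask = NULL) {
  if (is.character(spec)) spec <- region_spec(spec)
  if (is.null(shape)) shape <- dim(eye_mask)
  d2 <- dist2_grid(shape, od$centroid)
  m <- d2 >= (spec$inner_mult * od$radius)^2 &
       d2 < (spec$outer_mult * od$radius)^2
  if (!is.null(eye_mask)) m <- m & eye_mask
  if (!is.null(od_mask)) m <- m & !od_mask
  m
}

#' Assign segments to a region by majority membership
#'
#' A segment belongs to a region when at least half of its chain pixels lie
#' inside the region mask (an exact 50% split counts as inside).
#'
#' @param segments a \code{segment_set}.
#' @param mask logical region mask on the same grid.
#' @return the \code{segment_set} restricted to assigned segments.
#' @export
assign_to_region <- function(segments, mask) {
  stopifnot(inherits(segments, "segment_set"),
            all(segments$shape == dim(mask)))
  keep <- vapply(segments$segments, function(s)
    mean(mask[s$chain]) >= 0.5, logical(1))
  segments$segments <- segments$segments[keep]
  segments
}

#' Per-segment tortuosity index
#'
#' The default \code{"arc_chord"} mode returns arc length / chord length,
#' which is 1 exactly for a collinear chain and greater than 1 otherwise.
#' Closed loops (coincident endpoints, zero chord) are assigned the
#' configured cap and flagged, since loops are clinically highly tortuous
#' but have no finite arc/chord ratio. The \code{"literal"} mode computes
#' pixel count / squared chord length, an alternative reading of the index
#' definition retained for comparison; it is not dimensionless and is not
#' bounded below by 1.
#'
#' @param seg one segment from a \code{segment_set}.
#' @param loop_cap value assigned to closed loops (default 10).
#' @param mode \code{"arc_chord"} or \code{"literal"}.
#' @return tortuosity value; attribute \code{loop} marks capped loops.
#' @export
segment_tortuosity <- function(seg, loop_cap = 10,
                               mode = c("arc_chord", "literal")) {
  mode <- match.arg(mode)
  if (isTRUE(seg$closed) || seg$chord_len <= 0)
    return(structure(loop_cap, loop = TRUE))
  if (mode == "arc_chord") seg$arc_len / seg$chord_len
  else seg$lambda / seg$chord_len^2
}

#' Image-level tortuosity index T
#'
#' The mean of the top quartile of segment tortuosities: the values at or
#' above their own 75th percentile (linear-interpolation percentile,
#' \code{stats::quantile} type 7). With \code{method = "at_percentile"} the
#' percentile value itself is returned instead.
#'
#' @param tortuosities numeric vector of per-segment tortuosities.
#' @param prob percentile level (default 0.75).
#' @param method \code{"top_quartile_mean"} or \code{"at_percentile"}.
#' @return T, or \code{NA} for an empty input.
#' @export
image_tortuosity <- function(tortuosities, prob = 0.75,
                             method = c("top_quartile_mean",
                                        "at_percentile")) {
  method <- match.arg(method)
  if (length(tortuosities) == 0L) return(NA_real_)
  q <- stats::quantile(tortuosities, prob, type = 7, names = FALSE)
  if (method == "at_percentile") return(q)
  mean(tortuosities[tortuosities >= q])
}

#' Per-region feature vector (T, S)
#'
#' Assigns the pruned segments to each requested diagnostic region and
#' computes the region's tortuosity index T (top-quartile mean of segment
#' tortuosities) and segment count S. Regions with no assigned segment get
#' \code{T = NA} and \code{S = 0}.
#'
#' @param segments a pruned \code{segment_set}.
#' @param od an [od_geometry()].
#' @param eye_mask,od_mask logical masks.
#' @param regions character vector of region names.
#' @param loop_cap,tortuosity_mode,percentile passed to
#'   [segment_tortuosity()] and [image_tortuosity()].
#' @return data frame with one row per region: \code{region}, \code{T},
#'   \code{S}, \code{n} (segments entering T).
#' @export
extract_features <- function(segments, od, eye_mask, od_mask,
                             regions = c("DR1", "EDR1", "DR2"),
                             loop_cap = 10, tortuosity_mode = "arc_chord",
                             percentile = 0.75) {
  rows <- lapply(regions, function(rn) {
    m <- region_mask(rn, od, shape = segments$shape, eye_mask = eye_mask,
                     od_mask = od_mask)
    rs <- assign_to_region(segments, m)
    tort <- vapply(rs$segments, segment_tortuosity, numeric(1),
                   loop_cap = loop_cap, mode = tortuosity_mode)
    data.frame(region = rn,
               T = image_tortuosity(tort, prob = percentile),
               S = length(rs$segments),
               n = length(tort))
  })
  do.call(rbind, rows)
}
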