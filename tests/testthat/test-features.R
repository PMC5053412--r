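# Diagnostic regions and the (T, S) feature vector.

test_that("region masks match their analytic annulus areas and nesting", {
  od <- od_geometry(c(200, 180), c(200, 220))   # radius 20 at image center
  shape <- c(400L, 400L)
  dr1 <- region_mask("DR1", od, shape)
  edr1 <- region_mask("EDR1", od, shape)
  dr2 <- region_mask("DR2", od, shape)
  a_dr1 <- pi * (80^2)
  expect_lt(abs(sum(dr1) - a_dr1) / a_dr1, 0.02)
  a_dr2 <- pi * (160^2 - 80^2)
  expect_lt(abs(sum(dr2) - a_dr2) / a_dr2, 0.02)
  expect_true(all(edr1[dr1]))                 # DR1 inside EDR1
  ov <- edr1 & dr2                            # overlap = 4r-6r annulus
  expect_gt(sum(ov), 0)
  d <- sqrt(ropscreen:::dist2_grid(shape, od$centroid))
  expect_true(all(d[ov] >= 80 & d[ov] < 120))
  # OD interior is excluded when the OD mask is supplied
  odm <- compute_od_mask(od, shape)
  expect_false(any(region_mask("DR1", od, shape, od_mask = odm) & odm))
})

test_that("segments join a region by majority of their chain pixels", {
  mask <- matrix(FALSE, 20L, 20L)
  mask[, 1:10] <- TRUE
  seg <- function(cols) list(chain = cbind(5L, cols), eps1 = c(5L, cols[1L]),
                             eps2 = c(5L, cols[length(cols)]),
                             lambda = length(cols),
                             arc_len = length(cols) - 1,
                             chord_len = length(cols) - 1, closed = FALSE,
                             n_free_ends = 2L)
  ss <- structure(list(segments = list(seg(1:8),      # fully inside
                                       seg(8:17),     # 3 of 10 inside
                                       seg(6:15)),    # exactly half inside
                       branch_points = matrix(integer(), 0, 2),
                       end_points = matrix(integer(), 0, 2),
                       shape = c(20L, 20L)), class = "segment_set")
  kept <- assign_to_region(ss, mask)$segments
  expect_length(kept, 2L)
  expect_identical(vapply(kept, `[[`, integer(1), "lambda"), c(8L, 10L))
})

test_that("segment tortuosity follows the arc/chord definition", {
  line <- empty_raster(21L); line[11L, 5:14] <- TRUE
  s <- split_segments(line)$segments[[1L]]
  expect_identical(segment_tortuosity(s), 1)

  bend <- empty_raster(15L)
  bend[10L, 5:10] <- TRUE; bend[5:10, 10L] <- TRUE
  s <- split_segments(bend)$segments[[1L]]
  expect_equal(segment_tortuosity(s), 10 / sqrt(50), tolerance = 1e-9)

  # literal reading: pixel count over squared chord
  expect_equal(segment_tortuosity(s, mode = "literal"), 11 / 50)
})

test_that("a rasterized semicircle reads close to pi/2", {
  th <- seq(0, pi, length.out = 600)
  px <- unique(round(cbind(25 + 20 * sin(th), 25 + 20 * cos(th))))
  m <- empty_raster(50L); m[px] <- TRUE
  s <- split_segments(skeletonize(m))$segments[[1L]]
  cal <- chain_arc_length(s$chain, "calibrated") / s$chord_len
  expect_lt(abs(cal - pi / 2) / (pi / 2), 0.05)
  # the Freeman-weighted index carries a known upward quantization bias
  expect_lt(abs(segment_tortuosity(s) - pi / 2) / (pi / 2), 0.08)
})

test_that("closed loops are capped and flagged", {
  circ <- skeletonize(circle_raster(8))
  s <- split_segments(circ)$segments[[1L]]
  tor <- segment_tortuosity(s, loop_cap = 10)
  expect_identical(as.numeric(tor), 10)
  expect_true(attr(tor, "loop"))
})

test_that("image tortuosity is the top-quartile mean", {
  expect_equal(image_tortuosity(c(1.0, 1.1, 1.2, 2.0)), 2.0)
  expect_equal(image_tortuosity(c(1.0, 1.1, 1.2, 2.0),
                                method = "at_percentile"), 1.4)
  expect_equal(image_tortuosity(rep(1.3, 7)), 1.3)
  expect_equal(image_tortuosity(1.7), 1.7)
  expect_true(is.na(image_tortuosity(numeric(0))))
})

test_that("every segment fully inside DR1 is also assigned to EDR1", {
  ph <- small_phantom("aprop", seed = 21)
  res <- process_image(ph$image, ph$truth$od, rop_config("morphology"),
                       keep_intermediates = TRUE)
  segs <- res$intermediates$segments
  eye <- res$intermediates$eye_mask
  odm <- res$intermediates$od_mask
  dr1 <- region_mask("DR1", ph$truth$od, dim(eye), eye, odm)
  edr1 <- region_mask("EDR1", ph$truth$od, dim(eye), eye, odm)
  in_edr1 <- assign_to_region(segs, edr1)$segments
  key <- function(s) paste(s$chain[1L, ], s$chain[nrow(s$chain), ],
                           s$lambda, collapse = "|")
  edr1_keys <- vapply(in_edr1, key, character(1))
  for (s in segs$segments) {
    if (all(dr1[s$chain])) expect_true(key(s) %in% edr1_keys)
  }
})

test_that("feature T is scale-invariant for OD-anchored regions", {
  # the same analytic curves rendered at 1x and 2x, features from the
  # skeleton; regions scale with the OD radius so T should be stable
  draw <- function(scale) {
    side <- 160L * scale
    m <- matrix(FALSE, side, side)
    odc <- c(side / 2, side / 2)
    for (ang in c(0.4, 1.8, 3.4, 5.0)) {
      t <- seq(0, 80 * scale, by = 0.25)
      off <- 4 * scale * sin(2 * pi * t / (50 * scale) + ang)
      pts <- round(cbind(
        odc[1] + (12 * scale + t) * cos(ang) - off * sin(ang),
        odc[2] + (12 * scale + t) * sin(ang) + off * cos(ang)))
      ok <- pts[, 1] >= 1 & pts[, 1] <= side & pts[, 2] >= 1 &
        pts[, 2] <= side
      m[pts[ok, , drop = FALSE]] <- TRUE
    }
    od <- od_geometry(odc - c(0, 12 * scale), odc + c(0, 12 * scale))
    segs <- split_segments(skeletonize(m))
    f <- extract_features(segs, od, matrix(TRUE, side, side),
                          compute_od_mask(od, c(side, side)),
                          regions = "DR1")
    f$T
  }
  t1 <- draw(1L)
  t2 <- draw(2L)
  expect_lt(abs(t2 - t1) / t1, 0.03)
})

test_that("branch-rich phantoms yield higher segment counts than sparse ones", {
  count_dr1 <- function(label, seeds) {
    mean(vapply(seeds, function(s) {
      ph <- small_phantom(label, seed = s)
      r <- process_image(ph$image, ph$truth$od, rop_config("morphology"))
      r$features$S[r$features$region == "DR1"]
    }, numeric(1)))
  }
  seeds <- 301:306
  expect_gt(count_dr1("aprop", seeds), count_dr1("healthy", seeds))
})
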