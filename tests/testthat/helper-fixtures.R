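# Shared fixture builders: tiny rasters with known geometry, and reduced-size
# phantoms for unit tests (the acceptance tests use full-size phantoms).

empty_raster <- function(h = 21L, w = h) matrix(FALSE, h, w)

# two crossing 9-px lines sharing their center pixel
plus_skeleton <- function() {
  m <- empty_raster(21L)
  m[11L, 7:15] <- TRUE
  m[7:15, 11L] <- TRUE
  m
}

# vertical stem with two 6-px diagonal arms
y_skeleton <- function() {
  m <- empty_raster(21L)
  m[11:17, 11L] <- TRUE
  for (i in 1:6) {
    m[11L - i, 11L - i] <- TRUE
    m[11L - i, 11L + i] <- TRUE
  }
  m
}

# horizontal bar with a downward stub of the given length
t_skeleton <- function(stub_len) {
  m <- empty_raster(30L, 50L)
  m[5L, 3:43] <- TRUE
  m[5L + seq_len(stub_len), 23L] <- TRUE
  m
}

# rasterized circle of the given radius (8-connected ring after thinning)
circle_raster <- function(radius = 8, center = radius + 4) {
  side <- 2L * as.integer(center)
  th <- seq(0, 2 * pi, length.out = 50L * radius)
  px <- unique(round(cbind(center + radius * cos(th),
                           center + radius * sin(th))))
  m <- empty_raster(side, side)
  m[px] <- TRUE
  m
}

# small phantom used by unit tests; acceptance tests use the 640-px default
small_phantom <- function(label = "healthy", seed = 1L, ...) {
  over <- utils::modifyList(list(image_size = 320L, od_radius = 20,
                                 seed = seed), list(...))
  generate_phantom(do.call(phantom_preset, c(list(label), over)),
                   label = label)
}

# fundus image with prescribed per-channel values inside a disk field and a
# saturated ring, for preprocessing tests
synthetic_fundus <- function(side = 128L, ring_width = 6L,
                             base = c(120, 90, 50), noise = 0) {
  ctr <- (side + 1) / 2
  d <- sqrt(outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, `+`))
  fr <- side / 2 - 2
  px <- array(0, dim = c(side, side, 3L))
  for (k in 1:3) {
    ch <- matrix(5, side, side)
    ch[d <= fr] <- base[k]
    ch[d > fr - ring_width & d <= fr] <- 255
    if (noise > 0) ch <- ch + matrix(rnorm(side^2, 0, noise), side)
    px[, , k] <- pmin(pmax(round(ch), 0), 255)
  }
  fundus_image(px, id = "synthetic")
}

expect_no_2x2_block <- function(skel) {
  blk <- skel[-nrow(skel), -ncol(skel)] & skel[-1L, -ncol(skel)] &
    skel[-nrow(skel), -1L] & skel[-1L, -1L]
  expect_false(any(blk))
}
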