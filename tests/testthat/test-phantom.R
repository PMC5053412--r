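# Synthetic-fundus generator: analytic ground truth, determinism, and the
# statistical behavior of the class presets.

test_that("zero-amplitude phantoms have exactly straight centerlines", {
  ph <- generate_phantom(phantom_params(image_size = 320, od_radius = 20,
                                        tortuosity_amp = 0, n_trunks = 4,
                                        seed = 3))
  expect_gte(length(ph$truth$tortuosity), 4L)
  expect_equal(ph$truth$tortuosity, rep(1, length(ph$truth$tortuosity)),
               tolerance = 1e-9)
})

test_that("generation is bit-reproducible for a fixed seed", {
  p <- phantom_params(image_size = 320, od_radius = 20, seed = 42)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$centerlines, b$truth$centerlines)
})

test_that("true tortuosity increases with the perturbation amplitude", {
  mean_tort <- function(amp) {
    torts <- unlist(lapply(1:20, function(i) {
      ph <- generate_phantom(phantom_params(image_size = 320, od_radius = 20,
                                            tortuosity_amp = amp,
                                            seed = 500 + i))
      ph$truth$tortuosity
    }))
    mean(torts[is.finite(torts)])
  }
  m1 <- mean_tort(1)
  m6 <- mean_tort(6)
  expect_gt(m6, m1)
  # monotone over a finer grid at fixed per-level seeds
  grid <- vapply(c(0, 2, 4, 6), mean_tort, numeric(1))
  expect_true(all(diff(grid) >= 0))
})

test_that("expected branch count grows with branch_prob", {
  n_curves <- function(bp) {
    mean(vapply(1:20, function(i) {
      ph <- generate_phantom(phantom_params(image_size = 320, od_radius = 20,
                                            branch_prob = bp,
                                            seed = 900 + i))
      length(ph$truth$centerlines)
    }, numeric(1)))
  }
  counts <- vapply(c(0, 0.03, 0.08), n_curves, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3L], counts[1L])
})

test_that("rasterized chains track analytic arc length within 5%", {
  ph <- generate_phantom(phantom_params(image_size = 320, od_radius = 20,
                                        seed = 8))
  for (k in seq_along(ph$truth$centerlines)) {
    chain <- ph$truth$centerlines[[k]]
    if (nrow(chain) <= 30L) next
    analytic <- sum(sqrt(rowSums(diff(ph$truth$analytic[[k]])^2)))
    raster <- chain_arc_length(chain, convention = "calibrated")
    expect_lt(abs(raster - analytic) / analytic, 0.05)
  }
})

test_that("centerlines stay inside the illuminated field", {
  ph <- generate_phantom(phantom_preset("aprop", image_size = 320,
                                        od_radius = 20, seed = 5),
                         label = "aprop")
  n <- 320
  ctr <- (n + 1) / 2
  field_r <- n / 2 - 2 - ph$truth$params$ring_width
  for (chain in ph$truth$centerlines) {
    d <- sqrt((chain[, 1L] - ctr)^2 + (chain[, 2L] - ctr)^2)
    expect_true(all(d <= field_r))
  }
})

test_that("phantoms that cannot contain the inner diagnostic region are rejected", {
  expect_error(phantom_params(image_size = 128, od_radius = 32),
               "too small")
})

test_that("cohorts have the requested sizes, labels and reproducibility", {
  coh <- generate_cohort(15, 21, overrides = list(
    healthy = list(image_size = 320, od_radius = 20),
    aprop = list(image_size = 320, od_radius = 20)), seed = 7)
  expect_length(coh, 36L)
  labs <- vapply(coh, function(ph) ph$truth$label, character(1))
  expect_identical(sum(labs == "healthy"), 15L)
  expect_identical(sum(labs == "aprop"), 21L)

  two <- generate_cohort(1, 1, overrides = list(
    healthy = list(image_size = 320, od_radius = 20),
    aprop = list(image_size = 320, od_radius = 20)), seed = 1)
  expect_setequal(vapply(two, function(p) p$truth$label, character(1)),
                  c("healthy", "aprop"))
  expect_error(generate_cohort(-1, 5), "non-negative")
  expect_error(generate_cohort(1, 0), "at least 2")
})

test_that("identical presets make the class truths statistically indistinguishable", {
  same <- list(image_size = 320, od_radius = 20, tortuosity_amp = 2,
               tortuosity_freq = 2, branch_prob = 0.03,
               vascular_extent = 7, branch_extent = Inf)
  coh <- generate_cohort(10, 10, overrides = list(healthy = same,
                                                  aprop = same), seed = 3)
  tort_by <- function(lab) {
    unlist(lapply(coh, function(ph) {
      if (ph$truth$label == lab) ph$truth$tortuosity else NULL
    }))
  }
  a <- tort_by("healthy"); b <- tort_by("aprop")
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 2 * se)
})

test_that("a cohort written to disk round-trips through the manifest", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(1, 1, overrides = list(
    healthy = list(image_size = 320, od_radius = 20),
    aprop = list(image_size = 320, od_radius = 20)), seed = 11)
  man <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_identical(nrow(man), 2L)
  back <- read_cohort(dir)
  expect_length(back, 2L)
  expect_equal(back[[1L]]$image$pixels, coh[[1L]]$image$pixels)
  expect_equal(back[[1L]]$od$centroid, coh[[1L]]$truth$od$centroid)
  expect_identical(back[[2L]]$label, "aprop")
})
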