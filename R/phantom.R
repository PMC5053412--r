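# Synthetic-fundus phantoms: parametric vessel trees with analytic ground
# truth, used to validate every pipeline stage without clinical images.

#' Phantom generation parameters
#'
#' Bundles and validates the knobs of the synthetic-fundus generator. The
#' phantom is a circular illuminated field with a saturated outer ring, a
#' bright optic disc (OD), and dark vessel trees radiating from the OD rim.
#' Each vessel centerline is a radial line perturbed by a sinusoid normal to
#' its path, so its continuous arc/chord tortuosity is known exactly.
#'
#' @param image_size side of the square image in pixels.
#' @param od_center optic-disc center, \code{c(row, col)}; default image
#'   center.
#' @param od_radius optic-disc radius in pixels.
#' @param n_trunks number of primary vessels leaving the OD rim.
#' @param branch_prob probability per pixel of arc length of spawning a
#'   child branch.
#' @param tortuosity_amp amplitude (px) of the sinusoidal centerline
#'   perturbation; 0 gives perfectly straight vessels.
#' @param tortuosity_freq perturbation frequency in cycles per 100 px of arc.
#' @param vessel_width vessel diameter in pixels (Gaussian cross-section).
#' @param vascular_extent maximum vessel reach from the OD center, as a
#'   multiple of \code{od_radius}.
#' @param branch_extent radial zone (multiple of \code{od_radius}) within
#'   which branching may occur; \code{Inf} allows branching anywhere. The
#'   APROP preset concentrates branching within 6 OD radii of the disc.
#' @param ring_width width (px) of the saturated border ring.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (gray levels).
#' @param seed integer seed; phantoms are bit-reproducible for a fixed seed.
#' @return an object of class \code{phantom_params}.
#' @export
phantom_params <- function(image_size = 640L,
                           od_center = NULL,
                           od_radius = 32,
                           n_trunks = 6L,
                           branch_prob = 0.04,
                           tortuosity_amp = 3,
                           tortuosity_freq = 2,
                           vessel_width = 3,
                           vascular_extent = 7,
                           branch_extent = Inf,
                           ring_width = 10,
                           noise_sd = 3,
                           seed = 1L) {
  if (is.null(od_center)) od_center <- c(image_size, image_size) / 2
  stopifnot(image_size >= 64, od_radius > 0,
            branch_prob >= 0, branch_prob <= 1,
            tortuosity_amp >= 0, tortuosity_freq >= 0,
            vessel_width >= 1, vascular_extent > 0,
            ring_width >= 0, noise_sd >= 0, n_trunks >= 0)
  # The innermost diagnostic region spans 4 OD radii around the centroid;
  # an image that cannot contain it is unusable downstream.
  if (any(od_center - 4 * od_radius < 1) ||
      any(od_center + 4 * od_radius > image_size))
    stop("image_size too small: the 4*od_radius diagnostic region around ",
         "od_center does not fit inside the image", call. = FALSE)
  structure(list(image_size = as.integer(image_size), od_center = od_center,
                 od_radius = od_radius, n_trunks = as.integer(n_trunks),
                 branch_prob = branch_prob, tortuosity_amp = tortuosity_amp,
                 tortuosity_freq = tortuosity_freq,
                 vessel_width = vessel_width,
                 vascular_extent = vascular_extent,
                 branch_extent = branch_extent, ring_width = ring_width,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Class presets for phantom generation
#'
#' The healthy preset renders mildly wavy, sparsely branching vessels that
#' reach far into the periphery (a maturing retina); the APROP preset renders
#' strongly tortuous, densely branching vessels concentrated near the optic
#' disc, with branching restricted to within 6 OD radii.
#'
#' @param label \code{"healthy"} or \code{"aprop"}.
#' @param ... overrides passed on to [phantom_params()].
#' @return a \code{phantom_params} object.
#' @export
phantom_preset <- function(label = c("healthy", "aprop"), ...) {
  label <- match.arg(label)
  base <- if (label == "healthy") {
    list(tortuosity_amp = 1, tortuosity_freq = 1.5, branch_prob = 0.02,
         vascular_extent = 8, branch_extent = Inf)
  } else {
    list(tortuosity_amp = 5, tortuosity_freq = 2.5, branch_prob = 0.06,
         vascular_extent = 6, branch_extent = 6)
  }
  args <- utils::modifyList(base, list(...))
  do.call(phantom_params, args)
}

# One vessel centerline: start point, direction angle, arc length, sinusoid
# amplitude/frequency/phase. Sampled at ds px; the transverse offset is
# anchored to 0 at t = 0 so children join their parent exactly.
.make_curve <- function(start, angle, len, amp, freq, phase,
                        field_center, field_radius, ds = 0.5) {
  if (len < ds) return(NULL)
  t <- seq(0, len, by = ds)
  u <- c(cos(angle), sin(angle))
  nv <- c(-sin(angle), cos(angle))
  off <- amp * (sin(2 * pi * freq * t / 100 + phase) - sin(phase))
  pts <- cbind(start[1L] + t * u[1L] + off * nv[1L],
               start[2L] + t * u[2L] + off * nv[2L])
  # truncate at the first exit from the illuminated field
  d <- sqrt((pts[, 1L] - field_center[1L])^2 +
            (pts[, 2L] - field_center[2L])^2)
  out <- which(d > field_radius)
  if (length(out) > 0L) {
    if (out[1L] <= 4L) return(NULL)
    pts <- pts[seq_len(out[1L] - 1L), , drop = FALSE]
    t <- t[seq_len(nrow(pts))]
  }
  list(points = pts, t = t, angle = angle)
}

.curve_arc <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

.curve_tortuosity <- function(pts) {
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
  if (chord <= 0) return(Inf)
  .curve_arc(pts) / chord
}

#' Generate one synthetic fundus phantom
#'
#' Renders an 8-bit RGB fundus phantom and returns it together with its
#' ground truth: the analytic vessel centerlines (before rasterization),
#' their continuous arc/chord tortuosities, and the optic-disc geometry.
#' Vessels are dark (intensity dip of 60 gray levels in the red channel on a
#' background of 140) with a Gaussian cross-section; the optic disc is a
#' bright disk; the border ring is saturated at 255.
#'
#' @param params a [phantom_params()] object.
#' @param label class label stored in the truth record, \code{"healthy"} or
#'   \code{"aprop"}; purely annotative, geometry comes from \code{params}.
#' @return list with elements \code{image} (a \code{fundus_image}) and
#'   \code{truth} (a \code{phantom_truth}: analytic centerlines, rasterized
#'   chains, per-segment true tortuosity, OD geometry, label).
#' @examples
#' ph <- generate_phantom(phantom_params(image_size = 320, od_radius = 20,
#'                                       tortuosity_amp = 0, seed = 4))
#' all(abs(ph$truth$tortuosity - 1) < 1e-9)
#' @export
generate_phantom <- function(params, label = "healthy") {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  set.seed(p$seed)
  n <- p$image_size
  fc <- c(n + 1, n + 1) / 2
  fr <- n / 2 - 2                       # illuminated field radius
  inner_r <- fr - p$ring_width          # field interior (inside the ring)

  # --- grow the vessel tree -------------------------------------------------
  curves <- list()
  max_reach <- min(p$vascular_extent * p$od_radius, inner_r - 3)
  grow <- function(start, angle, len, depth) {
    cv <- .make_curve(start, angle, len, p$tortuosity_amp, p$tortuosity_freq,
                      stats::runif(1, 0, 2 * pi), fc, inner_r - 3)
    if (is.null(cv)) return(invisible(NULL))
    curves[[length(curves) + 1L]] <<- cv
    if (depth >= 3L || p$branch_prob <= 0) return(invisible(NULL))
    ds <- 0.5
    rad <- sqrt((cv$points[, 1L] - p$od_center[1L])^2 +
                (cv$points[, 2L] - p$od_center[2L])^2)
    allowed <- rad < p$branch_extent * p$od_radius & cv$t > 5
    spawn <- which(stats::runif(nrow(cv$points)) < p$branch_prob * ds &
                   allowed)
    for (i in spawn) {
      child_len <- stats::runif(1, 0.35, 0.65) * (len - cv$t[i])
      if (child_len < 15) next
      child_angle <- cv$angle +
        sample(c(-1, 1), 1L) * stats::runif(1, 0.35, 0.9)
      grow(cv$points[i, ], child_angle, child_len, depth + 1L)
      if (length(curves) >= 400L) return(invisible(NULL))
    }
    invisible(NULL)
  }
  if (p$n_trunks > 0L) {
    angles <- 2 * pi * (seq_len(p$n_trunks) - 1L) / p$n_trunks +
      stats::runif(p$n_trunks, -0.25, 0.25)
    for (a in angles) {
      u <- c(cos(a), sin(a))
      start <- p$od_center + p$od_radius * u
      len <- (max_reach - p$od_radius) * stats::runif(1, 0.85, 1)
      grow(start, a, len, 1L)
    }
  }

  # --- ground truth ---------------------------------------------------------
  # rounding a densely sampled curve leaves orthogonal detour pixels at
  # corners; dropping pixels whose chain neighbors touch each other yields
  # the minimal 8-connected chain, the form chain arc lengths assume
  minimize_chain <- function(p) {
    repeat {
      n <- nrow(p)
      if (n < 3L) return(p)
      drop <- logical(n)
      i <- 2L
      while (i < n) {
        if (max(abs(p[i - 1L, ] - p[i + 1L, ])) <= 1L) {
          drop[i] <- TRUE
          i <- i + 2L
        } else i <- i + 1L
      }
      if (!any(drop)) return(p)
      p <- p[!drop, , drop = FALSE]
    }
  }
  chains <- lapply(curves, function(cv) {
    pix <- round(cv$points)
    minimize_chain(pix[!duplicated(pix), , drop = FALSE])
  })
  torts <- vapply(curves, function(cv) .curve_tortuosity(cv$points),
                  numeric(1))
  ep_a <- p$od_center - c(0, p$od_radius)
  ep_b <- p$od_center + c(0, p$od_radius)
  truth <- structure(
    list(centerlines = chains,
         analytic = lapply(curves, `[[`, "points"),
         tortuosity = torts,
         od = od_geometry(ep_a, ep_b),
         label = label, params = p),
    class = "phantom_truth")

  # --- render ---------------------------------------------------------------
  d2c <- dist2_grid(c(n, n), fc)
  dcen <- sqrt(d2c)
  interior <- dcen <= inner_r
  ring <- dcen > inner_r & dcen <= fr

  cl <- matrix(FALSE, n, n)
  for (ch in chains) {
    ok <- ch[, 1L] >= 1 & ch[, 1L] <= n & ch[, 2L] >= 1 & ch[, 2L] <= n
    cl[ch[ok, , drop = FALSE]] <- TRUE
  }
  if (any(cl)) {
    dm <- as.matrix(EBImage::distmap(matrix(as.numeric(!cl), n, n)))
    sigma <- p$vessel_width / 2
    wv <- exp(-dm^2 / (2 * sigma^2))
  } else {
    wv <- matrix(0, n, n)
  }
  dod <- sqrt(dist2_grid(c(n, n), p$od_center))
  wod <- 1 / (1 + exp((dod - p$od_radius) / 1.5))

  # Red mimics real fundus photographs: bright but dominated by a smooth
  # illumination falloff, so the channel-selection rule discards it in favor
  # of the flatter green channel, which carries the vessel contrast.
  gain <- 1 - 0.25 * (dcen / inner_r)^2
  r <- (matrix(140, n, n) - 40 * wv + 70 * wod) * gain
  g <- matrix(95, n, n) - 60 * wv + 65 * wod
  b <- matrix(40, n, n) + 25 * wod
  for (nm in c("r", "g", "b")) {
    m <- get(nm)
    m[!interior] <- 8
    m[ring] <- 255
    m <- m + matrix(stats::rnorm(n * n, 0, p$noise_sd), n, n)
    assign(nm, round(pmin(pmax(m, 0), 255)))
  }

  img <- fundus_image(array(c(r, g, b), dim = c(n, n, 3L)),
                      id = sprintf("phantom_%s_seed%d", label, p$seed))
  list(image = img, truth = truth)
}

#' Generate a labelled synthetic cohort
#'
#' Produces \code{n_healthy} phantoms from the healthy preset followed by
#' \code{n_aprop} phantoms from the APROP preset. Per-image seeds are drawn
#' reproducibly from the master seed, so the whole cohort is deterministic.
#' Default cohort sizes mirror a screening study of 15 clinically healthy
#' and 21 APROP eyes.
#'
#' @param n_healthy,n_aprop per-class image counts (each >= 0, total >= 2).
#' @param overrides named list with optional elements \code{healthy} and
#'   \code{aprop}, each a list of [phantom_params()] overrides for that
#'   preset.
#' @param seed master integer seed.
#' @return list of phantoms as returned by [generate_phantom()], each with
#'   elements \code{image} and \code{truth}.
#' @export
generate_cohort <- function(n_healthy = 15L, n_aprop = 21L,
                            overrides = list(), seed = 7L) {
  if (n_healthy < 0 || n_aprop < 0) stop("cohort counts must be non-negative")
  if (n_healthy + n_aprop < 2) stop("need at least 2 images in total")
  set.seed(seed)
  total <- n_healthy + n_aprop
  seeds <- sample.int(2^20, total)
  labels <- rep(c("healthy", "aprop"), c(n_healthy, n_aprop))
  lapply(seq_len(total), function(i) {
    ov <- overrides[[labels[i]]] %||% list()
    ov$seed <- seeds[i]
    ph <- generate_phantom(do.call(phantom_preset, c(list(labels[i]), ov)),
                           label = labels[i])
    ph$image$id <- sprintf("%s_%02d", labels[i], i)
    ph
  })
}

#' @export
print.phantom_params <- function(x, ...) {
  cat("Phantom parameters:\n")
  cat(sprintf("  image %dx%d px, OD at (%.0f, %.0f) r=%.0f\n",
              x$image_size, x$image_size, x$od_center[1L], x$od_center[2L],
              x$od_radius))
  cat(sprintf("  %d trunks, branch_prob %.3f/px, amp %.1f px, freq %.2f/100px\n",
              x$n_trunks, x$branch_prob, x$tortuosity_amp, x$tortuosity_freq))
  cat(sprintf("  width %.1f px, extent %.1f r, ring %.0f px, noise sd %.1f, seed %d\n",
              x$vessel_width, x$vascular_extent, x$ring_width, x$noise_sd,
              x$seed))
  invisible(x)
}

#' Chain arc length of a rasterized pixel chain
#'
#' Sums Euclidean steps between consecutive chain pixels. The
#' \code{"freeman"} convention weighs orthogonal steps 1 and diagonal steps
#' sqrt(2) and is used for all pipeline features. The \code{"calibrated"}
#' convention uses the minimax step weights 0.960 / 1.358, which bound the
#' relative error against continuous straight-line length by about 4% at any
#' orientation; it serves as the oracle when checking raster chains against
#' analytic centerlines.
#'
#' @param chain n x 2 matrix of (row, col) pixel coordinates.
#' @param convention \code{"freeman"} or \code{"calibrated"}.
#' @return arc length in pixels.
#' @export
chain_arc_length <- function(chain, convention = c("freeman", "calibrated")) {
  convention <- match.arg(convention)
  if (nrow(chain) < 2L) return(0)
  st <- abs(diff(chain))
  diag <- st[, 1L] > 0 & st[, 2L] > 0
  if (convention == "freeman") sum(ifelse(diag, sqrt(2), 1))
  else sum(ifelse(diag, 1.358, 0.960))
}

#' Write a cohort of phantoms to disk
#'
#' Writes one PNG per phantom plus a JSON truth sidecar (OD endpoints, label,
#' rasterized centerlines) and a cohort manifest CSV (path, label, seed).
#'
#' @param cohort list of phantoms from [generate_cohort()].
#' @param dir output directory, created if missing.
#' @return invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(ph) {
    id <- ph$image$id
    img_path <- file.path(dir, paste0(id, ".png"))
    write_fundus(ph$image, img_path)
    od <- ph$truth$od
    sidecar <- list(od_endpoints = list(od$endpoint_a, od$endpoint_b),
                    label = ph$truth$label,
                    centerlines = lapply(ph$truth$centerlines, function(m)
                      unname(apply(m, 1L, function(r) as.integer(r),
                                   simplify = FALSE))))
    jsonlite::write_json(sidecar, file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE)
    data.frame(path = img_path, label = ph$truth$label,
               seed = ph$truth$params$seed)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
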