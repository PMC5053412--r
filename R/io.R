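# Image and annotation I/O. PNG is the native format; TIFF is supported when
# the 'tiff' package is available.

#' Read a fundus image from disk
#'
#' Reads PNG (or TIFF, if the \pkg{tiff} package is installed) into a
#' \code{fundus_image} with 8-bit intensities. Grayscale inputs are
#' replicated across the three channels; an alpha channel is dropped.
#'
#' @param path image path.
#' @param id identifier; default is the file name without extension.
#' @return a [fundus_image()].
#' @export
read_fundus <- function(path, id = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]
  fundus_image(round(px * 255), id = id %||% tools::file_path_sans_ext(
    basename(path)), path = path)
}

#' Write a fundus image or mask as PNG
#'
#' @param x a [fundus_image()], or a numeric/logical matrix (written as
#'   grayscale; logical masks as 1-bit black/white).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_fundus <- function(x, path) {
  if (inherits(x, "fundus_image")) {
    png::writePNG(x$pixels / 255, path)
  } else if (is.logical(x)) {
    png::writePNG(matrix(as.numeric(x), nrow(x)), path)
  } else {
    png::writePNG(pmin(pmax(x, 0), 255) / 255, path)
  }
  invisible(path)
}

#' Read an optic-disc annotation sidecar
#'
#' The sidecar is a JSON file with at least
#' \code{{"od_endpoints": [[r, c], [r, c]]}} in pixel coordinates, and
#' optionally a \code{"label"} field.
#'
#' @param path JSON path.
#' @return list with elements \code{od} (an [od_geometry()]) and
#'   \code{label} (character or \code{NA}).
#' @export
read_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- j$od_endpoints
  if (is.null(ep)) stop("annotation lacks 'od_endpoints': ", path,
                        call. = FALSE)
  ep <- matrix(unlist(ep), ncol = 2L, byrow = !is.matrix(ep))
  if (is.matrix(j$od_endpoints)) ep <- j$od_endpoints
  list(od = od_geometry(ep[1L, ], ep[2L, ]),
       label = j$label %||% NA_character_)
}

#' Read a cohort from a manifest
#'
#' The manifest is a CSV with columns \code{path} and optionally
#' \code{label}; each image must have a same-named \code{.json} annotation
#' sidecar next to it. Images without a readable annotation are skipped with
#' a warning.
#'
#' @param manifest path to the manifest CSV, or a directory containing
#'   \code{manifest.csv}.
#' @return list of entries \code{list(image, od, label, id)} suitable for
#'   [run_pipeline()].
#' @export
read_cohort <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(tab$path[i]))
    side <- paste0(tools::file_path_sans_ext(p), ".json")
    if (!file.exists(side)) {
      warning("skipping ", basename(p), ": no annotation sidecar",
              call. = FALSE)
      next
    }
    ann <- read_annotation(side)
    img <- read_fundus(p)
    out[[length(out) + 1L]] <- list(
      image = img, od = ann$od,
      label = tab$label[i] %||% ann$label, id = img$id)
  }
  out
}
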