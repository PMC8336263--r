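#' Construct an intensity raster
#'
#' An intensity raster is a non-negative numeric matrix in (row, col) order
#' holding one element's 2-D micro-XRF intensity map (a concentration proxy),
#' tagged with the element it maps. Values read from 8-bit TIFF are integers
#' in 0--255; derived rasters may be real-valued.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param element one of `BUNDLE_ELEMENTS` ("Zn", "K", "Ca", "Ni", "Compton").
#' @return the pixel matrix with class `xrf_raster` and an `element` attribute.
#' @export
xrf_raster <- function(pixels, element) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("raster dimensions must be positive")
  if (anyNA(pixels) || any(pixels < 0))
    stop("raster intensities must be non-negative and non-missing")
  element <- match.arg(element, BUNDLE_ELEMENTS)
  structure(pixels, element = element, class = c("xrf_raster", class(pixels)))
}

#' @export
print.xrf_raster <- function(x, ...) {
  cat(sprintf("<xrf_raster> %s, %d x %d, range [%g, %g]\n",
              attr(x, "element"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

raster_pixels <- function(x) {
  # strip attributes so downstream matrix algebra sees a plain matrix
  matrix(as.numeric(x), nrow = nrow(x), ncol = ncol(x))
}

#' Construct a co-registered scan bundle
#'
#' A bundle holds one raster per element in `BUNDLE_ELEMENTS` for a single
#' plant (or batch scan), all with identical dimensions.
#'
#' @param rasters named list with exactly the five element rasters
#'   (matrices or `xrf_raster` objects).
#' @param sample_id character scalar identifying the scan.
#' @param accession_id optional accession identifier (for heritability).
#' @param replicate optional replicate number within the accession.
#' @return an object of class `scan_bundle`.
#' @export
scan_bundle <- function(rasters, sample_id,
                        accession_id = NA_character_, replicate = NA_integer_) {
  missing_el <- setdiff(BUNDLE_ELEMENTS, names(rasters))
  if (length(missing_el) > 0L)
    stop("missing element raster(s): ", paste(missing_el, collapse = ", "))
  extra <- setdiff(names(rasters), BUNDLE_ELEMENTS)
  if (length(extra) > 0L)
    stop("unknown element raster(s): ", paste(extra, collapse = ", "))
  rasters <- rasters[BUNDLE_ELEMENTS]
  dims <- vapply(rasters, dim, integer(2))
  ref <- dims[, 1L]
  for (el in BUNDLE_ELEMENTS) {
    if (!identical(dim(rasters[[el]]), ref))
      stop(sprintf("dimension mismatch: %s is %dx%d but %s is %dx%d",
                   BUNDLE_ELEMENTS[1L], ref[1L], ref[2L],
                   el, nrow(rasters[[el]]), ncol(rasters[[el]])))
    if (any(rasters[[el]] < 0))
      stop("raster intensities must be non-negative (", el, ")")
  }
  structure(
    list(rasters = lapply(rasters, function(m)
           matrix(as.numeric(m), nrow = nrow(m), ncol = ncol(m))),
         sample_id = as.character(sample_id),
         accession_id = as.character(accession_id),
         replicate = as.integer(replicate)),
    class = "scan_bundle")
}

#' @export
print.scan_bundle <- function(x, ...) {
  d <- dim(x$rasters[[1L]])
  cat(sprintf("<scan_bundle> %s (%s rep %s), %d x %d, elements: %s\n",
              x$sample_id, x$accession_id, x$replicate, d[1L], d[2L],
              paste(names(x$rasters), collapse = ", ")))
  invisible(x)
}

bundle_dim <- function(bundle) dim(bundle$rasters[[1L]])

#' Construct a segmentation label map
#'
#' A per-pixel categorical map over background, petiole, margin, vein and
#' tissue, encoded with the integer codes in [LABEL_CODES].
#'
#' @param codes integer matrix with values in `LABEL_CODES` (0--4).
#' @return an integer matrix of class `seg_labels`.
#' @export
seg_labels <- function(codes) {
  if (!is.matrix(codes)) stop("`codes` must be a matrix")
  m <- matrix(as.integer(codes), nrow = nrow(codes), ncol = ncol(codes))
  bad <- setdiff(unique(as.vector(m)), unname(LABEL_CODES))
  if (length(bad) > 0L)
    stop("unknown label code(s): ", paste(sort(bad), collapse = ", "))
  structure(m, class = c("seg_labels", class(m)))
}

#' @export
print.seg_labels <- function(x, ...) {
  counts <- vapply(LABEL_CODES, function(k) sum(x == k), integer(1))
  cat(sprintf("<seg_labels> %d x %d: %s\n", nrow(x), ncol(x),
              paste(sprintf("%s=%d", names(LABEL_CODES), counts),
                    collapse = ", ")))
  invisible(x)
}

#' Per-class masks of a label map
#'
#' @param labels a `seg_labels` map.
#' @return named list of logical masks: one per substructure plus `plant`
#'   (all non-background pixels).
#' @export
label_masks <- function(labels) {
  out <- lapply(SUBSTRUCTURES, function(cl) {
    m <- unclass(labels) == LABEL_CODES[[cl]]
    m
  })
  names(out) <- SUBSTRUCTURES
  out$plant <- unclass(labels) != 0L
  out
}

assert_mask <- function(mask, name = deparse(substitute(mask))) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`", name, "` must be a logical matrix")
  invisible(mask)
}
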