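#' Read an element raster from a greyscale TIFF
#'
#' Reads a single-channel 8-bit greyscale TIFF (the usual micro-XRF export
#' format) as an intensity raster; 16-bit files are accepted and used as-is,
#' without rescaling. Pixel values are returned exactly as stored.
#'
#' @param path path to the TIFF file.
#' @param element one of `BUNDLE_ELEMENTS`.
#' @return an [xrf_raster()].
#' @export
read_raster <- function(path, element) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) stop("failed to decode TIFF '", path,
                                           "': ", conditionMessage(e)))
  if (length(dim(img)) == 3L)
    stop(sprintf("expected a single-channel greyscale TIFF, got %d channels: %s",
                 dim(img)[3L], path))
  xrf_raster(matrix(as.numeric(img), nrow = nrow(img)), element)
}

#' Write an intensity raster to a greyscale TIFF
#'
#' Values must be integers; 8-bit output is used when all values fit in
#' 0--255, 16-bit otherwise.
#'
#' @param raster matrix of non-negative integer intensities.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  v <- as.numeric(raster)
  if (any(v != floor(v)) || any(v < 0))
    stop("raster must hold non-negative integers for TIFF export")
  bits <- if (max(v) <= 255) 8L else 16L
  if (max(v) > 65535) stop("raster values exceed 16-bit range")
  tiff::writeTIFF(unclass(raster) / (2^bits - 1), path, bits.per.sample = bits)
  invisible(path)
}

#' Assemble a validated scan bundle from per-element TIFF paths
#'
#' @param paths named character vector or list mapping each element of
#'   `BUNDLE_ELEMENTS` to a TIFF path.
#' @param sample_id scan identifier.
#' @param accession_id,replicate optional identifiers, see [scan_bundle()].
#' @return a [scan_bundle()].
#' @export
load_bundle <- function(paths, sample_id,
                        accession_id = NA_character_, replicate = NA_integer_) {
  paths <- unlist(paths)
  missing_el <- setdiff(BUNDLE_ELEMENTS, names(paths))
  if (length(missing_el) > 0L)
    stop("missing element path(s): ", paste(missing_el, collapse = ", "))
  rasters <- lapply(BUNDLE_ELEMENTS, function(el) read_raster(paths[[el]], el))
  names(rasters) <- BUNDLE_ELEMENTS
  scan_bundle(rasters, sample_id, accession_id, replicate)
}

#' Read a bundle manifest CSV
#'
#' The manifest maps elements to raster files, one scan per `sample_id`.
#' Required columns: `sample_id`, `element`, `path`; optional columns
#' `accession_id` and `replicate`.
#'
#' @param path CSV file with a header row.
#' @param base_dir directory against which relative raster paths are resolved
#'   (defaults to the manifest's directory).
#' @return list of [scan_bundle()] objects.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "element", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  lapply(split(man, man$sample_id), function(rows) {
    p <- rows$path
    abs <- ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
    load_bundle(stats::setNames(abs, rows$element),
                sample_id = rows$sample_id[1L],
                accession_id = if ("accession_id" %in% names(rows))
                  rows$accession_id[1L] else NA_character_,
                replicate = if ("replicate" %in% names(rows))
                  rows$replicate[1L] else NA_integer_)
  })
}

#' Split a multi-plant batch scan into per-plant bundles
#'
#' Plants are the 8-connected components of `plant_mask` (diagonally touching
#' leaves belong to one plant). Each bundle is cropped to the component's
#' bounding box padded by `pad` pixels; components smaller than `min_area`
#' pixels are dropped with a warning.
#'
#' @param bundle a batch [scan_bundle()].
#' @param plant_mask logical foreground mask with the bundle's dimensions.
#' @param pad bounding-box padding in pixels (default 5).
#' @param min_area minimum component area in pixels (default 10).
#' @return list of cropped [scan_bundle()]s, ordered by first pixel in
#'   column-major scan order; empty list for an empty mask.
#' @export
split_plants <- function(bundle, plant_mask, pad = 5L, min_area = 10L) {
  stopifnot(inherits(bundle, "scan_bundle"))
  assert_mask(plant_mask)
  if (!identical(dim(plant_mask), bundle_dim(bundle)))
    stop("plant_mask dimensions do not match the bundle")
  lab <- label_components_8(plant_mask)
  k <- max(lab)
  if (k == 0L) return(list())
  areas <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(areas >= min_area)
  if (length(keep) < k)
    warning(sprintf("dropped %d component(s) smaller than %d px",
                    k - length(keep), min_area))
  nr <- nrow(plant_mask); nc <- ncol(plant_mask)
  out <- lapply(seq_along(keep), function(i) {
    id <- keep[i]
    px <- which(lab == id, arr.ind = TRUE)
    r0 <- max(1L, min(px[, 1L]) - pad); r1 <- min(nr, max(px[, 1L]) + pad)
    c0 <- max(1L, min(px[, 2L]) - pad); c1 <- min(nc, max(px[, 2L]) + pad)
    rasters <- lapply(bundle$rasters, function(m) m[r0:r1, c0:c1, drop = FALSE])
    b <- scan_bundle(rasters, sprintf("%s_plant%02d", bundle$sample_id, i),
                     bundle$accession_id, bundle$replicate)
    attr(b, "bbox") <- c(r0 = r0, r1 = r1, c0 = c0, c1 = c1)
    b
  })
  out
}

#' Write / read a segmentation label map as a single-channel TIFF
#'
#' Classes are stored with the integer codes in [LABEL_CODES]
#' (background = 0, petiole = 1, margin = 2, vein = 3, tissue = 4).
#' `read_labels` inverts `write_labels` exactly; unknown codes on read are a
#' format error.
#'
#' @param labels a [seg_labels()] map.
#' @param path TIFF file path.
#' @return `write_labels` returns `path` invisibly; `read_labels` returns a
#'   [seg_labels()].
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "seg_labels"))
  tiff::writeTIFF(unclass(labels) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("cannot read labels: no such file: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L)
    stop(sprintf("label file must be single-channel, got %d channels: %s",
                 dim(img)[3L], path))
  m <- matrix(as.integer(img), nrow = nrow(img))
  bad <- setdiff(unique(as.vector(m)), unname(LABEL_CODES))
  if (length(bad) > 0L)
    stop("label file contains unknown code(s): ",
         paste(sort(bad), collapse = ", "), " (", path, ")")
  seg_labels(m)
}

#' Read / write ground-truth pixel samples as CSV
#'
#' Columns: `row`, `col` (1-based pixel coordinates), `predicted_class`,
#' `true_class` (blank until annotated), classes drawn from [SUBSTRUCTURES].
#'
#' @param sample data.frame as produced by [sample_ground_truth_pixels()].
#' @param path CSV path.
#' @export
write_ground_truth <- function(sample, path) {
  utils::write.csv(sample, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("row", "col", "predicted_class", "true_class")
  if (!all(need %in% names(gt)))
    stop("ground-truth CSV must have columns: ", paste(need, collapse = ", "))
  for (col in c("predicted_class", "true_class")) {
    bad <- setdiff(unique(stats::na.omit(gt[[col]])), SUBSTRUCTURES)
    if (length(bad) > 0L)
      stop("invalid class(es) in ", col, ": ", paste(bad, collapse = ", "))
  }
  gt
}
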