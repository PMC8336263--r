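#' Concentration quotient (CQ)
#'
#' The mean intensity over a substructure divided by the mean intensity over
#' the plant: dimensionless, equal to 1 when the substructure mean equals the
#' plant mean, and invariant under global rescaling of the raster. An empty
#' substructure has no defined CQ and yields `NA` with a warning (never 0).
#'
#' @param raster intensity raster.
#' @param substructure logical mask, subset of `plant`.
#' @param plant logical plant-foreground mask, non-empty with non-zero mean.
#' @return numeric scalar (or `NA` for an empty substructure).
#' @export
concentration_quotient <- function(raster, substructure, plant) {
  assert_mask(substructure); assert_mask(plant)
  if (any(substructure & !plant))
    stop("substructure mask must be a subset of the plant mask")
  if (!any(plant)) stop("plant mask is empty")
  mp <- mean(raster[plant])
  if (mp == 0) stop("plant mean intensity is zero; CQ undefined")
  if (!any(substructure)) {
    warning("empty substructure: CQ undefined, returning NA")
    return(NA_real_)
  }
  mean(raster[substructure]) / mp
}

#' Pixel-level colocalization of two element maps
#'
#' Pearson correlation of the two rasters' values over the plant-foreground
#' pixels. Undefined (NA, with a warning) when either raster has zero
#' variance over the plant.
#'
#' @param raster_a,raster_b intensity rasters of equal dimensions.
#' @param plant logical plant mask with at least two pixels.
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
colocalization <- function(raster_a, raster_b, plant) {
  assert_mask(plant)
  if (sum(plant) < 2L) stop("need at least two plant pixels")
  a <- as.numeric(raster_a[plant]); b <- as.numeric(raster_b[plant])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance over the plant mask: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Z-scores of substructure means
#'
#' For each substructure, the substructure mean intensity minus the plant
#' mean, divided by the plant standard deviation (both over plant-foreground
#' pixel values). Undefined when the plant standard deviation is zero.
#'
#' @param raster intensity raster.
#' @param labels a [seg_labels()] map.
#' @param plant logical plant mask; defaults to all non-background labels.
#' @return named numeric vector over [SUBSTRUCTURES].
#' @export
zscore_substructure_means <- function(raster, labels,
                                      plant = unclass(labels) != 0L) {
  stopifnot(inherits(labels, "seg_labels"))
  assert_mask(plant)
  if (!any(plant)) stop("plant mask is empty")
  vals <- as.numeric(raster[plant])
  s <- stats::sd(vals)
  if (is.na(s) || s == 0) {
    warning("zero plant standard deviation: z-scores undefined")
    return(stats::setNames(rep(NA_real_, 4L), SUBSTRUCTURES))
  }
  mp <- mean(vals)
  vapply(SUBSTRUCTURES, function(cl) {
    m <- unclass(labels) == LABEL_CODES[[cl]]
    if (!any(m)) return(NA_real_)
    (mean(raster[m]) - mp) / s
  }, numeric(1))
}

cq_trait_names <- function() {
  as.vector(t(outer(XRF_ELEMENTS, SUBSTRUCTURES,
                    function(e, s) sprintf("cq_%s_%s", e, s))))
}

#' Per-plant CQ traits
#'
#' The 16 concentration quotients (4 elements x 4 substructures), using all
#' non-background label pixels as the plant denominator (so the pixel-count
#' weighted mean of the four substructure CQs is exactly 1 for each element).
#'
#' @param bundle a [scan_bundle()].
#' @param labels a [seg_labels()] map for this bundle.
#' @return named numeric vector `cq_<element>_<substructure>`.
#' @export
cq_traits <- function(bundle, labels) {
  stopifnot(inherits(bundle, "scan_bundle"), inherits(labels, "seg_labels"))
  masks <- label_masks(labels)
  out <- numeric(0)
  empty <- character(0)
  for (el in XRF_ELEMENTS) {
    r <- bundle$rasters[[el]]
    for (cl in SUBSTRUCTURES) {
      nm <- sprintf("cq_%s_%s", el, cl)
      if (!any(masks[[cl]])) {
        out[nm] <- NA_real_
        empty <- union(empty, cl)
      } else {
        out[nm] <- suppressWarnings(
          concentration_quotient(r, masks[[cl]], masks$plant))
      }
    }
  }
  if (length(empty) > 0L)
    warning("empty substructure(s), CQ set to NA: ",
            paste(empty, collapse = ", "))
  out
}

#' Full trait row for one plant
#'
#' Assembles the traits used for heritability analysis: plant size (count of
#' non-background pixels), per-element plant mean intensity, the 16
#' substructure CQs, relative substructure sizes, and pairwise pixel
#' colocalization correlations.
#'
#' @param bundle a [scan_bundle()].
#' @param labels a [seg_labels()] map for this bundle.
#' @return a one-row data.frame.
#' @export
plant_traits <- function(bundle, labels) {
  stopifnot(inherits(bundle, "scan_bundle"), inherits(labels, "seg_labels"))
  masks <- label_masks(labels)
  n_plant <- sum(masks$plant)
  row <- data.frame(sample_id = bundle$sample_id,
                    accession_id = bundle$accession_id,
                    replicate = bundle$replicate,
                    plant_size = n_plant,
                    stringsAsFactors = FALSE)
  if (n_plant == 0L) {
    warning("all-background labels: traits undefined for ", bundle$sample_id)
    for (el in XRF_ELEMENTS) row[[sprintf("mean_%s", el)]] <- NA_real_
    for (nm in cq_trait_names()) row[[nm]] <- NA_real_
    for (cl in SUBSTRUCTURES) row[[sprintf("relsize_%s", cl)]] <- NA_real_
  } else {
    for (el in XRF_ELEMENTS)
      row[[sprintf("mean_%s", el)]] <- mean(bundle$rasters[[el]][masks$plant])
    cq <- cq_traits(bundle, labels)
    for (nm in names(cq)) row[[nm]] <- cq[[nm]]
    for (cl in SUBSTRUCTURES)
      row[[sprintf("relsize_%s", cl)]] <- sum(masks[[cl]]) / n_plant
  }
  pairs <- utils::combn(XRF_ELEMENTS, 2L)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    row[[sprintf("coloc_%s_%s", a, b)]] <-
      if (n_plant < 2L) NA_real_ else
        suppressWarnings(colocalization(bundle$rasters[[a]],
                                        bundle$rasters[[b]], masks$plant))
  }
  row
}

#' Sample predicted pixels for blind ground-truth annotation
#'
#' For each substructure class, up to `n_per_class` pixels are sampled
#' uniformly without replacement from that class's predicted pixels (all of
#' them, with a warning, if fewer exist; a warning and skip if the class is
#' absent). The output rows are shuffled so the annotator is blind to the
#' predicted class; the `true_class` column is left blank for annotation.
#'
#' @param labels a [seg_labels()] map.
#' @param n_per_class pixels per class (default 1000).
#' @param seed integer seed making the sample reproducible.
#' @return data.frame with columns `row`, `col`, `predicted_class`,
#'   `true_class` (all `NA`).
#' @export
sample_ground_truth_pixels <- function(labels, n_per_class = 1000L, seed = 1L) {
  stopifnot(inherits(labels, "seg_labels"), n_per_class >= 1L)
  with_seed(seed, {
    recs <- lapply(SUBSTRUCTURES, function(cl) {
      px <- which(unclass(labels) == LABEL_CODES[[cl]], arr.ind = TRUE)
      if (nrow(px) == 0L) {
        warning("class '", cl, "' has no predicted pixels; skipped")
        return(NULL)
      }
      n <- min(n_per_class, nrow(px))
      if (n < n_per_class)
        warning(sprintf("class '%s' has only %d predicted pixels (< %d); all taken",
                        cl, nrow(px), n_per_class))
      sel <- px[sample.int(nrow(px), n), , drop = FALSE]
      data.frame(row = sel[, 1L], col = sel[, 2L],
                 predicted_class = cl, true_class = NA_character_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Confusion matrix of an annotated ground-truth sample
#'
#' Rows are ground-truth classes, columns predicted classes, in the canonical
#' [SUBSTRUCTURES] order; entry (r, c) counts records with true class r
#' predicted as c.
#'
#' @param sample annotated data.frame from [sample_ground_truth_pixels()]
#'   (`true_class` filled in).
#' @return 4x4 integer matrix.
#' @export
confusion_matrix <- function(sample) {
  blank <- which(is.na(sample$true_class))
  if (length(blank) > 0L)
    stop("blank true_class in record(s): ",
         paste(utils::head(blank, 10L), collapse = ", "))
  truth <- factor(sample$true_class, levels = SUBSTRUCTURES)
  pred <- factor(sample$predicted_class, levels = SUBSTRUCTURES)
  if (anyNA(truth) || anyNA(pred))
    stop("classes must be drawn from: ", paste(SUBSTRUCTURES, collapse = ", "))
  m <- table(truth, pred)
  matrix(as.integer(m), 4L, 4L, dimnames = list(SUBSTRUCTURES, SUBSTRUCTURES))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall numeric vectors in \[0, 1\].
#' @return F1 scores; `NA` where precision + recall is zero.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), NA_real_)
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' Precision of class i is the diagonal over the column sum (predicted as i);
#' recall is the diagonal over the row sum (truly i). Zero denominators yield
#' missing values.
#'
#' @param m square confusion matrix, ground truth in rows, predictions in
#'   columns.
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || any(m < 0))
    stop("confusion matrix must be square and non-negative")
  cls <- rownames(m)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(m)))
  d <- diag(m)
  colsum <- colSums(m); rowsum <- rowSums(m)
  precision <- ifelse(colsum > 0, d / colsum, NA_real_)
  recall <- ifelse(rowsum > 0, d / rowsum, NA_real_)
  data.frame(class = cls, precision = precision, recall = recall,
             f1 = f1_score(precision, recall),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Turn a (ground-truth) label map into an annotation table
#'
#' Lists every non-background pixel with its class -- the exhaustive
#' annotation a synthetic fixture provides, in the format
#' [evaluate_labels()] and [sensitivity_sweep()] consume.
#'
#' @param labels a [seg_labels()] map.
#' @return data.frame with columns `row`, `col`, `true_class`.
#' @export
ground_truth_from_labels <- function(labels) {
  stopifnot(inherits(labels, "seg_labels"))
  px <- which(unclass(labels) != 0L, arr.ind = TRUE)
  data.frame(row = px[, 1L], col = px[, 2L],
             true_class = names(LABEL_CODES)[unclass(labels)[px] + 1L],
             stringsAsFactors = FALSE)
}

#' Evaluate predicted labels at annotated pixel coordinates
#'
#' Looks up the predicted class of each annotated record in a (possibly
#' re-derived) label map and scores the predictions; records predicted as
#' background are dropped from the confusion matrix, with their count
#' attached as attribute `n_background`.
#'
#' @param labels a [seg_labels()] map.
#' @param truth annotated ground-truth data.frame (`row`, `col`,
#'   `true_class`).
#' @return data.frame from [precision_recall_f1()] with the confusion matrix
#'   as attribute `confusion`.
#' @export
evaluate_labels <- function(labels, truth) {
  stopifnot(inherits(labels, "seg_labels"))
  code <- unclass(labels)[cbind(truth$row, truth$col)]
  keep <- code != 0L
  sample <- data.frame(row = truth$row[keep], col = truth$col[keep],
                       predicted_class = names(LABEL_CODES)[code[keep] + 1L],
                       true_class = truth$true_class[keep],
                       stringsAsFactors = FALSE)
  m <- confusion_matrix(sample)
  out <- precision_recall_f1(m)
  attr(out, "confusion") <- m
  attr(out, "n_background") <- sum(!keep)
  out
}
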