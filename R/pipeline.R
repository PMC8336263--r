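#' Run configuration
#'
#' Bundles the segmentation parameters, sweep/noise settings and seeds of a
#' full run into one object that round-trips losslessly through a YAML file.
#'
#' @param params a [seg_params()].
#' @param noise_fractions label-noise fractions for robustness curves.
#' @param n_per_class ground-truth pixels sampled per class.
#' @param seed master seed.
#' @param out_dir output directory for artefacts.
#' @return an object of class `run_config`.
#' @export
run_config <- function(params = seg_params(),
                       noise_fractions = c(0, 0.05, 0.1, 0.2),
                       n_per_class = 1000L, seed = 1L, out_dir = ".") {
  stopifnot(inherits(params, "seg_params"))
  structure(list(params = params, noise_fractions = noise_fractions,
                 n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$params <- unclass(x$params)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(params = do.call(seg_params, x$params),
             noise_fractions = as.numeric(x$noise_fractions),
             n_per_class = x$n_per_class, seed = x$seed, out_dir = x$out_dir)
}

#' End-to-end pipeline: segmentation, traits, heritability
#'
#' Segments every bundle, assembles the per-plant trait table and, when the
#' table holds at least two accessions with replication, fits the per-trait
#' heritability report. Per-plant failures are logged and skipped, not fatal;
#' the summary reports the skip count. Re-running with an identical
#' configuration and input is bit-identical.
#'
#' @param bundles list of [scan_bundle()] objects, or a manifest CSV path
#'   (see [read_manifest()]).
#' @param config a [run_config()].
#' @return list with `traits` (data.frame), `heritability` (data.frame or
#'   `NULL`), `n_failed` and `failures` (named error messages).
#' @export
run_pipeline <- function(bundles, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(bundles)) bundles <- read_manifest(bundles)
  rows <- list()
  failures <- character(0)
  for (b in bundles) {
    res <- tryCatch({
      lab <- suppressWarnings(segment_bundle(b, config$params))
      suppressWarnings(plant_traits(b, lab))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[b$sample_id] <- conditionMessage(res)
      warning("skipping ", b$sample_id, ": ", conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  traits <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
  herit <- NULL
  if (!is.null(traits)) {
    acc <- traits$accession_id[!is.na(traits$accession_id)]
    if (length(unique(acc)) >= 2L && any(table(acc) >= 2L))
      herit <- suppressWarnings(heritability_report(traits))
  }
  list(traits = traits, heritability = herit,
       n_failed = length(failures), failures = failures)
}
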