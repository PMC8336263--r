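#' Fit a one-way random-effects model and extract variance components
#'
#' Fits the random-intercept model \eqn{P = G + \epsilon} (genotype and error
#' both random) by restricted maximum likelihood via [lme4::lmer()], and
#' returns the genotype variance, the residual variance and the broad-sense
#' heritability (repeatability) \eqn{H^2 = Var(G) / (Var(G) + Var(\epsilon))}.
#' Negative variance estimates are truncated at 0 by the fitter. For balanced
#' data the REML estimate agrees with the closed-form one-way ANOVA
#' method-of-moments estimator.
#'
#' Missing trait values are dropped with a message. At least two accessions
#' and at least one accession with two or more replicates are required
#' (otherwise the residual variance is unidentifiable).
#'
#' @param value numeric trait values, one per plant.
#' @param accession accession identifier per plant.
#' @return object of class `variance_components`: a list with `var_G`,
#'   `var_e`, `H2`, `n_accessions`, `n_total`, `n_dropped` and the advisory
#'   residual-vs-fitted correlation `resid_fitted_cor`.
#' @export
fit_random_effects <- function(value, accession) {
  stopifnot(length(value) == length(accession))
  keep <- !is.na(value) & !is.na(accession)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message("dropped ", n_dropped, " observation(s) with missing values")
  value <- as.numeric(value[keep])
  accession <- as.character(accession[keep])
  tab <- table(accession)
  if (length(tab) < 2L) stop("need at least two accessions")
  if (max(tab) < 2L)
    stop("all accessions are singletons: residual variance unidentifiable")
  if (stats::var(value) == 0) {
    warning("trait is constant: total variance is zero, H2 undefined")
    return(new_variance_components(0, 0, NA_real_, length(tab), length(value),
                                   n_dropped, NA_real_))
  }
  dat <- data.frame(value = value, accession = accession)
  # optimizer chatter on degenerate (zero-variance-component) fits is benign
  fit <- suppressWarnings(
    lme4::lmer(value ~ 1 + (1 | accession), data = dat, REML = TRUE,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 calc.derivs = FALSE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_G <- vc$vcov[vc$grp == "accession"]
  var_e <- vc$vcov[vc$grp == "Residual"]
  h2 <- if (var_G + var_e > 0) var_G / (var_G + var_e) else NA_real_
  dcor <- suppressWarnings(
    stats::cor(stats::fitted(fit), stats::resid(fit)))
  new_variance_components(var_G, var_e, h2, length(tab), length(value),
                          n_dropped, dcor)
}

new_variance_components <- function(var_G, var_e, h2, n_accessions, n_total,
                                    n_dropped = 0L, resid_fitted_cor = NA_real_) {
  structure(list(var_G = var_G, var_e = var_e, H2 = h2,
                 n_accessions = n_accessions, n_total = n_total,
                 n_dropped = n_dropped, resid_fitted_cor = resid_fitted_cor),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> var_G = %.4g, var_e = %.4g, H2 = %.3f (%d accessions, %d plants)\n",
              x$var_G, x$var_e, x$H2, x$n_accessions, x$n_total))
  invisible(x)
}

#' Broad-sense heritability from variance components
#'
#' \eqn{H^2 = Var(G) / (Var(G) + Var(\epsilon))}, in \[0, 1\]. Undefined
#' (NA, with a warning) when the total variance is zero.
#'
#' @param vc a `variance_components` object, or the genotype variance.
#' @param var_e residual variance (when `vc` is given as a number).
#' @return numeric scalar in \[0, 1\] or `NA`.
#' @export
heritability <- function(vc, var_e = NULL) {
  if (inherits(vc, "variance_components")) {
    var_G <- vc$var_G; var_e <- vc$var_e
  } else {
    var_G <- vc
    if (is.null(var_e)) stop("supply `var_e` or a variance_components object")
  }
  if (var_G < 0 || var_e < 0) stop("variances must be non-negative")
  if (var_G + var_e == 0) {
    warning("zero total variance: H2 undefined")
    return(NA_real_)
  }
  var_G / (var_G + var_e)
}

#' Closed-form ANOVA variance components for balanced designs
#'
#' One-way method-of-moments estimator: `var_G = max(0, (MSB - MSW) / k)`,
#' `var_e = MSW`, with `k` replicates per accession. Intended as an
#' independent check of the REML fit on balanced data.
#'
#' @inheritParams fit_random_effects
#' @return a `variance_components` object.
#' @export
anova_variance_components <- function(value, accession) {
  keep <- !is.na(value) & !is.na(accession)
  value <- as.numeric(value[keep]); accession <- as.character(accession[keep])
  tab <- table(accession)
  k <- unique(as.integer(tab))
  if (length(k) != 1L || k < 2L)
    stop("the ANOVA estimator requires a balanced design with >= 2 replicates")
  n <- length(tab)
  grand <- mean(value)
  gm <- tapply(value, accession, mean)
  msb <- k * sum((gm - grand)^2) / (n - 1)
  msw <- sum((value - gm[accession])^2) / (n * (k - 1))
  var_G <- max(0, (msb - msw) / k)
  h2 <- if (var_G + msw > 0) var_G / (var_G + msw) else NA_real_
  new_variance_components(var_G, msw, h2, n, length(value))
}

#' Heritability report over a trait table
#'
#' Fits [fit_random_effects()] to every trait column and reports variance
#' components, H2 and the advisory residual-vs-fitted correlation per trait.
#' Traits that are constant or all-missing are skipped with a warning.
#'
#' @param table data.frame with an accession column and numeric trait
#'   columns (e.g. from [panel_trait_table()] or [plant_traits()] rows).
#' @param traits trait column names; defaults to every numeric column except
#'   identifiers.
#' @param accession_col name of the accession column.
#' @return data.frame with one row per trait: `trait`, `var_G`, `var_e`,
#'   `H2`, `n_accessions`, `n_total`, `resid_fitted_cor`.
#' @export
heritability_report <- function(table, traits = NULL,
                                accession_col = "accession_id") {
  if (!accession_col %in% names(table))
    stop("no accession column '", accession_col, "' in the trait table")
  if (is.null(traits)) {
    num <- vapply(table, is.numeric, logical(1))
    traits <- setdiff(names(table)[num], c("replicate", accession_col))
  }
  rows <- lapply(traits, function(tr) {
    v <- table[[tr]]
    ok <- !is.na(v)
    if (!any(ok) || stats::var(v[ok]) == 0) {
      warning("trait '", tr, "' constant or all-missing; skipped")
      return(NULL)
    }
    vc <- suppressMessages(fit_random_effects(v, table[[accession_col]]))
    data.frame(trait = tr, var_G = vc$var_G, var_e = vc$var_e, H2 = vc$H2,
               n_accessions = vc$n_accessions, n_total = vc$n_total,
               resid_fitted_cor = vc$resid_fitted_cor,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
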