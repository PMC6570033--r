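#' Pearson correlation matrix of soil properties
#'
#' @param soils a soil table (see [read_soil_table()]).
#' @param properties character vector of numeric property columns; defaults
#'   to all nine of [soil_properties].
#' @param use missing-data handling: `"pairwise"` (default) computes each
#'   entry on pairwise-complete cases, `"complete"` drops every sample with
#'   any missing property first.
#' @return symmetric correlation matrix with unit diagonal.  Entries
#'   involving a zero-variance property are set to `NA` and the affected
#'   properties are reported in the `"flagged"` attribute (with a warning)
#'   rather than propagating silently.
#' @export
property_correlations <- function(soils, properties = soil_properties,
                                  use = c("pairwise", "complete")) {
  use <- match.arg(use)
  if (nrow(soils) < 3) stop("need at least 3 samples", call. = FALSE)
  x <- as.data.frame(soils)[, properties, drop = FALSE]
  if (!all(vapply(x, is.numeric, logical(1)))) {
    stop("all selected properties must be numeric", call. = FALSE)
  }
  if (use == "complete") x <- x[stats::complete.cases(x), , drop = FALSE]
  degenerate <- vapply(x, function(v) stats::sd(v, na.rm = TRUE) == 0,
                       logical(1))
  r <- suppressWarnings(
    stats::cor(x, use = "pairwise.complete.obs", method = "pearson"))
  if (any(degenerate)) {
    flagged <- properties[degenerate]
    warning("zero-variance propert",
            if (length(flagged) > 1) "ies: " else "y: ",
            paste(flagged, collapse = ", "),
            "; correlations undefined (NA)", call. = FALSE)
    r[flagged, ] <- NA_real_
    r[, flagged] <- NA_real_
    attr(r, "flagged") <- flagged
  }
  diag(r) <- 1
  r
}

#' Maximum-likelihood factor analysis of soil properties
#'
#' Standardizes the selected properties, extracts `n_factors` factors by
#' maximum likelihood ([stats::factanal()]), applies the promax rotation
#' and estimates factor scores by the regression method.  Variance
#' proportions are reported from the unrotated ML solution: after an
#' oblique rotation the per-factor "variance explained" is no longer
#' additive, so the unrotated sums of squared loadings (divided by the
#' number of variables) are the quantities whose cumulative sum is
#' meaningful.
#'
#' Samples with a missing value in any selected property are dropped by
#' default (`missing = "drop"`); `missing = "impute"` replaces missing
#' cells by the property mean instead.
#'
#' @inheritParams property_correlations
#' @param n_factors number of factors (default 2).
#' @param missing `"drop"` (default) or `"impute"`.
#' @param rotation rotation for the reported loadings and scores; the
#'   default `"promax"` is the only rotation the downstream proxy selection
#'   has been designed around.
#' @return object of class `soil_fa`: rotated `loadings` (sign convention:
#'   the largest-magnitude loading of each factor is positive),
#'   `variance_proportion` and `cumulative_proportion` (unrotated ML
#'   solution), `factor_scores`, `rotation`, `n_used`, `dropped` (sample
#'   ids excluded by missing-data handling).
#' @export
soil_factor_analysis <- function(soils, properties = soil_properties,
                                 n_factors = 2,
                                 missing = c("drop", "impute"),
                                 rotation = "promax") {
  missing <- match.arg(missing)
  x <- as.data.frame(soils)[, properties, drop = FALSE]
  p <- length(properties)
  # ML factor model degrees of freedom must be non-negative
  df <- ((p - n_factors)^2 - p - n_factors) / 2
  if (n_factors >= p || df < 0) {
    stop("n_factors = ", n_factors, " leaves no degrees of freedom for ",
         p, " variables", call. = FALSE)
  }
  dropped <- character(0)
  if (missing == "drop") {
    keep <- stats::complete.cases(x)
    dropped <- as.character(soils$sample_id[!keep])
    x <- x[keep, , drop = FALSE]
    ids <- as.character(soils$sample_id[keep])
  } else {
    for (col in names(x)) {
      x[[col]][is.na(x[[col]])] <- mean(x[[col]], na.rm = TRUE)
    }
    ids <- as.character(soils$sample_id)
  }
  if (nrow(x) <= length(properties)) {
    stop("need more complete samples (", nrow(x), ") than properties (",
         length(properties), ") for a full-rank correlation matrix",
         call. = FALSE)
  }
  z <- scale(as.matrix(x))

  unrot <- tryCatch(
    stats::factanal(z, factors = n_factors, rotation = "none"),
    error = function(e) stop("factor analysis did not converge: ",
                             conditionMessage(e), call. = FALSE))
  rot <- stats::factanal(z, factors = n_factors, rotation = rotation,
                         scores = "regression")
  if (!isTRUE(unrot$converged) || !isTRUE(rot$converged)) {
    stop("factor analysis did not converge (ML optimizer reported failure)",
         call. = FALSE)
  }
  if (any(unrot$uniquenesses <= 0.005 + 1e-12)) {
    warning("Heywood case: uniqueness at its lower bound for ",
            paste(names(which(unrot$uniquenesses <= 0.005 + 1e-12)),
                  collapse = ", "), call. = FALSE)
  }

  ss <- colSums(unclass(unrot$loadings)^2)
  loadings <- unclass(rot$loadings)
  scores <- rot$scores
  # sign convention: largest-|loading| entry of each factor positive
  for (j in seq_len(n_factors)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- ids

  structure(list(
    loadings = loadings,
    variance_proportion = as.numeric(ss) / p,
    cumulative_proportion = cumsum(as.numeric(ss)) / p,
    factor_scores = scores,
    rotation = rotation,
    variance_basis = "unrotated ML solution",
    n_used = nrow(x),
    dropped = dropped,
    properties = properties
  ), class = "soil_fa")
}

#' @export
print.soil_fa <- function(x, digits = 2, ...) {
  k <- length(x$variance_proportion)
  cat("Soil-property factor analysis (ML, ", x$rotation, " rotation, ",
      x$n_used, " samples)\n", sep = "")
  print(round(x$loadings, digits))
  cat("Variance proportions (", x$variance_basis, "): ",
      paste(sprintf("%.1f%%", 100 * x$variance_proportion), collapse = ", "),
      "; cumulative ",
      sprintf("%.1f%%", 100 * x$cumulative_proportion[k]), "\n", sep = "")
  invisible(x)
}

#' Select proxy explanatory variables from a factor analysis
#'
#' Partitions the properties by their dominant factor and returns one proxy
#' per factor.  Within a factor's group the highest-|loading| member is the
#' candidate, but a property on the preference list supersedes it when its
#' loading is within `prefer_margin` of the group maximum: CEC and pH are
#' the conventional, routinely measured drivers of metal sorption in soils,
#' so they are preferred over statistically interchangeable co-loading
#' properties (WHC, surface area, texture fractions).  A near-tie between
#' two non-preferred candidates (|loading| difference below `tie_tol`) is
#' reported in the `ties` attribute with a warning instead of being broken
#' silently.
#'
#' @param fa a `soil_fa` with at least 2 factors.
#' @param prefer preferred property names, strongest preference first.
#' @param prefer_margin how far (absolute loading units) a preferred
#'   property may trail the group maximum and still be chosen.
#' @param tie_tol loading difference below which a tie is flagged.
#' @return character vector, one property name per factor (factor order).
#' @export
select_proxies <- function(fa, prefer = c("cec", "ph"),
                           prefer_margin = 0.5, tie_tol = 0.05) {
  stopifnot(inherits(fa, "soil_fa"))
  k <- ncol(fa$loadings)
  if (k < 2) stop("proxy selection needs at least 2 factors", call. = FALSE)
  dominant <- apply(abs(fa$loadings), 1, which.max)
  chosen <- character(k)
  ties <- list()
  for (j in seq_len(k)) {
    group <- rownames(fa$loadings)[dominant == j]
    if (length(group) == 0) {
      stop("no property loads dominantly on factor ", j, call. = FALSE)
    }
    load <- abs(fa$loadings[group, j])
    top <- group[which.max(load)]
    pick <- top
    for (pref in prefer) {
      if (pref %in% group && load[pref] >= max(load) - prefer_margin) {
        pick <- pref
        break
      }
    }
    if (pick == top && length(group) > 1) {
      runner <- sort(load, decreasing = TRUE)[2]
      if (max(load) - runner < tie_tol) {
        ties[[length(ties) + 1]] <- group[order(load, decreasing = TRUE)][1:2]
        warning("factor ", j, ": loadings of ",
                paste(ties[[length(ties)]], collapse = " and "),
                " differ by < ", tie_tol, "; reporting the tie", call. = FALSE)
      }
    }
    chosen[j] <- pick
  }
  if (length(ties) > 0) attr(chosen, "ties") <- ties
  chosen
}
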