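# Calibration: expected-vs-observed regression on spike-in series, blend-based
# response-factor estimation, orthogonal released-glycan bridging, and
# design-of-experiments response surfaces for electrospray source parameters.

#' Expected-vs-observed calibration fit
#'
#' Least-squares regression of the measured proportion on the expected
#' proportion of a spike-in series. `kind = "linear"` fits slope + intercept;
#' `kind = "second-order"` adds a quadratic term (the curvature that shows up
#' when ionization propensities differ between the blended states).
#'
#' @param expected Expected proportions (from the blend design), in `[0, 1]`.
#' @param measured Measured raw proportions (quantified without correction).
#' @param kind "linear" or "second-order".
#' @return Object of class `mam_calfit` with coefficients, R-squared and
#'   residuals; supports `coef()`, `predict()`, `summary()`, `print()`.
#' @examples
#' fit <- fit_expected_observed(seq(0, 1, 0.25), seq(0, 1, 0.25))
#' fit$r_squared  # 1
#' @export
fit_expected_observed <- function(expected, measured,
                                  kind = c("linear", "second-order")) {
  kind <- match.arg(kind)
  stopifnot(length(expected) == length(measured))
  if (any(expected < 0 | expected > 1)) {
    stop("expected proportions must lie in [0, 1]", call. = FALSE)
  }
  n_min <- if (kind == "linear") 3L else 4L
  if (length(unique(expected)) < n_min) {
    stop(sprintf("need >= %d distinct levels for a %s fit", n_min, kind),
         call. = FALSE)
  }
  if (stats::var(expected) == 0) {
    stop("degenerate series: expected values are constant", call. = FALSE)
  }
  df <- data.frame(expected = expected, measured = measured)
  fit <- if (kind == "linear") {
    stats::lm(measured ~ expected, data = df)
  } else {
    stats::lm(measured ~ expected + I(expected^2), data = df)
  }
  structure(list(kind = kind, fit = fit,
                 coefficients = stats::coef(fit),
                 r_squared = summary(fit)$r.squared,
                 residuals = stats::residuals(fit),
                 data = df),
            class = "mam_calfit")
}

#' @export
coef.mam_calfit <- function(object, ...) object$coefficients

#' @export
predict.mam_calfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (!is.data.frame(newdata)) newdata <- data.frame(expected = newdata)
  stats::predict(object$fit, newdata = newdata)
}

#' @export
residuals.mam_calfit <- function(object, ...) object$residuals

#' @export
summary.mam_calfit <- function(object, ...) summary(object$fit, ...)

#' @export
print.mam_calfit <- function(x, ...) {
  cat(sprintf("<%s calibration fit, R^2 = %.5f>\n", x$kind, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' Estimate response factors from a blend series
#'
#' For each non-reference compound, the relative ionization propensity is the
#' slope through the origin of the measured share RATIO (compound over
#' reference) against the expected share ratio across blend levels. Under the
#' proportional-response model the measured share of compound i is
#' `RF_i e_i / sum_j RF_j e_j`, so the share ratio equals
#' `(RF_i / RF_ref) * (e_i / e_ref)` exactly, making the ratio slope an exact,
#' scale-invariant estimator of `RF_i / RF_ref`. Factors are normalized so the
#' reference compound is 1.
#'
#' @param series data.frame with columns `level`, `compound`,
#'   `expected_share`, `measured_share` (shares in `[0, 1]` per level).
#' @param reference Reference compound label (factor fixed at 1).
#' @param min_levels Minimum distinct usable levels per compound.
#' @return A `correction_model` with provenance "blend-fit". Compounds with
#'   no usable variation keep factor 1 (with a warning).
#' @export
estimate_response_factors <- function(series, reference, min_levels = 3L) {
  need <- c("level", "compound", "expected_share", "measured_share")
  missing_cols <- setdiff(need, names(series))
  if (length(missing_cols)) {
    stop("series missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!reference %in% series$compound) {
    stop("reference compound not present in series: ", reference, call. = FALSE)
  }
  ref <- series[series$compound == reference, c("level", "expected_share",
                                                "measured_share")]
  names(ref) <- c("level", "ref_expected", "ref_measured")
  factors <- c(stats::setNames(1, reference))
  for (cmp in setdiff(unique(series$compound), reference)) {
    sub <- merge(series[series$compound == cmp, ], ref, by = "level")
    ok <- sub$ref_expected > 0 & sub$ref_measured > 0 & sub$expected_share > 0
    sub <- sub[ok, ]
    x <- sub$expected_share / sub$ref_expected
    y <- sub$measured_share / sub$ref_measured
    if (length(unique(sub$level)) < min_levels || sum(x^2) == 0) {
      warning("compound '", cmp, "' has no usable blend variation; factor kept at 1",
              call. = FALSE)
      factors[cmp] <- 1
      next
    }
    factors[cmp] <- sum(x * y) / sum(x^2)
  }
  correction_model(factors = factors, provenance = "blend-fit")
}

#' Response factors from an equimolar mix
#'
#' A fully reduced, NEM-capped sample mixed 1:1 with nonreduced starting
#' material contains each bond's reduced and linked compounds in equal molar
#' amounts, so their area ratio IS the relative response factor. Applying the
#' resulting factors forces the equimolar mix to quantify at 50 %.
#'
#' @param areas Named analyte areas measured on the equimolar mix.
#' @param pairs List of `c(reduced, linked)` compound pairs.
#' @return A `correction_model` with provenance "equimolar-mix": the reduced
#'   compound of each pair carries factor `area_reduced / area_linked`
#'   relative to its linked partner.
#' @export
equimolar_mix_factors <- function(areas,
                                  pairs = list(c("lambda_reduced", "lambda_linked"),
                                               c("kappa_reduced", "kappa_linked"))) {
  factors <- c()
  for (p in pairs) {
    if (!all(p %in% names(areas))) next
    if (areas[[p[2]]] == 0 || areas[[p[1]]] == 0) {
      stop("zero area in equimolar mix for pair ", paste(p, collapse = "/"),
           call. = FALSE)
    }
    factors[p[1]] <- areas[[p[1]]] / areas[[p[2]]]
    factors[p[2]] <- 1
  }
  if (!length(factors)) stop("no usable pairs in equimolar mix", call. = FALSE)
  correction_model(factors = factors, provenance = "equimolar-mix")
}

#' Derive glycoform conversion factors from an orthogonal method
#'
#' Bridges raw MRM glycoform percentages to released-glycan (HILIC-2AB-style)
#' percentages: for each glycoform the conversion factor is the mean (or
#' median) over training lots of orthogonal % / raw MRM %. Applying the
#' factors to held-out raw percentages and renormalizing yields corrected
#' percentages on the orthogonal scale.
#'
#' @param paired data.frame with columns `lot`, `glycoform`,
#'   `mam_raw_percent`, `orthogonal_percent`.
#' @param method "mean" or "median" across lots.
#' @return A `correction_model` with provenance "orthogonal-bridge".
#' @export
derive_glyco_conversion <- function(paired, method = c("mean", "median")) {
  method <- match.arg(method)
  need <- c("lot", "glycoform", "mam_raw_percent", "orthogonal_percent")
  missing_cols <- setdiff(need, names(paired))
  if (length(missing_cols)) {
    stop("paired table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(paired$lot)) < 2L) {
    stop("need >= 2 training lots", call. = FALSE)
  }
  if (any(paired$mam_raw_percent == 0 & paired$orthogonal_percent > 0)) {
    stop("zero raw MRM percentage for a glycoform present orthogonally",
         call. = FALSE)
  }
  agg <- if (method == "mean") mean else stats::median
  ratio <- paired$orthogonal_percent / paired$mam_raw_percent
  conv <- tapply(ratio, paired$glycoform, agg)
  correction_model(conversions = stats::setNames(as.numeric(conv), names(conv)),
                   provenance = "orthogonal-bridge")
}

#' Fit a quadratic response surface to a DoE design
#'
#' Ordinary least-squares quadratic response surface over electrospray source
#' parameters: linear + quadratic (+ pairwise interaction, if requested)
#' terms, with factors centered and scaled to `[-1, 1]` internally. Raw
#' per-coefficient t-test p-values are reported.
#'
#' @param design data.frame of factor settings (one column per factor).
#' @param response Numeric response vector (one value per run).
#' @param interactions Include pairwise interaction terms?
#' @return Object of class `mam_doe`: coefficient table (estimate, p-value on
#'   the coded scale), the underlying `lm` fit, and a surface evaluator via
#'   `predict()`.
#' @export
fit_response_surface <- function(design, response, interactions = TRUE) {
  stopifnot(is.data.frame(design), nrow(design) == length(response))
  factors <- names(design)
  center <- vapply(design, function(v) mean(range(v)), numeric(1))
  halfr <- vapply(design, function(v) diff(range(v)) / 2, numeric(1))
  if (any(halfr == 0)) {
    stop("degenerate design: factor(s) without variation: ",
         paste(factors[halfr == 0], collapse = ", "), call. = FALSE)
  }
  coded <- as.data.frame(mapply(function(v, c0, h) (v - c0) / h,
                                design, center, halfr, SIMPLIFY = FALSE))
  terms <- c(factors, paste0("I(", factors, "^2)"))
  if (interactions && length(factors) > 1L) {
    cmb <- utils::combn(factors, 2)
    terms <- c(terms, apply(cmb, 2, paste, collapse = ":"))
  }
  n_coef <- length(terms) + 1L
  if (nrow(design) < n_coef + 1L) {
    stop(sprintf("need >= %d runs for %d coefficients", n_coef + 1L, n_coef),
         call. = FALSE)
  }
  fml <- stats::as.formula(paste(".response ~", paste(terms, collapse = " + ")))
  dat <- cbind(coded, .response = response)
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < n_coef) stop("rank-deficient design", call. = FALSE)
  sm <- summary(fit)$coefficients
  structure(list(factors = factors, center = center, half_range = halfr,
                 fit = fit,
                 coefficients = data.frame(term = rownames(sm),
                                           estimate = sm[, "Estimate"],
                                           p_value = sm[, "Pr(>|t|)"],
                                           row.names = NULL,
                                           stringsAsFactors = FALSE)),
            class = "mam_doe")
}

#' @export
predict.mam_doe <- function(object, newdata, ...) {
  coded <- as.data.frame(mapply(function(f) {
    (newdata[[f]] - object$center[[f]]) / object$half_range[[f]]
  }, object$factors, SIMPLIFY = FALSE))
  names(coded) <- object$factors
  stats::predict(object$fit, newdata = coded)
}

#' @export
coef.mam_doe <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
print.mam_doe <- function(x, ...) {
  cat(sprintf("<DoE response surface: %s>\n", paste(x$factors, collapse = ", ")))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Face-centered central composite design
#'
#' Corner points at the factor range extremes, face-center points, and
#' replicated center points: the standard design for fitting a full quadratic
#' response surface in a box-shaped region.
#'
#' @param ranges Named list of `c(low, high)` per factor.
#' @param n_center Number of center-point replicates.
#' @return data.frame of runs (one column per factor).
#' @export
face_centered_design <- function(ranges, n_center = 3L) {
  factors <- names(ranges)
  k <- length(factors)
  corners <- expand.grid(rep(list(c(-1, 1)), k))
  faces <- do.call(rbind, lapply(seq_len(k), function(i) {
    m <- matrix(0, 2, k)
    m[, i] <- c(-1, 1)
    m
  }))
  centers <- matrix(0, n_center, k)
  coded <- rbind(as.matrix(corners), faces, centers)
  out <- as.data.frame(mapply(function(i, f) {
    lo <- ranges[[f]][1]; hi <- ranges[[f]][2]
    (lo + hi) / 2 + coded[, i] * (hi - lo) / 2
  }, seq_len(k), factors, SIMPLIFY = FALSE))
  names(out) <- factors
  rownames(out) <- NULL
  out
}
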