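#' Construct a qPCR standard curve
#'
#' A standard curve is the linear relation `Cq = slope_ln * ln(x) + intercept`
#' between the quantification cycle and the natural log of the relative DNA
#' amount `x`. Amplification efficiency is derived from the slope via the
#' usual log10 convention: converting to `slope10 = slope_ln * ln(10)` and
#' applying `E = 10^(-1/slope10) - 1`. A valid assay has a negative slope;
#' a non-negative slope yields a curve flagged invalid (with a warning), and
#' an efficiency outside (0, 1.1] is also flagged.
#'
#' @param slope_ln Cq change per unit `ln(concentration)` (negative for a
#'   working assay).
#' @param intercept Cq at relative concentration 1.
#' @param r_squared Fit quality in `[0, 1]` (NA if unknown).
#' @param lod,loq Limit of detection / quantification, on the concentration
#'   scale (NA if undetermined).
#'
#' @return An object of class `standard_curve` with elements `slope_ln`,
#'   `intercept`, `r_squared`, `efficiency`, `lod`, `loq`, `valid`.
#' @seealso [fit_standard_curve()], [predict.standard_curve()], [quantify()]
#' @examples
#' curve <- standard_curve(-1.526, 41.232)
#' curve$efficiency  # ~0.926
#' @export
standard_curve <- function(slope_ln, intercept, r_squared = NA_real_,
                           lod = NA_real_, loq = NA_real_) {
  stopifnot(is.numeric(slope_ln), length(slope_ln) == 1L,
            is.numeric(intercept), length(intercept) == 1L)
  efficiency <- if (slope_ln < 0) 10^(-1 / (slope_ln * log(10))) - 1 else NA_real_
  valid <- isTRUE(slope_ln < 0)
  if (!valid) {
    warning("standard curve has non-negative slope; flagged invalid", call. = FALSE)
  } else if (!is.na(efficiency) && (efficiency <= 0 || efficiency > 1.1)) {
    warning(sprintf("amplification efficiency %.3f outside (0, 1.1]; check the assay",
                    efficiency), call. = FALSE)
    valid <- FALSE
  }
  if (!is.na(lod) && !is.na(loq) && lod > loq) {
    warning("LOD exceeds LOQ; check the dilution series", call. = FALSE)
  }
  structure(list(slope_ln = slope_ln, intercept = intercept,
                 r_squared = r_squared, efficiency = efficiency,
                 lod = lod, loq = loq, valid = valid),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve: Cq =", format(x$slope_ln), "* ln(x) +",
      format(x$intercept), "\n")
  cat(sprintf("  efficiency: %s   R^2: %s   %s\n",
              ifelse(is.na(x$efficiency), "NA", sprintf("%.1f%%", 100 * x$efficiency)),
              ifelse(is.na(x$r_squared), "NA", format(round(x$r_squared, 4))),
              if (x$valid) "valid" else "FLAGGED INVALID"))
  cat(sprintf("  LOD: %s   LOQ: %s (relative DNA amount)\n",
              format(x$lod), format(x$loq)))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(slope_ln = object$slope_ln, intercept = object$intercept)
}

#' Validate a dilution-series table
#'
#' A dilution series records, for each concentration level, the Cq of every
#' replicate reaction (`NA` = no amplification). Concentrations must be
#' strictly decreasing across levels in the canonical ordering; the table may
#' be supplied in any row order.
#'
#' @param x A `data.frame` with columns `concentration`, `rep`, `cq`.
#' @return The validated `data.frame` (classed `dilution_series`).
#' @export
dilution_series <- function(x) {
  need <- c("concentration", "rep", "cq")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("a dilution series needs columns: concentration, rep, cq", call. = FALSE)
  }
  if (any(!is.finite(x$concentration) | x$concentration <= 0)) {
    stop("concentrations must be positive and finite", call. = FALSE)
  }
  if (any(!is.na(x$cq) & (x$cq <= 0 | x$cq > 50))) {
    stop("Cq values must lie in (0, 50] or be NA (no amplification)", call. = FALSE)
  }
  x <- x[order(-x$concentration, x$rep), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("dilution_series", "data.frame")
  x
}

#' Fit a standard curve to a dilution series
#'
#' Ordinary least squares of Cq against `ln(concentration)`. By default the
#' fit uses the per-level mean Cq of amplifying replicates, which is robust
#' to unbalanced replicate dropout at the low-concentration end of the
#' series; set `use_replicates = TRUE` to fit all amplifying wells
#' individually. The limits of detection and quantification are then
#' determined from the replicate-level detection outcomes (see
#' [compute_lod_loq()]).
#'
#' @param series A dilution-series `data.frame` (see [dilution_series()]).
#' @param use_replicates Fit every amplifying replicate instead of level means.
#' @param p_detect,cv_max LOD/LOQ rule parameters, passed to
#'   [compute_lod_loq()].
#' @return A [standard_curve()] with `lod`/`loq` filled in.
#' @examples
#' conc <- rep(50 / 10^(0:3), each = 3)
#' ser <- dilution_series(data.frame(concentration = conc, rep = 1:3,
#'                                   cq = -1.526 * log(conc) + 41.232))
#' fit_standard_curve(ser)
#' @export
fit_standard_curve <- function(series, use_replicates = FALSE,
                               p_detect = 0.95, cv_max = 0.35) {
  series <- dilution_series(series)
  amp <- series[!is.na(series$cq), , drop = FALSE]
  if (nrow(amp) == 0L) stop("no amplifying replicates: cannot fit a standard curve",
                            call. = FALSE)
  if (length(unique(amp$concentration)) < 2L) {
    stop("need amplifying replicates at >= 2 distinct concentrations", call. = FALSE)
  }
  if (use_replicates) {
    dat <- data.frame(lx = log(amp$concentration), cq = amp$cq)
  } else {
    m <- tapply(amp$cq, amp$concentration, mean)
    dat <- data.frame(lx = log(as.numeric(names(m))), cq = as.numeric(m))
  }
  fit <- stats::lm(cq ~ lx, data = dat)
  slope <- unname(stats::coef(fit)[["lx"]])
  intercept <- unname(stats::coef(fit)[["(Intercept)"]])
  # R^2 from residuals directly; summary.lm warns on exact (noiseless) fits
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((dat$cq - mean(dat$cq))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  curve <- suppressWarnings(standard_curve(slope, intercept, r_squared = r2))
  if (!curve$valid) warning("fitted standard curve flagged invalid", call. = FALSE)
  lim <- compute_lod_loq(series, curve, p_detect = p_detect, cv_max = cv_max)
  curve$lod <- lim$lod
  curve$loq <- lim$loq
  curve
}

#' Predict Cq from a relative DNA amount
#'
#' Evaluates the standard-curve line at concentration `x` (which must be
#' strictly positive).
#'
#' @param object A `standard_curve`.
#' @param x Relative DNA amount(s), > 0.
#' @param ... Unused.
#' @return Predicted Cq value(s).
#' @export
predict.standard_curve <- function(object, x, ...) {
  if (missing(x)) stop("`x` (relative DNA amount) is required", call. = FALSE)
  if (any(!is.finite(x) | x <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  object$slope_ln * log(x) + object$intercept
}

#' Back-calculate relative DNA amounts from Cq values
#'
#' Inverts the standard curve: `x = exp((cq - intercept) / slope_ln)`.
#' `NA` Cq (no amplification) maps to `NA` quantity. `quantify()` applies the
#' inversion to a wells table, filling its `quantity` column.
#'
#' @param curve A `standard_curve`.
#' @param cq Numeric Cq values, `NA` for no amplification.
#' @return For `quantify_cq()`, numeric quantities; for `quantify()`, the
#'   wells `data.frame` with a `quantity` column.
#' @export
quantify_cq <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope_ln == 0) stop("standard curve has zero slope", call. = FALSE)
  exp((cq - curve$intercept) / curve$slope_ln)
}

#' @param wells A wells `data.frame` with a `cq` column (see [read_wells()]).
#' @rdname quantify_cq
#' @export
quantify <- function(curve, wells) {
  wells$quantity <- quantify_cq(curve, wells$cq)
  wells
}

#' Determine the limits of detection and quantification
#'
#' Applies a replicate-rate rule to the dilution series: the LOD is the
#' lowest concentration at which at least a fraction `p_detect` (default
#' 95%) of replicates amplified; the LOQ additionally requires the
#' coefficient of variation of the back-calculated concentrations at the
#' level to be at most `cv_max` (default 0.35). Either limit is `NA` when no
#' level qualifies.
#'
#' @param series A dilution-series `data.frame`.
#' @param curve The fitted `standard_curve` (used to back-calculate
#'   concentrations for the LOQ criterion).
#' @param p_detect Minimum replicate detection rate.
#' @param cv_max Maximum coefficient of variation for quantification.
#' @return A list with elements `lod` and `loq`.
#' @export
compute_lod_loq <- function(series, curve, p_detect = 0.95, cv_max = 0.35) {
  series <- dilution_series(series)
  conc <- sort(unique(series$concentration), decreasing = TRUE)
  rate <- cv <- numeric(length(conc))
  for (i in seq_along(conc)) {
    cq <- series$cq[series$concentration == conc[i]]
    rate[i] <- mean(!is.na(cq))
    q <- quantify_cq(curve, cq[!is.na(cq)])
    cv[i] <- if (length(q) >= 2L && mean(q) > 0) stats::sd(q) / mean(q) else NA_real_
  }
  det_ok <- rate >= p_detect
  lod <- if (any(det_ok)) min(conc[det_ok]) else NA_real_
  loq_ok <- det_ok & !is.na(cv) & cv <= cv_max
  loq <- if (any(loq_ok)) min(conc[loq_ok]) else NA_real_
  list(lod = lod, loq = loq)
}
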