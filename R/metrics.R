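#' @include AllClasses.R
NULL

#' ROI statistics on a 2D image plane
#'
#' Statistics over pixels whose centres fall inside the ROI (circle of the
#' given diameter or square of the given side).
#'
#' @param values numeric matrix (x by y).
#' @param xCoords,yCoords pixel-centre coordinates in mm.
#' @param roi list or one-row data.frame with `shape` ("circle" or "square"),
#'   `x`, `y` (centre, mm) and `size` (diameter or side, mm).
#' @return list with `mean`, `sd` (sample standard deviation) and `n`.
#' @export
roiStats <- function(values, xCoords, yCoords, roi) {
  stopifnot(nrow(values) == length(xCoords), ncol(values) == length(yCoords))
  dx <- outer(xCoords - roi$x, rep(1, length(yCoords)))
  dy <- outer(rep(1, length(xCoords)), yCoords - roi$y)
  inside <- if (roi$shape == "circle") {
    dx^2 + dy^2 <= (roi$size / 2)^2
  } else {
    abs(dx) <= roi$size / 2 & abs(dy) <= roi$size / 2
  }
  if (!any(inside)) stop("ROI contains no pixel centres")
  v <- values[inside]
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
       n = length(v))
}

#' Contrast-to-noise ratio
#'
#' CNR = (C_Au - C_bkg) / sigma_bkg.
#'
#' @param cAu mean signal in the gold ROI.
#' @param cBkg mean signal in the background ROI.
#' @param sdBkg standard deviation of the background ROI (> 0).
#' @return the CNR.
#' @export
cnr <- function(cAu, cBkg, sdBkg) {
  if (!is.finite(sdBkg) || sdBkg <= 0)
    stop("undefined CNR: background standard deviation must be positive")
  (cAu - cBkg) / sdBkg
}

#' Rose-criterion detectability
#'
#' A signal is detectable when CNR >= 4 (boundary inclusive).
#'
#' @param cnrValue CNR value(s).
#' @param threshold Rose threshold, default 4.
#' @return logical.
#' @export
roseDetectable <- function(cnrValue, threshold = 4) {
  cnrValue >= threshold
}

#' CNR of a gold ROI against a background ROI on one image plane
#'
#' @inheritParams roiStats
#' @param roiGold,roiBkg ROI specifications (see [roiStats()]).
#' @return list with `cnr`, `cAu`, `cBkg`, `sdBkg`, `detectable`.
#' @export
cnrFromImage <- function(values, xCoords, yCoords, roiGold, roiBkg) {
  g <- roiStats(values, xCoords, yCoords, roiGold)
  b <- roiStats(values, xCoords, yCoords, roiBkg)
  v <- cnr(g$mean, b$mean, b$sd)
  list(cnr = v, cAu = g$mean, cBkg = b$mean, sdBkg = b$sd,
       detectable = roseDetectable(v))
}

# coefficient of determination without summary.lm's perfect-fit warning
.rsq <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum(stats::resid(fit)^2) / sst
}

#' Gold concentration detection limit from a CNR-concentration line
#'
#' Least-squares line CNR = m c + q; the detection limit is the
#' concentration where the line crosses the Rose criterion,
#' (threshold - q) / m.
#'
#' @param concentrations gold concentrations, wt%.
#' @param cnrs matched CNR values.
#' @param threshold Rose threshold, default 4.
#' @return list with `limit` (wt%), `slope`, `intercept`, `r2`.
#' @export
detectionLimit <- function(concentrations, cnrs, threshold = 4) {
  stopifnot(length(concentrations) >= 2,
            length(concentrations) == length(cnrs))
  fit <- stats::lm(cnrs ~ concentrations)
  m <- stats::coef(fit)[[2]]; q <- stats::coef(fit)[[1]]
  if (!is.finite(m) || m <= 0)
    stop("no detection limit: CNR does not increase with concentration")
  r2 <- .rsq(fit, cnrs)
  list(limit = (threshold - q) / m, slope = m, intercept = q, r2 = r2)
}

#' Extrapolate the surface detection limit from depth-dependent limits
#'
#' Exponential model limit(z) = a exp(b z), fitted by least squares on
#' log(limit); `a` is the surface (depth 0) detection limit.
#'
#' @param depths beam depths, mm (>= 3 points).
#' @param limits detection limits, wt% (positive).
#' @return list with `a` (wt% at depth 0), `b` (1/mm), `r2`.
#' @export
extrapolateSurfaceLimit <- function(depths, limits) {
  stopifnot(length(depths) >= 3, length(depths) == length(limits))
  if (any(limits <= 0)) stop("detection limits must be positive")
  fit <- stats::lm(log(limits) ~ depths)
  list(a = exp(stats::coef(fit)[[1]]), b = stats::coef(fit)[[2]],
       r2 = .rsq(fit, log(limits)))
}

#' Cross-modality CNR comparison report
#'
#' Ranks modalities per ROI and reports mean percent improvement of the
#' reference modality over each other, computed as the mean of per-ROI CNR
#' ratios minus one (mean-of-ratios convention).
#'
#' @param cnrTable data.frame with columns `roi`, `modality`, `cnr`; every
#'   modality must cover the same ROI set.
#' @param reference modality the improvements are quoted for.
#' @return list with `table` (per-ROI CNRs, Rose flags and ratios) and
#'   `improvementPct` (named vector, one entry per non-reference modality).
#' @export
comparisonReport <- function(cnrTable, reference = "xfet") {
  mods <- unique(cnrTable$modality)
  rois <- unique(cnrTable$roi)
  if (!reference %in% mods) stop("reference modality missing from table")
  wide <- stats::reshape(cnrTable, idvar = "roi", timevar = "modality",
                         direction = "wide")
  for (m in mods) {
    col <- paste0("cnr.", m)
    if (any(is.na(wide[[col]]))) stop("ROI sets differ across modalities")
  }
  tab <- data.frame(roi = wide$roi)
  for (m in mods) {
    tab[[m]] <- wide[[paste0("cnr.", m)]]
    tab[[paste0(m, "_detectable")]] <- roseDetectable(tab[[m]])
  }
  others <- setdiff(mods, reference)
  imp <- vapply(others, function(m) {
    ratios <- tab[[reference]] / tab[[m]]
    (mean(ratios) - 1) * 100
  }, 0)
  for (m in others) tab[[paste0("ratio_vs_", m)]] <- tab[[reference]] / tab[[m]]
  list(table = tab, improvementPct = imp)
}
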