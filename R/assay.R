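# Plate-assay statistics: LDH percent cytotoxicity, viability ratios versus
# control, and LD50 estimation by a four-parameter log-logistic fit.

#' LDH percent cytotoxicity
#'
#' \deqn{100 \times \frac{Exp.LDH - background}{MaxLDH - background}}
#' where the maximum-release control comes from fully lysed cells and the
#' background from cell-free medium.  Values outside [0, 100] are returned
#' as computed (with a warning), never clipped: they flag drifting controls.
#'
#' @param experimental experimental LDH release signal (vectorized).
#' @param background medium background signal.
#' @param maxControl maximum-release control signal; must exceed
#'   \code{background}.
#' @return percent cytotoxicity.
#' @examples
#' ldhCytotoxicity(30, 10, 110)   # 20
#' @export
ldhCytotoxicity <- function(experimental, background, maxControl) {
  if (any(!is.finite(experimental)) || !is.finite(background) ||
      !is.finite(maxControl))
    stop("all signals must be finite")
  if (maxControl <= background)
    stop("degenerate controls: maximum-release control (", maxControl,
         ") must exceed medium background (", background, ")")
  pct <- 100 * (experimental - background) / (maxControl - background)
  if (any(pct < 0 | pct > 100))
    warning("cytotoxicity outside [0, 100]%: check plate controls")
  pct
}

#' Viability ratio versus control
#'
#' @param treated mean signal of treated wells (vectorized).
#' @param control mean signal of control wells; must be positive.
#' @return treated / control.
#' @export
viabilityRatio <- function(treated, control) {
  if (!is.finite(control) || control <= 0)
    stop("'control' must be a positive finite signal")
  treated / control
}

# 4PL log-logistic response at dose d (d > 0), parameterized on log10 dose:
# slope > 0 gives a response falling with dose (viability vs toxicant)
.fourPL <- function(dose, top, bottom, ld50, slope)
  bottom + (top - bottom) / (1 + 10^(slope * (log10(dose) - log10(ld50))))

#' Fit an LD50 from a dose-response series
#'
#' Four-parameter log-logistic fit (top, bottom, LD50, hill slope) on log10
#' dose by deterministic Levenberg-Marquardt least squares.  Initialization
#' is fixed: top = max response, bottom = min response, LD50 = the dose
#' whose response is nearest to the half-range, slope = 1.
#'
#' @param doses concentrations, strictly positive, micromolar (or any unit;
#'   the LD50 keeps it), sorted ascending.
#' @param responses viability ratios versus control, same length (replicate
#'   means or individual wells with repeated doses).
#' @param maxIter iteration cap for the optimizer; default 200.
#' @return list of class \code{"ld50Fit"}: \code{ld50}, \code{top},
#'   \code{bottom}, \code{slope}, \code{rss} (residual sum of squares),
#'   \code{fitted}, \code{converged}.
#' @examples
#' d <- c(1, 10, 50, 100, 200, 500, 1000)
#' y <- 1 / (1 + (d / 250))          # noiseless, LD50 = 250
#' fitLD50(d, y)$ld50
#' @export
fitLD50 <- function(doses, responses, maxIter = 200L) {
  if (length(doses) != length(responses))
    stop("'doses' and 'responses' must have the same length")
  if (any(!is.finite(doses)) || any(doses <= 0))
    stop("doses must be finite and strictly positive")
  if (any(!is.finite(responses)))
    stop("responses must be finite")
  if (length(unique(doses)) < 4L)
    stop("need at least 4 distinct dose levels spanning the transition")
  ord <- order(doses)
  doses <- doses[ord]; responses <- responses[ord]

  top0 <- max(responses); bottom0 <- min(responses)
  half <- (top0 + bottom0) / 2
  ld500 <- doses[which.min(abs(responses - half))]
  df <- data.frame(dose = doses, resp = responses)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ bottom + (top - bottom) /
        (1 + 10^(slope * (log10(dose) - log10(ld50)))),
      data = df,
      start = list(top = top0, bottom = bottom0, ld50 = ld500, slope = 1),
      lower = c(top = -Inf, bottom = -Inf, ld50 = min(doses) / 100,
                slope = 1e-3),
      upper = c(top = Inf, bottom = Inf, ld50 = max(doses) * 100,
                slope = 100),
      control = minpack.lm::nls.lm.control(maxiter = maxIter)),
    error = function(e)
      stop("LD50 fit failed to converge: ", conditionMessage(e),
           " (doses ", paste(range(doses), collapse = "-"),
           ", response range ",
           paste(sprintf("%.3g", range(responses)), collapse = "-"), ")",
           call. = FALSE))
  cf <- stats::coef(fit)
  structure(list(
    ld50 = unname(cf[["ld50"]]),
    top = unname(cf[["top"]]),
    bottom = unname(cf[["bottom"]]),
    slope = unname(cf[["slope"]]),
    rss = sum(stats::residuals(fit)^2),
    fitted = stats::fitted(fit),
    converged = TRUE), class = "ld50Fit")
}

#' @export
print.ld50Fit <- function(x, ...) {
  cat(sprintf(
    "4PL dose-response fit: LD50 = %.4g (top %.3g, bottom %.3g, slope %.3g, RSS %.3g)\n",
    x$ld50, x$top, x$bottom, x$slope, x$rss))
  invisible(x)
}
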