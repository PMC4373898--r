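#' Normalise a biosynthesis-inhibition cytometry readout
#'
#' Converts raw GFP fluorescence totals to percent of the DMSO control.
#' The untransfected-cell background is subtracted from every channel,
#' and the (background-corrected) cycloheximide value — protein already
#' present when treatment started — is subtracted from both the treated
#' and the control signal:
#' `100 * (treated - bg - (chx - bg)) / (dmso - bg - (chx - bg))`.
#' The result is invariant to adding a constant to all four raw channels.
#'
#' @param treated Raw fluorescence of cotransin-treated cells (vectorised).
#' @param dmso Raw fluorescence of the DMSO (vehicle) control.
#' @param chx Raw fluorescence of the cycloheximide control.
#' @param background Raw fluorescence of untransfected cells.
#' @return Percent of the DMSO control.
#' @examples
#' normalize_readout(600, 1000, 100, 50)  # 55.56
#' @export
normalize_readout <- function(treated, dmso, chx, background = 0) {
  if (any(c(treated, dmso, chx, background) < 0)) {
    stop("raw fluorescence values must be non-negative")
  }
  denom <- (dmso - background) - (chx - background)
  if (any(denom <= 0)) {
    stop("non-positive net DMSO signal; control channels inconsistent")
  }
  100 * ((treated - background) - (chx - background)) / denom
}

#' Sigmoidal concentration-response model
#'
#' Four-parameter logistic inhibition curve:
#' `bottom + (top - bottom) / (1 + (conc / ic50)^hill)`.
#' At `conc = 0` the response is `top`; at `conc = ic50` it is midway
#' between `top` and `bottom`.
#'
#' @param conc Concentration(s), micromolar, >= 0.
#' @param ic50 Half-maximal inhibitory concentration (> 0), micromolar.
#' @param hill Hill slope (> 0).
#' @param top,bottom Response asymptotes in percent (default 100 and 0).
#' @return Response in percent.
#' @export
dose_response <- function(conc, ic50, hill = 1, top = 100, bottom = 0) {
  stopifnot(ic50 > 0, all(conc >= 0), top > bottom)
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit an IC50 to concentration-response data
#'
#' Least-squares fit of the sigmoidal inhibition model with the top
#' asymptote fixed at 100% by default (the data are DMSO-normalised) and
#' the bottom asymptote free in \[0, top) — cotransin inhibition is
#' usually incomplete, so the floor must not be pinned to zero. The IC50
#' is parameterised on the log scale for stability. Degenerate data (no
#' decreasing trend) yield a fit-failure result, not an error.
#'
#' @param data data.frame with columns `concentration` (micromolar, > 0)
#'   and `response` (percent).
#' @param top Fixed top asymptote, or `NA` to fit it.
#' @param bottom Fixed bottom asymptote, or `NA` (default) to fit it.
#' @param hill Fixed Hill slope, or `NA` (default) to fit it.
#' @return An `ic50_fit` list: `converged`, `ic50`, `hill`, `top`,
#'   `bottom`, `se_log_ic50`, `residual_sd`, `n`, `message`, `fit` (the
#'   underlying `nls` object or `NULL`).
#' @examples
#' d <- generate_dose_response(ic50 = 6.5, cv = 0, seed = 1)
#' fit_ic50(d)$ic50
#' @export
fit_ic50 <- function(data, top = 100, bottom = NA, hill = NA) {
  conc <- data$concentration
  y <- data$response
  if (any(conc <= 0)) stop("concentrations must be positive for fitting")
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct concentrations spanning the transition")
  }
  fail <- function(msg) {
    structure(list(converged = FALSE, ic50 = NA_real_, hill = NA_real_,
                   top = top, bottom = bottom, se_log_ic50 = NA_real_,
                   residual_sd = NA_real_, n = length(y), message = msg,
                   fit = NULL),
              class = "ic50_fit")
  }
  # degenerate data: response does not decrease with concentration
  ord <- order(conc)
  means <- tapply(y[ord], conc[ord], mean)
  if (stats::sd(y) < 1e-8 || means[1] - means[length(means)] < 1e-6) {
    return(fail("no concentration-dependent decrease in response"))
  }
  top0 <- if (is.na(top)) max(means) else top
  bot0 <- if (is.na(bottom)) max(0, min(means) * 0.9) else bottom
  mid <- (top0 + bot0) / 2
  ic0 <- unique(conc)[which.min(abs(means - mid))]
  start <- list(log_ic50 = log(ic0))
  lower <- c(log_ic50 = log(min(conc)) - 10)
  upper <- c(log_ic50 = log(max(conc)) + 10)
  if (is.na(hill)) {
    start$hill <- 1
    lower <- c(lower, hill = 0.05)
    upper <- c(upper, hill = 10)
  }
  if (is.na(top)) {
    start$top <- top0
    lower <- c(lower, top = 0)
    upper <- c(upper, top = Inf)
  }
  if (is.na(bottom)) {
    start$bottom <- bot0
    lower <- c(lower, bottom = 0)
    upper <- c(upper, bottom = top0 * 0.999)
  }
  form <- stats::as.formula(paste(
    "y ~", if (is.na(bottom)) "bottom" else deparse(bottom),
    "+ (", if (is.na(top)) "top" else deparse(top),
    "-", if (is.na(bottom)) "bottom" else deparse(bottom),
    ") / (1 + exp(", if (is.na(hill)) "hill" else deparse(hill),
    "* (log(conc) - log_ic50)))"))
  df <- data.frame(conc = conc, y = y)
  fit <- tryCatch(
    stats::nls(form, data = df, start = start, algorithm = "port",
               lower = lower, upper = upper,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))["log_ic50"],
                 error = function(e) NA_real_)
  structure(list(
    converged = TRUE,
    ic50 = unname(exp(cf["log_ic50"])),
    hill = if (is.na(hill)) unname(cf["hill"]) else hill,
    top = if (is.na(top)) unname(cf["top"]) else top,
    bottom = if (is.na(bottom)) unname(cf["bottom"]) else bottom,
    se_log_ic50 = unname(se),
    residual_sd = stats::sigma(fit),
    n = length(y),
    message = "converged",
    fit = fit), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (!x$converged) {
    cat("IC50 fit failed:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("IC50 = %.3g uM (hill %.2f, top %.1f%%, bottom %.1f%%, n = %d)\n",
              x$ic50, x$hill, x$top, x$bottom, x$n))
  invisible(x)
}
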