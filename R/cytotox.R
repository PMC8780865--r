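# LDH cytotoxicity: percent-of-control conversion, four-parameter logistic
# dose-response fitting, ICx inversion, and acute-toxicity classification.

#' Four-parameter logistic dose-response function
#'
#' `f(x) = c + (d - c) / (1 + (x / e)^b)` parameterised on the natural dose
#' scale, so `x = 0` maps exactly to the lower asymptote `c` for `b > 0`
#' (no log transform of dose, hence no trouble with vehicle wells).
#'
#' @param x dose (uM), nonnegative.
#' @param b hill slope; `c` lower asymptote; `d` upper asymptote;
#'   `e` inflection dose (> 0).
#' @param c,d,e see `b`.
#' @return response at `x`; equals `(c + d) / 2` at `x = e` for any slope.
#' @export
four_pl <- function(x, b, c, d, e) {
  # (x/e)^b with the x = 0 limit handled explicitly for any b
  r <- ifelse(x == 0, 0, (x / e)^b)
  c + (d - c) * r / (1 + r)
}

#' Percent cytotoxicity from LDH absorbances
#'
#' `100 * (abs_sample - abs_nc) / (abs_pc - abs_nc)`: 0% at the untreated
#' negative control, 100% at the fully lysed positive control. Values
#' outside `[0, 100]` are possible and preserved.
#'
#' @param abs_sample,abs_nc,abs_pc absorbances (AU); vectors recycle.
#' @return percent cytotoxicity.
#' @export
#' @examples
#' cytotoxicity_percent(0.5, 0.2, 0.8) # 50
cytotoxicity_percent <- function(abs_sample, abs_nc, abs_pc) {
  if (any(abs_pc == abs_nc)) {
    stop("undefined denominator: positive and negative control absorbances are equal")
  }
  100 * (abs_sample - abs_nc) / (abs_pc - abs_nc)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of [four_pl()] by bounded Levenberg-Marquardt.
#' Initialisation: `c0 = min(response)`, `d0 = max(response)`, `e0` the
#' geometric mean of the positive doses, `b0 = 1`; `e` is constrained
#' positive. Degenerate (near-constant) responses return a flagged flat fit
#' rather than an error.
#'
#' @param concentrations doses in uM, >= 0; at least 5 distinct values
#'   including vehicle are recommended.
#' @param responses observed responses (percent cytotoxicity), finite.
#' @return an object of class `dose_response_fit`: list with `b`, `c`, `d`,
#'   `e`, `residual_sd`, `converged`, `flat`, `n`, and the data used.
#' @export
fit_4pl <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (any(!is.finite(responses))) stop("responses must be finite")
  if (any(concentrations < 0)) stop("concentrations must be nonnegative")
  x <- concentrations
  y <- responses
  out <- list(b = NA_real_, c = NA_real_, d = NA_real_, e = NA_real_,
              residual_sd = NA_real_, converged = FALSE, flat = FALSE,
              n = length(y), concentrations = x, responses = y)
  class(out) <- "dose_response_fit"
  if (stats::sd(y) < 1e-12) {
    out$flat <- TRUE
    out$c <- out$d <- mean(y)
    out$residual_sd <- 0
    return(out)
  }
  pos <- x[x > 0]
  start <- list(b = 1, c = min(y), d = max(y), e = geo_mean(pos))
  starts <- list(start,
                 utils::modifyList(start, list(b = 2)),
                 utils::modifyList(start, list(b = 0.5, e = stats::median(pos))),
                 utils::modifyList(start, list(e = max(pos) / 2)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ four_pl(x, b, c, d, e),
        start = s,
        lower = c(b = 1e-3, c = -Inf, d = -Inf, e = 1e-9),
        upper = c(b = 50, c = Inf, d = Inf, e = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(out)
  p <- as.list(stats::coef(best$fit))
  out[c("b", "c", "d", "e")] <- p[c("b", "c", "d", "e")]
  out$residual_sd <- sqrt(best$rss / max(1, out$n - 4))
  out$converged <- TRUE
  if (abs(out$d - out$c) < 1e-8) out$flat <- TRUE
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit: not converged",
        if (x$flat) "(flat response)" else "", "\n")
    return(invisible(x))
  }
  cat(sprintf("4PL fit: b = %.4g, c = %.4g, d = %.4g, e = %.4g uM (residual SD %.3g, n = %d)\n",
              x$b, x$c, x$d, x$e, x$residual_sd, x$n))
  invisible(x)
}

#' Predicted response from a 4PL fit
#' @param object a `dose_response_fit`.
#' @param newdata doses in uM.
#' @param ... unused.
#' @return predicted responses.
#' @export
predict.dose_response_fit <- function(object, newdata, ...) {
  if (!object$converged) stop("fit did not converge; no predictions available")
  four_pl(newdata, object$b, object$c, object$d, object$e)
}

#' Invert a 4PL fit to the dose producing x percent response
#'
#' Analytic inversion `e * ((d - c)/(x - c) - 1)^(-1/b)`; defined for
#' responses strictly between the asymptotes. With `c = 0, d = 100`,
#' `estimate_icx(fit, 50)` equals the inflection dose `e`.
#'
#' @param fit a converged `dose_response_fit`.
#' @param x target response percentage(s), in `(c, d)`.
#' @return dose(s) in uM.
#' @export
estimate_icx <- function(fit, x) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!fit$converged || fit$flat) {
    stop("ICx unavailable: fit not converged or response flat")
  }
  lo <- min(fit$c, fit$d); hi <- max(fit$c, fit$d)
  if (any(x <= lo) || any(x >= hi)) {
    stop(sprintf("target response outside the open asymptote range (%.3g, %.3g)",
                 lo, hi))
  }
  fit$e * ((fit$d - fit$c) / (x - fit$c) - 1)^(-1 / fit$b)
}

#' Classify a chemical's plate as acutely cytotoxic or not
#'
#' Converts sample-well absorbances to percent cytotoxicity against the
#' plate's control means, fits the 4PL, and calls the chemical acutely
#' cytotoxic when the dose-response fit beats a constant-mean model
#' (extra-sum-of-squares F-test, `p < f_alpha`) and the fitted maximal
#' response reaches `min_response` percent.
#'
#' @param plate data.frame of wells for one chemical with columns
#'   `concentration_uM`, `role` (`sample`/`NC`/`PC`) and `absorbance`.
#' @param f_alpha F-test significance level (default 0.05).
#' @param min_response minimal fitted maximal response, percent (default 10).
#' @param icx response levels at which to invert the curve (default 10, 50).
#' @return list with `chemical` (if present), `cytotoxic` flag, `fit`,
#'   `f_pvalue`, `max_response`, and an `icx` table (NA when unavailable).
#' @export
classify_acute <- function(plate, f_alpha = 0.05, min_response = 10,
                           icx = c(10, 50)) {
  need <- c("concentration_uM", "role", "absorbance")
  if (!all(need %in% names(plate))) {
    stop("plate needs columns concentration_uM, role, absorbance")
  }
  nc <- plate$absorbance[plate$role == "NC"]
  pc <- plate$absorbance[plate$role == "PC"]
  if (length(nc) == 0 || length(pc) == 0) stop("missing NC or PC control wells")
  smp <- plate[plate$role == "sample", , drop = FALSE]
  cyto <- cytotoxicity_percent(smp$absorbance, mean(nc), mean(pc))
  fit <- fit_4pl(smp$concentration_uM, cyto)
  n <- length(cyto)
  rss0 <- sum((cyto - mean(cyto))^2)
  f_p <- NA_real_
  max_resp <- NA_real_
  if (fit$converged && !fit$flat && n > 4) {
    rss1 <- fit$residual_sd^2 * (n - 4)
    fstat <- ((rss0 - rss1) / 3) / (rss1 / (n - 4))
    f_p <- stats::pf(fstat, 3, n - 4, lower.tail = FALSE)
    # largest fitted response over the tested dose range, relative to vehicle
    rng <- range(smp$concentration_uM)
    pred <- stats::predict(fit, seq(rng[1], rng[2], length.out = 200))
    max_resp <- max(pred) - pred[1]
  }
  cytotoxic <- isTRUE(!is.na(f_p) && f_p < f_alpha && max_resp >= min_response)
  icx_tab <- data.frame(x = icx, concentration_uM = NA_real_)
  if (cytotoxic) {
    for (i in seq_along(icx)) {
      icx_tab$concentration_uM[i] <- tryCatch(estimate_icx(fit, icx[i]),
                                              error = function(e) NA_real_)
    }
  }
  list(chemical = if ("chemical" %in% names(plate)) plate$chemical[1] else NA,
       cytotoxic = cytotoxic, fit = fit, f_pvalue = f_p,
       max_response = max_resp, icx = icx_tab)
}

#' Analyze a multi-chemical LDH plate panel
#'
#' Runs [classify_acute()] per chemical and returns one summary row each.
#'
#' @param plates data.frame of wells with a `chemical` column (as written by
#'   [generate_plate()] / [simulate_plate_panel()]).
#' @param ... passed to [classify_acute()].
#' @return list with `summary` (data.frame: chemical, cytotoxic, f_pvalue,
#'   max_response, ic10, ic50) and `fits` (named list of per-chemical
#'   classification results).
#' @export
analyze_plates <- function(plates, ...) {
  chems <- unique(plates$chemical)
  fits <- lapply(chems, function(ch) {
    classify_acute(plates[plates$chemical == ch, , drop = FALSE], ...)
  })
  names(fits) <- chems
  summary <- data.frame(
    chemical = chems,
    cytotoxic = vapply(fits, `[[`, logical(1), "cytotoxic"),
    f_pvalue = vapply(fits, `[[`, numeric(1), "f_pvalue"),
    max_response = vapply(fits, `[[`, numeric(1), "max_response"),
    ic10 = vapply(fits, function(f)
      f$icx$concentration_uM[match(10, f$icx$x)] %||% NA_real_, numeric(1)),
    ic50 = vapply(fits, function(f)
      f$icx$concentration_uM[match(50, f$icx$x)] %||% NA_real_, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(summary = summary, fits = fits)
}
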