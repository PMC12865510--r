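#' Regress the standardised MSLIP on log fragment area
#'
#' Fits `SES = beta0 + beta1 * (ln area - center) + beta2 * res`
#' (optionally plus a quadratic ln-area term `beta3`) by ordinary least
#' squares with normal errors.  Fragments with undefined SES are dropped
#' with a logged count.  The ln-area axis is centred (by default at the
#' mean ln area of the rows used, mirroring the common plotting convention
#' of placing the landscape's mean fragment area at x = 0); the fitted
#' values and the derived A_USR are invariant to the centering constant.
#'
#' @param table a data frame holding at least `area_ha` and `ses`
#'   (typically a `mslip_table` merged with [residual_richness()] output
#'   providing `res`).  A missing `res` column is treated as all-zero.
#' @param quadratic add a quadratic ln-area term (the two-crossings model).
#' @param center centering constant on the ln-area scale; default
#'   `mean(log(area_ha))` of the rows used.
#' @return A `mslip_area_fit`: coefficients `beta0`--`beta3`, covariance
#'   matrix `vcov`, 95% t-interval `ci95_beta1`, `n_used`, `n_dropped`,
#'   `center`, `quadratic`, the underlying `lm` object and the model data.
#' @export
fit_mslip_area <- function(table, quadratic = FALSE, center = NULL) {
  stopifnot(is.data.frame(table),
            all(c("area_ha", "ses") %in% names(table)))
  res <- if ("res" %in% names(table)) table$res else rep(0, nrow(table))
  keep <- is.finite(table$ses) & is.finite(table$area_ha) & is.finite(res)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " fragment(s) with undefined SES dropped from the fit")
  }
  need <- if (quadratic) 5L else 4L
  if (sum(keep) < need) {
    stop("need at least ", need, " fragments with defined SES")
  }
  d <- data.frame(ses = table$ses[keep],
                  area_ha = table$area_ha[keep],
                  res = res[keep])
  if (is.null(center)) center <- mean(log(d$area_ha))
  d$x <- log(d$area_ha) - center

  use_res <- stats::sd(d$res) > 0
  if (!use_res) {
    message("res is constant; beta2 fixed at 0")
  }
  form <- if (quadratic) {
    if (use_res) ses ~ x + res + I(x^2) else ses ~ x + I(x^2)
  } else {
    if (use_res) ses ~ x + res else ses ~ x
  }
  fit <- stats::lm(form, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("collinear predictors in MSLIP-area design matrix")
  muffle_perfect <- .muffle_perfect_fit

  beta0 <- unname(cf["(Intercept)"])
  beta1 <- unname(cf["x"])
  beta2 <- if (use_res) unname(cf["res"]) else 0
  beta3 <- if (quadratic) unname(cf["I(x^2)"]) else NA_real_
  ci <- muffle_perfect(stats::confint(fit, "x", level = 0.95))

  sm <- muffle_perfect(summary(fit))
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 vcov = muffle_perfect(stats::vcov(fit)),
                 ci95_beta1 = unname(ci[1, ]),
                 n_used = nrow(d), n_dropped = n_dropped,
                 center = center, quadratic = quadratic,
                 sigma = sm$sigma,
                 r_squared = sm$r.squared,
                 lm = fit, data = d),
            class = "mslip_area_fit")
}

#' @export
print.mslip_area_fit <- function(x, ...) {
  cat("MSLIP_SES ~ ln(area) regression (center =",
      format(x$center, digits = 4), ")\n")
  cat(sprintf("  beta0 = %.4g, beta1 = %.4g [%.4g, %.4g], beta2 = %.4g",
              x$beta0, x$beta1, x$ci95_beta1[1], x$ci95_beta1[2], x$beta2))
  if (x$quadratic) cat(sprintf(", beta3 = %.4g", x$beta3))
  cat(sprintf("\n  n = %d (%d dropped), R^2 = %.3f\n",
              x$n_used, x$n_dropped, x$r_squared))
  invisible(x)
}

# zero-crossings (in ha) of the fitted SES-area relation at res = 0
.fit_crossings <- function(fit) {
  b0 <- fit$beta0; b1 <- fit$beta1; b3 <- fit$beta3
  if (fit$quadratic && is.finite(b3) && b3 != 0) {
    disc <- b1^2 - 4 * b0 * b3
    if (disc < 0) return(list(crossings = numeric(0), primary = NA_real_))
    roots <- sort((-b1 + c(-1, 1) * sqrt(disc)) / (2 * b3))
    cross <- exp(fit$center + roots)
    # primary threshold = descending crossing (SES decreasing through 0)
    deriv <- 2 * b3 * roots + b1
    desc <- which(deriv < 0)
    primary <- if (length(desc)) cross[desc[1]] else cross[1]
    list(crossings = cross, primary = primary)
  } else {
    if (b1 == 0) return(list(crossings = numeric(0), primary = NA_real_))
    cross <- exp(fit$center - b0 / b1)
    list(crossings = cross, primary = cross)
  }
}

#' Area for unbiased species representation
#'
#' Solves the fitted MSLIP_SES-area relation (at residual richness 0) for
#' the fragment size where it crosses zero.  For the linear model this is
#' `exp(center - beta0/beta1)`; the quadratic model can yield zero, one or
#' two crossings, in which case the descending crossing (SES falling
#' through zero with increasing area) is reported as the threshold.  A
#' non-crossing fit is a reported state, not an error.  Uncertainty is
#' available as a nonparametric bootstrap over fragments (percentile
#' interval).
#'
#' @param fit a `mslip_area_fit`.
#' @param areas fragment areas defining the observed range for the
#'   `within_range` flag; defaults to the areas used in the fit.
#' @param bootstrap number of bootstrap resamples over fragments (0 = no
#'   bootstrap; a common choice is 999).
#' @param seed seed for the bootstrap (required when `bootstrap > 0`).
#' @param conf bootstrap interval level (default 0.95).
#' @return An `ausr_estimate`: `ausr_ha` (NA when undefined),
#'   `crossings`, `within_range`, `slope_sign` (`"negative"`,
#'   `"positive"`, or `"near_zero"` when the 95% CI of beta1 spans 0),
#'   and optionally `ci` with the bootstrap percentile interval.
#' @export
estimate_ausr <- function(fit, areas = NULL, bootstrap = 0, seed = NULL,
                          conf = 0.95) {
  stopifnot(inherits(fit, "mslip_area_fit"))
  if (is.null(areas)) areas <- fit$data$area_ha
  cr <- .fit_crossings(fit)
  ausr <- cr$primary
  within <- is.finite(ausr) && ausr >= min(areas) && ausr <= max(areas)
  slope_sign <- if (fit$ci95_beta1[1] <= 0 && fit$ci95_beta1[2] >= 0) {
    "near_zero"
  } else if (fit$beta1 < 0) "negative" else "positive"

  out <- list(ausr_ha = ausr, crossings = cr$crossings,
              within_range = within, slope_sign = slope_sign,
              beta1 = fit$beta1, area_range = range(areas))
  if (bootstrap > 0) {
    if (is.null(seed)) stop("seed required for the bootstrap")
    d <- fit$data
    boots <- withr::with_seed(seed, {
      vapply(seq_len(bootstrap), function(b) {
        idx <- sample.int(nrow(d), replace = TRUE)
        bf <- tryCatch(
          suppressMessages(fit_mslip_area(d[idx, , drop = FALSE],
                                          quadratic = fit$quadratic,
                                          center = fit$center)),
          error = function(e) NULL)
        if (is.null(bf)) NA_real_ else .fit_crossings(bf)$primary
      }, numeric(1))
    })
    fin <- boots[is.finite(boots)]
    a <- (1 - conf) / 2
    out$ci <- if (length(fin) >= 2) {
      unname(stats::quantile(fin, c(a, 1 - a)))
    } else c(NA_real_, NA_real_)
    out$boot_prop_defined <- length(fin) / bootstrap
    out$bootstrap <- bootstrap
  }
  class(out) <- "ausr_estimate"
  out
}

#' @export
print.ausr_estimate <- function(x, ...) {
  if (is.finite(x$ausr_ha)) {
    cat(sprintf("A_USR = %.4g ha (%s observed area range [%.4g, %.4g] ha)\n",
                x$ausr_ha, if (x$within_range) "within" else "outside",
                x$area_range[1], x$area_range[2]))
  } else {
    cat("A_USR undefined: fitted relation does not cross zero\n")
  }
  if (length(x$crossings) > 1) {
    cat("  crossings [ha]:", paste(format(x$crossings, digits = 4),
                                   collapse = ", "), "\n")
  }
  cat("  area slope sign:", x$slope_sign, "\n")
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap CI: [%.4g, %.4g] (%.0f%% of %d resamples defined)\n",
                x$ci[1], x$ci[2], 100 * x$boot_prop_defined, x$bootstrap))
  }
  invisible(x)
}

#' Classify fragments as small or large relative to A_USR
#'
#' Fragments strictly smaller than the threshold are `"small"`, fragments
#' at or above it `"large"` (boundary convention: a fragment exactly at
#' A_USR already achieves unbiased representation).  When the threshold is
#' undefined every fragment is `"unclassified"`.
#'
#' @param areas fragment areas in hectares.
#' @param ausr an `ausr_estimate` or a single numeric threshold.
#' @return Character vector of labels.
#' @export
classify_fragments <- function(areas, ausr) {
  thr <- if (inherits(ausr, "ausr_estimate")) ausr$ausr_ha else as.numeric(ausr)
  if (!is.finite(thr)) return(rep("unclassified", length(areas)))
  ifelse(areas < thr, "small", "large")
}
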