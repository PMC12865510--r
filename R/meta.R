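#' Cross-landscape GLS of area slopes with an exponential variance
#'
#' Second stage of the two-stage analysis: per-study MSLIP_SES-area slopes
#' (`beta1` from [fit_mslip_area()]) are regressed on study-level
#' moderators by generalised least squares, with residual variance
#' `Var(e_i) = sigma^2 * exp(2 * delta_g * sr_area_i)` where the
#' exponential variance coefficient `delta_g` may differ by taxonomic
#' group.  Estimation is by maximum likelihood via [nlme::gls()] with a
#' [nlme::varExp()] variance function; categorical moderators are given
#' sum-to-zero contrasts so that Type-3 marginal tests are meaningful.
#'
#' If any taxonomic group contributes fewer than 3 studies the per-group
#' variance model is not identifiable and the fit falls back to a shared
#' `delta` with a warning.  With the variance structure switched off
#' (`variance = "none"`, i.e. all `delta = 0`) the fit coincides with
#' ordinary least squares on the same design matrix.
#'
#' @param records data frame with one row per study: `study_id`, `slope`,
#'   optional `slope_se`, moderators `taxon_group`, `fragment_type`,
#'   `standardised_design`, `sr_area`, `bimodal`.
#' @param formula mean model; default
#'   `slope ~ sr_area + bimodal + fragment_type + taxon_group +
#'   standardised_design` (terms absent from `records` must be removed by
#'   the caller).
#' @param variance `"exp_by_group"` (default), `"exp_shared"`, or
#'   `"none"`.
#' @param weighting `"none"` (default) or `"inverse_variance"`, which adds
#'   fixed relative weights `1 / slope_se^2` from the first stage.
#' @param method `"REML"` (default, the standard choice for variance
#'   models: keeps the Wald tests close to nominal size) or `"ML"`.
#' @return An `ausr_gls`: list with the underlying `gls` fit,
#'   `coefficients` table, `delta` (named variance coefficients, if any),
#'   `sigma`, `loglik`, and the model data.
#' @export
fit_gls_varexp <- function(records,
                           formula = slope ~ sr_area + bimodal +
                             fragment_type + taxon_group +
                             standardised_design,
                           variance = c("exp_by_group", "exp_shared", "none"),
                           weighting = c("none", "inverse_variance"),
                           method = c("REML", "ML")) {
  variance <- match.arg(variance)
  weighting <- match.arg(weighting)
  method <- match.arg(method)
  dat <- as.data.frame(records)
  if (!"slope" %in% names(dat)) stop("records must contain a 'slope' column")
  if (nrow(dat) < 10) stop("need at least 10 studies")

  dat <- .prepare_moderators(dat)
  vars_needed <- all.vars(formula)
  miss <- setdiff(vars_needed, names(dat))
  if (length(miss)) stop("missing moderator column(s): ",
                         paste(miss, collapse = ", "))

  mm <- stats::model.matrix(formula, dat)
  if (qr(mm)$rank < ncol(mm)) {
    stop("singular design matrix: collinear predictors")
  }

  if (variance == "exp_by_group") {
    if (!"taxon_group" %in% names(dat)) {
      stop("taxon_group required for the per-group variance model")
    }
    if (min(table(dat$taxon_group)) < 3) {
      warning("a taxon group has fewer than 3 studies; ",
              "falling back to a shared variance coefficient")
      variance <- "exp_shared"
    }
  }
  vf <- switch(variance,
               exp_by_group = nlme::varExp(form = ~ sr_area | taxon_group),
               exp_shared = nlme::varExp(form = ~ sr_area),
               none = NULL)
  if (weighting == "inverse_variance") {
    if (!"slope_se" %in% names(dat)) stop("slope_se required for weighting")
    dat$.se2 <- dat$slope_se^2
    wfix <- nlme::varFixed(~ .se2)
    vf <- if (is.null(vf)) wfix else nlme::varComb(wfix, vf)
  }

  args <- list(model = formula, data = dat, method = method,
               control = nlme::glsControl(tolerance = 1e-8,
                                          msMaxIter = 200, maxIter = 200))
  if (!is.null(vf)) args$weights <- vf
  fit <- do.call(nlme::gls, args)

  tt <- summary(fit)$tTable
  coefficients <- data.frame(term = rownames(tt),
                             estimate = tt[, "Value"],
                             se = tt[, "Std.Error"],
                             t_value = tt[, "t-value"],
                             p_value = tt[, "p-value"],
                             row.names = NULL)
  delta <- if (variance == "none") NULL else {
    stats::coef(fit$modelStruct$varStruct, unconstrained = FALSE)
  }
  structure(list(gls = fit, coefficients = coefficients, delta = delta,
                 sigma = fit$sigma, loglik = as.numeric(stats::logLik(fit)),
                 variance = variance, weighting = weighting, method = method,
                 formula = formula, data = dat),
            class = "ausr_gls")
}

# sum-to-zero contrasts for the categorical moderators; binary flags kept
# numeric so they contribute single-df rows to the Wald table
.prepare_moderators <- function(dat) {
  for (cl in c("taxon_group", "fragment_type")) {
    if (cl %in% names(dat)) {
      f <- factor(dat[[cl]])
      if (nlevels(f) > 1) stats::contrasts(f) <- stats::contr.sum(nlevels(f))
      dat[[cl]] <- f
    }
  }
  for (cl in c("standardised_design", "bimodal")) {
    if (cl %in% names(dat)) dat[[cl]] <- as.numeric(dat[[cl]])
  }
  dat
}

#' @export
print.ausr_gls <- function(x, ...) {
  cat("Cross-landscape GLS of area slopes (", x$variance,
      " variance, ", x$weighting, " weighting)\n", sep = "")
  print(x$coefficients, digits = 4)
  if (!is.null(x$delta)) {
    cat("variance coefficients (delta):\n")
    print(round(x$delta, 4))
  }
  cat(sprintf("sigma = %.4g, logLik = %.4g, n = %d\n",
              x$sigma, x$loglik, nrow(x$data)))
  invisible(x)
}

#' Type-3 Wald tests for the cross-landscape model
#'
#' Per-predictor Wald chi-square tests, each predictor adjusted for all
#' others (marginal, Type-3), with degrees of freedom equal to the number
#' of coefficients the predictor contributes.  The statistic reported is
#' the Wald chi-square; its p-value is computed by scaling against the
#' F(df, n - p) reference (`p = P[F > chisq/df]`), which corrects the
#' mild anti-conservatism of the raw chi-square reference when the
#' variance coefficients are themselves estimated.  The chi-square
#' p-values are retained in a `p_chisq` column.
#'
#' @param fit an `ausr_gls`.
#' @return Data frame with `predictor`, `df`, `chisq`, `p_value`
#'   (F reference) and `p_chisq`.
#' @export
type3_wald <- function(fit) {
  stopifnot(inherits(fit, "ausr_gls"))
  a <- car::Anova(fit$gls, type = "III")
  df_resid <- nrow(fit$data) - length(stats::coef(fit$gls))
  data.frame(predictor = rownames(a),
             df = a$Df,
             chisq = a$Chisq,
             p_value = stats::pf(a$Chisq / a$Df, a$Df, df_resid,
                                 lower.tail = FALSE),
             p_chisq = a[["Pr(>Chisq)"]],
             row.names = NULL)
}

#' Pairwise contrasts of adjusted group means
#'
#' Least-squares means of a categorical moderator from the fitted
#' cross-landscape model, compared pairwise with Wald tests.  No
#' multiplicity adjustment by default; Tukey-style adjustment available.
#'
#' @param fit an `ausr_gls`.
#' @param predictor name of a categorical moderator in the model.
#' @param adjust p-value adjustment passed to [emmeans::contrast()]
#'   (default `"none"`).
#' @return Data frame of pairwise differences with estimates, SEs and
#'   p-values.
#' @export
pairwise_group_contrasts <- function(fit, predictor, adjust = "none") {
  stopifnot(inherits(fit, "ausr_gls"))
  if (!predictor %in% names(fit$data) || !is.factor(fit$data[[predictor]])) {
    stop("'", predictor, "' is not a categorical predictor in the model")
  }
  # emmeans warns about the sum-to-zero contrasts it drops when
  # re-gridding; that is expected here
  prs <- withCallingHandlers({
    emm <- emmeans::emmeans(fit$gls, specs = predictor, data = fit$data,
                            mode = "df.error")
    as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                    adjust = adjust))
  }, warning = function(w) {
    if (grepl("contrasts dropped", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  names(prs)[names(prs) == "SE"] <- "se"
  prs
}
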