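`%||%` <- function(a, b) if (is.null(a)) b else a

# noiseless or tiny exact fits trigger an uninformative lm warning
.muffle_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

#' End-to-end A_USR workflow on one study system
#'
#' Runs validate -> incidence -> MSLIP_SES -> ISAR/residual richness ->
#' SES-area regression -> A_USR -> small/large classification -> ranked
#' occupancy curve, and writes every result to `output_dir` (CSV for
#' tables, JSON for fits).  An undefined A_USR is a reported state, not a
#' failure.  All randomness flows from the single `seed` (the resampling
#' null uses `seed`, the bootstrap `seed + 1`), so reruns with identical
#' inputs reproduce every number.
#'
#' @param matrix_path,metadata_path input CSVs (see [read_dataset()]);
#'   ignored when `dataset` is supplied.
#' @param output_dir directory for the result bundle (created if needed).
#' @param dataset optionally an in-memory `occurrence_dataset`.
#' @param n_draws resampling draws for the null (default 1000).
#' @param seed integer seed (required).
#' @param quadratic include the quadratic ln-area term.
#' @param survey_design override the metadata survey design.
#' @param bootstrap bootstrap resamples for the A_USR interval (0 = none).
#' @param drop_empty_fragments passed to [validate_and_clean()].
#' @return Invisibly, a list with `dataset`, `mslip_table`, `isar`,
#'   `residuals`, `fit`, `ausr`, `classification`, `rsoc`, `sr_area`,
#'   `report`, `files`.
#' @export
run_ausr <- function(matrix_path = NULL, metadata_path = NULL, output_dir,
                     dataset = NULL, n_draws = 1000, seed,
                     quadratic = FALSE, survey_design = NULL,
                     bootstrap = 0, drop_empty_fragments = FALSE) {
  if (missing(seed)) stop("seed is required")
  if (is.null(dataset)) {
    if (is.null(matrix_path) || is.null(metadata_path)) {
      stop("either 'dataset' or both input paths must be given")
    }
    dataset <- read_dataset(matrix_path, metadata_path)
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  vc <- validate_and_clean(dataset, drop_empty_fragments = drop_empty_fragments)
  ds <- vc$dataset
  design <- survey_design %||% ds$meta$survey_design[1]

  tbl <- compute_mslip_ses(ds, n_draws = n_draws, seed = seed)
  isar <- fit_isar(tbl$area_ha, tbl$richness, design = design)
  rr <- residual_richness(isar, tbl$area_ha, tbl$richness)
  tbl$res <- rr$res
  fit <- fit_mslip_area(tbl, quadratic = quadratic)
  ausr <- estimate_ausr(fit, areas = tbl$area_ha, bootstrap = bootstrap,
                        seed = seed + 1L)
  labels <- classify_fragments(tbl$area_ha, ausr)
  rsoc <- fit_rsoc(compute_incidence(ds))
  sr_area <- tryCatch(sr_area_correlation(isar, rr, tbl$area_ha),
                      error = function(e) NA_real_)

  files <- c(
    mslip_table = file.path(output_dir, "mslip_table.csv"),
    classification = file.path(output_dir, "classification.csv"),
    isar = file.path(output_dir, "isar.json"),
    fit = file.path(output_dir, "mslip_area_fit.json"),
    ausr = file.path(output_dir, "ausr.json"),
    rsoc = file.path(output_dir, "rsoc.json"),
    report = file.path(output_dir, "validation_report.json"),
    run_info = file.path(output_dir, "run_info.json")
  )
  utils::write.csv(as.data.frame(tbl), files["mslip_table"], row.names = FALSE)
  utils::write.csv(data.frame(fragment_id = tbl$fragment_id,
                              area_ha = tbl$area_ha, label = labels),
                   files["classification"], row.names = FALSE)
  .write_json(list(c = isar$c, z = isar$z, r_squared = isar$r_squared,
                   design = isar$design, mean_richness = isar$mean_richness,
                   sr_area = sr_area), files["isar"])
  .write_json(list(beta0 = fit$beta0, beta1 = fit$beta1, beta2 = fit$beta2,
                   beta3 = fit$beta3, ci95_beta1 = fit$ci95_beta1,
                   center = fit$center, n_used = fit$n_used,
                   n_dropped = fit$n_dropped, r_squared = fit$r_squared,
                   quadratic = fit$quadratic), files["fit"])
  .write_json(list(ausr_ha = ausr$ausr_ha, crossings = ausr$crossings,
                   within_range = ausr$within_range,
                   slope_sign = ausr$slope_sign,
                   ci = ausr$ci %||% NULL), files["ausr"])
  .write_json(list(a = rsoc$a, b = rsoc$b, c = rsoc$c,
                   bimodal = rsoc$bimodal, converged = rsoc$converged,
                   rss = rsoc$rss), files["rsoc"])
  .write_json(vc$report, files["report"])
  .write_json(list(package = "ausr",
                   version = as.character(utils::packageVersion("ausr")),
                   seed = seed, n_draws = n_draws, quadratic = quadratic,
                   survey_design = design, bootstrap = bootstrap),
              files["run_info"])

  invisible(list(dataset = ds, mslip_table = tbl, isar = isar,
                 residuals = rr, fit = fit, ausr = ausr,
                 classification = labels, rsoc = rsoc, sr_area = sr_area,
                 report = vc$report, files = files))
}

#' Cross-landscape analysis of a study-slope table
#'
#' Fits the exponential-variance GLS of per-study area slopes on
#' moderators, the Type-3 Wald table, and pairwise group contrasts for
#' each categorical moderator, writing all results to `output_dir`.
#'
#' @param slope_table a study-slope data frame (one row per study; see
#'   [fit_gls_varexp()]) or the path of such a CSV.
#' @param output_dir output directory (created if needed).
#' @param variance,weighting passed to [fit_gls_varexp()].
#' @param contrast_predictors categorical moderators to contrast
#'   pairwise.
#' @return Invisibly, a list with `fit`, `wald`, `contrasts`, `files`.
#' @export
run_meta <- function(slope_table, output_dir,
                     variance = "exp_by_group", weighting = "none",
                     contrast_predictors = c("taxon_group",
                                             "fragment_type")) {
  if (is.character(slope_table)) {
    slope_table <- utils::read.csv(slope_table, stringsAsFactors = FALSE)
  }
  needed <- c("study_id", "slope", "taxon_group", "fragment_type",
              "standardised_design", "sr_area", "bimodal")
  miss <- setdiff(needed, names(slope_table))
  if (length(miss)) {
    stop("slope table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  fit <- fit_gls_varexp(slope_table, variance = variance,
                        weighting = weighting)
  wald <- type3_wald(fit)
  contrasts <- lapply(contrast_predictors, function(p) {
    tryCatch(pairwise_group_contrasts(fit, p), error = function(e) NULL)
  })
  names(contrasts) <- contrast_predictors

  files <- c(coefficients = file.path(output_dir, "gls_coefficients.csv"),
             wald = file.path(output_dir, "wald_table.csv"),
             meta = file.path(output_dir, "meta_fit.json"))
  utils::write.csv(fit$coefficients, files["coefficients"], row.names = FALSE)
  utils::write.csv(wald, files["wald"], row.names = FALSE)
  for (p in contrast_predictors) {
    if (!is.null(contrasts[[p]])) {
      fp <- file.path(output_dir, paste0("contrasts_", p, ".csv"))
      utils::write.csv(contrasts[[p]], fp, row.names = FALSE)
      files[paste0("contrasts_", p)] <- fp
    }
  }
  .write_json(list(variance = fit$variance, weighting = fit$weighting,
                   sigma = fit$sigma, loglik = fit$loglik,
                   delta = as.list(fit$delta %||% list()),
                   n_studies = nrow(fit$data)), files["meta"])

  invisible(list(fit = fit, wald = wald, contrasts = contrasts,
                 files = files))
}
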