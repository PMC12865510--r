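#' Configuration for a synthetic fragmented landscape
#'
#' Defines a generative model with area-dependent species selection: a
#' fraction of the pool are narrow-range "specialists" whose occupancy
#' probability rises with fragment area, the rest are wide-range species
#' occupying fragments independently of size.  Species `s` occupies
#' fragment `i` independently with probability
#' `p_is = plogis(base_logit_s + gamma_s * (ln a_i - mean(ln a)))`,
#' where `gamma_s = gamma_narrow` for specialists and 0 otherwise.
#' Larger fragments therefore accumulate low-incidence specialists, which
#' depresses their geometric-mean incidence and produces the negative
#' SES-area trend whose zero crossing the estimators target.
#'
#' Defaults describe a mid-sized, species-rich fragmentation study: 100
#' fragments with log-normal areas centred at 8.7 ha, a pool of 250
#' species half of which are specialists with a moderate area affinity.
#' Under these defaults the expected SES declines monotonically with
#' ln-area and crosses zero inside the sampled area range, so the
#' configuration carries a well-defined generative A_USR.
#'
#' @param n_fragments number of fragments (>= 2).
#' @param n_species size of the species pool (>= 2).
#' @param area_logmean,area_logsd log-normal area parameters (ln ha).
#' @param specialism_mix fraction of narrow-range species in `[0, 1]`.
#' @param gamma_narrow area affinity of narrow-range species (>= 0; 0
#'   removes all area dependence).
#' @param base_logit_narrow,base_logit_wide baseline occupancy logits at
#'   the mean ln-area.
#' @param seed integer seed (required).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_fragments = 100, n_species = 250,
                             area_logmean = log(8.7), area_logsd = 0.8,
                             specialism_mix = 0.5, gamma_narrow = 0.5,
                             base_logit_narrow = -0.25, base_logit_wide = 0,
                             seed) {
  if (n_fragments < 2) stop("degenerate config: n_fragments < 2")
  if (n_species < 2) stop("degenerate config: n_species < 2")
  if (specialism_mix < 0 || specialism_mix > 1) {
    stop("specialism_mix must lie in [0, 1]")
  }
  if (gamma_narrow < 0) stop("gamma_narrow must be >= 0")
  if (area_logsd <= 0) stop("area_logsd must be > 0")
  if (missing(seed)) stop("seed is required")
  structure(list(n_fragments = as.integer(n_fragments),
                 n_species = as.integer(n_species),
                 area_logmean = area_logmean, area_logsd = area_logsd,
                 specialism_mix = specialism_mix,
                 gamma_narrow = gamma_narrow,
                 base_logit_narrow = base_logit_narrow,
                 base_logit_wide = base_logit_wide,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# species-level generative parameters; narrow-range species first
.species_params <- function(cfg) {
  n_narrow <- round(cfg$specialism_mix * cfg$n_species)
  narrow <- seq_len(cfg$n_species) <= n_narrow
  list(narrow = narrow,
       base = ifelse(narrow, cfg$base_logit_narrow, cfg$base_logit_wide),
       gamma = ifelse(narrow, cfg$gamma_narrow, 0))
}

# occupancy probability matrix (fragments x species) given areas;
# ln-area centred at the realised mean, per the generative definition
.occupancy_probs <- function(cfg, areas, center = mean(log(areas))) {
  sp <- .species_params(cfg)
  x <- log(areas) - center
  stats::plogis(outer(x, sp$gamma) +
                  matrix(sp$base, nrow = length(areas),
                         ncol = cfg$n_species, byrow = TRUE))
}

#' Simulate a fragmented-landscape occurrence dataset
#'
#' Draws fragment areas from the configured log-normal, then independent
#' Bernoulli occupancies from the area-dependent probabilities of
#' [synthetic_config()].  Species that end up observed nowhere are dropped
#' with a logged count (their incidence would be undefined); the generative
#' truth (per-species class, areas, number dropped) is attached as the
#' `"truth"` attribute.
#'
#' @param cfg a `synthetic_config`.
#' @return An `occurrence_dataset`; reproducible for a fixed seed.
#' @export
simulate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  sp <- .species_params(cfg)
  out <- withr::with_seed(cfg$seed, {
    areas <- stats::rlnorm(cfg$n_fragments, cfg$area_logmean, cfg$area_logsd)
    p <- .occupancy_probs(cfg, areas)
    m <- matrix(as.integer(stats::runif(length(p)) < p),
                nrow = cfg$n_fragments)
    list(areas = areas, m = m)
  })
  m <- out$m
  dimnames(m) <- list(sprintf("f%04d", seq_len(cfg$n_fragments)),
                      sprintf("sp%04d", seq_len(cfg$n_species)))
  keep <- colSums(m) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " species with zero presences dropped from the ",
            "simulated landscape")
  }
  meta <- data.frame(fragment_id = rownames(m),
                     area_ha = out$areas,
                     survey_design = "effort_controlled",
                     stringsAsFactors = FALSE)
  ds <- occurrence_dataset(m[, keep, drop = FALSE], meta)
  attr(ds, "truth") <- list(narrow = sp$narrow[keep],
                            n_species_dropped = n_dropped,
                            config = cfg)
  ds
}

#' Expected SES as a function of fragment area (simulation oracle)
#'
#' Brute-force expectation of the standardised effect size for a fragment
#' of given area embedded in the configured landscape: for each replicate
#' a fresh landscape is simulated, a focal fragment is drawn at every grid
#' area from its occupancy probabilities, and its SES is computed against
#' the landscape's incidence pool using the exact moments of the
#' resampling null (closed form in the pool; no Monte-Carlo draws).  The
#' averaged curve and its zero crossing define the generative ground-truth
#' A_USR of the configuration, independently of the estimation pipeline.
#'
#' @param cfg a `synthetic_config`.
#' @param area_grid areas (ha) at which to evaluate the curve; default 21
#'   log-spaced points spanning +/- 2 area-log-SDs around the median area.
#' @param n_rep number of simulation replicates (default 2000; < 100
#'   triggers a warning).
#' @param seed integer seed; defaults to `cfg$seed + 1`.
#' @return A `ses_curve`: list with `area_grid`, `expected_ses`,
#'   `crossing_ha` (first descending zero crossing, NA if none),
#'   `crossings` (all sign changes), `n_rep`.
#' @export
expected_ses_curve <- function(cfg, area_grid = NULL, n_rep = 2000,
                               seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (n_rep < 100) warning("n_rep < 100: expected-SES curve will be noisy")
  if (is.null(area_grid)) {
    area_grid <- exp(seq(cfg$area_logmean - 2 * cfg$area_logsd,
                         cfg$area_logmean + 2 * cfg$area_logsd,
                         length.out = 21))
  }
  sp <- .species_params(cfg)
  ng <- length(area_grid)
  acc <- numeric(ng)
  cnt <- integer(ng)

  withr::with_seed(seed, {
    for (r in seq_len(n_rep)) {
      # focal fragment is embedded in the landscape: n_fragments - 1
      # background fragments plus the focal, whose presences count toward
      # the incidences exactly as in the estimation path
      nb <- cfg$n_fragments - 1L
      areas <- stats::rlnorm(nb, cfg$area_logmean, cfg$area_logsd)
      center <- mean(log(areas))
      p <- .occupancy_probs(cfg, areas, center)
      m <- matrix(stats::runif(length(p)) < p, nrow = nb)
      bg_counts <- colSums(m)

      xg <- log(area_grid) - center
      pf <- stats::plogis(outer(xg, sp$gamma) +
                            matrix(sp$base, nrow = ng, ncol = cfg$n_species,
                                   byrow = TRUE))
      occ <- matrix(stats::runif(length(pf)) < pf, nrow = ng)
      for (g in seq_len(ng)) {
        counts <- bg_counts + occ[g, ]
        obs <- counts > 0L
        if (!any(obs)) next
        pool <- counts[obs] / cfg$n_fragments
        res <- pool[occ[g, obs]]
        k <- length(res)
        if (k == 0) next
        mom <- .null_moments_exact(k, pool)
        if (mom$null_sd == 0) next
        acc[g] <- acc[g] + (exp(mean(log(res))) - mom$null_mean) / mom$null_sd
        cnt[g] <- cnt[g] + 1L
      }
    }
  })

  ses <- ifelse(cnt > 0, acc / cnt, NA_real_)
  cross <- .curve_crossings(area_grid, ses)
  structure(list(area_grid = area_grid, expected_ses = ses,
                 crossing_ha = cross$primary, crossings = cross$all,
                 n_rep = n_rep, seed = seed),
            class = "ses_curve")
}

# zero crossings of a tabulated curve in ln-area; primary = first
# descending (positive-to-negative) crossing, located by a local linear
# fit over the grid points around the sign change (averages out
# Monte-Carlo noise in the tabulated values)
.curve_crossings <- function(areas, ses) {
  la <- log(areas)
  all_cross <- numeric(0)
  primary <- NA_real_
  for (i in seq_len(length(ses) - 1)) {
    s1 <- ses[i]; s2 <- ses[i + 1]
    if (!is.finite(s1) || !is.finite(s2)) next
    if (s1 == 0) s1 <- .Machine$double.eps
    if (sign(s1) != sign(s2)) {
      lx <- la[i] + (0 - s1) * (la[i + 1] - la[i]) / (s2 - s1)
      all_cross <- c(all_cross, exp(lx))
      if (s1 > 0 && s2 < 0 && !is.finite(primary)) {
        win <- max(1, i - 2):min(length(ses), i + 3)
        win <- win[is.finite(ses[win])]
        if (length(win) >= 3) {
          cf <- stats::coef(stats::lm(ses[win] ~ la[win]))
          if (is.finite(cf[2]) && cf[2] < 0) lx <- -cf[1] / cf[2]
        }
        primary <- exp(lx)
      }
    }
  }
  list(all = all_cross, primary = primary)
}

#' @export
print.ses_curve <- function(x, ...) {
  cat("Expected SES curve over", length(x$area_grid), "areas,",
      x$n_rep, "replicates\n")
  if (is.finite(x$crossing_ha)) {
    cat(sprintf("  zero crossing (ground-truth A_USR): %.4g ha\n",
                x$crossing_ha))
  } else {
    cat("  no descending zero crossing on the grid\n")
  }
  invisible(x)
}

#' Simulate a collection of study systems
#'
#' Generates inputs for the cross-landscape stage.  In `"slopes"` mode the
#' per-study area slopes are drawn directly from a known moderator model
#' `slope = intercept + effects + sr_area term + heteroscedastic error`
#' (error SD `sigma * exp(delta_g * sr_area)` by taxonomic group), giving
#' exact ground truth for recovery and calibration tests of
#' [fit_gls_varexp()].  In `"landscapes"` mode full occurrence datasets
#' are simulated, with each study's specialist area-affinity drawn
#' log-normally around the base configuration so that generative slopes
#' are predominantly negative; these feed the end-to-end pipeline.
#'
#' @param n_studies number of study systems (default 30).
#' @param moderator_effects named list overriding any of `intercept`,
#'   `sr_area`, `taxon_group` (named vector), `fragment_type` (named
#'   vector), `standardised_design`, `bimodal`; unspecified effects are 0
#'   (intercept default -1.5).
#' @param seed integer seed (required).
#' @param output `"slopes"` (default) or `"landscapes"`.
#' @param sigma baseline residual SD of slopes (default 0.8).
#' @param delta named per-taxon-group exponential variance coefficients.
#' @param base_config `synthetic_config` template for `"landscapes"` mode
#'   (its seed field is re-drawn per study).
#' @param gamma_logsd between-study spread of the specialist affinity in
#'   `"landscapes"` mode (default 0.3).
#' @return For `"slopes"`: list with `slopes` (a study-slope data frame)
#'   and `true_effects`.  For `"landscapes"`: list with `datasets`,
#'   `moderators`, `configs`.
#' @export
simulate_study_collection <- function(n_studies = 30,
                                      moderator_effects = list(), seed,
                                      output = c("slopes", "landscapes"),
                                      sigma = 0.8,
                                      delta = c(birds = 0.5,
                                                invertebrates = 0.2,
                                                plants = 0,
                                                vertebrates = -0.3),
                                      base_config = NULL,
                                      gamma_logsd = 0.3) {
  output <- match.arg(output)
  if (missing(seed)) stop("seed is required")
  taxa <- c("birds", "invertebrates", "plants", "vertebrates")
  types <- c("forest", "grassland", "island")
  eff <- utils::modifyList(
    list(intercept = -1.5, sr_area = 0,
         taxon_group = stats::setNames(numeric(4), taxa),
         fragment_type = stats::setNames(numeric(3), types),
         standardised_design = 0, bimodal = 0),
    moderator_effects)

  withr::with_seed(seed, {
    tax <- sample(taxa, n_studies, replace = TRUE)
    ft <- sample(types, n_studies, replace = TRUE)
    std <- stats::rbinom(n_studies, 1, 0.5)
    bim <- stats::rbinom(n_studies, 1, 0.5)
    sr_area <- stats::rnorm(n_studies, 0.25, 0.15)

    if (output == "slopes") {
      mu <- eff$intercept + eff$sr_area * sr_area +
        eff$taxon_group[tax] + eff$fragment_type[ft] +
        eff$standardised_design * std + eff$bimodal * bim
      sd_i <- sigma * exp(delta[tax] * sr_area)
      slopes <- data.frame(
        study_id = sprintf("study%03d", seq_len(n_studies)),
        slope = as.numeric(mu + stats::rnorm(n_studies, 0, sd_i)),
        slope_se = stats::runif(n_studies, 0.15, 0.5),
        taxon_group = tax, fragment_type = ft,
        standardised_design = std, sr_area = sr_area, bimodal = bim,
        stringsAsFactors = FALSE)
      list(slopes = slopes, true_effects = eff)
    } else {
      if (is.null(base_config)) {
        base_config <- synthetic_config(n_fragments = 40, n_species = 60,
                                        seed = 1L)
      }
      gammas <- stats::rlnorm(n_studies,
                              log(max(base_config$gamma_narrow, 1e-6)),
                              gamma_logsd)
      study_seeds <- sample.int(.Machine$integer.max - 1L, n_studies)
      datasets <- vector("list", n_studies)
      configs <- vector("list", n_studies)
      for (j in seq_len(n_studies)) {
        cfg_j <- base_config
        cfg_j$gamma_narrow <- gammas[j]
        cfg_j$seed <- study_seeds[j]
        configs[[j]] <- cfg_j
        datasets[[j]] <- suppressMessages(simulate_landscape(cfg_j))
      }
      moderators <- data.frame(
        study_id = sprintf("study%03d", seq_len(n_studies)),
        taxon_group = tax, fragment_type = ft,
        standardised_design = std, bimodal = bim,
        gamma_narrow = gammas, stringsAsFactors = FALSE)
      list(datasets = datasets, moderators = moderators, configs = configs)
    }
  })
}
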