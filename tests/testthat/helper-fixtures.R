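# Small landscapes and independent oracles shared across test files.

# five-fragment worked example: focal fragment f2 holds exactly the three
# species with incidences {1.0, 0.8, 0.6}; richness rises with area and
# the rarer species sit in the larger fragments
demo_matrix <- function() {
  m <- matrix(c(
    1, 1, 0, 0, 0, 0, 0, 0,
    1, 1, 1, 0, 0, 0, 0, 0,
    1, 1, 1, 1, 0, 1, 0, 0,
    1, 1, 1, 1, 1, 0, 1, 0,
    1, 0, 0, 1, 1, 1, 1, 1), nrow = 5, byrow = TRUE)
  dimnames(m) <- list(paste0("f", 1:5), letters[1:8])
  m
}

demo_meta <- function() {
  data.frame(fragment_id = paste0("f", 1:5),
             area_ha = c(1, 5, 12, 40, 150),
             survey_design = "effort_controlled",
             stringsAsFactors = FALSE)
}

demo_dataset <- function() occurrence_dataset(demo_matrix(), demo_meta())

# independent geometric-mean oracle: product-root, no logs
geomean_oracle <- function(x) prod(x)^(1 / length(x))

# exhaustive enumeration of the resampling null: all pool^richness
# equiprobable outcomes (population SD)
enum_null <- function(pool, richness) {
  grids <- do.call(expand.grid, rep(list(pool), richness))
  gm <- apply(as.matrix(grids), 1, geomean_oracle)
  list(mean = mean(gm), sd = sqrt(mean((gm - mean(gm))^2)))
}

# mslip-ses pipeline on a dataset, returning the area fit
fit_from_dataset <- function(ds, n_draws = 500, seed = 1,
                             design = "effort_controlled", ...) {
  tbl <- suppressMessages(compute_mslip_ses(ds, n_draws = n_draws, seed = seed))
  isar <- fit_isar(tbl$area_ha, tbl$richness, design = design)
  tbl$res <- residual_richness(isar, tbl$area_ha, tbl$richness)$res
  suppressMessages(fit_mslip_area(tbl, ...))
}
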