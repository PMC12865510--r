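#' Construct an occurrence dataset
#'
#' Bundles a binary fragment-by-species matrix with per-fragment metadata
#' into the container used by every downstream computation.  Structural
#' invariants (binary cells, unique fragment ids, strictly positive areas,
#' matching row order) are enforced here; species observed in no fragment
#' are permitted at construction and are removed by [validate_and_clean()].
#'
#' @param matrix numeric matrix or data frame of 0/1 presences, fragments
#'   as rows (rownames = fragment ids), species as columns.
#' @param meta data frame with at least `fragment_id` and `area_ha`
#'   columns; optional columns `survey_design`
#'   (`"effort_controlled"` or `"standardised"`), `fragment_type`,
#'   `taxon_group`, `confidence`.
#' @return An object of class `occurrence_dataset`: a list with elements
#'   `matrix` (integer matrix) and `meta` (data frame), rows aligned.
#' @examples
#' m <- matrix(c(1, 1, 0, 1, 1, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("f1", "f2"), c("spA", "spB", "spC")))
#' meta <- data.frame(fragment_id = c("f1", "f2"), area_ha = c(2, 20))
#' occurrence_dataset(m, meta)
#' @export
occurrence_dataset <- function(matrix, meta) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m))) stop("matrix must have fragment ids as rownames")
  if (is.null(colnames(m))) stop("matrix must have species ids as colnames")
  storage.mode(m) <- "double"
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    stop("non-binary entry in presence-absence matrix")
  }
  storage.mode(m) <- "integer"

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("fragment_id", "area_ha") %in% names(meta))) {
    stop("metadata must contain columns 'fragment_id' and 'area_ha'")
  }
  meta$fragment_id <- as.character(meta$fragment_id)
  if (anyDuplicated(meta$fragment_id)) {
    stop("duplicate fragment ids in metadata")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate fragment ids in matrix")
  if (!is.numeric(meta$area_ha) || anyNA(meta$area_ha)) {
    stop("non-numeric area")
  }
  if (any(meta$area_ha <= 0)) stop("non-positive area")
  if (!setequal(rownames(m), meta$fragment_id)) {
    stop("fragment ids of matrix and metadata do not match")
  }
  # reconcile order: metadata follows matrix row order
  meta <- meta[match(rownames(m), meta$fragment_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (is.null(meta$survey_design)) meta$survey_design <- "effort_controlled"
  ok <- meta$survey_design %in% c("effort_controlled", "standardised")
  if (!all(ok)) stop("survey_design must be 'effort_controlled' or 'standardised'")

  structure(list(matrix = m, meta = meta), class = "occurrence_dataset")
}

#' @export
print.occurrence_dataset <- function(x, ...) {
  cat("Occurrence dataset:", nrow(x$matrix), "fragments x",
      ncol(x$matrix), "species\n")
  cat("  area range [ha]:",
      format(min(x$meta$area_ha), digits = 4), "-",
      format(max(x$meta$area_ha), digits = 4), "\n")
  cat("  survey design:", paste(unique(x$meta$survey_design), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a presence-absence matrix and fragment metadata from CSV
#'
#' The matrix file is a wide CSV with fragment ids in the first column and
#' species ids as header; the metadata file has one row per fragment with
#' `fragment_id` and `area_ha` (an `area` column is accepted as a synonym).
#' Fragment order is reconciled by id; ids are always treated as strings.
#'
#' @param matrix_path path to the wide 0/1 matrix CSV.
#' @param metadata_path path to the fragment metadata CSV.
#' @return A validated [occurrence_dataset()].
#' @export
read_dataset <- function(matrix_path, metadata_path) {
  wide <- utils::read.csv(matrix_path, check.names = FALSE,
                          colClasses = c("character"), encoding = "UTF-8")
  if (ncol(wide) < 2) stop("matrix file needs an id column plus species columns")
  ids <- wide[[1]]
  vals <- as.matrix(wide[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) stop("non-binary entry in presence-absence matrix")
  rownames(vals) <- ids

  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  if (!"area_ha" %in% names(meta) && "area" %in% names(meta)) {
    names(meta)[names(meta) == "area"] <- "area_ha"
  }
  if (!"fragment_id" %in% names(meta)) {
    stop("metadata must contain a 'fragment_id' column")
  }
  meta$fragment_id <- as.character(meta$fragment_id)
  if (!is.numeric(meta$area_ha)) stop("non-numeric area")
  missing <- setdiff(ids, meta$fragment_id)
  if (length(missing)) {
    stop("fragment ids missing from metadata: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(meta$fragment_id, ids)
  if (length(extra)) {
    stop("fragment ids missing from matrix: ", paste(extra, collapse = ", "))
  }
  occurrence_dataset(vals, meta)
}

#' Write a dataset back to matrix + metadata CSV files
#'
#' Inverse of [read_dataset()]; a read-write-read round trip reproduces the
#' matrix and metadata exactly.
#'
#' @param ds an `occurrence_dataset`.
#' @param matrix_path,metadata_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(ds, matrix_path, metadata_path) {
  stopifnot(inherits(ds, "occurrence_dataset"))
  wide <- data.frame(fragment_id = rownames(ds$matrix),
                     as.data.frame(ds$matrix), check.names = FALSE)
  utils::write.csv(wide, matrix_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$meta, metadata_path, row.names = FALSE, quote = FALSE)
  invisible(c(matrix_path, metadata_path))
}

#' Convert a long occurrence table to a wide presence-absence matrix
#'
#' Accommodates archive-style long tables (one row per fragment x species
#' record, e.g. pooled quadrat records).  Any listed record counts as a
#' presence unless a `presence` column says otherwise; duplicated records
#' collapse to a single presence.
#'
#' @param long data frame with fragment and species id columns.
#' @param fragment_col,species_col,presence_col column names; if
#'   `presence_col` is `NULL` every row is a presence.
#' @return Binary integer matrix, fragments as rows.
#' @export
long_to_wide <- function(long, fragment_col = "fragment_id",
                         species_col = "species_id", presence_col = NULL) {
  long <- as.data.frame(long)
  for (cl in c(fragment_col, species_col)) {
    if (!cl %in% names(long)) stop("missing column: ", cl)
  }
  f <- as.character(long[[fragment_col]])
  s <- as.character(long[[species_col]])
  if (!is.null(presence_col)) {
    keep <- long[[presence_col]] > 0
    f <- f[keep]
    s <- s[keep]
  }
  tab <- table(factor(f, levels = unique(f)), factor(s, levels = sort(unique(s))))
  m <- unclass(tab)
  m[m > 1] <- 1L
  storage.mode(m) <- "integer"
  dimnames(m) <- list(rownames(tab), colnames(tab))
  m
}

#' Validate and clean an occurrence dataset
#'
#' Drops species observed in no fragment (their landscape-scale incidence
#' would be 0, which is undefined for the geometric mean) and optionally
#' drops fragments containing no species.  Empty fragments retained are
#' flagged: their MSLIP (and hence SES) is undefined.  Cleaning is
#' idempotent.
#'
#' @param ds an `occurrence_dataset`.
#' @param drop_empty_species drop all-zero species columns (default TRUE).
#' @param drop_empty_fragments drop all-zero fragment rows (default FALSE:
#'   retained and flagged).
#' @return List with elements `dataset` (cleaned `occurrence_dataset`) and
#'   `report` (species/fragments dropped or flagged).
#' @export
validate_and_clean <- function(ds, drop_empty_species = TRUE,
                               drop_empty_fragments = FALSE) {
  stopifnot(inherits(ds, "occurrence_dataset"))
  m <- ds$matrix
  meta <- ds$meta

  empty_sp <- colnames(m)[colSums(m) == 0]
  if (length(empty_sp) && drop_empty_species) {
    warning(length(empty_sp), " species with no presences dropped: ",
            paste(empty_sp, collapse = ", "))
    m <- m[, colSums(m) > 0, drop = FALSE]
  }
  if (ncol(m) == 0) stop("dataset empty after cleaning: no species remain")

  empty_fr <- rownames(m)[rowSums(m) == 0]
  flagged <- character(0)
  if (length(empty_fr)) {
    if (drop_empty_fragments) {
      warning(length(empty_fr), " empty fragments dropped: ",
              paste(empty_fr, collapse = ", "))
      keep <- rowSums(m) > 0
      m <- m[keep, , drop = FALSE]
      meta <- meta[keep, , drop = FALSE]
    } else {
      flagged <- empty_fr
      message(length(empty_fr),
              " empty fragment(s) retained; MSLIP undefined for: ",
              paste(empty_fr, collapse = ", "))
    }
  }
  if (nrow(m) == 0) stop("dataset empty after cleaning: no fragments remain")

  report <- list(
    species_dropped = if (drop_empty_species) empty_sp else character(0),
    fragments_dropped = if (drop_empty_fragments) empty_fr else character(0),
    fragments_flagged = flagged
  )
  list(dataset = occurrence_dataset(m, meta), report = report)
}
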