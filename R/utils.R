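#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
NULL

# Shared validation helper: positive finite scalar count.
check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s",
                  name, deparse(substitute(x))))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a number in [%g, %g]", name, lo, hi))
  }
  as.numeric(x)
}

#' Canonicalize compound names
#'
#' Case-folds, trims, collapses internal whitespace and (optionally) maps
#' known synonyms to a single canonical spelling, so that peak-table names
#' and threshold-database names join reliably. The packaged synonym map
#' covers common alias pairs for dry-cured ham volatiles such as
#' "ethyl butyrate" vs "Butanoic acid, ethyl ester" and "valeraldehyde"
#' vs "pentanal".
#'
#' @param x Character vector of compound names.
#' @param synonyms A two-column data frame (`alias`, `canonical`) or `NULL`
#'   to use the packaged map. Pass an empty data frame to disable synonym
#'   resolution.
#' @return Character vector of canonical names (lower case).
#' @export
#' @examples
#' canonical_compound(c("  Hexanal ", "Ethyl   butyrate"))
canonical_compound <- function(x, synonyms = NULL) {
  if (is.null(synonyms)) synonyms <- default_synonyms()
  out <- tolower(trimws(x))
  out <- gsub("\\s+", " ", out)
  # strip spaces the typesetter put after separators inside systematic names
  out <- gsub("\\s*,\\s*", ", ", out)
  if (nrow(synonyms)) {
    key <- tolower(trimws(synonyms$alias))
    hit <- match(out, key)
    out[!is.na(hit)] <- tolower(synonyms$canonical[hit[!is.na(hit)]])
  }
  out
}

default_synonyms <- function() {
  path <- system.file("extdata", "compound_synonyms.csv", package = "aromalip")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Packaged odor-threshold table for dry-cured ham volatiles
#'
#' Returns the packaged table of 28 characteristic volatiles of 3-year
#' dry-cured Diannan small-ear pig ham: odor threshold (ug/kg), chemical
#' class, odor descriptor, and the published relative percentage content and
#' ROAV, which serve as a worked example and regression reference.
#'
#' @param reference Logical; if `TRUE` (default) include the
#'   `relative_content_percent` and `roav_reported` reference columns, else
#'   return only the threshold-database columns.
#' @return A tibble with one row per compound.
#' @export
#' @examples
#' ham_thresholds()[, 1:4]
ham_thresholds <- function(reference = TRUE) {
  path <- system.file("extdata", "ham_characteristic_volatiles.csv",
                      package = "aromalip")
  db <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!reference) {
    db <- db[, c("compound", "threshold_ug_per_kg", "chemical_class",
                 "descriptor")]
  }
  db
}
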