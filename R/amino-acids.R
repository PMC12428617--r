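# Taste-class annotation and key-selection for free amino acids. Free
# amino acids are the main non-volatile taste contributors in dry-cured
# meat; each is dominated by one taste class (sweet, bitter, umami,
# neutral, or the mixed sweet-bitter of lysine).

#' Default amino-acid taste-class map
#'
#' Covers the 20 proteinogenic amino acids plus L-ornithine, L-citrulline,
#' 4-aminobutyric acid and beta-alanine. Assignments follow the standard
#' flavor-chemistry classes (e.g. L-alanine sweet, L-valine neutral,
#' L-lysine sweet-bitter); pass your own two-column map to override.
#'
#' @return A tibble: amino_acid, taste_class.
#' @export
default_taste_map <- function() {
  path <- system.file("extdata", "taste_map_default.csv",
                      package = "aromalip")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

canonical_amino_acid <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Annotate amino acids with taste classes
#'
#' @param records A tibble with an `amino_acid` column (other columns pass
#'   through), or a character vector of names.
#' @param taste_map Two-column map (`amino_acid`, `taste_class`); default
#'   [default_taste_map()].
#' @param strict Error on unmapped names (default); otherwise label them
#'   "unknown".
#' @return The records with a `taste_class` column added.
#' @export
#' @examples
#' annotate_taste(c("L-alanine", "L-valine"))
annotate_taste <- function(records, taste_map = default_taste_map(),
                           strict = TRUE) {
  if (is.character(records)) records <- tibble(amino_acid = records)
  if (!"amino_acid" %in% names(records)) {
    abort("records need an `amino_acid` column")
  }
  key <- canonical_amino_acid(taste_map$amino_acid)
  hit <- match(canonical_amino_acid(records$amino_acid), key)
  if (anyNA(hit)) {
    missing <- records$amino_acid[is.na(hit)]
    if (strict) {
      abort(sprintf("no taste class for: %s", paste(missing, collapse = ", ")))
    }
    inform(sprintf("%d amino acid(s) without taste class marked \"unknown\"",
                   length(missing)))
  }
  cls <- taste_map$taste_class[hit]
  cls[is.na(hit)] <- "unknown"
  dplyr::mutate(records, taste_class = cls)
}

#' Select key amino acids by relative content
#'
#' Flags amino acids whose relative content meets `min_content`
#' (inclusive, default 40 on the input's own unit scale) as key, and ranks
#' all records by content. When the input carries several sample columns,
#' the mean across samples is used.
#'
#' @param records A tibble with `amino_acid` plus either a
#'   `relative_content` column or numeric sample columns.
#' @param min_content Inclusive key threshold, same units as the input.
#' @return Records with `relative_content` (mean over samples if needed),
#'   `is_key` and `rank` columns, sorted by descending content.
#' @export
#' @examples
#' aa <- tibble::tibble(amino_acid = c("L-alanine", "L-valine"),
#'                      relative_content = c(62, 39.9))
#' select_key_amino_acids(aa)
select_key_amino_acids <- function(records, min_content = 40) {
  if (!"amino_acid" %in% names(records)) {
    abort("records need an `amino_acid` column")
  }
  if (min_content < 0) abort("`min_content` must be >= 0")
  if (!"relative_content" %in% names(records)) {
    num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
    if (!length(num_cols)) abort("no numeric content columns found")
    records$relative_content <-
      rowMeans(as.matrix(records[, num_cols]), na.rm = TRUE)
  }
  out <- dplyr::mutate(records,
                       is_key = .data$relative_content >= min_content)
  out <- dplyr::arrange(out, dplyr::desc(.data$relative_content),
                        .data$amino_acid)
  dplyr::mutate(out, rank = dplyr::row_number())
}
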