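# Readers, writers, configuration and the end-to-end pipeline: screening ->
# C% -> threshold join -> ROAV -> classification -> class summary ->
# optional correlation blocks, with a JSON run manifest for reproducibility.

feature_col_for <- c(peaks = "compound", lipids = "lipid",
                     amino_acids = "amino_acid")

#' Read a feature table from CSV/TSV
#'
#' First column names the feature, remaining columns are numeric sample
#' values. The delimiter follows the file extension (`.tsv`/`.txt` = tab,
#' otherwise comma). For peak tables (`kind = "peaks"`), empty cells and
#' zeros are normalized to missing — a zero peak area means the compound
#' was not detected, and "absent" must stay distinguishable from "tiny".
#'
#' @param path File path.
#' @param kind "peaks", "lipids" or "amino_acids"; sets the expected
#'   feature-column name and missing-value convention.
#' @return A tibble with the feature column first.
#' @export
read_feature_table <- function(path, kind = c("peaks", "lipids",
                                              "amino_acids")) {
  kind <- match.arg(kind)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(raw) < 2) abort("feature tables need at least one sample column")
  names(raw)[1] <- feature_col_for[[kind]]
  feats <- as.character(raw[[1]])
  key <- if (kind == "peaks") canonical_compound(feats) else
    tolower(trimws(feats))
  dups <- unique(feats[duplicated(key)])
  if (length(dups)) {
    abort(sprintf("duplicate feature names: %s", paste(dups, collapse = ", ")))
  }
  for (j in 2:ncol(raw)) {
    col <- raw[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & nzchar(trimws(as.character(col))) & is.na(num))
      if (length(bad)) {
        abort(sprintf("non-numeric cell at row %d, column \"%s\": \"%s\"",
                      bad[1], names(raw)[j], col[bad[1]]))
      }
      col <- num
    }
    if (kind == "peaks") col[!is.na(col) & col == 0] <- NA_real_
    raw[[j]] <- col
  }
  raw[[1]] <- feats
  raw
}

#' Write a feature table to CSV
#'
#' Missing cells are written empty, matching the convention
#' [read_feature_table()] expects back; the round trip is lossless.
#'
#' @param table Feature table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' Write a synthetic table plus its ground-truth sidecar
#'
#' Saves a generated table as CSV and the generator's ground truth (spec
#' parameters, planted correlations, seed) as a JSON sidecar next to it.
#'
#' @param table A table from one of the generators.
#' @param path CSV output path; the sidecar gets the extension
#'   `.truth.json`.
#' @return `path`, invisibly.
#' @export
write_synthetic_bundle <- function(table, path) {
  write_feature_table(table, path)
  truth <- attr(table, "ground_truth")
  if (is.null(truth)) truth <- attr(table, "true_classes")
  sidecar <- sub("\\.[^.]+$", "", path)
  jsonlite::write_json(unclass(truth), paste0(sidecar, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles and validates every tunable of the end-to-end pipeline. The
#' defaults encode the standard screening constants: detection rate
#' strictly above 0.5, CV strictly below 0.30, ROAV bands at 1 and 0.1.
#'
#' @param min_detection_rate Detection-rate cutoff (strict `>`).
#' @param max_cv CV cutoff as a fraction (strict `<`).
#' @param inclusive Make both screening comparisons inclusive.
#' @param roav_characteristic_cutoff,roav_modifier_cutoff ROAV band edges.
#' @param adjust_method "bh" or "none" for correlation p-values.
#' @param seed Optional integer seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_detection_rate = 0.5,
                            max_cv = 0.30,
                            inclusive = FALSE,
                            roav_characteristic_cutoff = 1.0,
                            roav_modifier_cutoff = 0.1,
                            adjust_method = c("bh", "none"),
                            seed = NULL) {
  min_detection_rate <- check_fraction(min_detection_rate,
                                       "min_detection_rate")
  if (min_detection_rate >= 1) abort("`min_detection_rate` must be < 1")
  if (max_cv <= 0) abort("`max_cv` must be > 0")
  if (roav_characteristic_cutoff <= roav_modifier_cutoff ||
      roav_modifier_cutoff <= 0) {
    abort("ROAV cutoffs must be positive and ordered")
  }
  structure(list(
    min_detection_rate = min_detection_rate,
    max_cv = max_cv,
    inclusive = inclusive,
    roav_characteristic_cutoff = roav_characteristic_cutoff,
    roav_modifier_cutoff = roav_modifier_cutoff,
    adjust_method = match.arg(adjust_method),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full flavoromics pipeline
#'
#' Chains the screening filters, relative-content computation, threshold
#' join, standard selection, ROAV scoring, contribution classification and
#' chemical-class summary; when lipid and/or amino-acid blocks are
#' supplied, correlates each against the characteristic (ROAV >= 1)
#' volatiles' replicate areas. Optionally writes all exports plus a JSON
#' run manifest.
#'
#' @param peaks Peak table (tibble or path readable by
#'   [read_feature_table()]).
#' @param thresholds Threshold database; default the packaged ham table.
#' @param lipids,amino_acids Optional feature blocks for correlation.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for CSV/JSON exports.
#' @return A list: screened, annotated, roav (classified records),
#'   class_summary, correlations (possibly empty list), manifest.
#' @export
run_pipeline <- function(peaks,
                         thresholds = ham_thresholds(reference = FALSE),
                         lipids = NULL,
                         amino_acids = NULL,
                         config = pipeline_config(),
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  if (is.character(peaks)) peaks <- read_feature_table(peaks, "peaks")
  input_hashes <- list()
  screened <- stage("screening", screen_peaks(
    peaks, min_rate = config$min_detection_rate, max_cv = config$max_cv,
    inclusive = config$inclusive))
  annotated <- stage("threshold_join", join_thresholds(screened, thresholds))
  std <- stage("standard_selection", select_standard(annotated))
  roav <- stage("roav", compute_roav(annotated, std))
  roav <- stage("classification", classify_contribution(roav))
  class_summary <- if ("chemical_class" %in% names(roav)) {
    stage("class_summary", class_composition(roav))
  } else NULL

  correlations <- list()
  characteristic <- roav$compound[roav$category == "characteristic"]
  char_block <- peaks[canonical_compound(peaks$compound) %in%
                        canonical_compound(characteristic), , drop = FALSE]
  if (!is.null(lipids) && nrow(char_block) > 0) {
    if (is.character(lipids)) lipids <- read_feature_table(lipids, "lipids")
    correlations$lipids <- stage("correlation_lipids",
                                 block_correlate(lipids, char_block,
                                                 adjust = config$adjust_method))
  }
  if (!is.null(amino_acids) && nrow(char_block) > 0) {
    if (is.character(amino_acids)) {
      amino_acids <- read_feature_table(amino_acids, "amino_acids")
    }
    correlations$amino_acids <- stage("correlation_amino_acids",
                                      block_correlate(amino_acids, char_block,
                                                      adjust = config$adjust_method))
  }

  manifest <- list(
    package = "aromalip",
    version = as.character(utils::packageVersion("aromalip")),
    config = unclass(config),
    standard_compound = std,
    n_input_compounds = nrow(peaks),
    n_screened = nrow(screened),
    n_annotated = nrow(annotated),
    n_characteristic = length(characteristic),
    dropped_no_threshold = attr(annotated, "dropped")
  )

  result <- list(screened = screened, annotated = annotated, roav = roav,
                 class_summary = class_summary,
                 correlations = correlations, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(roav, file.path(out_dir, "roav_results.csv"), na = "")
    if (!is.null(class_summary)) {
      readr::write_csv(class_summary,
                       file.path(out_dir, "class_summary.csv"), na = "")
    }
    for (nm in names(correlations)) {
      readr::write_csv(correlations[[nm]],
                       file.path(out_dir,
                                 sprintf("correlation_%s.csv", nm)), na = "")
    }
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  result
}
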