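# Replicate quality screening of volatile peak tables: detection-rate and
# CV filters, relative percentage content (C%), and the odor-threshold join.
# A peak table is a tibble whose first column, `compound`, names the feature
# and whose remaining columns hold one replicate each; NA means non-detected.

area_matrix <- function(table) {
  if (!is.data.frame(table) || !"compound" %in% names(table)) {
    abort("a peak table needs a `compound` column")
  }
  if (ncol(table) < 3) abort("a peak table needs at least 2 sample columns")
  if (anyDuplicated(canonical_compound(table$compound))) {
    abort("compound names must be unique after canonicalization")
  }
  m <- as.matrix(table[, setdiff(names(table), "compound")])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) abort("peak areas must be non-negative")
  rownames(m) <- table$compound
  m
}

#' Per-compound replicate statistics
#'
#' Detection rate (fraction of replicates present), mean, sample (n-1)
#' standard deviation and coefficient of variation of the *detected*
#' replicate areas for each compound. These are the quantities the two
#' screening filters act on.
#'
#' @param table A peak table (`compound` column + replicate columns;
#'   `NA` = non-detected).
#' @return A tibble: compound, n_detected, detection_rate, mean_area,
#'   sd_area, cv (NA when fewer than 2 detected replicates).
#' @export
peak_stats <- function(table) {
  m <- area_matrix(table)
  n_rep <- ncol(m)
  n_det <- rowSums(!is.na(m))
  mean_a <- ifelse(n_det > 0, rowMeans(m, na.rm = TRUE), NA_real_)
  sd_a <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= 2) stats::sd(x) else NA_real_
  })
  tibble(
    compound = as.character(rownames(m) %||% character(0)),
    n_detected = as.integer(unname(n_det)),
    detection_rate = unname(n_det / n_rep),
    mean_area = as.numeric(unname(mean_a)),
    sd_area = as.numeric(unname(sd_a)),
    cv = as.numeric(unname(sd_a / mean_a))
  )
}

#' Detection-rate screening filter
#'
#' Retains compounds whose detection rate across replicates exceeds
#' `min_rate`. The comparison is strict (`>`) by default, so a compound seen
#' in exactly 2 of 4 replicates is removed at the default 0.5 cutoff; set
#' `inclusive = TRUE` for `>=`.
#'
#' @param table A peak table.
#' @param min_rate Minimum detection rate, default 0.5.
#' @param inclusive Use `>=` instead of the strict `>`.
#' @return The filtered peak table; attribute `report` holds the
#'   per-compound rates with a `retained` flag.
#' @export
#' @examples
#' pt <- tibble::tibble(compound = c("a", "b"),
#'                      r1 = c(1, 1), r2 = c(1, NA), r3 = c(1, NA), r4 = c(1, 1))
#' detection_rate_filter(pt)
detection_rate_filter <- function(table, min_rate = 0.5, inclusive = FALSE) {
  min_rate <- check_fraction(min_rate, "min_rate")
  stats_tbl <- peak_stats(table)
  keep <- if (inclusive) stats_tbl$detection_rate >= min_rate else
    stats_tbl$detection_rate > min_rate
  if (!any(keep)) warn("detection-rate filter removed every compound")
  out <- table[keep, , drop = FALSE]
  attr(out, "report") <- dplyr::mutate(stats_tbl, retained = keep)
  out
}

#' Coefficient-of-variation screening filter
#'
#' Retains compounds whose CV (sample standard deviation over mean of the
#' detected replicate areas) is below `max_cv`; strict (`<`) by default per
#' the usual "CV of less than 30%" reading. Compounds with fewer than two
#' detected replicates have no defined CV and are removed (reported in the
#' attached report).
#'
#' @param table A peak table.
#' @param max_cv Maximum CV as a fraction, default 0.30.
#' @param inclusive Use `<=` instead of the strict `<`.
#' @return Filtered peak table with a `report` attribute.
#' @export
cv_filter <- function(table, max_cv = 0.30, inclusive = FALSE) {
  if (!is.numeric(max_cv) || max_cv <= 0) abort("`max_cv` must be > 0")
  stats_tbl <- peak_stats(table)
  defined <- !is.na(stats_tbl$cv)
  if (any(!defined & stats_tbl$n_detected == 1L)) {
    inform(sprintf(
      "removed %d compound(s) with a single detected replicate (CV undefined)",
      sum(!defined & stats_tbl$n_detected == 1L)))
  }
  keep <- defined &
    (if (inclusive) stats_tbl$cv <= max_cv else stats_tbl$cv < max_cv)
  if (!any(keep)) warn("CV filter removed every compound")
  out <- table[keep, , drop = FALSE]
  attr(out, "report") <- dplyr::mutate(stats_tbl, retained = keep)
  out
}

#' Relative percentage content (C%)
#'
#' For a peak table that has already passed both screening filters, computes
#' each compound's mean detected area as a percentage of the summed mean
#' areas of all retained compounds. The output sums to exactly 100 and is
#' invariant to any global rescaling of the areas.
#'
#' @param table A screened peak table.
#' @return A tibble of screened-compound records: compound, n_detected,
#'   detection_rate, cv, mean_area, c_percent.
#' @export
#' @examples
#' pt <- tibble::tibble(compound = c("a", "b"), r1 = c(3, 1), r2 = c(3, 1))
#' relative_content(pt)  # 75 / 25
relative_content <- function(table) {
  stats_tbl <- peak_stats(table)
  if (any(stats_tbl$n_detected == 0L)) {
    abort(sprintf("all-missing compound(s) present: %s",
                  paste(stats_tbl$compound[stats_tbl$n_detected == 0L],
                        collapse = ", ")))
  }
  total <- sum(stats_tbl$mean_area)
  dplyr::transmute(
    stats_tbl,
    compound = .data$compound,
    n_detected = .data$n_detected,
    detection_rate = .data$detection_rate,
    cv = .data$cv,
    mean_area = .data$mean_area,
    c_percent = 100 * .data$mean_area / total
  )
}

#' Run both screening filters and compute C%
#'
#' Convenience wrapper: detection-rate filter, CV filter, then
#' [relative_content()]. The two filters commute because each uses only
#' per-compound statistics.
#'
#' @inheritParams detection_rate_filter
#' @inheritParams cv_filter
#' @return A screened-compound tibble (see [relative_content()]).
#' @export
screen_peaks <- function(table, min_rate = 0.5, max_cv = 0.30,
                         inclusive = FALSE) {
  table |>
    detection_rate_filter(min_rate, inclusive = inclusive) |>
    cv_filter(max_cv, inclusive = inclusive) |>
    relative_content()
}

#' Join odor-threshold annotations
#'
#' Inner-joins screened compounds to a threshold database on canonicalized
#' compound names. Compounds lacking a threshold record are dropped and
#' listed in the `dropped` attribute; the C% values are deliberately *not*
#' renormalized after the drop, so the denominator remains "all compounds
#' surviving the two screening filters" — which is why a tabulated subset's
#' C% column need not sum to 100.
#'
#' @param screened Output of [relative_content()] / [screen_peaks()].
#' @param db Threshold records: columns `compound`, `threshold_ug_per_kg`,
#'   and optionally `chemical_class`, `descriptor`. Default: the packaged
#'   ham table.
#' @param synonyms Synonym map passed to [canonical_compound()].
#' @return Annotated tibble with threshold columns added; attribute
#'   `dropped` names the unannotated compounds.
#' @export
join_thresholds <- function(screened, db = ham_thresholds(reference = FALSE),
                            synonyms = NULL) {
  if (!all(c("compound", "threshold_ug_per_kg") %in% names(db))) {
    abort("`db` needs columns `compound` and `threshold_ug_per_kg`")
  }
  if (any(db$threshold_ug_per_kg <= 0)) {
    abort("odor thresholds must be positive")
  }
  db <- dplyr::mutate(db, .key = canonical_compound(.data$compound, synonyms))
  dup <- db$.key[duplicated(db$.key)]
  if (length(dup)) {
    abort(sprintf("duplicate threshold entries for: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  left <- dplyr::mutate(screened,
                        .key = canonical_compound(.data$compound, synonyms))
  joined <- dplyr::inner_join(
    left, dplyr::select(db, -"compound"), by = ".key")
  dropped <- setdiff(left$compound, left$compound[left$.key %in% db$.key])
  if (length(dropped)) {
    inform(sprintf("%d compound(s) without threshold annotation dropped",
                   length(dropped)))
  }
  joined <- dplyr::select(joined, -".key")
  attr(joined, "dropped") <- dropped
  joined
}

#' Kovats retention index
#'
#' Linear (temperature-programmed) retention-index interpolation against an
#' n-alkane ladder: `RI = 100 n + 100 (t - t_n) / (t_{n+1} - t_n)` where the
#' query time `t` falls between the alkanes with `n` and `n + 1` carbons.
#'
#' @param retention_time Query retention time(s), minutes.
#' @param alkane_times Named numeric vector, names = carbon numbers, values
#'   = retention times (strictly increasing in carbon number).
#' @return Numeric retention index per query time.
#' @export
#' @examples
#' kovats_ri(5.5, c(`10` = 5, `11` = 6))  # 1050
kovats_ri <- function(retention_time, alkane_times) {
  carbons <- as.integer(names(alkane_times))
  if (anyNA(carbons)) abort("`alkane_times` names must be carbon numbers")
  o <- order(carbons)
  carbons <- carbons[o]; times <- as.numeric(alkane_times[o])
  if (any(diff(times) <= 0)) {
    abort("`alkane_times` must strictly increase with carbon number")
  }
  vapply(retention_time, function(t) {
    if (t < times[1] || t > times[length(times)]) {
      abort(sprintf(
        "retention time %.3f not bracketed by the alkane ladder (C%d at %.3f .. C%d at %.3f)",
        t, carbons[1], times[1], carbons[length(carbons)], times[length(times)]))
    }
    i <- findInterval(t, times, rightmost.closed = TRUE)
    100 * carbons[i] + 100 * (carbons[i + 1] - carbons[i]) *
      (t - times[i]) / (times[i + 1] - times[i])
  }, numeric(1))
}
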