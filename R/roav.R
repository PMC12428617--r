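# Relative odor activity value (ROAV) scoring. The flavor contribution of a
# compound scales with its relative content C% and inversely with its odor
# threshold T; the compound maximizing C%/T is the reference ("standard")
# whose ROAV is fixed at 100, and every other compound scores
#
#   ROAV_A = 100 * (C%_A / C%_stan) * (T_stan / T_A)
#
# so ROAV is dimensionless, bounded by 100, and invariant to any positive
# rescaling of all C% values.

check_annotated <- function(records) {
  need <- c("compound", "c_percent", "threshold_ug_per_kg")
  if (!all(need %in% names(records))) {
    abort(sprintf("annotated records need columns: %s",
                  paste(need, collapse = ", ")))
  }
  if (nrow(records) == 0L) abort("no annotated compounds to score")
  if (any(records$threshold_ug_per_kg <= 0)) {
    bad <- records$compound[records$threshold_ug_per_kg <= 0]
    abort(sprintf("non-positive threshold for: %s", paste(bad, collapse = ", ")))
  }
  invisible(records)
}

#' Select the flavor standard compound
#'
#' The standard is the compound with the greatest flavor contribution,
#' operationalized as the maximal contribution ratio C%/T; its ROAV is
#' later fixed at 100. Ties are broken deterministically by canonical name
#' order and logged.
#'
#' @param records Annotated screened compounds (columns `compound`,
#'   `c_percent`, `threshold_ug_per_kg`), e.g. from [join_thresholds()].
#' @return The standard compound's name (scalar character).
#' @export
#' @examples
#' recs <- tibble::tibble(compound = c("a", "b"),
#'                        c_percent = c(2, 10),
#'                        threshold_ug_per_kg = c(1, 100))
#' select_standard(recs)  # "a": 2/1 beats 10/100
select_standard <- function(records) {
  check_annotated(records)
  ratio <- records$c_percent / records$threshold_ug_per_kg
  top <- which(ratio == max(ratio))
  if (length(top) > 1L) {
    top <- top[order(canonical_compound(records$compound[top]))]
    inform(sprintf("contribution-ratio tie broken by name order: %s chosen",
                   records$compound[top[1]]))
  }
  records$compound[top[1]]
}

#' Compute ROAV scores
#'
#' Applies `ROAV_A = 100 (C%_A / C%_stan) (T_stan / T_A)` to every record.
#' The standard scores exactly 100; when the standard is the contribution
#' maximizer (the default via [select_standard()]) every other score is
#' below 100.
#'
#' @param records Annotated screened compounds.
#' @param standard Name of the standard compound; default picks it with
#'   [select_standard()].
#' @return The records with `roav` and `is_standard` columns added, sorted
#'   as given.
#' @export
compute_roav <- function(records, standard = NULL) {
  check_annotated(records)
  if (is.null(standard)) standard <- select_standard(records)
  key <- canonical_compound(records$compound)
  std_i <- match(canonical_compound(standard), key)
  if (is.na(std_i)) abort(sprintf("standard %s not present in records", standard))
  c_stan <- records$c_percent[std_i]
  t_stan <- records$threshold_ug_per_kg[std_i]
  if (c_stan <= 0) abort("standard compound has non-positive C%")
  out <- dplyr::mutate(
    records,
    roav = 100 * (.data$c_percent / c_stan) *
      (t_stan / .data$threshold_ug_per_kg),
    is_standard = dplyr::row_number() == std_i
  )
  out$roav[std_i] <- 100  # exact by definition
  out
}

#' Classify flavor-contribution categories
#'
#' Standard ROAV bands: `roav >= 1` marks a characteristic flavor compound,
#' `0.1 <= roav < 1` a modifier with an important modulating effect, and
#' `roav < 0.1` is reported as negligible for completeness.
#'
#' @param records Records carrying a `roav` column.
#' @return Records with a `category` factor added
#'   (characteristic/modifier/negligible); attribute `category_counts`
#'   tabulates the three bands.
#' @export
classify_contribution <- function(records) {
  if (!"roav" %in% names(records)) abort("records lack a `roav` column")
  cat <- ifelse(records$roav >= 1, "characteristic",
                ifelse(records$roav >= 0.1, "modifier", "negligible"))
  out <- dplyr::mutate(
    records,
    category = factor(cat, levels = c("characteristic", "modifier",
                                      "negligible"))
  )
  attr(out, "category_counts") <- table(out$category)
  out
}

#' Integer percentage shares by the largest-remainder method
#'
#' Allocates integer percentages to counts so the shares sum to exactly
#' 100: each group first gets the floor of its exact quota, then the
#' leftover points go to the largest fractional remainders, ties broken by
#' descending count and then by name.
#'
#' @param counts Named integer vector of group counts.
#' @return Named integer vector of shares summing to 100.
#' @export
#' @examples
#' largest_remainder_shares(c(a = 1, b = 1, c = 1))  # 34 33 33
largest_remainder_shares <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("`counts` must be fully named")
  }
  if (any(counts < 0) || sum(counts) == 0) {
    abort("`counts` must be non-negative with a positive total")
  }
  quota <- 100 * counts / sum(counts)
  share <- floor(quota)
  left <- 100L - as.integer(sum(share))
  if (left > 0L) {
    rem <- quota - share
    ord <- order(-rem, -counts, names(counts))
    share[ord[seq_len(left)]] <- share[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(share), names(counts))
}

#' Chemical-class composition summary
#'
#' Counts compounds per chemical class and converts the counts to integer
#' percentage shares via [largest_remainder_shares()], so the printed
#' shares always total 100.
#'
#' @param records Records with a `chemical_class` column, or any character
#'   vector of classes.
#' @param classes Optional named map compound -> class overriding the
#'   records' own column; unmapped compounds fall into "other" with a
#'   message.
#' @return A tibble: chemical_class, count, percent_share (sorted by
#'   descending count, then name).
#' @export
class_composition <- function(records, classes = NULL) {
  if (is.character(records)) {
    cls <- records
  } else if (!is.null(classes)) {
    cls <- unname(classes[records$compound])
    if (anyNA(cls)) {
      inform(sprintf("%d unmapped compound(s) assigned class \"other\"",
                     sum(is.na(cls))))
      cls[is.na(cls)] <- "other"
    }
  } else {
    if (!"chemical_class" %in% names(records)) {
      abort("records lack a `chemical_class` column and no `classes` map given")
    }
    cls <- as.character(records$chemical_class)
  }
  counts <- table(cls)
  counts_v <- stats::setNames(as.integer(counts), names(counts))
  shares <- largest_remainder_shares(counts_v)
  out <- tibble(
    chemical_class = names(counts_v),
    count = unname(counts_v),
    percent_share = as.integer(unname(shares))
  )
  dplyr::arrange(out, dplyr::desc(.data$count), .data$chemical_class)
}
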