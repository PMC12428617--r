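# Small in-code fixtures shared across test files.

# peak table from a compound x replicate matrix (NA = non-detected)
peaks_from_matrix <- function(m, compounds = NULL) {
  if (is.null(compounds)) compounds <- sprintf("c%02d", seq_len(nrow(m)))
  out <- tibble::tibble(compound = compounds)
  reps <- tibble::as_tibble(m, .name_repair = "minimal")
  names(reps) <- sprintf("rep_%d", seq_len(ncol(m)))
  dplyr::bind_cols(out, reps)
}

# annotated records straight from the packaged reference table
table1_records <- function() {
  db <- ham_thresholds()
  tibble::tibble(
    compound = db$compound,
    chemical_class = db$chemical_class,
    c_percent = db$relative_content_percent,
    threshold_ug_per_kg = db$threshold_ug_per_kg,
    roav_reported = db$roav_reported
  )
}

# independent brute-force recomputation of the screening pipeline, written
# as plain loops so it shares no code with the implementation
brute_force_screen <- function(m, min_rate = 0.5, max_cv = 0.30) {
  keep <- logical(nrow(m))
  stats_list <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    det <- x[!is.na(x)]
    rate <- length(det) / length(x)
    cv <- if (length(det) >= 2) stats::sd(det) / mean(det) else NA_real_
    keep[i] <- rate > min_rate && !is.na(cv) && cv < max_cv
    stats_list[[i]] <- list(rate = rate, cv = cv,
                            mean = if (length(det)) mean(det) else NA_real_)
  }
  means <- vapply(stats_list, `[[`, numeric(1), "mean")[keep]
  list(keep = keep,
       c_percent = 100 * means / sum(means),
       stats = stats_list)
}

paper_key_lipid_names <- function() {
  c("TG(13: 1_20: 0_20: 0)", "TG(O-8: 0_14: 0_14: 1)",
    "TG(8: 0_18: 1_26: 1)", "DG(O-15: 1_20: 3)", "PC(O-34: 3)",
    "SM(11: 1; 2O/30: 3)", "Cer(15: 1; 2O/26: 5)", "SHexCer(37: 1; 2O)",
    "FAHFA(20: 4/18: 0)", "NAGly(16: 0/18: 1)",
    "PE-Cer(14: 3; 2O/23: 1; O)", "DGCC(23: 0_22: 2)", "DGCC(18: 0_30: 0)",
    "ST(24: 1; O3; T/20: 1)")
}
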