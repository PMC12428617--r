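# Synthetic data with known ground truth for every downstream stage:
# replicate peak tables with controlled CV and detection dropout, shorthand
# lipid tables drawn from the class grammar, and feature blocks with planted
# Pearson correlations.

# Run `code` under an explicit Mersenne-Twister stream without disturbing
# the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Specify a synthetic replicate peak table
#'
#' Bundles and validates the ground-truth parameters of a simulated GC-MS
#' peak table: per-compound true relative contents, replicate
#' coefficient of variation, detection-dropout probability and the RNG seed.
#' Replicate noise is log-normal, parameterized so the *arithmetic* CV of a
#' replicate equals `replicate_cv` (sdlog^2 = log(1 + cv^2)); peak areas are
#' positive and right-skewed, which matches instrument behaviour.
#'
#' @param n_compounds Number of compounds.
#' @param n_replicates Number of replicate samples (default 4, the usual
#'   biological replication for a single ham group).
#' @param true_relative_content Per-compound proportions summing to 1;
#'   default equal shares.
#' @param replicate_cv Per-compound CV as a fraction (recycled).
#' @param dropout_prob Per-compound probability that a replicate is
#'   non-detected (recycled).
#' @param seed Integer seed for the generator's private RNG stream.
#' @param compounds Optional compound names.
#' @param total_area Arbitrary total-area scale; downstream relative
#'   statistics are invariant to it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds,
                           n_replicates = 4,
                           true_relative_content = NULL,
                           replicate_cv = 0.1,
                           dropout_prob = 0,
                           seed = 1L,
                           compounds = NULL,
                           total_area = 1e6) {
  n_compounds <- check_count(n_compounds, "n_compounds")
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (is.null(true_relative_content)) {
    true_relative_content <- rep(1 / n_compounds, n_compounds)
  }
  if (length(true_relative_content) != n_compounds) {
    abort("`true_relative_content` must have one entry per compound")
  }
  if (any(true_relative_content < 0)) {
    abort("`true_relative_content` must be non-negative")
  }
  if (abs(sum(true_relative_content) - 1) > 1e-9) {
    abort("`true_relative_content` must sum to 1 (within 1e-9)")
  }
  replicate_cv <- rep_len(as.numeric(replicate_cv), n_compounds)
  if (any(replicate_cv < 0)) abort("`replicate_cv` must be >= 0")
  dropout_prob <- rep_len(as.numeric(dropout_prob), n_compounds)
  if (any(dropout_prob < 0 | dropout_prob > 1)) {
    abort("`dropout_prob` must lie in [0, 1]")
  }
  if (is.null(compounds)) {
    compounds <- sprintf("compound_%03d", seq_len(n_compounds))
  }
  if (anyDuplicated(compounds)) abort("`compounds` must be unique")
  structure(
    list(n_compounds = n_compounds, n_replicates = n_replicates,
         true_relative_content = as.numeric(true_relative_content),
         replicate_cv = replicate_cv, dropout_prob = dropout_prob,
         seed = as.integer(seed), compounds = compounds,
         total_area = total_area),
    class = "synthetic_spec"
  )
}

#' Generate a replicate peak table
#'
#' Draws a compounds-by-replicates matrix of peak areas from the spec's
#' ground truth. Detected entries come from a log-normal with arithmetic
#' mean proportional to the true relative content and arithmetic CV equal to
#' `replicate_cv`; non-detections are encoded as `NA` (missing, not zero, so
#' "absent" stays distinguishable from "tiny"). Identical seeds give
#' bit-identical tables.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with a `compound` column and one numeric column per
#'   replicate; attribute `ground_truth` carries the spec.
#' @export
#' @examples
#' generate_peak_table(synthetic_spec(3, 4, replicate_cv = 0, seed = 7))
generate_peak_table <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be created by synthetic_spec()")
  }
  mu <- spec$true_relative_content * spec$total_area
  with_seed(spec$seed, {
    areas <- matrix(NA_real_, spec$n_compounds, spec$n_replicates)
    for (i in seq_len(spec$n_compounds)) {
      cv <- spec$replicate_cv[i]
      if (cv == 0) {
        row <- rep(mu[i], spec$n_replicates)
      } else {
        sdlog <- sqrt(log(1 + cv^2))
        meanlog <- log(mu[i]) - sdlog^2 / 2
        row <- stats::rlnorm(spec$n_replicates, meanlog, sdlog)
      }
      drop <- stats::runif(spec$n_replicates) < spec$dropout_prob[i]
      row[drop] <- NA_real_
      areas[i, ] <- row
    }
    out <- tibble(compound = spec$compounds)
    reps <- as_tibble(areas, .name_repair = "minimal")
    names(reps) <- sprintf("rep_%d", seq_len(spec$n_replicates))
    out <- dplyr::bind_cols(out, reps)
    attr(out, "ground_truth") <- spec
    out
  })
}

# ---- lipid name generation --------------------------------------------------

# chains per class; 1-chain classes are emitted in sum-composition form
.chain_counts <- c(
  TG = 3, DG = 2, MG = 1, DGCC = 2, DGTS = 2, MGDG = 2, DGDG = 2,
  PC = 2, PE = 2, PS = 2, PI = 2, PG = 2, PA = 2,
  SM = 2, Cer = 2, HexCer = 2, SHexCer = 2, `PE-Cer` = 2,
  FAHFA = 2, NAGly = 2, FA = 1, ST = 2, CE = 1, SE = 1, PR = 1
)

.sphingoid_classes <- c("SM", "Cer", "HexCer", "SHexCer", "PE-Cer")

random_lipid_name <- function(class_code) {
  n_chain <- .chain_counts[[class_code]]
  carbons <- sample(8:26, n_chain, replace = TRUE)
  dbs <- vapply(carbons, function(cc) sample(0:min(6L, cc), 1L), integer(1))
  chains <- paste0(carbons, ":", dbs)
  if (class_code %in% .sphingoid_classes) {
    # long-chain base carries two hydroxyls in shorthand (";2O")
    chains[1] <- paste0(chains[1], ";2O")
    sep <- "/"
  } else if (class_code %in% c("FAHFA", "NAGly")) {
    sep <- "/"
  } else {
    sep <- "_"
    if (class_code %in% c("TG", "DG", "PC", "PE") &&
        stats::runif(1) < 0.15) {
      chains[1] <- paste0("O-", chains[1])
    }
  }
  paste0(class_code, "(", paste(chains, collapse = sep), ")")
}

#' Generate a synthetic lipid abundance table
#'
#' Draws shorthand lipid species names from the class grammar with classes
#' sampled according to `subclass_weights`, plus log-normal relative
#' abundances. Every generated name is guaranteed to parse with
#' [parse_lipid()].
#'
#' @param n_species Number of species to draw.
#' @param subclass_weights Named numeric vector of class-code weights, e.g.
#'   `c(TG = 25.29, DG = 13.43)`; need not be normalized.
#' @param seed Integer seed.
#' @param n_samples Number of sample columns (default 4).
#' @return A tibble with a `lipid` column and one abundance column per
#'   sample; attribute `true_classes` records each species' drawn class.
#' @export
#' @examples
#' generate_lipid_table(5, c(TG = 2, PC = 1), seed = 1)
generate_lipid_table <- function(n_species, subclass_weights, seed = 1L,
                                 n_samples = 4) {
  n_species <- check_count(n_species, "n_species")
  n_samples <- check_count(n_samples, "n_samples")
  codes <- names(subclass_weights)
  bad <- setdiff(codes, names(.chain_counts))
  if (length(bad)) {
    abort(sprintf("unknown class code(s): %s; valid codes: %s",
                  paste(bad, collapse = ", "),
                  paste(names(.chain_counts), collapse = ", ")))
  }
  if (any(subclass_weights < 0) || sum(subclass_weights) <= 0) {
    abort("`subclass_weights` must be non-negative with a positive sum")
  }
  with_seed(seed, {
    classes <- sample(codes, n_species, replace = TRUE,
                      prob = subclass_weights / sum(subclass_weights))
    names_out <- character(n_species)
    seen <- character(0)
    for (i in seq_len(n_species)) {
      nm <- random_lipid_name(classes[i])
      tries <- 0L
      while (nm %in% seen && tries < 100L) {
        nm <- random_lipid_name(classes[i])
        tries <- tries + 1L
      }
      if (nm %in% seen) nm <- paste0(nm, "#", i)  # pathological fallback
      seen <- c(seen, nm)
      names_out[i] <- nm
    }
    ab <- matrix(stats::rlnorm(n_species * n_samples, 0, 1),
                 n_species, n_samples)
    out <- tibble(lipid = names_out)
    abt <- as_tibble(ab, .name_repair = "minimal")
    names(abt) <- sprintf("S%d", seq_len(n_samples))
    out <- dplyr::bind_cols(out, abt)
    attr(out, "true_classes") <- stats::setNames(classes, names_out)
    out
  })
}

#' Generate lipid and volatile blocks with planted correlations
#'
#' Builds two feature-by-sample blocks whose planted pairs have population
#' Pearson correlation exactly equal to `target_r` via a bivariate-normal
#' latent construction: the lipid feature is a standard normal `z` and the
#' paired volatile is `r*z + sqrt(1-r^2)*e`, both shifted to mean 10, sd 1
#' (Pearson r is affine-invariant, so the planted correlation is
#' preserved). With `|target_r| = 1` the pair is exactly affine and the
#' sample correlation is +/-1 with no Monte-Carlo error. Non-planted
#' features are generated independently.
#'
#' @param planted A data frame with columns `lipid_feature`,
#'   `volatile_feature`, `target_r` (one row per planted pair).
#' @param n_samples Number of shared samples (>= 3).
#' @param seed Integer seed.
#' @param n_extra_lipids,n_extra_volatiles Independent decoy features to add.
#' @return A list with tibbles `lipids` and `volatiles` (feature column +
#'   sample columns) and the `ground_truth` planted table.
#' @export
generate_correlated_blocks <- function(planted, n_samples, seed = 1L,
                                       n_extra_lipids = 0,
                                       n_extra_volatiles = 0) {
  planted <- as_tibble(planted)
  need <- c("lipid_feature", "volatile_feature", "target_r")
  if (!all(need %in% names(planted))) {
    abort("`planted` needs columns lipid_feature, volatile_feature, target_r")
  }
  if (any(abs(planted$target_r) > 1)) abort("|target_r| must be <= 1")
  if (n_samples < 3) abort("`n_samples` must be >= 3")
  if (anyDuplicated(planted$lipid_feature) ||
      anyDuplicated(planted$volatile_feature)) {
    abort("each feature may appear in at most one planted pair")
  }
  with_seed(seed, {
    lip <- list(); vol <- list()
    for (k in seq_len(nrow(planted))) {
      r <- planted$target_r[k]
      z <- stats::rnorm(n_samples)
      if (abs(r) == 1) {
        w <- sign(r) * z
      } else {
        w <- r * z + sqrt(1 - r^2) * stats::rnorm(n_samples)
      }
      lip[[planted$lipid_feature[k]]] <- z + 10
      vol[[planted$volatile_feature[k]]] <- w + 10
    }
    for (k in seq_len(n_extra_lipids)) {
      lip[[sprintf("decoy_lipid_%02d", k)]] <- stats::rnorm(n_samples) + 10
    }
    for (k in seq_len(n_extra_volatiles)) {
      vol[[sprintf("decoy_volatile_%02d", k)]] <- stats::rnorm(n_samples) + 10
    }
    samp <- sprintf("S%d", seq_len(n_samples))
    as_block <- function(lst, feature_col) {
      m <- do.call(rbind, lst)
      colnames(m) <- samp
      dplyr::bind_cols(tibble(!!feature_col := names(lst)),
                       as_tibble(m))
    }
    list(lipids = as_block(lip, "lipid"),
         volatiles = as_block(vol, "compound"),
         ground_truth = planted)
  })
}
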