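# Pearson block correlation between two feature-by-sample blocks (e.g. key
# lipids vs characteristic volatiles). Each pair's significance comes from
# the exact t transform t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees
# of freedom; Benjamini-Hochberg FDR adjustment across the whole grid is on
# by default because a 14 x 28 grid of unadjusted p-values invites
# over-reading.

block_matrix <- function(block, feature_col = NULL) {
  if (is.matrix(block)) {
    if (is.null(rownames(block))) {
      abort("matrix blocks need feature rownames")
    }
    storage.mode(block) <- "double"
    return(block)
  }
  if (!is.data.frame(block)) abort("blocks must be data frames or matrices")
  if (is.null(feature_col)) {
    feature_col <- intersect(c("compound", "lipid", "amino_acid", "feature"),
                             names(block))[1]
    if (is.na(feature_col)) {
      abort("cannot find a feature-name column (compound/lipid/amino_acid/feature)")
    }
  }
  m <- as.matrix(block[, setdiff(names(block), feature_col)])
  storage.mode(m) <- "double"
  rownames(m) <- block[[feature_col]]
  m
}

#' Pearson block correlation
#'
#' Correlates every feature of `block_a` against every feature of
#' `block_b` over their shared samples, on pairwise-complete observations.
#' Zero-variance features carry no correlation information and are
#' excluded with a message. With very few samples (n = 4 replicate hams is
#' typical) p-values are reported but flagged low-power.
#'
#' @param block_a,block_b Feature-by-sample blocks: data frames whose
#'   first/feature column is `compound`, `lipid`, `amino_acid` or
#'   `feature`, or numeric matrices with feature rownames and sample
#'   colnames.
#' @param method Only "pearson" is defined.
#' @param adjust "bh" (Benjamini-Hochberg, default) or "none".
#' @return A tibble: feature_a, feature_b, r, n, p_value, p_adjusted,
#'   sign; attribute `excluded` lists zero-variance features.
#' @export
#' @examples
#' a <- matrix(1:8, 2, 4, dimnames = list(c("x", "y"), paste0("S", 1:4)))
#' block_correlate(a, a)
block_correlate <- function(block_a, block_b, method = "pearson",
                            adjust = c("bh", "none")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  a <- block_matrix(block_a); b <- block_matrix(block_b)
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) < 3) {
    abort(sprintf("only %d shared sample(s); need at least 3",
                  length(shared)))
  }
  a <- a[, shared, drop = FALSE]; b <- b[, shared, drop = FALSE]
  zero_var <- function(m) {
    apply(m, 1, function(x) {
      x <- x[!is.na(x)]
      length(x) < 2 || stats::sd(x) == 0
    })
  }
  za <- zero_var(a); zb <- zero_var(b)
  excluded <- c(rownames(a)[za], rownames(b)[zb])
  if (length(excluded)) {
    inform(sprintf("excluded %d zero-variance feature(s): %s",
                   length(excluded), paste(excluded, collapse = ", ")))
  }
  a <- a[!za, , drop = FALSE]; b <- b[!zb, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("no features left after zero-variance exclusion")
  }
  if (length(shared) <= 5) {
    inform(sprintf(
      "n = %d shared samples: p-values have low power at this sample size",
      length(shared)))
  }
  pairs <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)),
                       KEEP.OUT.ATTRS = FALSE)
  res <- purrr::pmap_dfr(pairs, function(ia, ib) {
    x <- a[ia, ]; y <- b[ib, ]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3) {
      return(tibble(feature_a = rownames(a)[ia], feature_b = rownames(b)[ib],
                    r = NA_real_, n = n, p_value = NA_real_))
    }
    r <- stats::cor(x[ok], y[ok])
    p <- if (abs(r) >= 1) 0 else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tval), df = n - 2)
    }
    tibble(feature_a = rownames(a)[ia], feature_b = rownames(b)[ib],
           r = r, n = n, p_value = p)
  })
  suppressed <- sum(is.na(res$r))
  if (suppressed) {
    inform(sprintf("%d pair(s) with fewer than 3 complete observations suppressed",
                   suppressed))
    res <- res[!is.na(res$r), , drop = FALSE]
  }
  res$p_adjusted <- if (adjust == "bh") {
    stats::p.adjust(res$p_value, method = "BH")
  } else res$p_value
  res$sign <- ifelse(res$r > 0, "positive",
                     ifelse(res$r < 0, "negative", "zero"))
  attr(res, "excluded") <- excluded
  res
}

#' Correlation results as heatmap-ready matrices
#'
#' Pivots long-form correlation results into a rectangular r matrix
#' (rows = feature_a, columns = feature_b, order preserved from the
#' results, no clustering) plus a companion adjusted-p matrix.
#'
#' @param results Output of [block_correlate()].
#' @return A list with matrices `r` and `p_adjusted`.
#' @export
correlation_matrix <- function(results) {
  ra <- unique(results$feature_a); rb <- unique(results$feature_b)
  r <- matrix(NA_real_, length(ra), length(rb), dimnames = list(ra, rb))
  p <- r
  idx <- cbind(match(results$feature_a, ra), match(results$feature_b, rb))
  r[idx] <- results$r
  p[idx] <- results$p_adjusted
  list(r = r, p_adjusted = p)
}
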