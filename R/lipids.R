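# Shorthand lipid nomenclature: parsing, canonical formatting, category
# assignment and abundance aggregation.
#
# Grammar accepted by parse_lipid():
#   Name      := ClassCode '(' ChainSpec (Sep ChainSpec)* ')'
#   Sep       := '_' (sn positions unknown) | '/' (sn positions known)
#   ChainSpec := [ 'O-' | 'P-' ] carbons ':' double_bonds ( ';' token )*
# where a token like "O", "2O", "O2", "3O" counts extra oxygens
# (hydroxyl/oxo modifications) and any other token (e.g. the occasional
# "T") is preserved verbatim rather than rejected. A name with a single
# ChainSpec and no separator is a sum-composition (species-level) name.
# Whitespace after ':' and ';', as introduced by typesetting, is stripped.

#' Default lipid class-code registry
#'
#' Maps shorthand class codes to the six top-level lipid categories:
#' GL glycerolipids (including the betaine lipids DGCC/DGTS and the
#' glycosyldiacylglycerols), GP glycerophospholipids, SP sphingolipids,
#' FA fatty acyls, ST sterol lipids and PR prenol lipids. PE-Cer is a
#' ceramide backbone and sits under SP; NAGly (N-acyl glycine) and FAHFA
#' sit under FA following the LIPID MAPS convention. Override any
#' assignment by passing a modified copy to the `registry` arguments.
#'
#' @return Named character vector: class code -> category.
#' @export
default_lipid_registry <- function() {
  c(
    TG = "GL", DG = "GL", MG = "GL", DGCC = "GL", DGTS = "GL",
    MGDG = "GL", DGDG = "GL",
    PC = "GP", PE = "GP", PS = "GP", PI = "GP", PG = "GP", PA = "GP",
    SM = "SP", Cer = "SP", HexCer = "SP", SHexCer = "SP", `PE-Cer` = "SP",
    FAHFA = "FA", NAGly = "FA", FA = "FA",
    ST = "ST", CE = "ST", SE = "ST",
    PR = "PR"
  )
}

#' Assign a lipid class code to its category
#'
#' @param class_code Shorthand class code, e.g. "TG".
#' @param registry Code -> category map; default [default_lipid_registry()].
#' @param lenient If `TRUE`, unregistered codes return "unknown" instead of
#'   erroring.
#' @return Category string.
#' @export
#' @examples
#' categorize("SM")  # "SP"
categorize <- function(class_code, registry = default_lipid_registry(),
                       lenient = FALSE) {
  hit <- registry[class_code]
  if (anyNA(hit)) {
    if (lenient) {
      hit[is.na(hit)] <- "unknown"
    } else {
      abort(sprintf(
        "unknown lipid class code \"%s\"; registered codes: %s",
        paste(class_code[is.na(hit)], collapse = ", "),
        paste(names(registry), collapse = ", ")))
    }
  }
  unname(hit)
}

parse_oxy_token <- function(tok) {
  # returns extra-oxygen count or NA when the token is not an oxygen count
  if (grepl("^[0-9]*O$", tok)) {
    n <- sub("O$", "", tok)
    return(if (nzchar(n)) as.integer(n) else 1L)
  }
  if (grepl("^O[0-9]+$", tok)) return(as.integer(sub("^O", "", tok)))
  NA_integer_
}

parse_chain_spec <- function(spec, raw_name, offset) {
  m <- regmatches(spec, regexec("^(O-|P-)?([0-9]+):([0-9]+)(.*)$", spec))[[1]]
  if (length(m) == 0L) {
    abort(sprintf("malformed chain \"%s\" in \"%s\" (at character %d)",
                  spec, raw_name, offset))
  }
  carbons <- as.integer(m[3]); dbs <- as.integer(m[4])
  if (dbs > carbons) {
    abort(sprintf("chain \"%s\" in \"%s\": %d double bonds exceed %d carbons",
                  spec, raw_name, dbs, carbons))
  }
  extra_ox <- 0L; extra_tokens <- character(0)
  rest <- m[5]
  if (nzchar(rest)) {
    if (!startsWith(rest, ";")) {
      abort(sprintf("malformed chain \"%s\" in \"%s\" (at character %d)",
                    spec, raw_name, offset))
    }
    for (tok in strsplit(sub("^;", "", rest), ";", fixed = TRUE)[[1]]) {
      n <- parse_oxy_token(tok)
      if (is.na(n)) extra_tokens <- c(extra_tokens, tok) else
        extra_ox <- extra_ox + n
    }
  }
  list(carbons = carbons, double_bonds = dbs,
       ether_prefix = if (is.na(m[2]) || !nzchar(m[2])) "none" else m[2],
       extra_oxygens = extra_ox, extra_tokens = extra_tokens)
}

#' Parse a shorthand lipid name
#'
#' Parses names like `TG(13:1_20:0_20:0)`, `PC(O-34:3)`,
#' `Cer(15:1;2O/26:5)` or `ST(24:1;O3;T/20:1)` into a structured record:
#' class code, category, individual chains (or sum composition), ether
#' prefixes, extra-oxygen counts and any unrecognized suffix tokens
#' (preserved verbatim). Spaces after ":" and ";" are treated as
#' typography and stripped.
#'
#' @param name One shorthand lipid name.
#' @param registry Class-code registry, see [default_lipid_registry()].
#' @param lenient Passed to [categorize()].
#' @return An object of class `lipid_species`: a list with raw_name,
#'   class_code, category, chains, sum_carbons, sum_double_bonds,
#'   sum_extra_oxygens, ether_prefix, sn_positions_known,
#'   is_sum_composition, extra_tokens.
#' @export
#' @examples
#' sp <- parse_lipid("TG(13:1_20:0_20:0)")
#' sp$sum_carbons  # 53
parse_lipid <- function(name, registry = default_lipid_registry(),
                        lenient = FALSE) {
  stopifnot(length(name) == 1L)
  raw <- name
  x <- gsub("\\s+", "", name)
  m <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9-]*?)\\((.*)\\)$", x))[[1]]
  if (length(m) == 0L) {
    abort(sprintf("cannot parse \"%s\": expected ClassCode(...)", raw))
  }
  class_code <- m[2]
  category <- categorize(class_code, registry, lenient = lenient)
  inner <- m[3]
  if (!nzchar(inner)) abort(sprintf("empty chain list in \"%s\"", raw))
  has_slash <- grepl("/", inner, fixed = TRUE)
  has_under <- grepl("_", inner, fixed = TRUE)
  specs <- strsplit(inner, "[/_]")[[1]]
  offsets <- cumsum(c(nchar(class_code) + 2L,
                      utils::head(nchar(specs) + 1L, -1L)))
  chains <- Map(parse_chain_spec, specs, MoreArgs = list(raw_name = raw),
                offset = offsets)
  chains <- unname(chains)
  sum_comp <- length(chains) == 1L && !has_slash && !has_under
  sn_known <- has_slash && !has_under
  structure(list(
    raw_name = raw,
    class_code = class_code,
    category = category,
    chains = if (sum_comp) list() else chains,
    sum_carbons = sum(vapply(chains, `[[`, integer(1), "carbons")),
    sum_double_bonds = sum(vapply(chains, `[[`, integer(1), "double_bonds")),
    sum_extra_oxygens = sum(vapply(chains, `[[`, integer(1), "extra_oxygens")),
    ether_prefix = {
      pref <- vapply(chains, `[[`, character(1), "ether_prefix")
      if (any(pref != "none")) pref[pref != "none"][1] else "none"
    },
    sn_positions_known = sn_known,
    is_sum_composition = sum_comp,
    extra_tokens = unlist(lapply(chains, `[[`, "extra_tokens")),
    .sum_spec = if (sum_comp) chains[[1]] else NULL
  ), class = "lipid_species")
}

format_chain_spec <- function(ch) {
  out <- paste0(if (ch$ether_prefix != "none") ch$ether_prefix else "",
                ch$carbons, ":", ch$double_bonds)
  if (ch$extra_oxygens > 0) {
    out <- paste0(out, ";",
                  if (ch$extra_oxygens == 1L) "O" else
                    paste0(ch$extra_oxygens, "O"))
  }
  for (tok in ch$extra_tokens) out <- paste0(out, ";", tok)
  out
}

#' Canonical shorthand form of a parsed lipid
#'
#' Renders a `lipid_species` back to compact shorthand (no whitespace,
#' oxygen counts normalized to the "nO" digit-first style). The round trip
#' `parse_lipid(format_lipid(x))` is structurally identical to `x`.
#'
#' @param species A `lipid_species` from [parse_lipid()].
#' @return Canonical name string.
#' @export
#' @examples
#' format_lipid(parse_lipid("TG(13: 1_20: 0_20: 0)"))  # "TG(13:1_20:0_20:0)"
format_lipid <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  chains <- if (species$is_sum_composition) list(species$.sum_spec) else
    species$chains
  sep <- if (species$sn_positions_known) "/" else "_"
  paste0(species$class_code, "(",
         paste(vapply(chains, format_chain_spec, character(1)),
               collapse = sep), ")")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s  [%s / %s]  C%d:%d",
              format_lipid(x), x$category, x$class_code,
              x$sum_carbons, x$sum_double_bonds))
  if (x$sum_extra_oxygens > 0) cat(sprintf(" +%dO", x$sum_extra_oxygens))
  if (length(x$extra_tokens)) {
    cat(sprintf("  (unparsed: %s)", paste(x$extra_tokens, collapse = ",")))
  }
  cat("\n")
  invisible(x)
}

#' Annotate a vector of lipid names
#'
#' Vectorized wrapper around [parse_lipid()] returning one row per name.
#'
#' @param names Character vector of shorthand names.
#' @inheritParams parse_lipid
#' @return A tibble: lipid, class_code, category, n_chains, sum_carbons,
#'   sum_double_bonds, sum_extra_oxygens, ether_prefix,
#'   sn_positions_known, is_sum_composition, extra_tokens.
#' @export
annotate_lipids <- function(names, registry = default_lipid_registry(),
                            lenient = FALSE) {
  rows <- lapply(names, function(nm) {
    sp <- parse_lipid(nm, registry, lenient = lenient)
    tibble(
      lipid = nm,
      canonical = format_lipid(sp),
      class_code = sp$class_code,
      category = sp$category,
      n_chains = length(sp$chains),
      sum_carbons = sp$sum_carbons,
      sum_double_bonds = sp$sum_double_bonds,
      sum_extra_oxygens = sp$sum_extra_oxygens,
      ether_prefix = sp$ether_prefix,
      sn_positions_known = sp$sn_positions_known,
      is_sum_composition = sp$is_sum_composition,
      extra_tokens = paste(sp$extra_tokens, collapse = ";")
    )
  })
  dplyr::bind_rows(rows)
}

#' Abundance shares by lipid category or class
#'
#' Parses every species name, groups by category or class code, and
#' reports the per-group percentage of total abundance (computed within
#' each sample, then averaged over samples) together with species counts.
#' Shares sum to 100 at each level.
#'
#' @param table Lipid table: `lipid` column + numeric sample columns.
#' @param level "category" (default) or "class_code".
#' @param registry Class-code registry.
#' @return A tibble: group, n_species, share_percent (descending share).
#' @export
class_shares <- function(table, level = c("category", "class_code"),
                         registry = default_lipid_registry()) {
  level <- match.arg(level)
  ann <- annotate_lipids(table$lipid, registry)
  grp <- ann[[level]]
  samp_cols <- setdiff(names(table), "lipid")
  m <- as.matrix(table[, samp_cols]); storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) abort("abundances must be non-negative")
  groups <- sort(unique(grp))
  per_sample <- vapply(seq_along(samp_cols), function(j) {
    col <- m[, j]
    tot <- sum(col, na.rm = TRUE)
    if (tot == 0) return(stats::setNames(rep(0, length(groups)), groups))
    s <- tapply(col, factor(grp, levels = groups), sum, na.rm = TRUE)
    s[is.na(s)] <- 0
    as.numeric(s) / tot * 100
  }, numeric(length(groups)))
  per_sample <- matrix(per_sample, nrow = length(groups),
                       dimnames = list(groups, samp_cols))
  share <- rowMeans(per_sample)
  counts <- table(grp)
  out <- tibble(
    group = names(share),
    n_species = as.integer(counts[names(share)]),
    share_percent = as.numeric(share)
  )
  dplyr::arrange(out, dplyr::desc(.data$share_percent))
}

#' Select key lipids by mean abundance
#'
#' Ranks species by mean relative abundance across samples and returns the
#' top `top_n` (default 14), with deterministic name tie-breaks.
#'
#' @param table Lipid table (`lipid` column + sample columns).
#' @param top_n Number of species to keep.
#' @param method Ranking statistic; only "mean_abundance" is defined.
#' @return A tibble: rank, lipid, mean_abundance.
#' @export
select_key_lipids <- function(table, top_n = 14,
                              method = "mean_abundance") {
  method <- match.arg(method)
  top_n <- check_count(top_n, "top_n")
  samp_cols <- setdiff(names(table), "lipid")
  m <- as.matrix(table[, samp_cols]); storage.mode(m) <- "double"
  means <- rowMeans(m, na.rm = TRUE)
  if (top_n > nrow(table)) {
    warn(sprintf("top_n = %d exceeds the %d available species; returning all",
                 top_n, nrow(table)))
    top_n <- nrow(table)
  }
  ord <- order(-means, table$lipid)
  idx <- ord[seq_len(top_n)]
  tibble(rank = seq_len(top_n),
         lipid = table$lipid[idx],
         mean_abundance = as.numeric(means[idx]))
}
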