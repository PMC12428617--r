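test_that("all 14 key lipid names parse, check chain sums, and round-trip", {
  expected_cat <- c("GL", "GL", "GL", "GL", "GP", "SP", "SP", "SP",
                    "FA", "FA", "SP", "GL", "GL", "ST")
  for (i in seq_along(paper_key_lipid_names())) {
    nm <- paper_key_lipid_names()[i]
    sp <- parse_lipid(nm)
    expect_equal(sp$category, expected_cat[i], info = nm)
    if (!sp$is_sum_composition) {
      expect_equal(sp$sum_carbons,
                   sum(vapply(sp$chains, `[[`, integer(1), "carbons")),
                   info = nm)
      expect_equal(sp$sum_double_bonds,
                   sum(vapply(sp$chains, `[[`, integer(1), "double_bonds")),
                   info = nm)
    }
    canon <- format_lipid(sp)
    expect_false(grepl(" ", canon, fixed = TRUE))
    rt <- parse_lipid(canon)
    rt$raw_name <- sp$raw_name  # raw spelling is the only allowed difference
    expect_equal(rt, sp, info = nm)
  }
})

test_that("parser extracts structure fields faithfully", {
  tg <- parse_lipid("TG(13:1_20:0_20:0)")
  expect_equal(tg$class_code, "TG")
  expect_equal(tg$category, "GL")
  expect_equal(length(tg$chains), 3L)
  expect_equal(tg$sum_carbons, 53L)
  expect_equal(tg$sum_double_bonds, 1L)
  expect_false(tg$sn_positions_known)

  pc <- parse_lipid("PC(O-34:3)")
  expect_true(pc$is_sum_composition)
  expect_equal(length(pc$chains), 0L)
  expect_equal(pc$sum_carbons, 34L)
  expect_equal(pc$sum_double_bonds, 3L)
  expect_equal(pc$ether_prefix, "O-")

  cer <- parse_lipid("Cer(15:1;2O/26:5)")
  expect_equal(cer$category, "SP")
  expect_equal(length(cer$chains), 2L)
  expect_equal(cer$chains[[1]]$extra_oxygens, 2L)
  expect_equal(cer$chains[[2]]$extra_oxygens, 0L)
  expect_true(cer$sn_positions_known)

  # "O2" and "2O" dialects mean the same oxygen count
  expect_equal(parse_lipid("Cer(15:1;O2/26:5)")$sum_extra_oxygens,
               parse_lipid("Cer(15:1;2O/26:5)")$sum_extra_oxygens)

  # uninterpretable suffix tokens survive without failing the parse
  st <- parse_lipid("ST(24:1;O3;T/20:1)")
  expect_equal(st$sum_extra_oxygens, 3L)
  expect_equal(st$extra_tokens, "T")
})

test_that("parser rejects malformed input with useful errors", {
  expect_error(parse_lipid("XX(16:0)"), "registered codes")
  expect_equal(parse_lipid("XX(16:0)", lenient = TRUE)$category, "unknown")
  expect_error(parse_lipid("TG(16:0_bad)"), "character")
  expect_error(parse_lipid("TG(2:5)"), "double bonds exceed")
  expect_error(parse_lipid("TG"), "ClassCode")
  expect_error(parse_lipid("TG()"), "empty chain")
})

test_that("categorize maps codes per the default registry and is overridable", {
  expect_equal(categorize("TG"), "GL")
  expect_equal(categorize("SM"), "SP")
  expect_equal(categorize("NAGly"), "FA")
  expect_equal(categorize("PE-Cer"), "SP")
  expect_equal(categorize("NAGly", registry = c(NAGly = "GP")), "GP")
  expect_error(categorize("nope"), "registered codes")
})

test_that("1000 grammar-fuzzed names round-trip through parse/format", {
  w <- stats::setNames(rep(1, length(default_lipid_registry())),
                       names(default_lipid_registry()))
  lt <- generate_lipid_table(1000, w, seed = 404)
  for (nm in lt$lipid) {
    sp <- parse_lipid(nm)
    rt <- parse_lipid(format_lipid(sp))
    rt$raw_name <- sp$raw_name
    expect_equal(rt, sp, info = nm)
  }
})

test_that("class shares sum to 100 at both levels and split abundance correctly", {
  tab <- tibble::tibble(lipid = c("TG(16:0_18:1_18:0)", "PC(34:2)"),
                        S1 = c(1, 3), S2 = c(1, 3))
  by_cat <- class_shares(tab, "category")
  expect_equal(sort(by_cat$share_percent), c(25, 75))
  expect_equal(by_cat$group[by_cat$share_percent == 75], "GP")
  expect_equal(sum(by_cat$share_percent), 100)
  by_class <- class_shares(tab, "class_code")
  expect_equal(sum(by_class$share_percent), 100)

  one <- class_shares(tibble::tibble(lipid = "SM(18:1;2O/16:0)", S1 = 4))
  expect_equal(one$share_percent, 100)

  # generator round-trip: shares track the planted weights
  w <- c(TG = 25.29, DG = 13.43, DGCC = 8.47, DGTS = 6.26, MGDG = 6.06)
  big <- generate_lipid_table(10000, w, seed = 31, n_samples = 2)
  got <- class_shares(big, "class_code")
  for (code in names(w)) {
    expect_lt(abs(got$share_percent[got$group == code] - 100 * w[[code]] / sum(w)),
              3)
  }
})

test_that("key-lipid selection ranks by mean abundance with name tie-breaks", {
  tab <- tibble::tibble(lipid = c("TG(16:0_18:1_18:0)", "PC(34:2)",
                                  "DG(16:0_18:1)"),
                        S1 = c(5, 1, 3), S2 = c(5, 1, 3))
  top <- select_key_lipids(tab, 2)
  expect_equal(top$lipid, c("TG(16:0_18:1_18:0)", "DG(16:0_18:1)"))
  expect_equal(top$rank, 1:2)

  all_ranked <- select_key_lipids(tab, 3)
  expect_equal(all_ranked$mean_abundance, c(5, 3, 1))

  expect_warning(over <- select_key_lipids(tab, 10), "exceeds")
  expect_equal(nrow(over), 3)

  # planted abundance order is recovered from a noiseless table
  planted <- tibble::tibble(lipid = sprintf("TG(%d:0_18:0_18:0)", 10:14),
                            S1 = 5:1, S2 = 5:1)
  expect_equal(select_key_lipids(planted, 5)$lipid, planted$lipid)
})
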