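test_that("the standard is the compound with maximal C%/T", {
  recs <- table1_records()
  expect_equal(select_standard(recs), "1-Octen-3-ol")

  single <- recs[1, ]
  expect_equal(select_standard(single), single$compound)

  two <- tibble::tibble(compound = c("a", "b"), c_percent = c(2, 10),
                        threshold_ug_per_kg = c(1, 100))
  expect_equal(select_standard(two), "a")

  expect_error(select_standard(recs[0, ]), "no annotated")
  expect_message(
    tie <- select_standard(tibble::tibble(
      compound = c("zeta", "alpha"), c_percent = c(1, 1),
      threshold_ug_per_kg = c(2, 2))),
    "tie")
  expect_equal(tie, "alpha")
})

test_that("ROAV follows the ratio formula and fixes the standard at 100", {
  recs <- table1_records()
  out <- compute_roav(recs)
  expect_equal(out$roav[out$compound == "1-Octen-3-ol"], 100)
  expect_equal(sum(out$is_standard), 1L)
  expect_true(all(out$roav <= 100 + 1e-9))
  # hexanal: 100 * (4.6181/4.2624) * (1.00/4.00)
  expect_equal(out$roav[out$compound == "Hexanal"],
               100 * (4.6181 / 4.2624) / 4, tolerance = 1e-12)

  # self-ratio and factor arithmetic
  toy <- tibble::tibble(compound = c("std", "same", "quarter"),
                        c_percent = c(4, 4, 2),
                        threshold_ug_per_kg = c(1, 1, 2))
  r <- compute_roav(toy, "std")
  expect_equal(r$roav, c(100, 100, 25))

  expect_error(compute_roav(
    tibble::tibble(compound = "x", c_percent = 1,
                   threshold_ug_per_kg = 0)), "x")
})

test_that("ROAV is invariant to positive rescaling of all C% values", {
  recs <- table1_records()
  scaled <- recs
  scaled$c_percent <- scaled$c_percent * 7.3
  expect_equal(compute_roav(scaled)$roav, compute_roav(recs)$roav)
})

test_that("select + compute match a direct two-line recomputation", {
  set.seed(77)
  for (k in 1:50) {
    n <- sample(2:10, 1)
    recs <- tibble::tibble(
      compound = sprintf("v%02d", seq_len(n)),
      c_percent = runif(n, 0.001, 10),
      threshold_ug_per_kg = 10^runif(n, -2, 4))
    ratio <- recs$c_percent / recs$threshold_ug_per_kg
    expect_equal(select_standard(recs), recs$compound[which.max(ratio)])
    expect_equal(compute_roav(recs)$roav, 100 * ratio / max(ratio))
  }
})

test_that("contribution bands use the stated closed/half-open boundaries", {
  recs <- tibble::tibble(compound = letters[1:5],
                         roav = c(100, 1, 0.999, 0.1, 0.0999))
  got <- classify_contribution(recs)
  expect_equal(as.character(got$category),
               c("characteristic", "characteristic", "modifier",
                 "modifier", "negligible"))
  # idempotent
  expect_equal(classify_contribution(got)$category, got$category)
})

test_that("the reference table yields 15 characteristic compounds, not the prose 28", {
  # The published narrative calls all 28 tabulated compounds characteristic,
  # but applying the stated ROAV >= 1 rule to the tabulated scores gives 15;
  # the package reports the rule's result and documents the inconsistency.
  recs <- table1_records()
  n_printed <- sum(recs$roav_reported >= 1)
  expect_identical(n_printed, 15L)
  got <- classify_contribution(compute_roav(recs))
  expect_identical(sum(got$category == "characteristic"), 15L)
  expect_identical(nrow(recs), 28L)
})

test_that("largest-remainder shares sum to 100 with the documented tie rule", {
  expect_equal(largest_remainder_shares(c(a = 1, b = 1, c = 1)),
               c(a = 34L, b = 33L, c = 33L))
  expect_equal(largest_remainder_shares(c(solo = 9)), c(solo = 100L))

  # the published volatile-class counts: remainder tie between ester (12.5)
  # and other (17.5) resolves to the larger count
  shares <- largest_remainder_shares(
    c(aldehyde = 15, alcohol = 19, ketone = 9, ester = 10, acid = 13,
      other = 14))
  expect_equal(shares,
               c(aldehyde = 19L, alcohol = 24L, ketone = 11L, ester = 12L,
                 acid = 16L, other = 18L))
  expect_equal(sum(shares), 100L)

  set.seed(5)
  for (k in 1:30) {
    counts <- sample(1:40, sample(2:8, 1), replace = TRUE)
    names(counts) <- paste0("g", seq_along(counts))
    expect_equal(sum(largest_remainder_shares(counts)), 100L)
  }
})

test_that("class composition counts classes and carries exact shares", {
  recs <- table1_records()
  cc <- class_composition(recs)
  expect_equal(sum(cc$count), 28L)
  expect_equal(sum(cc$percent_share), 100L)
  expect_equal(cc$count[cc$chemical_class == "aldehyde"], 6L)
  expect_equal(cc$count[cc$chemical_class == "alcohol"], 8L)

  # character-vector entry point and unmapped fallback
  expect_equal(class_composition(c("x", "x", "y"))$count, c(2L, 1L))
  mapped <- suppressMessages(class_composition(
    tibble::tibble(compound = c("a", "b")), classes = c(a = "ester")))
  expect_equal(sort(mapped$chemical_class), c("ester", "other"))
})
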