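test_that("detection-rate filter uses the strict > cutoff by default", {
  m <- rbind(c(1, 1, 1, 1),    # 4/4 -> retained
             c(1, 1, NA, NA),  # 2/4 = 0.5 -> removed under strict >
             c(1, 1, 1, NA))   # 3/4 -> retained
  pt <- peaks_from_matrix(m, c("full", "half", "threequarter"))
  kept <- detection_rate_filter(pt)
  expect_equal(kept$compound, c("full", "threequarter"))
  report <- attr(kept, "report")
  expect_equal(report$detection_rate, c(1, 0.5, 0.75))
  # inclusive toggle admits the boundary case
  expect_equal(detection_rate_filter(pt, inclusive = TRUE)$compound,
               pt$compound)
})

test_that("CV filter computes sd/mean over detected replicates, strict <", {
  m <- rbind(c(10, 10, 10, 10),   # CV 0 -> retained
             c(1, 1, 1, 100),     # CV = 49.5/25.75 -> removed
             c(90, 100, 110, NA)) # CV = 0.1 -> retained
  pt <- peaks_from_matrix(m, c("flat", "spiky", "mild"))
  kept <- cv_filter(pt)
  expect_equal(kept$compound, c("flat", "mild"))
  rep <- attr(kept, "report")
  expect_equal(rep$cv, c(0, 49.5 / 25.75, 0.1))
})

test_that("single-detection compounds have undefined CV and are removed", {
  m <- rbind(c(5, NA, NA, NA), c(1, 1, 1, 1))
  pt <- peaks_from_matrix(m, c("lonely", "ok"))
  expect_message(kept <- cv_filter(pt), "single detected replicate")
  expect_equal(kept$compound, "ok")
})

test_that("relative content is proportional, sums to 100, scale-invariant", {
  pt <- peaks_from_matrix(rbind(c(3, 3), c(1, 1)), c("a", "b"))
  rc <- relative_content(pt)
  expect_equal(rc$c_percent, c(75, 25))
  one <- relative_content(peaks_from_matrix(rbind(c(2, 2)), "solo"))
  expect_equal(one$c_percent, 100)

  scaled <- pt
  scaled[, -1] <- scaled[, -1] * 1000
  expect_equal(relative_content(scaled)$c_percent, rc$c_percent)
})

test_that("screening statistics are invariant to sample-column permutation", {
  set.seed(14)
  m <- matrix(rlnorm(40, meanlog = 2, sdlog = 0.2), 10, 4)
  m[sample(length(m), 6)] <- NA
  pt <- peaks_from_matrix(m)
  perm <- pt[, c(1, 4, 2, 5, 3)]
  names(perm) <- names(pt)
  expect_equal(suppressMessages(screen_peaks(pt)),
               suppressMessages(screen_peaks(perm)))
})

test_that("the two screening filters commute", {
  set.seed(8)
  for (k in 1:20) {
    m <- matrix(rlnorm(32, meanlog = 2, sdlog = runif(1, 0, 0.6)), 8, 4)
    m[runif(length(m)) < 0.25] <- NA
    pt <- peaks_from_matrix(m)
    ab <- suppressMessages(suppressWarnings(
      cv_filter(detection_rate_filter(pt))))
    ba <- suppressMessages(suppressWarnings(
      detection_rate_filter(cv_filter(pt))))
    expect_equal(ab$compound, ba$compound)
  }
})

test_that("screening matches an independent brute-force recomputation", {
  set.seed(300)
  for (k in 1:100) {
    n <- sample(2:20, 1)
    m <- matrix(rlnorm(n * 4, meanlog = 3, sdlog = runif(1, 0.05, 0.8)),
                n, 4)
    m[runif(length(m)) < 0.2] <- NA
    m <- m[rowSums(!is.na(m)) > 0, , drop = FALSE]
    if (nrow(m) == 0) next
    oracle <- brute_force_screen(m)
    if (!any(oracle$keep)) {
      # empty survivors propagate as an empty record set, not an error
      empty <- suppressWarnings(suppressMessages(
        screen_peaks(peaks_from_matrix(m))))
      expect_equal(nrow(empty), 0L)
      next
    }
    got <- suppressMessages(suppressWarnings(
      screen_peaks(peaks_from_matrix(m))))
    expect_equal(got$compound,
                 sprintf("c%02d", which(oracle$keep)))
    expect_equal(got$c_percent, oracle$c_percent)
    expect_equal(sum(got$c_percent), 100)
  }
})

test_that("threshold join is an inner join that never renormalizes C%", {
  screened <- tibble::tibble(
    compound = c("Hexanal", "unknown_X"),
    n_detected = c(4L, 4L), detection_rate = c(1, 1), cv = c(0.1, 0.1),
    mean_area = c(10, 5), c_percent = c(200 / 3, 100 / 3))
  db <- tibble::tibble(compound = "hexanal", threshold_ug_per_kg = 4,
                       chemical_class = "aldehyde", descriptor = "grassy")
  ann <- suppressMessages(join_thresholds(screened, db))
  expect_equal(nrow(ann), 1)
  expect_equal(ann$c_percent, 200 / 3)  # not bumped back to 100
  expect_equal(attr(ann, "dropped"), "unknown_X")

  # synonym-aware matching joins alias spellings
  db2 <- tibble::tibble(compound = "Butanoic acid, ethyl ester",
                        threshold_ug_per_kg = 0.1)
  s2 <- screened
  s2$compound <- c("ethyl butyrate", "other")
  ann2 <- suppressMessages(join_thresholds(s2, db2))
  expect_equal(nrow(ann2), 1)

  expect_error(join_thresholds(
    screened, tibble::tibble(compound = c("Hexanal", "hexanal"),
                             threshold_ug_per_kg = c(4, 4))),
    "duplicate")
  empty <- suppressMessages(join_thresholds(
    screened, tibble::tibble(compound = character(0),
                             threshold_ug_per_kg = numeric(0))))
  expect_equal(nrow(empty), 0)
  expect_equal(sort(attr(empty, "dropped")), sort(screened$compound))
})

test_that("kovats retention indices interpolate linearly on the ladder", {
  ladder <- c(`10` = 5.0, `11` = 6.0, `12` = 6.8)
  expect_equal(kovats_ri(5.0, ladder), 1000)
  expect_equal(kovats_ri(5.5, ladder), 1050)
  expect_equal(kovats_ri(5.25, ladder), 1025)
  expect_equal(kovats_ri(6.8, ladder), 1200)
  expect_error(kovats_ri(4.0, ladder), "not bracketed")
  expect_error(kovats_ri(5, c(`10` = 5, `11` = 4)), "increase")
})
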