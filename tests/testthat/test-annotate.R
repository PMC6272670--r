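lib <- build_library()

test_that("spectrum construction sorts, deduplicates and validates peaks", {
  s <- ms2_spectrum(400, c(300.2, 100.1, 100.10004), c(1, 2, 5))
  expect_equal(nrow(s$peaks), 2)  # duplicates at 4 dp collapse
  expect_equal(s$peaks$mz[1], 100.10004)  # more intense centroid kept
  expect_true(!is.unsorted(s$peaks$mz))
  expect_error(ms2_spectrum(100, c(50, 200)), "precursor")
  expect_error(ms2_spectrum(400, c(-1, 100)), "positive")
  expect_error(ms2_spectrum(400, 100, intensity = -5), "non-negative")
})

test_that("peak matching pairs expected ions with nearest peaks", {
  s <- ms2_spectrum(390, c(137.0599, 163.0755, 223.0973))
  expected <- data.frame(label = c("[A]+", "[B]+", "[M+H-A]+"),
                         mz = c(137.0603, 163.0754, 223.0970))
  ev <- match_peaks(s, expected, tol_mda = 10)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$ppm[ev$label == "[A]+"], -2.92)
  # empty spectrum gives empty evidence
  expect_equal(nrow(match_peaks(ms2_spectrum(390, numeric(0)),
                                expected, 10)), 0)
  # one peak between two close expected ions is used exactly once
  s1 <- ms2_spectrum(390, 200.0003)
  two <- data.frame(label = c("x", "y"), mz = c(200.0000, 200.0005))
  ev1 <- match_peaks(s1, two, tol_mda = 10)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$label, "y")  # nearer expected ion wins
})

test_that("greedy matching equals the exhaustive oracle in-regime", {
  # instances drawn like real spectra: expected ions separated by much more
  # than the tolerance, peaks = subset of ions + noise + decoys
  set.seed(31)
  for (i in 1:40) {
    ne <- sample(2:5, 1)
    expected_mz <- sort(100 + cumsum(runif(ne, 0.05, 50)))
    present <- sample(ne, sample(1:ne, 1))
    peaks <- expected_mz[present] + rnorm(length(present), 0, 0.002)
    peaks <- c(peaks, runif(sample(0:2, 1), 100, 400))
    s <- ms2_spectrum(500, peaks)
    expected <- data.frame(label = paste0("e", seq_len(ne)),
                           mz = expected_mz)
    ev <- match_peaks(s, expected, tol_mda = 10)
    oracle <- exhaustive_match_count(expected_mz, s$peaks$mz, 10)
    expect_equal(nrow(ev), oracle$count)
    expect_equal(sum(abs(ev$mda)) / 1000, oracle$dev, tolerance = 1e-9)
  }
})

test_that("evidence count is non-decreasing in the match tolerance", {
  s <- simulate_spectrum(lib[[18]], "[M+Na]+",
                         sim_config(seed = 5, sigma_mass_mda = 4))
  expected <- diagnostic_fragments(lib[[18]], "[M+Na]+")
  counts <- vapply(c(1, 2, 5, 10, 20), function(tol) {
    nrow(match_peaks(s, expected, tol))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("neutral-loss detection finds sugar ladders and small losses", {
  # two sequential glucose losses from a sodiated di-glucoside
  s20 <- ms2_spectrum(721.2309, c(559.1743, 397.1295), adduct = "[M+Na]+")
  nl <- detect_neutral_losses(s20)
  glc <- nl[nl$loss == "Glc", ]
  expect_equal(nrow(glc), 2)
  expect_equal(glc$parent_mz, c(721.2309, 559.1743))
  # rhamnose then glucose from the flavonoid neohesperidoside
  s25 <- ms2_spectrum(579.1719, c(433.1125, 271.0605), adduct = "[M+H]+")
  nl25 <- detect_neutral_losses(s25)
  expect_equal(nl25$loss[nl25$parent_mz == 579.1719], "Rha")
  expect_true(any(nl25$loss == "Glc" & nl25$parent_mz == 433.1125))
  # a sugar difference between unrelated peaks (depth > 2) is not reported
  s_deep <- ms2_spectrum(900, c(700.30, 538.2472), adduct = "[M+H]+")
  expect_equal(nrow(detect_neutral_losses(s_deep)), 0)
  # single peak with no valid difference
  expect_equal(nrow(detect_neutral_losses(ms2_spectrum(500, 137.06))), 0)
  # water/CO/HCOH cascades are found peak-to-peak (bergenin pattern)
  s15 <- ms2_spectrum(329.0865, c(293.0663, 275.0549, 263.0555, 247.0610))
  nl15 <- detect_neutral_losses(s15)
  expect_true(any(nl15$loss == "H2O" & nl15$parent_mz == 293.0663))
  expect_true(any(nl15$loss == "HCOH" & nl15$parent_mz == 293.0663))
  expect_true(any(nl15$loss == "CO" & nl15$parent_mz == 275.0549))
})

test_that("subclass calls follow the diagnostic-ion decision rule", {
  # trachelogenin-type evidence: [C+H]+ present
  s12 <- ms2_spectrum(411.1, c(137.0613, 151.0770, 247.0977))
  expect_equal(classify_subclass(s12)$subclass_call,
               "lignano-8'-hydroxy-9,9'-lactone")
  # matairesinol-type evidence: [B]+ and [M+H-A]+
  s11 <- ms2_spectrum(381.2, c(137.0607, 163.0762, 223.0968))
  expect_equal(classify_subclass(s11)$subclass_call,
               "lignano-9,9'-lactone")
  # a shared benzyl cation alone never decides
  expect_equal(classify_subclass(ms2_spectrum(381.2, 137.0603))$subclass_call,
               "undetermined")
  # [M+H-A]+-consistent evidence alone suffices for the 9,9' call
  s8 <- ms2_spectrum(683.3, c(137.0601, 237.1117))
  expect_equal(classify_subclass(s8)$subclass_call, "lignano-9,9'-lactone")
})

test_that("identification recovers compounds and reports isomer ties", {
  # clean simulation of tracheloside: truth in the reported tie set
  s7 <- simulate_spectrum(lib[[7]], "[M+Na]+",
                          sim_config(seed = 3, sigma_mass_mda = 0))
  r7 <- identify_spectrum(s7)
  expect_true(7 %in% r7$tie_ids)
  expect_equal(r7$best_match, 7)
  expect_gte(r7$score, 4)
  # published flavonoid glycoside spectrum
  s25 <- ms2_spectrum(579.1719, c(433.1125, 271.0605), adduct = "[M+H]+")
  expect_equal(identify_spectrum(s25)$best_match, 25)
  # isomeric nortrachelogenin monoglucosides stay tied on MS evidence
  s21 <- ms2_spectrum(559.1792, c(397.1328, 159.0415), adduct = "[M+Na]+")
  r21 <- identify_spectrum(s21)
  expect_equal(r21$tie_ids, c(2L, 3L, 21L))
  # a retention ordering annotates but does not re-rank
  r21b <- identify_spectrum(s21, rt_order = c(21L, 3L, 2L))
  expect_equal(r21b$tie_ids, r21$tie_ids)
  expect_equal(r21b$rt_annotation, c(21L, 3L, 2L))
  expect_equal(r21b$best_match, r21$best_match)
  # precursor far from every library compound: no match, subclass still set
  s_none <- ms2_spectrum(999.9, c(137.0603, 247.0965))
  r_none <- identify_spectrum(s_none)
  expect_true(is.na(r_none$best_match))
  expect_equal(r_none$subclass_call, "lignano-8'-hydroxy-9,9'-lactone")
})

test_that("identification is deterministic", {
  s <- simulate_spectrum(lib[[9]], "[M+Na]+", sim_config(seed = 8))
  r1 <- identify_spectrum(s)
  r2 <- identify_spectrum(s)
  expect_identical(r1[c("best_match", "tie_ids", "score", "subclass_call")],
                   r2[c("best_match", "tie_ids", "score", "subclass_call")])
  expect_identical(r1$evidence, r2$evidence)
})
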