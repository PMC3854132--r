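# Dose-response inversion, Loewe index, combination index and synergy maps.

bg48 <- treatment_condition(horizon = 48)
dr_ly <- dose_response(ref, "LY294002", bg48, dose_max = 200)
dr_bad <- dose_response(ref, "BADS112A", bg48, dose_max = 200)

test_that("dose-response inversion round-trips and flags unreachable effects", {
  x <- dr_ly(2)
  expect_equal(dr_ly(invert_dose_response(dr_ly, x)), x, tolerance = 1e-3)
  # effect below the zero-dose response -> dose 0
  expect_identical(invert_dose_response(dr_ly, dr_ly(0) - 5), 0)
  # effect above the plateau -> typed error, distinct from numerical failure
  expect_error(invert_dose_response(dr_ly, 99.9), class = "unreachable_effect")
})

test_that("a sham combination scores Loewe CI = 1 for every split and level", {
  sham <- function(a, b) dr_ly(a + b)
  for (tot in c(0.5, 2, 10)) {
    for (frac in c(0, 0.25, 0.5, 0.9, 1)) {
      ci <- loewe_index(tot * frac, tot * (1 - frac), dr_ly, dr_ly, sham)
      expect_equal(ci, 1, tolerance = 1e-2)
    }
  }
})

test_that("the BADS112A + LY294002 pair is Loewe-synergistic on the 25% isobologram", {
  combo <- combination_effect(ref, "BADS112A", "LY294002", bg48)
  iso <- isobologram(ref, effect = 25, n = 6)
  expect_gt(nrow(iso), 2)
  cis <- mapply(function(a, b) loewe_index(a, b, dr_bad, dr_ly, combo),
                iso$d1, iso$d2)
  expect_true(all(cis < 1))
})

test_that("the total-dose combination index has the contracted sign semantics", {
  # self-combination at any split is exactly additive
  expect_equal(ci_from_effects(30, 30, 30), 1)
  combo_sham <- function(a, b) dr_ly(a + b)
  expect_equal(combination_index(0.6, 1.4, dr_ly, dr_ly, combo_sham), 1,
               tolerance = 1e-9)
  # combined beating both singles is synergy, and conversely
  expect_lt(ci_from_effects(20, 25, 30), 1)
  expect_gt(ci_from_effects(20, 35, 30), 1)
  expect_error(combination_index(0, 0, dr_ly, dr_ly, combo_sham),
               "at least one dose")
})

test_that("synergy maps are deterministic and causally consistent", {
  m1 <- synergy_map(ref, stress = 0, n = 5)
  m2 <- synergy_map(ref, stress = 0, n = 5)
  expect_identical(m1, m2)
  expect_true(all(m1$label[m1$ci < 1 - 1e-6] == "synergy"))
  expect_true(all(m1$label[m1$ci > 1 + 1e-6] == "antagonism"))
  # stress switched on only after the horizon is indistinguishable from none
  bg_late <- treatment_condition(stress = 100, stress_onset = 48, horizon = 48)
  combo_late <- combination_effect(ref, "BADS112A", "LY294002", bg_late)
  combo_none <- combination_effect(ref, "BADS112A", "LY294002", bg48)
  expect_equal(combo_late(1, 1), combo_none(1, 1), tolerance = 1e-9)
})

test_that("high stress splits the synergy map into two contiguous regions", {
  m0 <- synergy_map(ref, stress = 0, n = 8)
  m1 <- synergy_map(ref, stress = 100, n = 8)
  expect_identical(count_ci_regions(m1), 2L)
  # synergy survives only at high doses under stress
  hi <- m1$d1 == max(m1$d1) & m1$d2 == max(m1$d2)
  lo <- m1$d1 == min(m1$d1) & m1$d2 == min(m1$d2)
  expect_lt(m1$ci[hi], 1)
  expect_gte(m1$ci[lo], 1)
  # and the overall synergistic fraction shrinks relative to no stress in the
  # standard-to-high LY dose range
  sel <- m0$d2 >= 1
  expect_gt(mean(m0$ci[sel] < 1), mean(m1$ci[sel] < 1))
})

test_that("region labels are stable under grid refinement", {
  coarse <- synergy_map(ref, stress = 100, n = 10)
  fine <- synergy_map(ref, stress = 100, n = 28)
  gc_ <- attr(coarse, "grid"); gf <- attr(fine, "grid")
  shared_f <- outer(round(log10(gf), 10), round(log10(gc_), 10), `==`)
  idx <- apply(shared_f, 2, which)
  expect_length(idx, 10) # coarse axis embeds in the fine axis
  key_c <- paste(round(log10(coarse$d1), 8), round(log10(coarse$d2), 8))
  key_f <- paste(round(log10(fine$d1), 8), round(log10(fine$d2), 8))
  m <- match(key_c, key_f)
  expect_true(all(!is.na(m)))
  agree <- mean((coarse$ci < 1) == (fine$ci[m] < 1))
  expect_gte(agree, 0.95)
})

test_that("stress induces dose-dependent resistance on the response surface", {
  surf <- resistance_surface(ref, stress_levels = c(0, 100), n = 4)
  s0 <- surf[surf$stress == 0, ]
  s1 <- surf[surf$stress == 100, ]
  # stress lowers apoptosis at every grid cell
  expect_true(all(s1$apoptosis_pct < s0$apoptosis_pct))
  # without stress the surface stays in a high, narrow band at active doses
  act <- s0$d1 >= 1 & s0$d2 >= 1
  expect_gt(min(s0$apoptosis_pct[act]), 30)
  # under stress, high vs low LY doses separate even at maximal BADS112A
  at_max_bad <- s1[s1$d1 == max(s1$d1), ]
  expect_gt(max(at_max_bad$apoptosis_pct) - min(at_max_bad$apoptosis_pct), 10)
})
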