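test_that("element groupings partition and exclude Pm/Sc", {
  es <- element_set()
  expect_length(es$reys, 15)
  expect_setequal(c(es$lreys, es$hreys), es$reys)
  expect_length(intersect(es$lreys, es$hreys), 0)
  expect_true(all(es$critical %in% es$reys))
  expect_true(all(es$excessive %in% es$reys))
  expect_length(intersect(es$critical, es$excessive), 0)
  expect_false(any(c("Pm", "Sc") %in% es$reys))
  expect_true("Y" %in% es$hreys)
})

test_that("shipped UCC set has the values the downstream indices rely on", {
  ucc <- load_reference_set("ucc_rudnick_gao_2003")
  expect_equal(unname(ucc$values["Lu"]), 0.31)
  expect_equal(unname(ucc$values["Gd"]), 4.0)
  expect_true(all(element_set()$reys %in% names(ucc$values)))
  expect_true(all(element_set()$hms %in% names(ucc$values)))
  expect_true(all(ucc$values > 0))
  expect_identical(ucc$ef_reference, "Mn")
})

test_that("NASC set covers all 15 REYs with positive values", {
  nasc <- load_reference_set("nasc_gromet_1984")
  expect_true(all(element_set()$reys %in% names(nasc$values)))
  expect_true(all(nasc$values > 0))
})

test_that("missing elements and files are reported by name", {
  ucc <- load_reference_set("ucc_rudnick_gao_2003")
  expect_error(reyrisk:::ref_values(ucc, c("La", "Xx")), "Xx")
  expect_error(load_reference_set("no_such_set"), "no_such_set")
  # a set without Mn cannot serve the enrichment factor
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(element = c("La", "Ce"), value = c(31, 63)),
            path, row.names = FALSE)
  small <- load_reference_set(path)
  conc <- conc_row(c(La = 31, Mn = 775))
  expect_error(enrichment_factor(conc, small, "La"), "Mn")
})

test_that("toxicity response coefficients match the Hakanson-type table", {
  tox <- default_toxicology()
  tr <- setNames(tox$tr, tox$element)
  hm_expect <- c(Hg = 40, Cd = 30, As = 10, Cu = 5, Ni = 5, Co = 5,
                 Pb = 5, Cr = 2, Mn = 1, Zn = 1)
  rey_expect <- c(Lu = 20, Ho = 10, Tb = 10, Tm = 10, Eu = 10,
                  Pr = 5, Sm = 5, Yb = 5, Dy = 5, Er = 5, Gd = 5,
                  Y = 2, Nd = 2, Ce = 1, La = 1)
  for (el in names(hm_expect)) expect_equal(unname(tr[el]), unname(hm_expect[el]))
  for (el in names(rey_expect)) expect_equal(unname(tr[el]), unname(rey_expect[el]))
  expect_equal(sum(tr[element_set()$reys]), 96)
})

test_that("every REY carries the common RfD and CSF", {
  tox <- default_toxicology()
  reys <- element_set()$reys
  idx <- match(reys, tox$element)
  expect_true(all(tox$rfd[idx] == 0.02))
  expect_true(all(tox$csf[idx] == 3.2e-12))
  expect_true(all(is.na(tox$rfd) | tox$rfd > 0))
})

test_that("reference and toxicology tables round-trip through CSV", {
  ucc <- load_reference_set("ucc_rudnick_gao_2003")
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_set(ucc, path)
  back <- load_reference_set(path)
  expect_equal(back$values, ucc$values)

  tox <- default_toxicology()
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_toxicology(tox, path2)
  back2 <- load_toxicology(path2)
  expect_equal(back2$tr, tox$tr)
  expect_equal(back2$rfd, tox$rfd)
  expect_equal(back2$csf, tox$csf)
})

test_that("exposure profiles satisfy the averaging-time invariants", {
  p <- default_exposure_profiles()
  expect_equal(p$child$averaging_time_nc, 2190)      # 6 y x 365 d
  expect_equal(p$adult$averaging_time_nc, 24 * 365)
  expect_equal(p$child$averaging_time_ca, 25550)     # 70 y x 365 d
  expect_equal(p$adult$averaging_time_ca, 25550)
  expect_equal(p$child$unit_conversion, 1e-6)
  expect_equal(p$child$ingestion_rate, 200)
  expect_equal(p$adult$body_weight, 70)
  expect_error(exposure_profile("child", ingestion_rate = -1,
                                exposure_frequency = 350,
                                exposure_duration = 6, body_weight = 15,
                                skin_area = 2373, adherence_factor = 0.2,
                                dermal_absorption = 0.001,
                                inhalation_rate = 7.6),
               "positive")
})
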