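tox <- default_toxicology()
profiles <- default_exposure_profiles()
es <- element_set()

test_that("ingestion dose matches hand substitution", {
  conc <- conc_row(c(La = 240.5))
  d <- daily_dose(conc, profiles$child, "ingestion")
  # 240.5 * 200 * 350 * 6 / (15 * 2190 * 1e6)
  expect_equal(d$add_nc, 240.5 * 200 * 350 * 6 / (15 * 2190 * 1e6))
  expect_equal(d$add_nc, 3.075e-3, tolerance = 1e-3)
  # lifetime averaging dilutes the dose
  expect_lt(d$ladd_ca, d$add_nc)
  expect_equal(d$ladd_ca, d$add_nc * 2190 / 25550)
})

test_that("zero concentration gives zero dose on all pathways", {
  conc <- conc_row(c(La = 0))
  d <- daily_dose(conc, profiles$adult)
  expect_equal(d$add_nc, rep(0, 3))
  expect_equal(d$ladd_ca, rep(0, 3))
})

test_that("adult/child ingestion dose ratio follows the exposure factors", {
  conc <- conc_row(c(Ce = 100))
  dc <- daily_dose(conc, profiles$child, "ingestion")
  da <- daily_dose(conc, profiles$adult, "ingestion")
  # per-year doses scale as (IR/BW); ED cancels against AT_nc = ED*365
  expect_equal(da$add_nc / dc$add_nc, (100 / 200) / (70 / 15))
})

test_that("a dose equal to the RfD yields a unit hazard quotient", {
  p <- profiles$child
  rfd <- 0.02
  # choose C so the ingestion ADD alone equals the RfD
  C <- rfd * p$body_weight * p$averaging_time_nc * 1e6 /
    (p$ingestion_rate * p$exposure_frequency * p$exposure_duration)
  d <- daily_dose(conc_row(c(La = C)), p, elements = "La")
  add <- setNames(d$add_nc, d$pathway)
  expect_equal(unname(add["ingestion"]) / rfd, 1)
  # and the full HQ is the pathway sum of ADD/RfD
  hq <- hazard(conc_row(c(La = C)), p, tox, "La")
  expect_equal(hq$summary$hi, sum(add) / rfd)
})

test_that("the mean-ash REY hazard matches the reported receptor gap", {
  conc <- lumped_rey_conc(240.5)
  hz <- hazard(conc, profiles, tox, es$reys)
  hi <- setNames(hz$summary$hi, hz$summary$receptor)
  expect_equal(unname(signif(hi["child"], 2)), 0.15)
  expect_equal(unname(signif(hi["adult"], 2)), 0.017)
  # children receive the larger dose per kg body weight
  expect_gt(hi["child"], 9 * hi["adult"])
})

test_that("cancer risk applies the common REY slope factor to ingestion", {
  conc <- lumped_rey_conc(240.5)
  cr <- cancer_risk(conc, profiles, tox, es$reys)
  tcr <- setNames(cr$summary$tcr, cr$summary$receptor)
  expect_equal(unname(signif(tcr["child"], 2)), 8.4e-16)
  expect_equal(unname(signif(tcr["adult"], 2)), 3.6e-16)
  # equals LADD * CSF computed directly
  d <- daily_dose(conc, profiles$child, "ingestion", elements = es$reys)
  expect_equal(unname(tcr["child"]), sum(d$ladd_ca) * 3.2e-12)
})

test_that("elements without a CSF contribute zero cancer risk", {
  conc <- conc_row(c(Hg = 1, As = 10))
  cr <- cancer_risk(conc, profiles$adult, tox, c("Hg", "As"))
  expect_equal(cr$cr$cr[cr$cr$element == "Hg"], 0)
  expect_gt(cr$cr$cr[cr$cr$element == "As"], 0)
  expect_equal(cr$summary$tcr, sum(cr$cr$cr))
})

test_that("HI and TCR are linear in concentration", {
  conc1 <- lumped_rey_conc(150)
  conc2 <- lumped_rey_conc(300)
  h1 <- hazard(conc1, profiles$child, tox, es$reys)$summary$hi
  h2 <- hazard(conc2, profiles$child, tox, es$reys)$summary$hi
  expect_equal(h2, 2 * h1)
  t1 <- cancer_risk(conc1, profiles$adult, tox, es$reys)$summary$tcr
  t2 <- cancer_risk(conc2, profiles$adult, tox, es$reys)$summary$tcr
  expect_equal(t2, 2 * t1)
})

test_that("ingestion dominates the hazard under default exposure factors", {
  set.seed(11)
  for (i in 1:5) {
    vals <- setNames(runif(15, 0.1, 200), es$reys)
    conc <- conc_row(vals)
    for (p in profiles) {
      d <- daily_dose(conc, p, elements = es$reys)
      by_pw <- tapply(d$add_nc, d$pathway, sum)
      expect_gt(by_pw[["ingestion"]] / sum(by_pw), 0.95)
    }
  }
})

test_that("summing HQ over elements then pathways commutes", {
  conc <- conc_row(c(serbia_fly_means(), As = 60, Cd = 1))
  p <- profiles$child
  elems <- c(es$reys, "As", "Cd")
  d <- daily_dose(conc, p, elements = elems)
  rfd <- setNames(tox$rfd[match(elems, tox$element)], elems)
  hq_by_element <- tapply(d$add_nc / rfd[d$element], d$element, sum)
  hq_by_pathway <- tapply(d$add_nc / rfd[d$element], d$pathway, sum)
  expect_equal(sum(hq_by_element), sum(hq_by_pathway))
  expect_equal(sum(hq_by_element),
               hazard(conc, p, tox, elems)$summary$hi)
})

test_that("REY and HM partial sums add up to the totals", {
  conc <- conc_row(c(serbia_fly_means(), As = 60, Cd = 1, Hg = 0.15))
  hz <- hazard(conc, profiles, tox)
  expect_equal(hz$summary$hi_rey + hz$summary$hi_hm, hz$summary$hi)
  cr <- cancer_risk(conc, profiles, tox)
  expect_equal(cr$summary$tcr_rey + cr$summary$tcr_hm, cr$summary$tcr)
})

test_that("a missing RfD is a loud error", {
  tox2 <- tox
  tox2$rfd[tox2$element == "La"] <- NA
  expect_error(hazard(conc_row(c(La = 10)), profiles$child, tox2, "La"), "La")
})
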