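test_that("the prostate mask matches the analytic ellipsoid volume", {
  spec <- phantom_spec()  # 224 x 224 x 16 at 0.29 x 0.29 x 3 mm
  pr <- make_prostate(spec)
  vox_vol <- prod(spec$spacing)
  analytic <- 4 / 3 * pi * prod(spec$semiaxes_mm)
  expect_equal(sum(pr$data) * vox_vol, analytic, tolerance = 0.02)
  expect_error(make_prostate(phantom_spec(semiaxes_mm = c(20, 17, 30))),
               "bounds")
  expect_error(phantom_spec(semiaxes_mm = c(20, 0, 15)), "positive")
})

test_that("cases are bit-identical for one seed and differ across seeds", {
  les <- list(lesion_desc(6, peak = 0.9, placement = "straddling",
                          contact_mm = 10))
  spec <- phantom_spec(shape = c(96, 96, 10), spacing = c(0.6, 0.6, 3),
                       semiaxes_mm = c(22, 18, 12), lesions = les,
                       noise = 0.05, seed = 7)
  a <- make_case(spec)
  b <- make_case(spec)
  expect_identical(a$p_ca$data, b$p_ca$data)
  expect_identical(a$prostate$data, b$prostate$data)
  spec2 <- spec; spec2$seed <- 8L
  c_ <- make_case(spec2)
  expect_false(identical(a$p_ca$data, c_$p_ca$data))
  expect_identical(a$gt_cancer$data, c_$gt_cancer$data)  # geometry is seed-free
})

test_that("ground-truth masks satisfy the EPE containment invariants", {
  ph <- small_phantom(list(
    lesion_desc(8, peak = 0.95, placement = "straddling", contact_mm = 14),
    lesion_desc(4, peak = 0.8, placement = "interior", theta = pi),
    lesion_desc(3, peak = 0.7, placement = "exterior", theta = pi / 2)))
  expect_true(all(ph$gt_epe$data <= ph$gt_cancer$data))   # gt_epe subset
  expect_equal(sum(ph$gt_epe$data * ph$prostate$data), 0) # extracapsular only
  expect_true(any(ph$gt_epe$data != 0))
  expect_equal(ph$lesions$crosses, c(TRUE, FALSE, FALSE))
  expect_equal(ph$lesions$contact_full_mm[2:3], c(0, 0))

  # interior-only case has empty gt_epe
  ph_in <- small_phantom(list(lesion_desc(5, placement = "interior")))
  expect_equal(sum(ph_in$gt_epe$data), 0)

  # infeasible contact arc and out-of-span placement are errors
  expect_error(lesion_desc(5, placement = "straddling", contact_mm = 12),
               "infeasible")
  expect_error(small_phantom(list(lesion_desc(4, placement = "straddling",
                                              contact_mm = 6, z_mm = 40))),
               "span")
})

test_that("probability field peaks inside lesions and noise stays bounded", {
  ph <- small_phantom(list(lesion_desc(7, peak = 0.9,
                                       placement = "straddling",
                                       contact_mm = 12, z_mm = 1.5)),
                      noise = 0.05, seed = 3)
  expect_true(max(ph$p_ca$data) <= 1 && min(ph$p_ca$data) >= 0)
  expect_equal(max(ph$p_ca$data), 0.9, tolerance = 0.06)
  outside_lesion <- ph$p_ca$data[ph$gt_cancer$data == 0]
  expect_true(all(outside_lesion <= 0.05 + 1e-12))
})

test_that("oracle contact agrees with the pipeline measurement at alpha -> 0", {
  # the measured value sits between the bare geometric contact and the
  # tolerance-inflated envelope; 3 px absolute slack plus 5% on the upper
  # envelope covers contour discretization and the polyline staircase bias
  set.seed(41)
  for (k in 1:4) {
    r <- runif(1, 5.5, 9)
    ph <- make_case(phantom_spec(lesions = list(
      lesion_desc(r, peak = runif(1, 0.75, 0.95), placement = "straddling",
                  contact_mm = runif(1, 0.5, 1) * 2 * r,
                  theta = runif(1, 0, 2 * pi), z_mm = runif(1, -3, 3))),
      noise = 0, seed = 40 + k))
    comp <- components_3d(threshold_map(
      apply_mask(ph$p_ca, dilate_mask(ph$prostate, 32)), 0))[[1]]
    meas <- contact_length(comp, ph$prostate)
    px <- ph$spec$spacing[1]
    lo <- ph$lesions$contact_full_mm[1] - 3 * px
    hi <- 1.05 * oracle_contact(ph, 1, 0, inflate_mm = sqrt(2) * px) + 3 * px
    expect_gte(meas, lo)
    expect_lte(meas, hi)
  }
})

test_that("cohorts are reproducible, respect prevalence, and feed roc_sweep", {
  coh <- make_cohort(4, epe_prevalence = 0.5, seed = 5,
                     shape = c(128, 128, 14), spacing = c(0.6, 0.6, 3))
  coh2 <- make_cohort(4, epe_prevalence = 0.5, seed = 5,
                      shape = c(128, 128, 14), spacing = c(0.6, 0.6, 3))
  expect_identical(lapply(coh, function(x) x$p_ca$data),
                   lapply(coh2, function(x) x$p_ca$data))
  # prefix property: the first cases of a longer cohort are unchanged
  coh6 <- make_cohort(6, epe_prevalence = 0.5, seed = 5,
                      shape = c(128, 128, 14), spacing = c(0.6, 0.6, 3))
  expect_identical(coh6[[2]]$p_ca$data, coh[[2]]$p_ca$data)

  none <- make_cohort(5, epe_prevalence = 0, seed = 6,
                      shape = c(128, 128, 14), spacing = c(0.6, 0.6, 3))
  expect_true(all(vapply(none, function(x) sum(x$gt_epe$data) == 0,
                         logical(1))))

  # observed prevalence within binomial error of the target
  coh_p <- make_cohort(24, epe_prevalence = 0.5, seed = 7,
                       shape = c(128, 128, 14), spacing = c(0.6, 0.6, 3))
  pos <- sum(vapply(coh_p, function(x) any(x$gt_epe$data != 0), logical(1)))
  expect_true(abs(pos / 24 - 0.5) <= 3 * sqrt(0.25 / 24))
})

test_that("cohorts round-trip to disk with a manifest and oracle sidecars", {
  coh <- make_cohort(2, epe_prevalence = 1, seed = 9,
                     shape = c(128, 128, 14), spacing = c(0.6, 0.6, 3))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2L)
  p <- read_volume(man$prob_path[1], kind = "probability")
  expect_equal(p$data, coh[[1]]$p_ca$data, tolerance = 1e-6)
  oracle <- jsonlite::read_json(file.path(dir, "case001_oracle.json"),
                                simplifyVector = TRUE)
  expect_equal(oracle$contact_full_mm, coh[[1]]$lesions$contact_full_mm,
               tolerance = 1e-9)
})
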