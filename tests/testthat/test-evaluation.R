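test_that("patient calls and confusion counts follow the standard definitions", {
  z <- prob_vol(array(0, c(6, 6, 2)))
  expect_false(patient_call(z))
  nz <- z; nz$data[17] <- 0.4
  expect_true(patient_call(nz))

  cc <- confusion(rep(TRUE, 4), rep(TRUE, 4))
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 4L, fp = 0L, tn = 0L, fn = 0L))
  cc2 <- confusion(rep(FALSE, 4), rep(TRUE, 4))
  expect_equal(cc2$fn, 4L)
  # six sextants, two GT positives, predictions exactly on them
  gt <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  cc3 <- confusion(gt, gt)
  expect_equal(unclass(cc3)[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 0L, tn = 4L, fn = 0L))
  expect_equal(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 6L)
  expect_error(confusion(TRUE, c(TRUE, FALSE)), "length")
})

test_that("sensitivity and specificity handle perfect, partial and undefined cases", {
  ss <- function(tp, fp, tn, fn)
    sens_spec(confusion(c(rep(TRUE, tp + fp), rep(FALSE, tn + fn)),
                        c(rep(TRUE, tp), rep(FALSE, fp),
                          rep(FALSE, tn), rep(TRUE, fn))))
  expect_equal(ss(2, 0, 4, 0), list(sensitivity = 1, specificity = 1))
  expect_equal(ss(2, 2, 2, 0), list(sensitivity = 1, specificity = 0.5))
  expect_equal(ss(0, 1, 0, 1), list(sensitivity = 0, specificity = 0))
  # undefined components surface as NA, not 0
  expect_true(is.na(ss(0, 1, 1, 0)$sensitivity))
  expect_true(is.na(ss(1, 0, 0, 1)$specificity))
})

test_that("auc is the endpoint-augmented trapezoid, invariant to point order", {
  pt <- function(fpr, tpr) data.frame(fpr = fpr, tpr = tpr)
  expect_equal(auc(pt(0, 1)), 1)
  expect_equal(auc(pt(0.5, 0.5)), 0.5)
  expect_equal(auc(pt(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))), 0.5)
  shuffled <- pt(c(0.8, 0.2, 0.5), c(0.8, 0.2, 0.5))
  expect_equal(auc(shuffled), 0.5)
  # hand trapezoid: (0,0)-(0,.9)-(.3,1)-(1,1) -> .3*(.9+1)/2 + .7*1 = 0.985
  expect_equal(auc(pt(c(0, 0.3), c(0.9, 1))), 0.985, tolerance = 1e-12)
  expect_true(is.na(auc(pt(NA_real_, NA_real_))))
})

tiny_cases <- function(n_pos = 2, n_neg = 2, noise = 0, seed0 = 100) {
  cases <- list()
  for (i in seq_len(n_pos))
    cases[[length(cases) + 1]] <- small_phantom(
      list(lesion_desc(8.5, peak = 0.9 - 0.1 * (i - 1),
                       placement = "straddling", contact_mm = 16,
                       theta = i)), noise = noise, seed = seed0 + i)
  for (i in seq_len(n_neg))
    cases[[length(cases) + 1]] <- small_phantom(
      list(lesion_desc(4.5, peak = 0.9, placement = "interior",
                       theta = -i)), noise = noise, seed = seed0 + 50 + i)
  cases
}

test_that("roc_sweep uses the default 21-step alpha grid and separates a
           clean cohort perfectly", {
  cases <- tiny_cases()
  params <- pipeline_params(dilation_radius = 15)
  sw <- roc_sweep(cases, params = params)
  expect_equal(sw$patient$points$alpha, seq(0, 1, by = 0.05))
  expect_equal(nrow(sw$patient$points), 21L)
  # interior-only cases can never be predicted positive, straddling cases
  # are detected at low alpha: perfect ranking at both levels
  expect_equal(sw$patient$auc, 1.0)
  expect_true(all(sw$patient$points$fpr == 0))
  expect_error(roc_sweep(cases, grid = c(0.5, 0.2)), "increasing")
})

test_that("roc_sweep reports undefined AUC for single-class cohorts", {
  neg_only <- tiny_cases(n_pos = 0, n_neg = 2)
  sw <- roc_sweep(neg_only, grid = c(0.1, 0.5),
                  params = pipeline_params(dilation_radius = 15))
  expect_true(is.na(sw$patient$auc))
})

test_that("grid_search_tcl tabulates one row per threshold with fold averaging", {
  cases <- tiny_cases(n_pos = 1, n_neg = 1)
  params <- pipeline_params(dilation_radius = 15)
  tab <- grid_search_tcl(cases, tcl_values = c(5, 25), grid = c(0.1, 0.3),
                         params = params)
  expect_equal(tab$tcl_mm, c(5, 25))
  expect_equal(nrow(tab), 2L)
  # the straddling lesion's contact (~16 mm) lies between the two
  # thresholds: the positive case is detected at 5 mm, never at 25 mm
  expect_equal(tab$patient_auc[1], 1.0)
  expect_equal(tab$patient_auc[2], 0.5)

  tab_f <- grid_search_tcl(tiny_cases(n_pos = 2, n_neg = 2),
                           tcl_values = 5, grid = c(0.1, 0.3),
                           params = params, folds = c(1, 2, 1, 2))
  expect_equal(nrow(tab_f), 1L)
  expect_equal(tab_f$patient_auc, 1.0)
})
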