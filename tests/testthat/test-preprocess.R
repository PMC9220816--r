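rand_img <- function(seed, d = c(16, 16, 4), shift = 0, scale = 1) {
  set.seed(seed)
  vol3d(array(shift + scale * rgamma(prod(d), 3, 1), d), c(1, 1, 1),
        "intensity")
}

test_that("landmarks of a single image equal its own percentile values", {
  img <- rand_img(1)
  lm <- learn_landmarks(list(img))
  direct <- unname(quantile(as.vector(img$data),
                            probs = c(1, seq(10, 90, 10), 99) / 100))
  expect_equal(lm$values, direct)
})

test_that("cohort landmarks are per-percentile means (direct quantile oracle)", {
  a <- rand_img(2)
  b <- a
  b$data <- 3 * a$data + 5  # affine rescale of the same histogram
  pct <- seq(10, 90, 10)
  lm <- learn_landmarks(list(a, b), percentiles = pct)
  qa <- unname(quantile(as.vector(a$data), pct / 100))
  qb <- unname(quantile(as.vector(b$data), pct / 100))
  expect_equal(lm$values, (qa + qb) / 2)

  # identical cohort members give zero landmark spread around either member
  lm2 <- learn_landmarks(list(a, a, a), percentiles = pct)
  expect_equal(lm2$values, qa)
})

test_that("standardize is the identity for self-learned landmarks and maps
           affine rescales back onto the reference", {
  ref <- rand_img(3)
  lm <- learn_landmarks(list(ref))
  out <- standardize(ref, lm)
  expect_equal(out$data, ref$data, tolerance = 1e-12)

  doubled <- ref
  doubled$data <- 2 * ref$data
  mapped <- standardize(doubled, lm)
  expect_equal(mapped$data, ref$data, tolerance = 1e-9)
})

test_that("standardize is monotone and preserves grid and spacing", {
  img <- rand_img(4)
  other <- rand_img(5, shift = 10, scale = 2)
  lm <- learn_landmarks(list(other))
  out <- standardize(img, lm)
  expect_identical(dim(out), dim(img))
  expect_identical(out$spacing, img$spacing)
  o <- order(as.vector(img$data))
  expect_true(all(diff(as.vector(out$data)[o]) >= -1e-12))
  expect_error(standardize(vol3d(array(1, c(4, 4, 2)), c(1, 1, 1)), lm),
               "percentile|constant")
})

test_that("zscore_region normalizes the region to mean 0, sd 1 and is idempotent", {
  img <- rand_img(6)
  reg <- mask_vol(array(as.numeric(array(runif(prod(dim(img$data))),
                                         dim(img$data)) > 0.6),
                        dim(img$data)))
  out <- zscore_region(img, reg)
  vals <- out$data[reg$data != 0]
  expect_equal(mean(vals), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((vals - mean(vals))^2)), 1, tolerance = 1e-9)
  twice <- zscore_region(out, reg)
  expect_equal(twice$data, out$data, tolerance = 1e-9)

  # two-voxel region {1, 3}: population sd 1, so values map to -1 and +1
  small <- vol3d(array(c(1, 3, 7, 9), c(2, 2, 1)), c(1, 1, 1), "intensity")
  rsm <- mask_vol(array(c(1, 1, 0, 0), c(2, 2, 1)))
  zs <- zscore_region(small, rsm)
  expect_equal(zs$data[1:2], c(-1, 1))

  expect_error(zscore_region(img, mask_vol(array(0, dim(img$data)))), "empty")
  const <- vol3d(array(5, dim(img$data)), c(1, 1, 1), "intensity")
  expect_error(zscore_region(const, reg), "variance")
})

test_that("landmark sets persist through JSON and reject non-monotone values", {
  lm <- learn_landmarks(list(rand_img(7)))
  f <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, f)
  back <- read_landmarks(f)
  expect_equal(back$percentiles, lm$percentiles)
  expect_equal(back$values, lm$values)
  expect_error(landmark_set(c(10, 50, 90), c(1, 1, 2)), "increasing")
  expect_error(landmark_set(c(10, 90), c(1)), "matching")
})
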