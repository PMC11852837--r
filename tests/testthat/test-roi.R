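# Reslicing, enhancing-lesion segmentation and feature extraction.

test_that("identical grids pass through reslicing untouched", {
  img <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  aff <- diag(c(1.72, 1.72, 3, 1))
  out <- reslice_to_reference(img, aff, dim(img), aff)
  expect_identical(out$data, img)
  expect_true(all(out$in_field))
})

test_that("an integer one-voxel translation moves a delta by one voxel", {
  img <- array(0, c(7, 7, 5))
  img[4, 4, 3] <- 1
  aff <- diag(c(2, 2, 2, 1))
  shifted <- aff
  shifted[1, 4] <- 2  # source shifted +1 voxel along x in world space
  out <- reslice_to_reference(img, shifted, dim(img), aff)
  expect_equal(out$data[5, 4, 3], 1, tolerance = 1e-12)
  expect_equal(sum(out$data, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("disjoint fields of view raise a geometry error", {
  img <- array(1, c(4, 4, 4))
  aff <- diag(4)
  far <- diag(4); far[1:3, 4] <- 1000
  expect_error(reslice_to_reference(img, aff, c(4L, 4L, 4L), far),
               class = "gliopred_geometry_error")
})

test_that("a missing or singular affine is a header error", {
  img <- array(1, c(4, 4, 4))
  expect_error(reslice_to_reference(img, matrix(0, 4, 4), c(4L, 4L, 4L),
                                    diag(4)),
               class = "gliopred_header_error")
})

make_t1_pair <- function(seed = 21) {
  set.seed(seed)
  dims <- c(20, 20, 8)
  brain <- array(TRUE, dims)
  pre <- array(100, dims) + rnorm(prod(dims), 0, 2)
  rim <- array(FALSE, dims)
  rim[8:12, 8:12, 4:5] <- TRUE
  rim[9:11, 9:11, 4:5] <- FALSE  # hollow ring
  post <- pre + 10 * 2 * rim + rnorm(prod(dims), 0, 2)  # contrast 10 * SD
  list(pre = pre, post = post, brain = brain, rim = rim)
}

test_that("a planted enhancing rim is segmented with Dice >= 0.90", {
  x <- make_t1_pair()
  seg <- segment_enhancing(x$post, x$pre, x$brain)
  dice <- 2 * sum(seg$mask & x$rim) / (sum(seg$mask) + sum(x$rim))
  expect_gte(dice, 0.90)
})

test_that("identical pre and post images give an empty mask with a warning", {
  x <- make_t1_pair()
  expect_warning(seg <- segment_enhancing(x$post, x$post, x$brain),
                 class = "gliopred_empty_mask_warning")
  expect_equal(sum(seg$mask), 0)
})

test_that("seed points restrict segmentation to the seeded component", {
  set.seed(33)
  dims <- c(24, 24, 6)
  brain <- array(TRUE, dims)
  pre <- array(100, dims) + rnorm(prod(dims), 0, 1)
  lesA <- array(FALSE, dims); lesA[4:7, 4:7, 3:4] <- TRUE
  lesB <- array(FALSE, dims); lesB[16:19, 16:19, 3:4] <- TRUE
  post <- pre + 25 * (lesA | lesB) + rnorm(prod(dims), 0, 1)
  seg <- segment_enhancing(post, pre, brain,
                           seeds = matrix(c(5, 5, 3), 1))
  expect_true(all(seg$mask[lesA] | !any(seg$mask[lesA])))
  expect_gte(sum(seg$mask & lesA) / sum(lesA), 0.9)
  expect_equal(sum(seg$mask & lesB), 0)
  expect_equal(seg$n_components, 1L)
})

test_that("small components below the voxel floor are discarded", {
  set.seed(41)
  dims <- c(16, 16, 6)
  brain <- array(TRUE, dims)
  pre <- array(100, dims) + rnorm(prod(dims), 0, 1)
  speck <- array(FALSE, dims); speck[3, 3, 3] <- TRUE
  blob <- array(FALSE, dims); blob[9:12, 9:12, 3:4] <- TRUE
  post <- pre + 30 * (speck | blob) + rnorm(prod(dims), 0, 1)
  seg <- segment_enhancing(post, pre, brain, min_component_voxels = 10)
  expect_equal(sum(seg$mask & speck), 0)
  expect_gt(sum(seg$mask & blob), 0)
})

test_that("feature extraction reproduces hand-computed order statistics", {
  dims <- c(5, 1, 1)
  mask <- array(TRUE, dims)
  rcbv <- array(c(1, 2, 3, 4, 10), dims)
  fa <- array(0.2, dims); cl <- array(0.05, dims)
  fv <- extract_features(mask, list(fa = fa, cl = cl, rcbv = rcbv))
  expect_equal(fv$rcbv_max, 7.6)        # 90th percentile, interpolated
  expect_equal(fv$fa_median, 0.2)

  mask4 <- array(TRUE, c(4, 1, 1))
  md <- array(c(1, 2, 3, 4) * 1e-3, c(4, 1, 1))
  fv2 <- extract_features(mask4, list(fa = array(0.1, c(4, 1, 1)),
                                      cl = array(0.02, c(4, 1, 1)),
                                      rcbv = array(2, c(4, 1, 1)),
                                      md = md))
  expect_equal(fv2$md_min, 1.3e-3)      # 10th percentile, interpolated
  expect_equal(fv2$md_median, 2.5e-3)
})

test_that("constant maps collapse to the constants", {
  dims <- c(3, 3, 2)
  mask <- array(TRUE, dims)
  fv <- extract_features(mask, list(fa = array(0.2, dims),
                                    cl = array(0.07, dims),
                                    rcbv = array(3, dims),
                                    md = array(1.1e-3, dims)))
  expect_equal(fv$fa_median, 0.2)
  expect_equal(fv$rcbv_max, 3)
  expect_equal(fv$md_min, 1.1e-3)
})

test_that("features ignore voxel ordering and count excluded NaNs", {
  set.seed(55)
  dims <- c(10, 1, 1)
  mask <- array(TRUE, dims)
  vals <- runif(10)
  perm <- sample(10)
  f1 <- extract_features(mask, list(fa = array(vals, dims),
                                    cl = array(vals / 4, dims),
                                    rcbv = array(vals * 5, dims)))
  f2 <- extract_features(mask, list(fa = array(vals[perm], dims),
                                    cl = array(vals[perm] / 4, dims),
                                    rcbv = array(vals[perm] * 5, dims)))
  expect_equal(f1$fa_median, f2$fa_median)
  expect_equal(f1$rcbv_max, f2$rcbv_max)

  fa_nan <- array(vals, dims); fa_nan[3] <- NaN
  f3 <- extract_features(mask, list(fa = fa_nan,
                                    cl = array(vals / 4, dims),
                                    rcbv = array(vals * 5, dims)))
  expect_equal(f3$n_excluded, 1L)
  expect_equal(f3$fa_median, median(vals[-3]))
})

test_that("percentile bounds and insertion monotonicity hold", {
  set.seed(66)
  dims <- c(30, 1, 1)
  mask <- array(TRUE, dims)
  rc <- runif(30, 0, 6)
  maps <- list(fa = array(0.1, dims), cl = array(0.02, dims),
               rcbv = array(rc, dims), md = array(runif(30, 0.5, 2) * 1e-3,
                                                  dims))
  fv <- extract_features(mask, maps)
  expect_gte(fv$rcbv_max, median(rc))
  expect_lte(fv$md_min, fv$md_median)

  # appending voxels above the current 90th percentile cannot lower rcbv_max
  dims2 <- c(35, 1, 1)
  mask2 <- array(TRUE, dims2)
  rc2 <- c(rc, rep(max(rc) + 1, 5))
  maps2 <- list(fa = array(0.1, dims2), cl = array(0.02, dims2),
                rcbv = array(rc2, dims2))
  fv2 <- extract_features(mask2, maps2)
  expect_gte(fv2$rcbv_max, fv$rcbv_max)
})

test_that("empty masks and mismatched grids are errors", {
  mask <- array(FALSE, c(2, 2, 2))
  maps <- list(fa = array(0.1, c(2, 2, 2)), cl = array(0.1, c(2, 2, 2)),
               rcbv = array(1, c(2, 2, 2)))
  expect_error(extract_features(mask, maps),
               class = "gliopred_feature_extraction_error")
  expect_error(extract_features(array(TRUE, c(2, 2, 2)),
                                list(fa = array(0.1, c(3, 2, 2)))),
               class = "gliopred_geometry_error")
})

test_that("the tail-mean percentile convention is available and recorded", {
  dims <- c(5, 1, 1)
  mask <- array(TRUE, dims)
  maps <- list(fa = array(0.2, dims), cl = array(0.05, dims),
               rcbv = array(c(1, 2, 3, 4, 10), dims))
  fv <- extract_features(mask, maps, convention = "tail_mean")
  expect_equal(fv$rcbv_max, 10)  # mean of values >= 7.6
  expect_equal(fv$percentile_convention, "tail_mean")
})
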