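make_affine <- function(scale = c(1, 1, 1), origin = c(0, 0, 0)) {
  a <- diag(4)
  diag(a)[1:3] <- scale
  a[1:3, 4] <- origin
  a
}

test_that("lesion image constructor validates its inputs", {
  expect_error(lesion_image(matrix(0, 2, 2)), "3-D")
  expect_error(lesion_image(array(2, c(2, 2, 2))), "\\[0, 1\\]")
  expect_error(lesion_image(array(NA_real_, c(2, 2, 2))), "finite")
  bad_affine <- diag(4); bad_affine[1, 1] <- 0
  expect_error(lesion_image(array(0, c(2, 2, 2)), bad_affine), "invertible")
})

test_that("binarization uses a strict threshold and is idempotent", {
  v <- array(0, c(2, 2, 2))
  v[1, 1, 1] <- 0.31; v[2, 1, 1] <- 0.3; v[1, 2, 1] <- 0.29
  b <- binarize_lesion(lesion_image(v), 0.3)
  expect_equal(b$voxels[1, 1, 1], 1)
  expect_equal(b$voxels[2, 1, 1], 0)  # exactly at threshold: not lesioned
  expect_equal(b$voxels[1, 2, 1], 0)
  b2 <- binarize_lesion(b, 0.3)
  expect_identical(b2$voxels, b$voxels)
  expect_warning(binarize_lesion(b, 0.6), "already binary")
  zero <- binarize_lesion(lesion_image(array(0, c(3, 3, 3))))
  expect_true(all(zero$voxels == 0))
  expect_error(binarize_lesion(lesion_image(array(runif(8), c(2, 2, 2))), 1.5),
               "threshold")
})

test_that("binarization matches the element-wise comparison oracle", {
  withr::with_seed(21, {
    v <- array(runif(1000), c(10, 10, 10))
    b <- binarize_lesion(lesion_image(v), 0.3)
    expect_identical(as.vector(b$voxels), as.numeric(as.vector(v) > 0.3))
  })
})

test_that("lesion loads are exact region ratios", {
  lab <- array(0L, c(4, 4, 1))
  lab[1:2, 1:4, 1] <- 1L  # region 1: 8 voxels
  lab[3:4, 1:2, 1] <- 2L  # region 2: 4 voxels
  les <- array(0, c(4, 4, 1))
  les[1:2, 1, 1] <- 1     # 2 lesioned voxels inside region 1
  les[3:4, 1:2, 1] <- 1   # all of region 2
  fs <- compute_lesion_loads(lesion_image(les), atlas_parcellation(lab))
  expect_equal(unname(fs$loads[1]), 0.25)
  expect_equal(unname(fs$loads[2]), 1.0)
})

test_that("zero-voxel regions are reported as missing", {
  lab <- array(0L, c(2, 2, 2))
  lab[1, 1, 1] <- 3L  # region ids 1 and 2 never occur
  fs <- compute_lesion_loads(lesion_image(array(0, c(2, 2, 2))),
                             atlas_parcellation(lab))
  expect_true(is.na(fs$loads[1]) && is.na(fs$loads[2]))
  expect_equal(unname(fs$loads[3]), 0)
})

test_that("grid mismatch and non-binary input are hard errors", {
  img <- lesion_image(array(0, c(2, 2, 2)))
  atl <- atlas_parcellation(array(1L, c(3, 3, 3)))
  expect_error(compute_lesion_loads(img, atl), "grids differ")
  cont <- lesion_image(array(runif(8), c(2, 2, 2)))
  expect_error(compute_lesion_loads(cont, atlas_parcellation(array(1L, c(2, 2, 2)))),
               "binary")
})

test_that("loads match a brute-force voxel enumeration on random volumes", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      les <- array(rbinom(6 * 5 * 4, 1, 0.4), c(6, 5, 4))
      lab <- array(sample(0:5, 6 * 5 * 4, replace = TRUE), c(6, 5, 4))
      fs <- compute_lesion_loads(lesion_image(les), atlas_parcellation(lab))
      for (r in 1:5) {
        denom <- 0L; numer <- 0L
        for (i in 1:6) for (j in 1:5) for (k in 1:4) {
          if (lab[i, j, k] == r) {
            denom <- denom + 1L
            if (les[i, j, k] == 1) numer <- numer + 1L
          }
        }
        want <- if (denom == 0) NA_real_ else numer / denom
        expect_equal(unname(fs$loads[r]), want)
      }
    }
  })
})

test_that("volumes follow voxel counts, voxel size and hemisphere sign", {
  # 4x4x4 of 1 mm^3 voxels entirely at world x < 0
  les <- array(1, c(4, 4, 4))
  img <- lesion_image(les, make_affine(origin = c(-10, 0, 0)))
  v <- compute_volumes(img)
  expect_equal(unname(v), c(0.064, 0.064, 0))

  empty <- lesion_image(array(0, c(3, 3, 3)))
  expect_equal(unname(compute_volumes(empty)), c(0, 0, 0))
})

test_that("midline voxels count in total only; classification matches brute force", {
  withr::with_seed(41, {
    les <- array(rbinom(5 * 3 * 3, 1, 0.5), c(5, 3, 3))
    # voxel i has world x = i - 3: x in {-2,-1,0,1,2}
    img <- lesion_image(les, make_affine(origin = c(-2, 0, 0)))
    v <- compute_volumes(img)
    left <- right <- mid <- 0L
    for (i in 1:5) for (j in 1:3) for (k in 1:3) {
      if (les[i, j, k] == 1) {
        x <- (i - 1) - 2
        if (x < 0) left <- left + 1L else if (x > 0) right <- right + 1L
        else mid <- mid + 1L
      }
    }
    expect_equal(unname(v["left"]), left / 1000)
    expect_equal(unname(v["right"]), right / 1000)
    expect_equal(unname(v["total"]), (left + right + mid) / 1000)
  })
})

test_that("volumes scale with voxel size while loads do not", {
  withr::with_seed(51, {
    les <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
    lab <- array(sample(1:3, 64, replace = TRUE), c(4, 4, 4))
    a1 <- make_affine(scale = c(1, 1, 1), origin = c(-2, 0, 0))
    a2 <- make_affine(scale = c(2, 1, 1), origin = c(-4, 0, 0))
    f1 <- compute_lesion_loads(lesion_image(les, a1), atlas_parcellation(lab, a1))
    f2 <- compute_lesion_loads(lesion_image(les, a2), atlas_parcellation(lab, a2))
    expect_equal(f1$loads, f2$loads)
    expect_equal(2 * f1$total_volume, f2$total_volume)
  })
})

test_that("load-weighted region counts never exceed the lesion total", {
  withr::with_seed(61, {
    les <- array(rbinom(125, 1, 0.4), c(5, 5, 5))
    lab <- array(sample(0:4, 125, replace = TRUE), c(5, 5, 5))
    fs <- compute_lesion_loads(lesion_image(les), atlas_parcellation(lab))
    region_sizes <- tabulate(lab[lab > 0], nbins = 4)
    covered <- sum(fs$loads * region_sizes, na.rm = TRUE)
    expect_lte(covered, sum(les) + 1e-9)
  })
})

test_that("NIfTI images round-trip through the readers", {
  skip_if_not_installed("RNifti")
  dir <- withr::local_tempdir()
  les_path <- file.path(dir, "lesion.nii.gz")
  atl_path <- file.path(dir, "atlas.nii.gz")
  withr::with_seed(71, {
    v <- array(runif(27), c(3, 3, 3))
    lab <- array(sample(0:2, 27, replace = TRUE), c(3, 3, 3))
  })
  RNifti::writeNifti(RNifti::asNifti(v), les_path)
  RNifti::writeNifti(RNifti::asNifti(lab * 1.0), atl_path)
  img <- read_lesion_image(les_path)
  atl <- read_atlas(atl_path)
  expect_equal(as.vector(img$voxels), as.vector(v), tolerance = 1e-6)
  bin <- binarize_lesion(img, 0.3)
  fs <- compute_lesion_loads(bin, atl)
  expect_length(fs$loads, 2)
  row <- lesion_feature_row(fs, "P00042")
  expect_identical(row$patient_id, "P00042")
  expect_equal(row$total_volume, fs$total_volume)
})
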