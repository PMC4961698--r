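mask_of <- function(n_total, idx) {
  m <- array(FALSE, c(n_total, 1, 1)); m[idx, 1, 1] <- TRUE; m
}

test_that("dice matches its closed forms", {
  a <- mask_of(300, 1:100)
  b <- mask_of(300, 21:120)     # |a|=|b|=100, overlap 80
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, mask_of(300, 201:220)), 0)
  expect_equal(dice(a, b), 0.8)
  expect_equal(dice(mask_of(10, integer(0)), mask_of(10, integer(0))), 1)
  expect_error(dice(a, mask_of(299, 1)), "mismatch")
})

test_that("pvd and pvo match their closed forms", {
  c1 <- mask_of(300, 1:90)
  c2 <- mask_of(300, 1:110)
  expect_equal(pvd(c1, c2), 20)          # 100 * 2*20/200
  expect_equal(pvd(c1, c1), 0)
  expect_equal(pvd(mask_of(10, integer(0)), mask_of(10, 1:5)), 200)
  expect_error(pvd(mask_of(10, integer(0)), mask_of(10, integer(0))), "empty")
  b <- mask_of(300, 21:120)
  expect_equal(pvo(mask_of(300, 1:100), b), 80)
  expect_equal(pvo(c1, c1), 100)
  expect_equal(pvo(c1, mask_of(300, 200:250)), 0)
})

test_that("pvo equals 100 * dice and both are symmetric", {
  set.seed(3)
  for (i in 1:5) {
    a <- array(runif(125) > 0.6, c(5, 5, 5))
    b <- array(runif(125) > 0.6, c(5, 5, 5))
    if (sum(a) + sum(b) == 0) next
    expect_equal(pvo(a, b), 100 * dice(a, b))
    expect_equal(pvo(a, b), pvo(b, a))
    expect_equal(pvd(a, b), pvd(b, a))
    expect_equal(dice(a, b), dice(b, a))
    # invariant under mirroring both inputs
    expect_equal(dice(a[5:1, , ], b[5:1, , ]), dice(a, b))
  }
})

test_that("asymmetry ratio is signed, normalized and antisymmetric", {
  expect_equal(asymmetry_ratio(100, 100), 0)
  expect_equal(asymmetry_ratio(110, 90), 20)
  expect_equal(asymmetry_ratio(90, 110), -20)
  expect_error(asymmetry_ratio(0, 0), "zero")
})

test_that("structure_dict validates pairing", {
  d <- structure_dict(label = c(11, 12, 4),
                      name = c("hippocampus L", "hippocampus R", "brainstem"),
                      hemisphere = c("left", "right", "midline"),
                      paired_label = c(12, 11, NA))
  expect_s3_class(d, "structure_dict")
  expect_error(structure_dict(11, "x", "left", NA), "paired label")
  expect_error(structure_dict(c(11, 12), c("a", "b"), c("left", "right"),
                              c(12, 13)), "not symmetric|not in dictionary")
  expect_error(structure_dict(c(11, 12), c("a", "b"), c("left", "left"),
                              c(12, 11)), "opposite hemisphere")
})

test_that("structure_volumes reports volumes, ICC share and asymmetry", {
  ph <- sphere_world(n = 25, radius = 10, noise = 0)
  dict <- structure_dict(1, "sphere", "midline", NA)
  rep <- structure_volumes(ph$labels, dict, icc_volume_cm3 = 10)
  count <- sum(as.array(ph$labels) == 1L)
  expect_equal(rep$volume_cm3, count / 1000)
  expect_equal(rep$pct_icc, 100 * count / 1000 / 10)
  expect_lt(abs(rep$volume_cm3 - 4.189) / 4.189, 0.02)

  ph2 <- lateral_world()
  dict2 <- structure_dict(c(11, 12), c("L", "R"), c("left", "right"), c(12, 11))
  rep2 <- structure_volumes(ph2$labels, dict2)
  expect_equal(rep2$volume_cm3[1], rep2$volume_cm3[2])  # mirrored spheres
  expect_equal(rep2$asymmetry_pct, c(0, 0))
  # absent structure: volume 0, asymmetry from the pair's volumes
  only_left <- vol3d(array(ifelse(as.array(ph2$labels) == 12L, 0L,
                                  as.array(ph2$labels)), dim(ph2$labels)))
  rep3 <- structure_volumes(only_left, dict2)
  expect_equal(rep3$volume_cm3[2], 0)
  # pair-level ratio reported on both rows: left twice as reference mean
  expect_equal(rep3$asymmetry_pct, c(200, 200))
  # unknown labels are named in the error
  bad <- vol3d(array(c(99L, rep(0L, 26)), c(3, 3, 3)))
  expect_error(structure_volumes(bad, dict2), "99")
})
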