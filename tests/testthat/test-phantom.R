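# frozen oracle: brute-force voxelized-sphere count, radius 10 at a voxel
# center -> computed once by scanning every voxel of a 25^3 grid
brute_sphere_count <- function(radius, n = 2 * radius + 5) {
  ctr <- rep((n + 1) / 2, 3)
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  sum((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= radius^2)
}

test_that("voxelized sphere volume matches brute force and analytic value", {
  ph <- sphere_world(n = 25, radius = 10, noise = 0)
  count <- sum(as.array(ph$labels) == 1L)
  expect_identical(count, brute_sphere_count(10, 25))
  expect_lt(abs(count - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("noiseless phantom is piecewise constant at the class means", {
  ph <- sphere_world(noise = 0)
  img <- as.array(ph$intensity)
  lab <- as.array(ph$labels)
  expect_true(all(img[lab == 1L] == 150))
  expect_true(all(img[lab == 0L] == 50))
})

test_that("generation is bit-reproducible for a fixed seed", {
  a <- sphere_world(noise = 7, seed = 99)
  b <- sphere_world(noise = 7, seed = 99)
  expect_identical(as.array(a$intensity), as.array(b$intensity))
  expect_identical(as.array(a$labels), as.array(b$labels))
  c <- sphere_world(noise = 7, seed = 100)
  expect_false(identical(as.array(a$intensity), as.array(c$intensity)))
})

test_that("phantom generation does not disturb the caller's RNG", {
  set.seed(5); before <- rnorm(3)
  set.seed(5); invisible(sphere_world(noise = 3, seed = 1)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("a primitive exceeding the grid is rejected by name", {
  expect_error(
    phantom_spec(grid_shape = c(20, 20, 20),
                 structures = list(list(label = 3L, shape = "sphere",
                                        center = c(18, 10, 10), radii = 5,
                                        mean = 100))),
    "structure 1.*label 3.*exceeds grid")
  expect_error(
    phantom_spec(grid_shape = c(20, 20, 20),
                 structures = list(
                   list(label = 1L, center = c(10, 10, 10), radii = 3, mean = 1),
                   list(label = 1L, center = c(10, 10, 10), radii = 2, mean = 2))),
    "distinct")
})

test_that("bias field is smooth, multiplicative and bounded by amplitude", {
  spec <- phantom_spec(grid_shape = rep(24, 3),
                       structures = list(list(label = 1L, center = rep(12, 3),
                                              radii = 8, mean = 100)),
                       background_mean = 50, bias_field = list(amplitude = 0.2),
                       seed = 3)
  ph <- make_phantom(spec)
  flat <- make_phantom(phantom_spec(grid_shape = rep(24, 3),
                                    structures = spec$structures,
                                    background_mean = 50, seed = 3))
  ratio <- as.array(ph$intensity) / as.array(flat$intensity)
  expect_true(all(ratio >= 0.8 - 1e-9 & ratio <= 1.2 + 1e-9))
  expect_gt(max(ratio) - min(ratio), 0.05)  # actually varies
})

test_that("zero deformation and zero noise reproduce the base exactly", {
  ph <- sphere_world(noise = 0)
  lib <- make_library(ph$intensity, ph$labels,
                      deform_spec(3, displacement_amplitude = 0,
                                  per_template_noise_sigma = 0))
  expect_length(lib, 3)
  for (t in lib) {
    expect_equal(as.array(t$intensity), as.array(ph$intensity))
    expect_identical(as.vector(as.array(t$labels)), as.vector(as.array(ph$labels)))
  }
})

test_that("deformed libraries preserve the label set and are seeded", {
  ph <- sphere_world(n = 28, radius = 7, noise = 0)
  lib <- deformed_sphere_library(ph, 20, amplitude = 2, noise = 5, seed = 11)
  expect_length(lib, 20)
  for (t in lib)
    expect_true(all(unique(as.vector(as.array(t$labels))) %in% c(0L, 1L)))
  lib2 <- deformed_sphere_library(ph, 20, amplitude = 2, noise = 5, seed = 11)
  expect_identical(as.array(lib[[7]]$intensity), as.array(lib2[[7]]$intensity))
})

test_that("2 mm deformations move the sphere but keep it overlapping", {
  ph <- sphere_world(n = 32, radius = 8, noise = 0)
  lib <- deformed_sphere_library(ph, 5, amplitude = 2, smoothness = 8,
                                 noise = 0, seed = 2)
  for (t in lib) {
    d <- dice(as.array(t$labels) == 1L, as.array(ph$labels) == 1L)
    expect_gt(d, 0)
    expect_lt(d, 1)
  }
})

test_that("excessive displacement amplitude is rejected", {
  ph <- sphere_world(n = 24, radius = 10, noise = 0)  # 2-voxel margin
  expect_error(make_library(ph$intensity, ph$labels, deform_spec(2, 5, 8)),
               "too large")
})

test_that("flip augmentation doubles the library and swaps lateral labels", {
  ph <- lateral_world()
  lib <- deformed_sphere_library(ph, 3, amplitude = 1, noise = 2, seed = 4)
  aug <- flip_augment(lib, axis = 1, swap = cbind(11L, 12L))
  expect_length(aug, 6)
  expect_true(attr(aug, "flip_augmented"))
  # mirrored copy of template 1: reflected 11-voxels now carry 12
  l1 <- as.array(lib[[1]]$labels)
  m1 <- as.array(aug[[4]]$labels)
  refl <- l1[dim(l1)[1]:1, , ]
  expect_identical(m1 == 12L, refl == 11L)
  expect_identical(m1 == 11L, refl == 12L)
  # labeled voxel counts preserved per template (reflection is volume-preserving)
  expect_equal(sum(m1 != 0L), sum(l1 != 0L))
})

test_that("flipping the mirrored half again restores the originals", {
  ph <- lateral_world()
  lib <- deformed_sphere_library(ph, 2, amplitude = 1, noise = 2, seed = 8)
  aug <- flip_augment(lib, axis = 1, swap = cbind(11L, 12L))
  back <- flip_augment(aug[3:4], axis = 1, swap = cbind(11L, 12L))
  for (i in 1:2) {
    expect_identical(as.array(back[[i + 2]]$intensity), as.array(lib[[i]]$intensity))
    expect_identical(as.vector(as.array(back[[i + 2]]$labels)),
                     as.vector(as.array(lib[[i]]$labels)))
  }
})

test_that("swap on a 2-voxel toy volume matches the coordinate-reflection oracle", {
  lab <- vol3d(array(c(11L, 12L), c(2, 1, 1)))
  img <- vol3d(array(c(1, 2), c(2, 1, 1)))
  lib <- atlas_library(list(list(intensity = img, labels = lab)))
  aug <- flip_augment(lib, axis = 1, swap = cbind(11L, 12L))
  # reflection sends voxel 1 -> 2; label 11 there becomes 12 after the swap
  expect_identical(as.vector(as.array(aug[[2]]$labels)), c(11L, 12L))
  expect_equal(as.vector(as.array(aug[[2]]$intensity)), c(2, 1))
})

test_that("lateralized labels without a swap table are rejected", {
  ph <- lateral_world()
  lib <- atlas_library(list(list(intensity = ph$intensity, labels = ph$labels)))
  expect_error(flip_augment(lib, lateralized = c(11L, 12L)),
               "not in swap table")
  expect_silent(flip_augment(lib, swap = cbind(11L, 12L),
                             lateralized = c(11L, 12L)))
})
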