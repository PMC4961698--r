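const_lib <- function(vals, labels = NULL, d = c(length(vals[[1]]), 1, 1)) {
  # tiny helper: templates from explicit intensity vectors (labels default 0)
  atlas_library(lapply(seq_along(vals), function(i) {
    list(intensity = vol3d(array(vals[[i]], d)),
         labels = vol3d(array(if (is.null(labels)) 0L else labels[[i]], d)))
  }))
}

test_that("fusion_params validates its fields", {
  p <- fusion_params()
  expect_equal(p$n_templates, 25L)
  expect_equal(p$patch_size_1, 3L)
  expect_equal(p$patch_size_2, 5L)
  expect_equal(p$search_radius, 4L)
  expect_equal(p$sigma_d, sqrt(2))
  expect_error(fusion_params(patch_size_1 = 4), "odd")
  expect_error(fusion_params(lambda = 0), "lambda")
  expect_error(fusion_params(scale_weights = c(0.7, 0.7)), "summing to 1")
  expect_error(fusion_params(ss_threshold = 1.5), "0, 1")
})

test_that("select_templates ranks by SSD with stable ties", {
  subj <- vol3d(array(0, c(5, 1, 1)))
  lib <- const_lib(list(c(1, 2, 0, 0, 0),    # SSD 5
                        c(1, 0, 0, 0, 0),    # SSD 1
                        c(1, 1, 1, 0, 0)))   # SSD 3
  mask <- array(TRUE, c(5, 1, 1))
  sel <- select_templates(subj, lib, mask, 2)
  expect_equal(attr(sel, "index"), c(2L, 3L))
  expect_equal(attr(sel, "ssd"), c(1, 3))
  # n >= library size: whole ranked library
  all3 <- select_templates(subj, lib, mask, 10)
  expect_equal(attr(all3, "index"), c(2L, 3L, 1L))
  expect_error(select_templates(subj, lib, array(FALSE, c(5, 1, 1)), 2),
               "empty region mask")
})

test_that("structural similarity matches its closed forms", {
  p <- array(c(0, 2, 1, 3), c(4, 1, 1))
  expect_equal(structural_similarity(p, p), 1)
  a <- array(c(0, 2), c(2, 1, 1))     # mean 1, sd 1
  b <- array(c(1, 3), c(2, 1, 1))     # mean 2, sd 1
  expect_equal(structural_similarity(a, b), 0.8)
  expect_lt(structural_similarity(a, -a), 0)
  # both constant: 1 when equal means, luminance term otherwise
  c1 <- array(5, c(2, 1, 1)); c2 <- array(10, c(2, 1, 1))
  expect_equal(structural_similarity(c1, c1), 1)
  expect_equal(structural_similarity(c1, c2), 2 * 50 / 125)
  expect_error(structural_similarity(p, a), "same size")
})

test_that("adaptive_h2 is lambda * min distance + epsilon", {
  subj <- vol3d(array(0, c(1, 1, 1)))
  lib <- const_lib(list(2, 3), d = c(1, 1, 1))   # squared distances 4 and 9
  h2 <- adaptive_h2(subj, c(1, 1, 1), lib, patch_size = 1, search_radius = 1,
                    lambda = 0.15, epsilon = 1e-4)
  expect_equal(h2, 0.15 * 4 + 1e-4)
  h2b <- adaptive_h2(subj, c(1, 1, 1), lib, 1, 1, lambda = 0.30,
                     epsilon = 1e-4)
  expect_equal(h2b - 1e-4, 2 * (h2 - 1e-4))      # linear in lambda
  # identical patch in the library -> h2 = epsilon
  lib0 <- const_lib(list(0), d = c(1, 1, 1))
  expect_equal(adaptive_h2(subj, c(1, 1, 1), lib0, 1, 1, epsilon = 1e-4), 1e-4)
})

test_that("patch_weight matches its closed forms and the ss gate", {
  img <- vol3d(array(seq_len(27), c(3, 3, 3)))
  p <- extract_patch(img, c(2, 2, 2), 3)
  expect_equal(patch_weight(p, p, h2 = 1), 1)    # both exponents zero
  # ss gate: negated patch fails any th >= 0
  img_neg <- vol3d(-array(seq_len(27), c(3, 3, 3)))
  q <- extract_patch(img_neg, c(2, 2, 2), 3)
  expect_equal(patch_weight(p, q, h2 = 1), 0)
  # ||p - q||^2 = h2 at zero spatial offset -> exp(-1)
  img_off <- vol3d(array(seq_len(27) + 0.1, c(3, 3, 3)))
  q2 <- extract_patch(img_off, c(2, 2, 2), 3)
  expect_equal(patch_weight(p, q2, h2 = 27 * 0.01), exp(-1), tolerance = 1e-12)
  expect_error(patch_weight(p, p, h2 = 0), "h2")
})

test_that("unanimous templates give a unit vote for their label", {
  d <- c(7, 7, 7)
  lab <- array(0L, d); lab[2:6, 2:6, 2:6] <- 1L
  set.seed(1)
  lib <- atlas_library(lapply(1:2, function(i)
    list(intensity = vol3d(array(rnorm(prod(d), 100, 5), d)),
         labels = vol3d(lab))))
  subj <- vol3d(array(rnorm(prod(d), 100, 5), d))
  mask <- array(FALSE, d); mask[4, 4, 4] <- TRUE
  v <- blockwise_vote(subj, lib, mask, patch_size = 3,
                      fusion_params(search_radius = 1, block_size = 1,
                                    ss_threshold = 0))
  k1 <- match(1L, v$labels)
  expect_equal(v$votes[4, 4, 4, k1], 1)
  expect_equal(sum(v$votes[4, 4, 4, ]), 1)
})

test_that("block size 1 reproduces the literal voxel-wise oracle to 1e-10", {
  d <- c(8, 8, 8)
  set.seed(42)
  base <- sphere_world(n = 8, radius = 3, bg = 60, fg = 160, noise = 4,
                       seed = 3)
  lib <- deformed_sphere_library(base, 2, amplitude = 1, smoothness = 4,
                                 noise = 4, seed = 9)
  mask <- array(FALSE, d); mask[2:6, 2:6, 2:6] <- TRUE   # includes boundary-2
  pars <- fusion_params(search_radius = 1, block_size = 1)
  v <- blockwise_vote(base$intensity, lib, mask, patch_size = 3, pars)
  o <- oracle_vote(as.array(base$intensity),
                   lapply(lib, function(t) as.array(t$intensity)),
                   lapply(lib, function(t) as.array(t$labels)),
                   mask, patch_r = 1, search_r = 1, block_r = 0,
                   lambda = pars$lambda, eps = pars$epsilon,
                   sigma_d = pars$sigma_d, th = pars$ss_threshold)
  expect_equal(v$labels, o$labels)
  expect_lt(max(abs(v$votes - o$votes)), 1e-10)
})

test_that("block-wise voting matches the brute-force block oracle", {
  d <- c(5, 5, 5)
  set.seed(7)
  lab <- array(0L, d); lab[2:4, 2:4, 2:4] <- 1L
  tmpl_int <- array(rnorm(prod(d), 100, 10), d)
  lib <- atlas_library(list(list(intensity = vol3d(tmpl_int),
                                 labels = vol3d(lab))))
  subj <- vol3d(tmpl_int + rnorm(prod(d), 0, 2))
  mask <- array(TRUE, d)
  pars <- fusion_params(search_radius = 1, block_size = 3, ss_threshold = 0.5)
  v <- blockwise_vote(subj, lib, mask, patch_size = 3, pars)
  o <- oracle_vote(as.array(subj), list(tmpl_int), list(lab), mask,
                   patch_r = 1, search_r = 1, block_r = 1,
                   lambda = pars$lambda, eps = pars$epsilon,
                   sigma_d = pars$sigma_d, th = 0.5)
  expect_lt(max(abs(v$votes - o$votes)), 1e-10)
  # and in the per-block normalization variant
  pars2 <- fusion_params(search_radius = 1, block_size = 3,
                         ss_threshold = 0.5, normalize_blocks = TRUE)
  v2 <- blockwise_vote(subj, lib, mask, patch_size = 3, pars2)
  o2 <- oracle_vote(as.array(subj), list(tmpl_int), list(lab), mask,
                    patch_r = 1, search_r = 1, block_r = 1,
                    lambda = pars$lambda, eps = pars$epsilon,
                    sigma_d = pars$sigma_d, th = 0.5, normalize_blocks = TRUE)
  expect_lt(max(abs(v2$votes - o2$votes)), 1e-10)
})

test_that("votes are conserved: per-voxel sums are 1 where votes were cast", {
  for (seed in 1:3) {
    base <- sphere_world(n = 12, radius = 4, noise = 5, seed = seed)
    lib <- deformed_sphere_library(base, 3, amplitude = 1, smoothness = 4,
                                   noise = 5, seed = seed + 10)
    mask <- region_mask_from_library(lib, 1L, 2L)
    v <- blockwise_vote(base$intensity, lib, mask, patch_size = 3,
                        fusion_params(search_radius = 2))
    sums <- apply(v$votes, 1:3, sum)
    voted <- sums > 0
    expect_true(all(mask[] <= voted))            # every masked voxel voted
    expect_lt(max(abs(sums[voted] - 1)), 1e-6)
    expect_true(all(v$votes >= 0))
  }
})

test_that("multiscale late fusion averages and renormalizes", {
  mk <- function(a, b) structure(list(
    votes = array(c(a, b), c(1, 1, 1, 2)), labels = c(0L, 1L),
    voxel_size = c(1, 1, 1)), class = "vote_map")
  v1 <- mk(0.3, 0.7); v2 <- mk(0.9, 0.1)
  f <- multiscale_fuse(v1, v2)
  expect_equal(f$votes[1, 1, 1, ], c(0.6, 0.4))
  expect_equal(multiscale_fuse(v1, v1)$votes, v1$votes)   # idempotence
  # v1 = 1, v2 = 0 -> fused 0.5
  f2 <- multiscale_fuse(mk(0, 1), mk(1, 0))
  expect_equal(f2$votes[1, 1, 1, 2], 0.5)
  v3 <- mk(0.5, 0.5); v3$labels <- c(0L, 2L)
  expect_error(multiscale_fuse(v1, v3), "label sets")
  expect_error(multiscale_fuse(v1, v2, weights = c(0.6, 0.6)), "summing to 1")
})

test_that("label decision takes the argmax with ties to the smallest label", {
  mk <- function(vv, labels) structure(list(
    votes = array(vv, c(1, 1, 1, length(vv))), labels = labels,
    voxel_size = c(1, 1, 1)), class = "vote_map")
  expect_equal(as.vector(as.array(decide_labels(mk(c(0.2, 0.5, 0.3), 0:2)))), 1L)
  expect_equal(as.vector(as.array(decide_labels(mk(c(0.4, 0.6), 0:1)))), 1L)
  expect_equal(as.vector(as.array(decide_labels(mk(c(0.6, 0.4), 0:1)))), 0L)
  expect_equal(as.vector(as.array(decide_labels(mk(c(0.5, 0.5), 0:1)))), 0L)
  # exhaustive binary check around the 0.5 threshold
  for (v1 in c(0.49, 0.5, 0.51)) {
    lab <- as.vector(as.array(decide_labels(mk(c(1 - v1, v1), 0:1))))
    expect_equal(lab, if (v1 > 0.5) 1L else 0L)
  }
})

test_that("self-segmentation reproduces the single template exactly", {
  base <- sphere_world(n = 24, radius = 6, noise = 5, seed = 17)
  lib <- atlas_library(list(list(intensity = base$intensity,
                                 labels = base$labels)))
  mask <- region_mask_from_library(lib, 1L, 2L)
  seg <- segment(base$intensity, lib, mask,
                 fusion_params(n_templates = 1, search_radius = 2))
  expect_identical(as.array(seg)[mask], as.array(base$labels)[mask])
})

test_that("mirroring subject and library mirrors the segmentation", {
  ph <- lateral_world(n = 26, radius = 5, noise = 4, seed = 31)
  lib <- deformed_sphere_library(ph, 3, amplitude = 1, smoothness = 6,
                                 noise = 4, seed = 32)
  swap <- cbind(11L, 12L)
  pars <- fusion_params(n_templates = 3, search_radius = 2)
  mask <- region_mask_from_library(lib, c(11L, 12L), 2L)
  seg <- segment(ph$intensity, lib, mask, pars)

  mlib <- flip_augment(lib, axis = 1, swap = swap)[(length(lib) + 1):(2 * length(lib))]
  msub <- mirror_volume(ph$intensity, 1)
  mmask <- as.array(mirror_volume(vol3d(array(as.integer(mask), dim(mask))), 1)) != 0
  mseg <- segment(msub, mlib, mmask, pars)

  # mirror of the unmirrored output with lateral labels swapped
  expected <- as.array(mirror_volume(seg, 1))
  sw <- expected
  sw[expected == 11L] <- 12L
  sw[expected == 12L] <- 11L
  got <- as.array(mseg)
  attributes(got) <- list(dim = dim(got))
  attributes(sw) <- list(dim = dim(sw))
  expect_identical(got, sw)
})
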