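#' Fusion engine parameters
#'
#' All constants of the non-local label fusion engine with the defaults
#' found optimal for subcortical segmentation on 1 mm isotropic grids:
#' N = 25 selected templates, patch edges 3 and 5 voxels (the two scales of
#' the late fusion), a 9x9x9 search volume (radius 4), 3x3x3 vote blocks,
#' bandwidth scale lambda = 0.15, stability constant epsilon = 1e-4,
#' spatial bandwidth sigma_d = sqrt(2) mm, structural-similarity gate 0.9,
#' and equal late-fusion weights.
#'
#' @param n_templates number of templates selected from the library (N).
#' @param patch_size_1,patch_size_2 odd patch cube edges in voxels (the two
#'   similarity scales).
#' @param search_radius half-width of the cubic search volume in voxels
#'   (4 gives 9x9x9).
#' @param block_size odd cube edge of the block-wise vote.
#' @param lambda bandwidth scale of the adaptive kernel width.
#' @param epsilon stability constant added to the minimal patch distance.
#' @param sigma_d spatial bandwidth in mm.
#' @param ss_threshold structural-similarity gate in `[0, 1]`; comparisons
#'   at or below it get weight zero.
#' @param scale_weights nonnegative pair summing to 1, late-fusion weights
#'   of the two patch scales.
#' @param normalize_blocks if `TRUE`, each block's votes are normalized by
#'   its total weight before the overcomplete aggregation; the default
#'   (`FALSE`) normalizes once per voxel after aggregation.
#' @return object of class `fusion_params`.
#' @export
fusion_params <- function(n_templates = 25L, patch_size_1 = 3L,
                          patch_size_2 = 5L, search_radius = 4L,
                          block_size = 3L, lambda = 0.15, epsilon = 1e-4,
                          sigma_d = sqrt(2), ss_threshold = 0.9,
                          scale_weights = c(0.5, 0.5),
                          normalize_blocks = FALSE) {
  chk_odd <- function(v, nm) {
    v <- as.integer(v)
    if (v < 1L || v %% 2L == 0L) stop(nm, " must be a positive odd integer")
    v
  }
  p <- list(n_templates = as.integer(n_templates),
            patch_size_1 = chk_odd(patch_size_1, "patch_size_1"),
            patch_size_2 = chk_odd(patch_size_2, "patch_size_2"),
            search_radius = as.integer(search_radius),
            block_size = chk_odd(block_size, "block_size"),
            lambda = lambda, epsilon = epsilon, sigma_d = sigma_d,
            ss_threshold = ss_threshold,
            scale_weights = as.numeric(scale_weights),
            normalize_blocks = isTRUE(normalize_blocks))
  if (p$n_templates < 1L) stop("n_templates must be >= 1")
  if (p$search_radius < 1L) stop("search_radius must be >= 1")
  if (p$lambda <= 0) stop("lambda must be > 0")
  if (p$epsilon <= 0) stop("epsilon must be > 0")
  if (p$sigma_d <= 0) stop("sigma_d must be > 0")
  if (p$ss_threshold < 0 || p$ss_threshold > 1)
    stop("ss_threshold must be in [0, 1]")
  if (length(p$scale_weights) != 2L || any(p$scale_weights < 0) ||
      abs(sum(p$scale_weights) - 1) > 1e-12)
    stop("scale_weights must be two nonnegative numbers summing to 1")
  structure(p, class = "fusion_params")
}

#' Select the most similar templates
#'
#' Ranks the library by the sum of squared intensity differences (SSD) to
#' the subject over a region mask and returns the `n` best, the template
#' preselection that precedes voting. Deterministic: ties break toward the
#' lower library index.
#'
#' @param subject intensity [vol3d], already on the library intensity scale.
#' @param library an [atlas_library].
#' @param region_mask binary volume; the comparison region.
#' @param n number of templates to keep; if `n >=` library size the whole
#'   ranked library is returned.
#' @return an [atlas_library] subset with attributes `ssd` and `index`
#'   (ranked SSDs and original library indices).
#' @export
select_templates <- function(subject, library, region_mask, n) {
  stopifnot(inherits(library, "atlas_library"))
  inside <- as.vector(as_array3d(region_mask) != 0)
  if (!any(inside)) stop("empty region mask")
  sv <- as.vector(as_array3d(subject))[inside]
  ssd <- vapply(library, function(t) {
    stop_if_grid_mismatch(subject, t$intensity, "subject and template")
    sum((sv - as.vector(as_array3d(t$intensity))[inside])^2)
  }, numeric(1))
  ord <- order(ssd)                       # stable: ties keep library order
  keep <- ord[seq_len(min(as.integer(n), length(library)))]
  out <- library[keep]
  attr(out, "ssd") <- ssd[keep]
  attr(out, "index") <- keep
  out
}

#' Extract a cubic intensity patch
#'
#' @param image intensity [vol3d].
#' @param center voxel coordinates (1-based, length 3) of the patch center.
#' @param size odd cube edge in voxels.
#' @return numeric array of edge `size` with attributes `center_mm` (center
#'   coordinates in mm) and `valid` (logical array, `FALSE` where the patch
#'   ran off the grid; those entries are NA).
#' @export
extract_patch <- function(image, center, size) {
  size <- as.integer(size)
  if (size %% 2L == 0L) stop("patch size must be odd")
  r <- size %/% 2L
  d <- dim(image)
  vs <- voxel_size(image)
  idx <- lapply(1:3, function(a) center[a] + (-r):r)
  out <- array(NA_real_, rep(size, 3))
  ok <- list(idx[[1]] >= 1 & idx[[1]] <= d[1],
             idx[[2]] >= 1 & idx[[2]] <= d[2],
             idx[[3]] >= 1 & idx[[3]] <= d[3])
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    as_array3d(image)[idx[[1]][ok[[1]]], idx[[2]][ok[[2]]], idx[[3]][ok[[3]]]]
  structure(out, center_mm = (center - 1) * vs, valid = !is.na(out))
}

#' Structural similarity between two patches
#'
#' The luminance-times-contrast product
#' `ss = (2 mu_p mu_q / (mu_p^2 + mu_q^2)) * (2 sd_p sd_q / (sd_p^2 + sd_q^2))`
#' used to gate patch comparisons before the expensive distance weight is
#' computed. Equals 1 for identical non-constant patches and is negative
#' when the means have opposite signs. If both patches are constant, ss is
#' 1 when their means are equal and otherwise the luminance term alone (the
#' sd term is treated as 1); patch entries marked invalid (off-grid) are
#' ignored.
#'
#' @param p,q patches from [extract_patch] (or plain numeric arrays of the
#'   same size).
#' @return scalar in `[-1, 1]`.
#' @export
structural_similarity <- function(p, q) {
  if (!identical(dim(p), dim(q))) stop("patches must have the same size")
  ok <- is.finite(p) & is.finite(q)
  pv <- p[ok]; qv <- q[ok]
  if (length(pv) == 0L) stop("no overlapping valid patch entries")
  m1 <- mean(pv); m2 <- mean(qv)
  s1 <- sqrt(mean((pv - m1)^2)); s2 <- sqrt(mean((qv - m2)^2))
  tiny <- 1e-12
  lum <- if (m1^2 + m2^2 < tiny) 1 else 2 * m1 * m2 / (m1^2 + m2^2)
  if (s1 < tiny && s2 < tiny)
    return(if (abs(m1 - m2) < tiny) 1 else lum)
  con <- if (s1^2 + s2^2 < tiny) 1 else 2 * s1 * s2 / (s1^2 + s2^2)
  lum * con
}

#' Adaptive bandwidth h^2 at a voxel
#'
#' The kernel bandwidth is tied to the best match available:
#' `h^2 = lambda * min ||P(x_i) - P(x_sj)||^2 + epsilon`, the minimum taken
#' over every candidate patch in the search volume of every selected
#' template. When the subject patch exists verbatim in the library the
#' minimum is 0 and `h^2 = epsilon`, making the exact match dominate.
#'
#' @param subject intensity [vol3d].
#' @param center voxel coordinates (1-based) of the subject patch center.
#' @param selected an [atlas_library] (the selected templates).
#' @param patch_size odd patch edge.
#' @param search_radius search half-width in voxels.
#' @param lambda bandwidth scale.
#' @param epsilon stability constant.
#' @return scalar `h^2` in squared intensity units.
#' @export
adaptive_h2 <- function(subject, center, selected, patch_size,
                        search_radius, lambda = 0.15, epsilon = 1e-4) {
  dists <- candidate_patch_dist2(subject, center, selected, patch_size,
                                 search_radius)
  if (length(dists) == 0L)
    stop("no candidate patches in the search volume at voxel ",
         paste(center, collapse = ","))
  lambda * min(dists) + epsilon
}

# squared patch distances to all in-grid candidates (cropped + rescaled)
candidate_patch_dist2 <- function(subject, center, selected, patch_size,
                                  search_radius) {
  p <- extract_patch(subject, center, patch_size)
  d <- dim(subject)
  offs <- expand.grid(dx = -search_radius:search_radius,
                      dy = -search_radius:search_radius,
                      dz = -search_radius:search_radius)
  out <- numeric(0)
  for (t in selected) {
    for (r in seq_len(nrow(offs))) {
      ctr <- center + as.integer(offs[r, ])
      if (any(ctr < 1) || any(ctr > d)) next
      q <- extract_patch(t$intensity, ctr, patch_size)
      out <- c(out, patch_dist2(p, q))
    }
  }
  out
}

# squared L2 patch distance over jointly valid entries, rescaled to the
# full patch volume so cropped candidates stay comparable
patch_dist2 <- function(p, q) {
  ok <- is.finite(p) & is.finite(q)
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  sum((p[ok] - q[ok])^2) * length(p) / n
}

#' Weight of one patch comparison
#'
#' `w = exp(-||c_p - c_q||^2 / (2 sigma_d^2)) * exp(-||p - q||^2 / h2)`
#' when the structural similarity of the patches exceeds the gate, else
#' exactly 0. The first factor downweights spatially distant samples (the
#' locality principle); the second is the non-local means intensity kernel.
#'
#' @param p,q patches from [extract_patch] (carrying `center_mm`).
#' @param h2 bandwidth from [adaptive_h2]; must be > 0.
#' @param params a [fusion_params] (uses `sigma_d` and `ss_threshold`).
#' @return nonnegative scalar weight.
#' @export
patch_weight <- function(p, q, h2, params = fusion_params()) {
  if (h2 <= 0) stop("h2 must be > 0")
  if (structural_similarity(p, q) <= params$ss_threshold) return(0)
  cp <- attr(p, "center_mm"); cq <- attr(q, "center_mm")
  if (is.null(cp) || is.null(cq))
    stop("patches must carry center_mm (use extract_patch)")
  d2 <- sum((cp - cq)^2)
  exp(-d2 / (2 * params$sigma_d^2)) * exp(-patch_dist2(p, q) / h2)
}

#' Block-wise overcomplete non-local voting
#'
#' Runs the voting kernel at one patch scale: for every voxel of the region
#' mask, candidate patches of all selected templates inside the search
#' volume are compared (structural-similarity gate, adaptive bandwidth,
#' spatial weighting) and each accepted weight votes for the whole label
#' block around the matched template voxel; overlapping block votes are
#' summed and the per-voxel label vector normalized to 1. With
#' `block_size = 1` this reduces to classical voxel-wise non-local label
#' fusion. Voxels where every comparison is gated out receive a uniform
#' vote over the labels observed in their search volume and are counted in
#' the `n_fallback` attribute.
#'
#' @param subject intensity [vol3d] on the library intensity scale.
#' @param selected an [atlas_library] (typically from [select_templates]).
#' @param region_mask binary volume of voxels to label.
#' @param patch_size odd patch edge for this scale.
#' @param params a [fusion_params].
#' @return a `vote_map`: list with `votes` (4D array, x-y-z-label),
#'   `labels` (label values), `voxel_size`, and attributes `n_fallback`,
#'   `fallback_voxels`.
#' @export
blockwise_vote <- function(subject, selected, region_mask, patch_size,
                           params = fusion_params()) {
  stopifnot(inherits(selected, "atlas_library"))
  stopifnot(inherits(params, "fusion_params"))
  mask <- as_array3d(region_mask) != 0
  if (!any(mask)) stop("empty region mask")
  for (t in selected) stop_if_grid_mismatch(subject, t$intensity,
                                            "subject and template")
  labels <- library_labels(selected)
  d <- dim(subject)
  res <- cpp_blockwise_vote(
    as.numeric(as_array3d(subject)), as.integer(d),
    as.numeric(voxel_size(subject)),
    lapply(selected, function(t) as.numeric(as_array3d(t$intensity))),
    lapply(selected, function(t) as.integer(as_array3d(t$labels))),
    as.logical(mask), as.integer(labels),
    as.integer(patch_size) %/% 2L, params$search_radius,
    params$block_size %/% 2L, params$lambda, params$epsilon,
    params$sigma_d, params$ss_threshold, params$normalize_blocks)
  votes <- array(res$votes, c(d, length(labels)))
  structure(list(votes = votes, labels = labels,
                 voxel_size = voxel_size(subject)),
            n_fallback = res$n_fallback,
            fallback_voxels = res$fallback_voxels,
            class = "vote_map")
}

#' @export
print.vote_map <- function(x, ...) {
  d <- dim(x$votes)
  cat(sprintf("<vote_map> %d x %d x %d voxels, %d labels (%s)\n",
              d[1], d[2], d[3], d[4], paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Late fusion of two vote maps
#'
#' Element-wise weighted average of the vote maps computed at two patch
#' scales, `v = w1 v1 + w2 v2` (default weights 0.5/0.5), renormalized per
#' voxel.
#'
#' @param v1,v2 `vote_map`s on the same grid with the same label set.
#' @param weights nonnegative pair summing to 1.
#' @return fused `vote_map`.
#' @export
multiscale_fuse <- function(v1, v2, weights = c(0.5, 0.5)) {
  if (!identical(v1$labels, v2$labels))
    stop("vote maps have different label sets")
  if (!identical(dim(v1$votes), dim(v2$votes)))
    stop("vote maps have different grids")
  if (length(weights) != 2L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-12)
    stop("weights must be two nonnegative numbers summing to 1")
  v <- weights[1] * v1$votes + weights[2] * v2$votes
  tot <- apply(v, 1:3, sum)
  nz <- tot > 0
  K <- dim(v)[4]
  for (k in seq_len(K)) {
    vk <- v[, , , k]
    vk[nz] <- vk[nz] / tot[nz]
    v[, , , k] <- vk
  }
  structure(list(votes = v, labels = v1$labels, voxel_size = v1$voxel_size),
            class = "vote_map")
}

#' Final label decision
#'
#' Picks, per voxel, the most voted label; exact ties break toward the
#' smallest label value (background-favouring for the usual 0-first label
#' sets; in the binary case a vote of exactly 0.5 goes to background).
#' Voxels with no votes get `background`.
#'
#' @param votes a `vote_map`.
#' @param background label assigned where no votes were cast, default 0.
#' @return a label [vol3d] (integer).
#' @export
decide_labels <- function(votes, background = 0L) {
  stopifnot(inherits(votes, "vote_map"))
  v <- votes$votes
  d <- dim(v)
  if (d[4] < 1L) stop("empty vote vector")
  nvox <- prod(d[1:3])
  m <- matrix(v, nvox, d[4])
  tot <- rowSums(m)
  best <- max.col(m, ties.method = "first")   # labels sorted -> smallest wins
  out <- votes$labels[best]
  out[tot <= 0] <- as.integer(background)
  vol3d(array(as.integer(out), d[1:3]), votes$voxel_size)
}

#' Region mask for a set of structure labels
#'
#' Union of the given labels across the selected templates, dilated by the
#' search radius: the standard multi-atlas restriction of computation to
#' where the library says the structures can plausibly be.
#'
#' @param selected an [atlas_library].
#' @param labels integer label values of interest; default all non-zero
#'   labels in the library.
#' @param search_radius dilation radius in voxels.
#' @return logical 3D array.
#' @export
region_mask_from_library <- function(selected, labels = NULL,
                                     search_radius = 4L) {
  if (is.null(labels)) labels <- setdiff(library_labels(selected), 0L)
  d <- dim(selected[[1]]$labels)
  m <- array(FALSE, d)
  for (t in selected) m <- m | (as_array3d(t$labels) %in% labels)
  dim(m) <- d
  dilate_mask(m, search_radius)
}

#' Segment a subject by multi-scale non-local label fusion
#'
#' The full fusion chain: template preselection by SSD, block-wise voting
#' at the two patch scales, late fusion of the two vote maps, and the
#' argmax label decision. Deterministic given inputs and parameters. The
#' subject must already be on the library's intensity scale (see
#' [tms_estimate_means] and [piecewise_linear_map]).
#'
#' @param subject intensity [vol3d].
#' @param library an [atlas_library].
#' @param region_mask binary volume of voxels to label; see
#'   [region_mask_from_library].
#' @param params a [fusion_params].
#' @return label [vol3d]; background (0) outside the mask. The fused
#'   `vote_map` is attached as attribute `votes`.
#' @export
segment <- function(subject, library, region_mask, params = fusion_params()) {
  stopifnot(inherits(params, "fusion_params"))
  selected <- select_templates(subject, library, region_mask,
                               params$n_templates)
  v1 <- blockwise_vote(subject, selected, region_mask,
                       params$patch_size_1, params)
  v2 <- blockwise_vote(subject, selected, region_mask,
                       params$patch_size_2, params)
  fused <- multiscale_fuse(v1, v2, params$scale_weights)
  lab <- decide_labels(fused)
  out <- as_array3d(lab)
  out[as_array3d(region_mask) == 0] <- 0L
  structure(vol3d(array(as.integer(out), dim(lab)), voxel_size(lab)),
            votes = fused)
}
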