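#' Synthetic phantom specification
#'
#' Describes a seeded synthetic intensity/label volume: a set of geometric
#' structures (spheres, ellipsoids, boxes) with per-structure label and mean
#' intensity, embedded in a background, with optional Gaussian noise and a
#' smooth multiplicative bias field. Phantoms stand in for co-registered
#' T1-weighted-like images and their expert label maps, so the rest of the
#' package is testable without any imaging data.
#'
#' @param grid_shape integer length-3, grid size in voxels.
#' @param voxel_size mm per axis (scalar or length-3), default 1 mm isotropic.
#' @param structures list of structures, each a list with fields `label`
#'   (positive integer), `shape` (`"sphere"`, `"ellipsoid"` or `"box"`),
#'   `center` (voxel coordinates, 1-based, length 3), `radii` (voxels;
#'   scalar for spheres, length 3 otherwise), `mean` (intensity). Later
#'   structures overwrite earlier ones where they overlap.
#' @param background_label integer label of unlabeled space, default 0.
#' @param background_mean background intensity, default 0.
#' @param noise_sigma standard deviation of additive Gaussian noise, in
#'   intensity units; default 0.
#' @param bias_field `NULL` or a list with `amplitude` (fraction of the mean
#'   foreground intensity, e.g. 0.2 for a 20% modulation) and `order`
#'   (polynomial order, default 2) describing a smooth multiplicative field.
#' @param seed integer RNG seed; generation is bit-reproducible for a fixed
#'   spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size = 1, structures,
                         background_label = 0L, background_mean = 0,
                         noise_sigma = 0, bias_field = NULL, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  if (length(structures) < 1L) stop("at least one structure required")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  labels <- vapply(structures, function(s) as.integer(s$label), integer(1))
  if (anyDuplicated(labels)) stop("structure labels must be distinct")
  if (any(labels < 0L)) stop("labels must be non-negative")
  if (any(labels == as.integer(background_label)))
    stop("structure label equals background label")
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    s$shape <- match.arg(s$shape %||% "sphere", c("sphere", "ellipsoid", "box"))
    if (length(s$center) != 3L) stop("structure ", i, ": center must be length 3")
    r <- s$radii
    if (s$shape == "sphere") { if (length(r) == 1L) r <- rep(r, 3L) }
    if (length(r) != 3L) stop("structure ", i, ": radii must be length 1 or 3")
    if (any(r <= 0)) stop("structure ", i, ": radii must be > 0")
    if (any(s$center - r < 1) || any(s$center + r > grid_shape))
      stop("structure ", i, " (label ", s$label, ") exceeds grid bounds")
    s$radii <- r
    structures[[i]] <- s
  }
  if (!is.null(bias_field)) {
    if (is.null(bias_field$amplitude) || bias_field$amplitude < 0)
      stop("bias_field$amplitude must be >= 0")
    bias_field$order <- as.integer(bias_field$order %||% 2L)
  }
  structure(list(grid_shape = grid_shape,
                 voxel_size = if (length(voxel_size) == 1L) rep(voxel_size, 3L) else voxel_size,
                 structures = structures,
                 background_label = as.integer(background_label),
                 background_mean = background_mean,
                 noise_sigma = noise_sigma, bias_field = bias_field,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic intensity/label phantom
#'
#' Rasterizes the structures of a [phantom_spec] onto the grid (a voxel
#' belongs to a structure when its center lies inside the primitive), builds
#' the intensity volume as per-label class means, applies the optional
#' multiplicative bias field, and adds Gaussian noise. Deterministic for a
#' fixed spec and seed.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `intensity` ([vol3d], double) and `labels`
#'   ([vol3d], integer).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  lab <- array(spec$background_label, d)
  img <- array(spec$background_mean, d)
  cx <- seq_len(d[1]); cy <- seq_len(d[2]); cz <- seq_len(d[3])
  for (s in spec$structures) {
    inside <- switch(s$shape,
      sphere = ,
      ellipsoid = {
        ux <- ((cx - s$center[1]) / s$radii[1])^2
        uy <- ((cy - s$center[2]) / s$radii[2])^2
        uz <- ((cz - s$center[3]) / s$radii[3])^2
        outer(outer(ux, uy, `+`), uz, `+`) <= 1
      },
      box = {
        ux <- abs(cx - s$center[1]) <= s$radii[1]
        uy <- abs(cy - s$center[2]) <= s$radii[2]
        uz <- abs(cz - s$center[3]) <= s$radii[3]
        outer(outer(ux, uy, `&`), uz, `&`)
      })
    lab[inside] <- s$label
    img[inside] <- s$mean
  }
  with_seed(spec$seed, {
    if (!is.null(spec$bias_field)) {
      img <- img * bias_field_array(d, spec$bias_field)
    }
    if (spec$noise_sigma > 0) {
      img <- img + array(stats::rnorm(prod(d), 0, spec$noise_sigma), d)
    }
  })
  list(intensity = vol3d(img, spec$voxel_size),
       labels = vol3d(array(as.integer(lab), d), spec$voxel_size))
}

# smooth multiplicative field 1 + amplitude * f, max|f| = 1; seeded
# random low-order polynomial in coordinates normalized to [-1, 1]
bias_field_array <- function(d, bf) {
  xs <- lapply(d, function(n) if (n > 1) seq(-1, 1, length.out = n) else 0)
  ord <- bf$order
  f <- array(0, d)
  # random coefficients for all monomials x^i y^j z^k, 0 < i+j+k <= order
  for (i in 0:ord) for (j in 0:ord) for (k in 0:ord) {
    if (i + j + k == 0 || i + j + k > ord) next
    coef <- stats::rnorm(1)
    f <- f + coef * outer(outer(xs[[1]]^i, xs[[2]]^j, `*`), xs[[3]]^k, `*`)
  }
  m <- max(abs(f))
  if (m > 0) f <- f / m
  1 + bf$amplitude * f
}

#' Library deformation specification
#'
#' Parameters of the random smooth displacement fields used to derive a
#' template library from one base phantom, emulating inter-subject
#' anatomical variability statistically.
#'
#' @param n_templates number of templates to generate.
#' @param displacement_amplitude RMS displacement magnitude in mm.
#' @param displacement_smoothness Gaussian kernel width (sigma, mm) of the
#'   smooth random field.
#' @param per_template_noise_sigma additive Gaussian intensity noise per
#'   template.
#' @param seed integer RNG seed.
#' @return object of class `deform_spec`.
#' @export
deform_spec <- function(n_templates, displacement_amplitude = 2,
                        displacement_smoothness = 8,
                        per_template_noise_sigma = 0, seed = 1L) {
  n_templates <- as.integer(n_templates)
  if (n_templates < 1L) stop("n_templates must be >= 1")
  if (displacement_amplitude < 0) stop("displacement_amplitude must be >= 0")
  if (displacement_smoothness <= 0) stop("displacement_smoothness must be > 0")
  if (per_template_noise_sigma < 0) stop("per_template_noise_sigma must be >= 0")
  structure(list(n_templates = n_templates,
                 displacement_amplitude = displacement_amplitude,
                 displacement_smoothness = displacement_smoothness,
                 per_template_noise_sigma = per_template_noise_sigma,
                 seed = as.integer(seed)),
            class = "deform_spec")
}

#' Atlas library constructor
#'
#' An ordered collection of co-registered (intensity, label) template pairs,
#' the prior knowledge of the fusion engine.
#'
#' @param templates list of lists, each with `intensity` and `labels`
#'   [vol3d]s on a common grid.
#' @param flip_augmented logical, whether mirrored copies are included.
#' @return object of class `atlas_library`.
#' @export
atlas_library <- function(templates, flip_augmented = FALSE) {
  if (length(templates) < 1L) stop("library must contain at least one template")
  g <- templates[[1]]$intensity
  for (i in seq_along(templates)) {
    t <- templates[[i]]
    if (is.null(t$intensity) || is.null(t$labels))
      stop("template ", i, " must have intensity and labels")
    stop_if_grid_mismatch(g, t$intensity, paste0("template ", i, " intensity"))
    stop_if_grid_mismatch(g, t$labels, paste0("template ", i, " labels"))
  }
  structure(templates, flip_augmented = flip_augmented, class = "atlas_library")
}

#' @export
print.atlas_library <- function(x, ...) {
  d <- dim(x[[1]]$intensity)
  cat(sprintf("<atlas_library> %d templates on %d x %d x %d grid%s\n",
              length(x), d[1], d[2], d[3],
              if (isTRUE(attr(x, "flip_augmented"))) " (flip-augmented)" else ""))
  invisible(x)
}

#' @export
`[.atlas_library` <- function(x, i) {
  atlas_library(unclass(x)[i], flip_augmented = attr(x, "flip_augmented"))
}

#' Labels present in a library
#' @param library an [atlas_library].
#' @return sorted integer vector of all label values occurring in any template.
#' @export
library_labels <- function(library) {
  sort(unique(unlist(lapply(library, function(t) unique(as.vector(t$labels))))))
}

#' Generate a deformed template library from a base phantom
#'
#' Applies, per template, one random smooth displacement field to both the
#' intensity and the label volume (the same field, so the pair stays
#' consistent): Gaussian-smoothed white-noise components scaled to the
#' requested RMS magnitude, backward warping with trilinear interpolation
#' for intensities and nearest-neighbour for labels, then per-template
#' additive Gaussian noise. The label set can only shrink, never grow.
#'
#' @param base_intensity,base_labels the base pair ([vol3d]s, same grid).
#' @param deform a [deform_spec].
#' @return an [atlas_library] of `n_templates` pairs.
#' @export
make_library <- function(base_intensity, base_labels, deform) {
  stopifnot(inherits(deform, "deform_spec"))
  stop_if_grid_mismatch(base_intensity, base_labels, "base pair")
  d <- dim(base_intensity)
  vs <- voxel_size(base_intensity)
  bg <- as.integer(names(which.max(table(as.vector(base_labels)))))
  # guard: displacement must not push labeled anatomy off the grid
  if (deform$displacement_amplitude > 0) {
    idx <- which(as_array3d(base_labels) != bg, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      margin_vox <- min(pmin(t(idx) - 1, d - t(idx)))
      # RMS-scale displacements beyond the labeled margin push anatomy off-grid
      if (deform$displacement_amplitude / min(vs) > margin_vox)
        stop("displacement_amplitude ", deform$displacement_amplitude,
             " mm too large: structures would leave the grid (margin ",
             margin_vox, " voxels)")
    }
  }
  templates <- with_seed(deform$seed, {
    lapply(seq_len(deform$n_templates), function(i) {
      if (deform$displacement_amplitude > 0) {
        disp <- random_displacement(d, vs, deform$displacement_amplitude,
                                    deform$displacement_smoothness)
        img <- warp_volume(as_array3d(base_intensity), disp, vs, "linear")
        lab <- warp_volume(as_array3d(base_labels), disp, vs, "nearest")
      } else {
        img <- as_array3d(base_intensity)
        lab <- as_array3d(base_labels)
      }
      if (deform$per_template_noise_sigma > 0)
        img <- img + array(stats::rnorm(prod(d), 0, deform$per_template_noise_sigma), d)
      list(intensity = vol3d(img, vs), labels = vol3d(array(as.integer(lab), d), vs))
    })
  })
  atlas_library(templates)
}

# random smooth displacement field: list of 3 arrays (mm), RMS magnitude = amp
random_displacement <- function(d, vs, amplitude_mm, smoothness_mm) {
  comps <- lapply(1:3, function(ax) {
    w <- array(stats::rnorm(prod(d)), d)
    gaussian_smooth3d(w, smoothness_mm / vs)
  })
  rms <- sqrt(mean(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2))
  if (rms > 0) comps <- lapply(comps, function(a) a * amplitude_mm / rms)
  comps
}

# separable Gaussian smoothing; sigma per axis in voxels
gaussian_smooth3d <- function(x, sigma_vox) {
  d <- dim(x)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    n <- d[ax]
    # dense band matrix: renormalized at the edges (truncated kernel)
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      ok <- idx + off >= 1 & idx + off <= n
      K[cbind(idx[ok], (idx + off)[ok])] <- k[off + r + 1]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    xp <- aperm(x, perm)
    dim(xp) <- c(d[ax], prod(d[-ax]))
    xp <- K %*% xp
    dim(xp) <- c(d[ax], d[setdiff(1:3, ax)])
    x <- aperm(xp, order(perm))
  }
  x
}

# backward warp: output(x) = input(x + disp(x)/voxel); trilinear or NN
warp_volume <- function(x, disp, vs, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(x)
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3])))
  src <- cbind(g[, 1] + as.vector(disp[[1]]) / vs[1],
               g[, 2] + as.vector(disp[[2]]) / vs[2],
               g[, 3] + as.vector(disp[[3]]) / vs[3])
  # clamp to grid; guarded upstream so labeled anatomy never reaches here
  for (j in 1:3) src[, j] <- pmin(pmax(src[, j], 1), d[j])
  if (method == "nearest") {
    ii <- round(src)
    out <- x[cbind(ii[, 1], ii[, 2], ii[, 3])]
  } else {
    f0 <- floor(src)
    fr <- src - f0
    f1 <- pmin(f0 + 1, matrix(d, nrow(src), 3, byrow = TRUE))
    out <- 0
    for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
      w <- (if (bx) fr[, 1] else 1 - fr[, 1]) *
           (if (by) fr[, 2] else 1 - fr[, 2]) *
           (if (bz) fr[, 3] else 1 - fr[, 3])
      ix <- if (bx) f1[, 1] else f0[, 1]
      iy <- if (by) f1[, 2] else f0[, 2]
      iz <- if (bz) f1[, 3] else f0[, 3]
      out <- out + w * x[cbind(ix, iy, iz)]
    }
  }
  array(out, d)
}

#' Flip-augment a template library
#'
#' Doubles a library by mirroring every template across the mid-sagittal
#' plane (grid axis `axis`), exploiting approximate bilateral symmetry:
#' originals first, mirrored copies after. Lateralized labels (left/right
#' pairs) must be swapped in the mirrored copies via `swap`; mirroring is an
#' involution, so flipping the mirrored half again restores the originals.
#'
#' @param library an [atlas_library].
#' @param axis mid-sagittal grid axis, default 1 (x).
#' @param swap `NULL` or a two-column integer matrix / data.frame of
#'   (left label, right label) pairs to exchange in mirrored copies.
#' @param lateralized optional integer vector of labels known to be
#'   lateralized; an error is raised if any is present in the library but
#'   missing from `swap`.
#' @return an [atlas_library] of exactly twice the size, flagged
#'   `flip_augmented`.
#' @export
flip_augment <- function(library, axis = 1L, swap = NULL, lateralized = NULL) {
  stopifnot(inherits(library, "atlas_library"))
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  if (!is.null(swap)) {
    swap <- as.matrix(swap)
    if (ncol(swap) != 2L) stop("swap must have two columns (left, right)")
    storage.mode(swap) <- "integer"
  }
  present <- library_labels(library)
  if (!is.null(lateralized)) {
    missing_lat <- intersect(as.integer(lateralized), present)
    covered <- if (is.null(swap)) integer(0) else as.vector(swap)
    missing_lat <- setdiff(missing_lat, covered)
    if (length(missing_lat) > 0)
      stop("lateralized labels present but not in swap table: ",
           paste(missing_lat, collapse = ", "))
  }
  mirrored <- lapply(library, function(t) {
    mi <- mirror_volume(t$intensity, axis)
    ml <- mirror_volume(t$labels, axis)
    if (!is.null(swap)) {
      v <- as_array3d(ml)
      out <- v
      for (r in seq_len(nrow(swap))) {
        out[v == swap[r, 1]] <- swap[r, 2]
        out[v == swap[r, 2]] <- swap[r, 1]
      }
      ml <- vol3d(out, voxel_size(ml))
    }
    list(intensity = mi, labels = ml)
  })
  atlas_library(c(unclass(library), mirrored), flip_augmented = TRUE)
}
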