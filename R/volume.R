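#' 3D volume container
#'
#' A `vol3d` is a plain 3D array carrying its voxel dimensions in mm, the
#' common currency of the package: intensity volumes are double arrays, label
#' volumes integer arrays. All volumes taking part in one fusion run must
#' share a grid (same array dimensions and voxel size), typically a 1 mm
#' isotropic stereotactic grid.
#'
#' @param data 3D numeric or integer array.
#' @param voxel_size numeric length-1 or length-3, mm per axis. Default 1 mm
#'   isotropic.
#' @return object of class `vol3d` (an array with a `voxel_size` attribute).
#' @export
vol3d <- function(data, voxel_size = 1) {
  if (length(dim(data)) != 3L)
    stop("vol3d requires a 3D array, got ", length(dim(data)), " dims")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 1 or 3 positive finite numbers (mm)")
  structure(data, voxel_size = voxel_size, class = c("vol3d", class(data)))
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x)
  vs <- attr(x, "voxel_size")
  cat(sprintf("<vol3d> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, %s\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3], typeof(x)))
  rng <- range(x, finite = TRUE)
  cat(sprintf("  range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Voxel size accessor
#' @param x a `vol3d` (bare arrays are treated as 1 mm isotropic).
#' @return numeric length-3, mm per axis.
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size")
  if (is.null(vs)) rep(1, 3L) else vs
}

#' Voxel volume in mm^3
#' @param x a `vol3d` or voxel-size vector.
#' @export
voxel_volume <- function(x) {
  vs <- if (is.numeric(x) && is.null(dim(x))) x else voxel_size(x)
  prod(vs)
}

# strip class for arithmetic, keep geometry
as_array3d <- function(x) {
  a <- unclass(x)
  attr(a, "voxel_size") <- NULL
  a
}

same_grid <- function(a, b) {
  identical(dim(a), dim(b)) && isTRUE(all.equal(voxel_size(a), voxel_size(b)))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " are not on the same grid: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

#' Mirror a volume across a grid axis
#'
#' Reverses voxel order along one axis, e.g. the first (x) axis of a
#' stereotactic grid to mirror across the mid-sagittal plane. The operation
#' is an involution: applying it twice restores the input bit-for-bit.
#'
#' @param x a `vol3d`.
#' @param axis axis index in 1..3 (default 1, the x/left-right axis).
#' @export
mirror_volume <- function(x, axis = 1L) {
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  idx <- lapply(dim(x), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  out <- do.call(`[`, c(list(as_array3d(x)), idx, list(drop = FALSE)))
  vol3d(out, voxel_size(x))
}

#' Dilate a binary mask by a cubic structuring element
#'
#' Chebyshev (box) dilation by `radius` voxels, the neighbourhood geometry
#' used for the cubic search volumes of the fusion engine. Implemented as a
#' separable running OR along each axis.
#'
#' @param mask logical 3D array or `vol3d` of 0/1.
#' @param radius non-negative integer, voxels.
#' @return logical array of the same dimensions.
#' @export
dilate_mask <- function(mask, radius) {
  radius <- as.integer(radius)
  if (radius < 0) stop("radius must be >= 0")
  m <- as_array3d(mask) != 0
  if (radius == 0L) return(m)
  d <- dim(m)
  for (ax in 1:3) {
    acc <- m
    for (s in seq_len(radius)) {
      acc <- acc | shift_array(m, ax, s) | shift_array(m, ax, -s)
    }
    m <- acc
  }
  m
}

# shift along axis `ax` by `by` voxels, zero/FALSE fill
shift_array <- function(x, ax, by) {
  d <- dim(x)
  out <- array(if (is.logical(x)) FALSE else 0, d)
  n <- d[ax]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  is <- id <- lapply(d, seq_len)
  is[[ax]] <- src; id[[ax]] <- dst
  out[id[[1]], id[[2]], id[[3]]] <- x[is[[1]], is[[2]], is[[3]]]
  out
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
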