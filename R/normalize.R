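#' Tissue mean intensities
#'
#' Container for the estimated CSF/GM/WM class mean intensities. Must be
#' strictly increasing (CSF is darkest on T1-weighted images, WM brightest).
#'
#' @param mu_csf,mu_gm,mu_wm class mean intensities.
#' @return object of class `tissue_means`.
#' @export
tissue_means <- function(mu_csf, mu_gm, mu_wm) {
  m <- c(csf = mu_csf, gm = mu_gm, wm = mu_wm)
  if (any(!is.finite(m))) stop("tissue means must be finite")
  if (!(m[1] >= 0 && m[1] < m[2] && m[2] < m[3]))
    stop("tissue means must satisfy 0 <= csf < gm < wm, got ",
         paste(signif(m, 6), collapse = ", "))
  structure(as.list(m), names = c("mu_csf", "mu_gm", "mu_wm"),
            class = "tissue_means")
}

#' @export
print.tissue_means <- function(x, ...) {
  cat(sprintf("<tissue_means> CSF %.2f | GM %.2f | WM %.2f\n",
              x$mu_csf, x$mu_gm, x$mu_wm))
  invisible(x)
}

#' Intensity normalization targets
#'
#' Target class means of the standardized intensity scale. The defaults put
#' CSF at 50, GM at 150 and WM at 250, the scale every library template is
#' mapped to.
#'
#' @param target_csf,target_gm,target_wm target intensities, strictly
#'   increasing.
#' @export
norm_targets <- function(target_csf = 50, target_gm = 150, target_wm = 250) {
  t <- c(target_csf, target_gm, target_wm)
  if (!all(diff(t) > 0)) stop("targets must be strictly increasing")
  structure(list(target_csf = t[1], target_gm = t[2], target_wm = t[3]),
            class = "norm_targets")
}

#' Robust trimmed-mean estimation of tissue class means
#'
#' Estimates the CSF, GM and WM mean intensities from the voxels of a mask
#' by robust 3-class 1D clustering: voxels are iteratively assigned to the
#' nearest current class mean, the fraction of each class farthest from its
#' center is discarded (the surrogate for excluding partial-volume voxels,
#' which sit between the pure-tissue modes), and each mean is recomputed as
#' the trimmed mean, to a fixed point. Initialization is from the 10th/50th/
#' 90th percentiles of the masked intensities.
#'
#' @param image an intensity [vol3d].
#' @param mask binary volume (non-zero = inside); typically the intracranial
#'   cavity.
#' @param trim fraction of each class discarded farthest from its center,
#'   default 0.25.
#' @param tol convergence tolerance on the largest mean shift, intensity
#'   units; default 1e-3.
#' @param max_iter iteration cap, default 100.
#' @return a [tissue_means].
#' @export
tms_estimate_means <- function(image, mask, trim = 0.25, tol = 1e-3,
                               max_iter = 100L) {
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  inside <- as_array3d(mask) != 0
  if (!any(inside)) stop("empty mask")
  x <- as.vector(as_array3d(image))[as.vector(inside)]
  if (any(!is.finite(x))) stop("non-finite intensities inside mask")
  if (length(unique(x)) < 3L)
    stop("degenerate histogram: fewer than 3 distinct intensities in mask")
  mu <- as.numeric(stats::quantile(x, c(0.10, 0.50, 0.90), names = FALSE))
  if (any(diff(mu) <= 0))
    stop("degenerate histogram: percentile initialization not increasing")
  for (iter in seq_len(max_iter)) {
    # nearest-mean assignment via midpoints (means are sorted)
    cls <- findInterval(x, c((mu[1] + mu[2]) / 2, (mu[2] + mu[3]) / 2)) + 1L
    new_mu <- mu
    for (k in 1:3) {
      xk <- x[cls == k]
      if (length(xk) == 0L) next
      if (trim > 0 && length(xk) > 4L) {
        dev <- abs(xk - mu[k])
        keep <- dev <= stats::quantile(dev, 1 - trim, names = FALSE)
        xk <- xk[keep]
      }
      new_mu[k] <- mean(xk)
    }
    shift <- max(abs(new_mu - mu))
    mu <- sort(new_mu)
    if (shift < tol) break
  }
  if (any(diff(mu) <= 0))
    stop("degenerate histogram: tissue means collapsed")
  tissue_means(mu[1], mu[2], mu[3])
}

#' Piecewise-linear intensity standardization
#'
#' Maps intensities so the estimated class means land on the target scale:
#' the mapping is continuous and monotone with breakpoints (0, 0),
#' (mu_csf, target_csf), (mu_gm, target_gm), (mu_wm, target_wm), extends
#' above mu_wm with the slope of the last segment, and clips below 0.
#'
#' @param image an intensity [vol3d].
#' @param means a [tissue_means] estimated from the image.
#' @param targets a [norm_targets]; default 50/150/250.
#' @return the standardized intensity [vol3d].
#' @export
piecewise_linear_map <- function(image, means, targets = norm_targets()) {
  stopifnot(inherits(means, "tissue_means"))
  stopifnot(inherits(targets, "norm_targets"))
  bx <- c(0, means$mu_csf, means$mu_gm, means$mu_wm)
  by <- c(0, targets$target_csf, targets$target_gm, targets$target_wm)
  if (any(diff(bx) <= 0)) stop("tissue means must be strictly increasing and > 0")
  x <- as.vector(as_array3d(image))
  y <- numeric(length(x))
  last_slope <- (by[4] - by[3]) / (bx[4] - bx[3])
  seg <- findInterval(x, bx, rightmost.closed = FALSE)  # 0..4
  below <- seg <= 0L
  above <- seg >= 4L
  mid <- !below & !above
  if (any(mid)) {
    s <- seg[mid]
    y[mid] <- by[s] + (x[mid] - bx[s]) * (by[s + 1] - by[s]) / (bx[s + 1] - bx[s])
  }
  if (any(above)) y[above] <- by[4] + (x[above] - bx[4]) * last_slope
  if (any(below)) y[below] <- 0     # x < 0: clip at the 0 -> 0 anchor
  y[y < 0] <- 0
  vol3d(array(y, dim(image)), voxel_size(image))
}
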