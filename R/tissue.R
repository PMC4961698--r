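#' Partial-volume tissue classification inside the intracranial cavity
#'
#' Intensity-driven two-tissue linear mixing: a voxel whose (normalized)
#' intensity lies between two adjacent tissue means `mu_a < I < mu_b` is
#' modelled as a mixture holding fraction `(I - mu_a)/(mu_b - mu_a)` of the
#' brighter tissue and the complement of the darker one, and none of the
#' third; intensities at or below the CSF mean are pure CSF, at or above
#' the WM mean pure WM. The crisp label is the tissue of largest fraction,
#' an exact 0.5/0.5 tie going to the lower-intensity tissue.
#'
#' @param image intensity [vol3d], already on the normalized scale.
#' @param icc_mask binary intracranial cavity mask.
#' @param means a [tissue_means] (typically re-estimated on the normalized
#'   image).
#' @return list with `pvc` (a `pvc_maps`: list of `csf`, `gm`, `wm`
#'   fraction [vol3d]s, zero outside the ICC) and `crisp` (label [vol3d]:
#'   0 background, 1 CSF, 2 GM, 3 WM).
#' @export
classify_tissues <- function(image, icc_mask, means) {
  stopifnot(inherits(means, "tissue_means"))
  inside <- as_array3d(icc_mask) != 0
  if (!any(inside)) stop("empty ICC mask")
  d <- dim(image)
  vs <- voxel_size(image)
  x <- as_array3d(image)
  mu <- c(means$mu_csf, means$mu_gm, means$mu_wm)

  csf <- gm <- wm <- array(0, d)
  xi <- x[inside]
  fc <- fg <- fw <- numeric(length(xi))
  lo <- xi <= mu[1]
  hi <- xi >= mu[3]
  mid1 <- xi > mu[1] & xi < mu[2]          # CSF/GM mixture
  mid2 <- xi >= mu[2] & xi < mu[3]         # GM/WM mixture
  fc[lo] <- 1
  fw[hi] <- 1
  a <- (xi[mid1] - mu[1]) / (mu[2] - mu[1])
  fg[mid1] <- a; fc[mid1] <- 1 - a
  b <- (xi[mid2] - mu[2]) / (mu[3] - mu[2])
  fw[mid2] <- b; fg[mid2] <- 1 - b
  csf[inside] <- fc; gm[inside] <- fg; wm[inside] <- fw

  # crisp: argmax fraction; exact tie -> lower-intensity tissue
  frac <- cbind(fc, fg, fw)
  crisp_in <- max.col(frac, ties.method = "first")
  crisp <- array(0L, d)
  crisp[inside] <- as.integer(crisp_in)

  pvc <- structure(list(csf = vol3d(csf, vs), gm = vol3d(gm, vs),
                        wm = vol3d(wm, vs), icc_mask = inside),
                   class = "pvc_maps")
  list(pvc = pvc, crisp = vol3d(crisp, vs))
}

#' Tissue volumes from partial-volume maps
#'
#' Integrates each tissue fraction over the grid: `volume_t = sum(fraction_t)
#' * voxel_volume / 1000` cm^3. By construction the three volumes sum to the
#' intracranial cavity volume.
#'
#' @param pvc a `pvc_maps` from [classify_tissues].
#' @param voxel_volume_mm3 voxel volume in mm^3; default from the maps'
#'   voxel size.
#' @return named numeric: `csf`, `gm`, `wm`, `icc`, all in cm^3.
#' @export
tissue_volumes <- function(pvc, voxel_volume_mm3 = NULL) {
  stopifnot(inherits(pvc, "pvc_maps"))
  if (is.null(voxel_volume_mm3)) voxel_volume_mm3 <- voxel_volume(pvc$csf)
  v <- vapply(pvc[c("csf", "gm", "wm")],
              function(f) sum(as_array3d(f)) * voxel_volume_mm3 / 1000,
              numeric(1))
  c(v, icc = sum(pvc$icc_mask) * voxel_volume_mm3 / 1000)
}
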