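#' Dice overlap coefficient
#'
#' `2 |A n B| / (|A| + |B|)` between two binary volumes; the standard
#' segmentation-accuracy statistic. Defined as 1 when both masks are empty
#' (identical empty segmentations).
#'
#' @param a,b binary volumes (non-zero = foreground) on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("grid mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  av <- as_array3d(a) != 0
  bv <- as_array3d(b) != 0
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0L) return(1)
  2 * sum(av & bv) / (na + nb)
}

#' Percent volume difference
#'
#' Test-retest volume reproducibility: `100 * 2 * | |C1| - |C2| | /
#' (|C1| + |C2|)`, i.e. the absolute volume difference referenced to the
#' mean of the two segmentations (so neither order matters). 0 for equal
#' volumes, 200 when one mask is empty.
#'
#' @param c1,c2 binary volumes on the same grid, not both empty.
#' @return percent.
#' @export
pvd <- function(c1, c2) {
  if (!identical(dim(c1), dim(c2))) stop("grid mismatch")
  n1 <- sum(as_array3d(c1) != 0)
  n2 <- sum(as_array3d(c2) != 0)
  if (n1 + n2 == 0L) stop("both masks empty")
  100 * 2 * abs(n1 - n2) / (n1 + n2)
}

#' Percent volume overlap
#'
#' `100 * 2 |C1 n C2| / (|C1| + |C2|)`, i.e. Dice expressed as a percent of
#' the mean segmentation volume; 100 for identical masks.
#'
#' @param c1,c2 binary volumes on the same grid, not both empty.
#' @return percent.
#' @export
pvo <- function(c1, c2) {
  if (!identical(dim(c1), dim(c2))) stop("grid mismatch")
  v1 <- as_array3d(c1) != 0
  v2 <- as_array3d(c2) != 0
  n1 <- sum(v1); n2 <- sum(v2)
  if (n1 + n2 == 0L) stop("both masks empty")
  100 * (2 * sum(v1 & v2) / (n1 + n2))   # exactly 100 * dice
}

#' Left/right asymmetry ratio
#'
#' Signed normalized volume difference of a paired structure,
#' `100 * (L - R) / ((L + R)/2)`: positive when the left structure is
#' larger, antisymmetric under swapping sides.
#'
#' @param vol_left,vol_right volumes (any common unit), not both zero.
#' @return signed percent.
#' @export
asymmetry_ratio <- function(vol_left, vol_right) {
  if (vol_left + vol_right <= 0) stop("both volumes zero")
  100 * (vol_left - vol_right) / ((vol_left + vol_right) / 2)
}

#' Structure dictionary
#'
#' Maps label values to structure names, hemisphere tags and left/right
#' pairings, the metadata needed to report per-structure volumes and
#' asymmetries. Pairing must be symmetric and paired labels must carry
#' opposite hemisphere tags.
#'
#' @param label integer label values.
#' @param name structure names.
#' @param hemisphere one of `"left"`, `"right"`, `"midline"` per label.
#' @param paired_label the partner label for lateralized structures, `NA`
#'   for midline ones.
#' @return a `structure_dict` data.frame.
#' @export
structure_dict <- function(label, name, hemisphere, paired_label = NA) {
  d <- data.frame(label = as.integer(label), name = as.character(name),
                  hemisphere = as.character(hemisphere),
                  paired_label = as.integer(paired_label),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$label)) stop("duplicate labels in dictionary")
  if (!all(d$hemisphere %in% c("left", "right", "midline")))
    stop("hemisphere must be left, right or midline")
  for (i in seq_len(nrow(d))) {
    p <- d$paired_label[i]
    if (is.na(p)) {
      if (d$hemisphere[i] != "midline")
        stop("lateralized structure '", d$name[i], "' lacks a paired label")
      next
    }
    j <- match(p, d$label)
    if (is.na(j)) stop("paired label ", p, " of '", d$name[i], "' not in dictionary")
    if (d$paired_label[j] != d$label[i])
      stop("pairing not symmetric for labels ", d$label[i], " and ", p)
    if (d$hemisphere[i] == d$hemisphere[j] || d$hemisphere[i] == "midline")
      stop("paired labels ", d$label[i], " and ", p,
           " must carry opposite hemisphere tags")
  }
  class(d) <- c("structure_dict", "data.frame")
  d
}

#' Per-structure volumetry report
#'
#' Tabulates, for every structure of the dictionary, its volume, its share
#' of the intracranial cavity, and (for lateralized structures) the
#' left/right asymmetry ratio computed from the pair's volumes. Labels in
#' the volume but absent from the dictionary (other than background 0) are
#' an error.
#'
#' @param labels label [vol3d].
#' @param dict a [structure_dict].
#' @param voxel_volume_mm3 voxel volume in mm^3; default from the volume.
#' @param icc_volume_cm3 reference intracranial volume in cm^3; `NA`
#'   suppresses the percent column.
#' @return `volumetry_report` data.frame with columns `name`, `label`,
#'   `hemisphere`, `volume_cm3`, `pct_icc`, `asymmetry_pct`.
#' @export
structure_volumes <- function(labels, dict, voxel_volume_mm3 = NULL,
                              icc_volume_cm3 = NA_real_) {
  stopifnot(inherits(dict, "structure_dict"))
  if (is.null(voxel_volume_mm3)) voxel_volume_mm3 <- voxel_volume(labels)
  lv <- as.vector(as_array3d(labels))
  present <- setdiff(unique(lv), 0L)
  unknown <- setdiff(present, dict$label)
  if (length(unknown) > 0)
    stop("labels not in dictionary: ", paste(sort(unknown), collapse = ", "))
  counts <- vapply(dict$label, function(l) sum(lv == l), numeric(1))
  vol_cm3 <- counts * voxel_volume_mm3 / 1000
  pct <- if (is.na(icc_volume_cm3)) rep(NA_real_, nrow(dict))
         else 100 * vol_cm3 / icc_volume_cm3
  asym <- rep(NA_real_, nrow(dict))
  for (i in seq_len(nrow(dict))) {
    p <- dict$paired_label[i]
    if (is.na(p)) next
    j <- match(p, dict$label)
    l <- if (dict$hemisphere[i] == "left") vol_cm3[i] else vol_cm3[j]
    r <- if (dict$hemisphere[i] == "left") vol_cm3[j] else vol_cm3[i]
    asym[i] <- if (l + r > 0) asymmetry_ratio(l, r) else NA_real_
  }
  out <- data.frame(name = dict$name, label = dict$label,
                    hemisphere = dict$hemisphere, volume_cm3 = vol_cm3,
                    pct_icc = pct, asymmetry_pct = asym,
                    stringsAsFactors = FALSE)
  class(out) <- c("volumetry_report", "data.frame")
  out
}
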