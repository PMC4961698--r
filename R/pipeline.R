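#' Read a pipeline / phantom configuration file
#'
#' JSON (always available) or YAML (if the `yaml` package is installed).
#'
#' @param path config file path, `.json`, `.yaml` or `.yml`.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
}

#' Remove bright voxels from ventricle labels
#'
#' The lateral-ventricle label convention keeps only CSF-like voxels:
#' ventricle-labeled voxels whose normalized intensity is at or above the
#' threshold (default 100, between the CSF target 50 and the GM target 150)
#' are reassigned to background. All other labels are untouched. Intended
#' as optional post-fusion cleanup on images normalized to the 50/150/250
#' scale.
#'
#' @param labels label [vol3d].
#' @param image normalized intensity [vol3d] on the same grid.
#' @param ventricle_labels integer label values treated as ventricles.
#' @param threshold intensity cutoff, default 100.
#' @return cleaned label [vol3d].
#' @export
apply_ventricle_threshold <- function(labels, image, ventricle_labels,
                                      threshold = 100) {
  stop_if_grid_mismatch(labels, image, "labels and image")
  x <- as_array3d(image)
  rng <- range(x, finite = TRUE)
  if (threshold < rng[1] || threshold > rng[2])
    warning("threshold ", threshold, " outside the image intensity range [",
            signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  lv <- as_array3d(labels)
  drop <- (lv %in% as.integer(ventricle_labels)) & (x >= threshold)
  lv[drop] <- 0L
  vol3d(array(as.integer(lv), dim(labels)), voxel_size(labels))
}

load_manifest_library <- function(entries, base_dir, subject = NULL) {
  templates <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    ip <- file.path(base_dir, e$intensity)
    lp <- file.path(base_dir, e$labels)
    for (p in c(ip, lp)) if (!file.exists(p))
      stop("library file missing: ", p)
    t <- list(intensity = read_nifti(ip), labels = read_nifti(lp))
    t$labels <- vol3d(array(as.integer(as_array3d(t$labels)), dim(t$labels)),
                      voxel_size(t$labels))
    if (!is.null(subject) && !same_grid(subject, t$intensity))
      stop("template not on the subject grid: ", ip)
    t
  })
  atlas_library(templates)
}

dict_from_config <- function(d) {
  if (is.character(d)) {
    if (grepl("\\.csv$", d)) {
      df <- utils::read.csv(d)
      return(structure_dict(df$label, df$name, df$hemisphere, df$paired_label))
    }
    d <- jsonlite::fromJSON(d, simplifyDataFrame = FALSE)
  }
  if (is.list(d) && !is.data.frame(d)) {
    d <- data.frame(
      label = vapply(d, function(r) as.integer(r$label), integer(1)),
      name = vapply(d, function(r) as.character(r$name), character(1)),
      hemisphere = vapply(d, function(r) as.character(r$hemisphere), character(1)),
      paired_label = vapply(d, function(r)
        as.integer(r$paired_label %||% NA_integer_), integer(1)),
      stringsAsFactors = FALSE)
  }
  structure_dict(d$label, d$name, d$hemisphere, d$paired_label)
}

params_from_config <- function(p) {
  if (is.null(p)) return(fusion_params())
  do.call(fusion_params, p)
}

#' Run the full segmentation pipeline
#'
#' Orchestrates the in-scope stages on an already-preprocessed subject
#' (denoising, inhomogeneity correction and stereotactic registration are
#' assumed done externally): intensity normalization to the library scale,
#' then per configured scale a library-driven region mask, multi-scale
#' fusion segmentation, optional ventricle-intensity cleanup and a
#' volumetry report, and finally partial-volume tissue classification
#' inside the intracranial mask. All outputs (NIfTI volumes, CSV and JSON
#' reports, a run manifest with parameters and input checksums) are written
#' under `output_dir`; runs are deterministic for identical inputs.
#'
#' @param config a named list (see the package vignette) or path to a
#'   JSON/YAML config file.
#' @return invisibly, a list with the per-scale label volumes, reports,
#'   tissue volumes and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    base_dir <- dirname(normalizePath(config))
    config <- read_config(config)
  } else base_dir <- config$base_dir %||% "."
  out_dir <- config$output_dir %||% "nlfuse_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }

  subj_path <- file.path(base_dir, config$subject)
  if (!file.exists(subj_path)) stop("subject volume not found: ", subj_path)
  subject <- read_nifti(subj_path)
  logf("loaded subject %s (%s voxels)", subj_path,
       paste(dim(subject), collapse = "x"))

  icc <- NULL
  if (!is.null(config$icc_mask)) {
    icc_path <- file.path(base_dir, config$icc_mask)
    if (!file.exists(icc_path)) stop("ICC mask not found: ", icc_path)
    icc <- read_nifti(icc_path)
    stop_if_grid_mismatch(subject, icc, "subject and ICC mask")
  }

  targets <- do.call(norm_targets, as.list(config$targets %||% list()))
  norm_mask <- if (!is.null(icc)) icc else
    vol3d(array(as.integer(as_array3d(subject) > 0), dim(subject)),
          voxel_size(subject))
  if (isTRUE(config$normalize %||% TRUE)) {
    means <- tms_estimate_means(subject, norm_mask)
    logf("TMS means: CSF %.2f GM %.2f WM %.2f", means$mu_csf, means$mu_gm,
         means$mu_wm)
    subject <- piecewise_linear_map(subject, means, targets)
    write_nifti(subject, file.path(out_dir, "subject_normalized.nii.gz"))
    logf("intensity-normalized subject to targets %g/%g/%g",
         targets$target_csf, targets$target_gm, targets$target_wm)
  }

  icc_vol_cm3 <- if (!is.null(icc))
    sum(as_array3d(icc) != 0) * voxel_volume(subject) / 1000 else NA_real_

  results <- list()
  for (sc in config$scales %||% list()) {
    nm <- sc$name %||% "scale"
    params <- params_from_config(sc$params)
    lib <- load_manifest_library(sc$library, base_dir, subject)
    logf("[%s] %d templates, params: N=%d P=%d/%d search=%d block=%d", nm,
         length(lib), params$n_templates, params$patch_size_1,
         params$patch_size_2, 2 * params$search_radius + 1,
         params$block_size)
    rl <- if (!is.null(sc$structure_labels)) as.integer(sc$structure_labels)
          else NULL
    mask <- region_mask_from_library(lib, rl, params$search_radius)
    seg <- segment(subject, lib, mask, params)
    vent <- sc$ventricle
    if (!is.null(vent) && isTRUE(vent$enabled %||% TRUE)) {
      seg2 <- apply_ventricle_threshold(seg, subject,
                                        as.integer(vent$labels),
                                        vent$threshold %||% 100)
      logf("[%s] ventricle threshold %g removed %d voxels", nm,
           vent$threshold %||% 100,
           sum(as_array3d(seg) != as_array3d(seg2)))
      seg <- seg2
    }
    seg_path <- file.path(out_dir, paste0("labels_", nm, ".nii.gz"))
    write_nifti(seg, seg_path, datatype = "int16")
    res <- list(labels = seg, path = seg_path)
    if (!is.null(sc$dict)) {
      dict <- dict_from_config(sc$dict)
      rep <- structure_volumes(seg, dict, voxel_volume(subject), icc_vol_cm3)
      utils::write.csv(rep, file.path(out_dir, paste0("report_", nm, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(rep, file.path(out_dir, paste0("report_", nm, ".json")),
                           dataframe = "rows", na = "null", auto_unbox = TRUE,
                           digits = NA)
      res$report <- rep
    }
    logf("[%s] wrote %s", nm, seg_path)
    results[[nm]] <- res
  }

  tissue <- NULL
  if (!is.null(icc)) {
    means2 <- tms_estimate_means(subject, icc)
    cls <- classify_tissues(subject, icc, means2)
    for (t in c("csf", "gm", "wm"))
      write_nifti(cls$pvc[[t]], file.path(out_dir, paste0("pvc_", t, ".nii.gz")),
                  datatype = "float32")
    write_nifti(cls$crisp, file.path(out_dir, "tissue_crisp.nii.gz"),
                datatype = "int16")
    tissue <- tissue_volumes(cls$pvc)
    jsonlite::write_json(as.list(tissue), file.path(out_dir, "tissue_volumes.json"),
                         auto_unbox = TRUE, digits = NA)
    logf("tissue volumes (cm^3): CSF %.3f GM %.3f WM %.3f ICC %.3f",
         tissue["csf"], tissue["gm"], tissue["wm"], tissue["icc"])
  }

  inputs <- c(subj_path,
              unlist(lapply(config$scales %||% list(), function(sc)
                unlist(lapply(sc$library, function(e)
                  file.path(base_dir, c(e$intensity, e$labels)))))))
  manifest <- list(package = "nlfuse",
                   version = as.character(utils::packageVersion("nlfuse")),
                   seed = config$seed %||% NA,
                   targets = unclass(targets),
                   input_checksums = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("run complete; manifest written")
  invisible(list(scales = results, tissue = tissue, output_dir = out_dir))
}

#' Generate a phantom (and optionally a library) from a config file
#'
#' Drives [make_phantom], [make_library] and [flip_augment] from a
#' JSON/YAML spec and writes NIfTI volumes plus a library manifest, so
#' synthetic test worlds can be produced from the command line.
#'
#' @param spec path to a config file or an equivalent named list with a
#'   `phantom` block (fields of [phantom_spec]) and optional `deform`
#'   ([deform_spec] fields) and `flip` (`axis`, `swap` pairs) blocks.
#' @param out_dir output directory.
#' @return invisibly, the manifest list.
#' @export
generate_phantom_bundle <- function(spec, out_dir) {
  if (is.character(spec)) spec <- read_config(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph_cfg <- spec$phantom %||% stop("config must contain a 'phantom' block")
  ph_cfg$structures <- lapply(ph_cfg$structures, function(s) {
    s$center <- as.numeric(s$center); s$radii <- as.numeric(s$radii); s
  })
  ph <- make_phantom(do.call(phantom_spec, ph_cfg))
  write_nifti(ph$intensity, file.path(out_dir, "phantom_intensity.nii.gz"))
  write_nifti(ph$labels, file.path(out_dir, "phantom_labels.nii.gz"))
  manifest <- list(phantom = list(intensity = "phantom_intensity.nii.gz",
                                  labels = "phantom_labels.nii.gz"))
  if (!is.null(spec$deform)) {
    lib <- make_library(ph$intensity, ph$labels,
                        do.call(deform_spec, spec$deform))
    if (!is.null(spec$flip)) {
      swap <- if (!is.null(spec$flip$swap))
        do.call(rbind, lapply(spec$flip$swap, as.integer)) else NULL
      lib <- flip_augment(lib, axis = spec$flip$axis %||% 1L, swap = swap)
    }
    entries <- lapply(seq_along(lib), function(i) {
      ip <- sprintf("template_%03d_intensity.nii.gz", i)
      lp <- sprintf("template_%03d_labels.nii.gz", i)
      write_nifti(lib[[i]]$intensity, file.path(out_dir, ip))
      write_nifti(lib[[i]]$labels, file.path(out_dir, lp))
      list(intensity = ip, labels = lp)
    })
    manifest$library <- entries
    manifest$flip_augmented <- isTRUE(attr(lib, "flip_augmented"))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "library_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Evaluate a segmentation against a reference
#'
#' Computes the requested overlap/reproducibility metrics per label value
#' present in either volume.
#'
#' @param pred,truth label [vol3d]s (or NIfTI paths) on the same grid.
#' @param metrics subset of `c("dice", "pvd", "pvo")`.
#' @return data.frame, one row per non-background label.
#' @export
evaluate_segmentation <- function(pred, truth,
                                  metrics = c("dice", "pvd", "pvo")) {
  if (is.character(pred)) pred <- read_nifti(pred)
  if (is.character(truth)) truth <- read_nifti(truth)
  stop_if_grid_mismatch(pred, truth, "pred and truth")
  metrics <- match.arg(metrics, several.ok = TRUE)
  labs <- sort(setdiff(union(unique(as.vector(as_array3d(pred))),
                             unique(as.vector(as_array3d(truth)))), 0))
  rows <- lapply(labs, function(l) {
    a <- as_array3d(pred) == l
    b <- as_array3d(truth) == l
    r <- list(label = l)
    if ("dice" %in% metrics) r$dice <- dice(a, b)
    if ("pvd" %in% metrics) r$pvd <- if (sum(a) + sum(b) > 0) pvd(a, b) else NA
    if ("pvo" %in% metrics) r$pvo <- if (sum(a) + sum(b) > 0) pvo(a, b) else NA
    as.data.frame(r)
  })
  do.call(rbind, rows)
}
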