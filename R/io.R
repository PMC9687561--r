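#' Read and write the pipeline's file formats
#'
#' NIfTI for maps and masks (via RNifti, with voxel dimensions carried in
#' the header), FSL-style plain-text bval/bvec tables, JSON sidecars for echo
#' times, and CSV for labels, volumes and profiles.
#' @name hippoaxis_io
NULL

#' @rdname hippoaxis_io
#' @param x 3D/4D numeric array (a `parameter_map` or mask).
#' @param grid A [voxel_grid()] providing voxel dimensions.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @export
write_map_nifti <- function(x, grid, path) {
  img <- RNifti::asNifti(unclass(x) * 1)
  RNifti::pixdim(img) <- grid$vox_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname hippoaxis_io
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  grid <- voxel_grid(d[1:3], RNifti::pixdim(img)[1:3])
  structure(as.array(img), grid = grid, class = c("parameter_map", "array"))
}

#' @rdname hippoaxis_io
#' @export
read_mask_nifti <- function(path) {
  img <- read_map_nifti(path)
  m <- as.array(img) > 0.5
  attr(m, "grid") <- attr(img, "grid")
  m
}

#' Export a synthetic cohort as a NIfTI file tree
#'
#' Writes one parameter map per animal/side/day/parameter
#' (`<id>_<side>_<day>_<parameter>.nii.gz`, NA outside the mask), the masks
#' as uint8 NIfTI, the label table as CSV, and a ground-truth JSON sidecar
#' per animal/side holding the analytic centerline control points and the
#' per-day volumes.
#'
#' @param cohort A `hippo_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hippo_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_labels_csv(cohort_labels(cohort), file.path(dir, "labels.csv"))
  grid <- cohort$grid
  for (an in cohort$animals) {
    for (side in c("ipsi", "contra")) {
      sd_ <- an$sides[[side]]
      ctl_keep <- seq(1, nrow(sd_$centerline$points), by = 50)
      jsonlite::write_json(
        list(animal_id = an$id, side = side,
             centerline_mm = sd_$centerline$points[ctl_keep, ],
             arc_length_mm = sd_$centerline$s[ctl_keep],
             volumes_mm3 = as.list(sd_$volumes)),
        file.path(dir, sprintf("%s_%s_truth.json", an$id, side)),
        auto_unbox = TRUE, digits = NA)
      for (day in names(sd_$masks)) {
        idx <- sd_$indices[sd_$masks[[day]]]
        m <- indices_to_array(idx, grid)
        img <- RNifti::asNifti(m * 1L)
        RNifti::pixdim(img) <- grid$vox_mm
        RNifti::writeNifti(img, file.path(dir,
          sprintf("%s_%s_%s_mask.nii.gz", an$id, side, day)),
          datatype = "uint8")
        maps <- sd_$maps[[day]]
        for (p in colnames(maps)) {
          a <- array(NA_real_, grid$shape)
          a[idx] <- maps[, p]
          write_map_nifti(a, grid, file.path(dir,
            sprintf("%s_%s_%s_%s.nii.gz", an$id, side, day, p)))
        }
      }
    }
  }
  invisible(dir)
}

#' @rdname hippoaxis_io
#' @param bvals,bvecs Protocol as in [synthesize_dwi()].
#' @param prefix Path prefix; writes `<prefix>.bval` and `<prefix>.bvec`.
#' @export
write_bvals_bvecs <- function(bvals, bvecs, prefix) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(t(bvecs), 1, paste, collapse = " "),
             paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' @rdname hippoaxis_io
#' @export
read_bvals_bvecs <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bv <- do.call(rbind, lapply(readLines(paste0(prefix, ".bvec")),
                              function(l) scan(text = l, quiet = TRUE)))
  if (nrow(bv) != 3) stop("bvec file must have 3 rows (x, y, z)")
  list(bvals = bvals, bvecs = t(bv))
}

#' @rdname hippoaxis_io
#' @param echo_times Echo times (ms).
#' @export
write_echo_times <- function(echo_times, path) {
  jsonlite::write_json(list(echo_times_ms = echo_times), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname hippoaxis_io
#' @export
read_echo_times <- function(path) {
  as.numeric(jsonlite::read_json(path, simplifyVector = TRUE)$echo_times_ms)
}

#' @rdname hippoaxis_io
#' @param labels Label tibble (animal_id, group, epilepsy, cognition).
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname hippoaxis_io
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "epilepsy", "cognition")
  if (!all(need %in% names(df))) {
    stop("label CSV must have columns: ", paste(need, collapse = ", "))
  }
  df$epilepsy <- as.logical(df$epilepsy)
  df$cognition <- as.logical(df$cognition)
  tibble::as_tibble(df)
}

#' @rdname hippoaxis_io
#' @param profiles Profile tibble ([cohort_profiles()] layout).
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname hippoaxis_io
#' @export
read_profiles_csv <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
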