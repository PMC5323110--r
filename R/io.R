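# File interfaces: NIfTI volumes (via RNifti), motion and phenotype TSV,
# JSON sidecars.

#' Write a 3D or 4D array as NIfTI
#'
#' @param arr numeric array
#' @param path output path (`.nii` or `.nii.gz`)
#' @param voxel_size_mm isotropic voxel size
#' @param affine 4x4 voxel-to-world affine (optional)
#' @param tr_s repetition time for 4D data (optional)
#' @return the path, invisibly
#' @export
write_nifti_map <- function(arr, path, voxel_size_mm = 3, affine = NULL,
                            tr_s = NULL) {
  pd <- rep(voxel_size_mm, 3)
  if (length(dim(arr)) == 4) pd <- c(pd, if (is.null(tr_s)) 1 else tr_s)
  img <- RNifti::asNifti(arr + 0)
  RNifti::pixdim(img) <- pd
  if (!is.null(affine))
    RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file
#' @return numeric array with an `affine` attribute
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "affine") <- structure(RNifti::xform(img), imagedim = NULL)
  out
}

#' Read a BOLD NIfTI as a [bold_series()]
#'
#' @param path 4D NIfTI file
#' @param mask logical 3D array (or path to a mask NIfTI)
#' @param tr_s repetition time; taken from the header if missing
#' @return a [bold_series()]
#' @export
read_bold <- function(path, mask, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (is.null(tr_s)) tr_s <- if (length(pd) >= 4) pd[4] else 1
  if (is.character(mask)) mask <- read_nifti_map(mask) > 0.5
  bold_series(as.array(img), tr_s = tr_s, voxel_size_mm = pd[1],
              mask = mask, affine = RNifti::xform(img))
}

#' Write a motion trace as TSV
#'
#' @param motion a [motion_trace()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_motion_tsv <- function(motion, path) {
  utils::write.table(as.data.frame(motion$params), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motion trace from TSV
#'
#' @param path TSV with the six named parameter columns
#' @return a [motion_trace()]
#' @export
read_motion_tsv <- function(path) {
  motion_trace(as.matrix(utils::read.delim(path)))
}

#' Write a full synthetic cohort to disk
#'
#' Emits per-subject BOLD (4D NIfTI), GM probability map (3D NIfTI) and
#' motion TSV, shared brain/WM/CSF masks and an integer region-label atlas,
#' the phenotype table (TSV), and the ground truth as JSON.
#'
#' @param cohort an `fc_cohort` from [generate_cohort()]
#' @param dir output directory (created if needed)
#' @param images write the 4D BOLD volumes (set `FALSE` for a
#'   phenotypes-and-masks-only export)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir, images = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- cohort$atlas
  vx <- atlas$voxel_size_mm
  aff <- atlas$affine
  write_nifti_map(array(as.numeric(atlas$brain_mask), atlas$grid_shape),
                  file.path(dir, "brain_mask.nii.gz"), vx, aff)
  for (tm in c("wm", "csf")) {
    m <- array(0, atlas$grid_shape)
    m[atlas$regions[[tm]]] <- 1
    write_nifti_map(m, file.path(dir, paste0(tm, "_mask.nii.gz")), vx, aff)
  }
  al <- atlas_labels(atlas)
  write_nifti_map(al$labels, file.path(dir, "atlas_labels.nii.gz"), vx, aff)
  jsonlite::write_json(al$names, file.path(dir, "atlas_labels.json"))
  sub <- cohort$subjects
  keep <- setdiff(names(sub), c("latent_em", "latent_ef"))
  utils::write.table(sub[keep], file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(truth[setdiff(names(truth), "networks")],
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_len(nrow(sub))) {
    id <- sub$subject_id[i]
    write_motion_tsv(cohort$motion[[i]],
                     file.path(dir, paste0(id, "_motion.tsv")))
    write_nifti_map(cohort$gm[[i]], file.path(dir, paste0(id, "_gm.nii.gz")),
                    vx, aff)
    if (images) {
      bold <- generate_bold(sub[i, ], atlas, truth, cohort$n_volumes,
                            cohort$tr_s)
      write_nifti_map(bold$data, file.path(dir, paste0(id, "_bold.nii.gz")),
                      vx, aff, tr_s = cohort$tr_s)
    }
  }
  invisible(dir)
}

#' Write a scrub report as JSON
#'
#' @param report a `scrub_report` from [scrub()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_scrub_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
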