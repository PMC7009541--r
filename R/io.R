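# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer implemented
# from the standard's 348-byte header layout. No R NIfTI package is part of
# this stack, so the format support lives here: enough for 3-D/4-D volumes,
# the common datatypes, scl scaling and the sform affine. All volumes written
# by this package are float64 with an sform carrying the stored affine.

nifti_datatypes <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                        `4` = list(what = "integer", size = 2, signed = TRUE),
                        `8` = list(what = "integer", size = 4, signed = TRUE),
                        `16` = list(what = "numeric", size = 4, signed = TRUE),
                        `64` = list(what = "numeric", size = 8, signed = TRUE),
                        `256` = list(what = "integer", size = 1, signed = TRUE),
                        `512` = list(what = "integer", size = 2, signed = FALSE))

open_read <- function(path) gzfile(path, "rb")   # reads plain files too

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return Numeric array (3-D or 4-D) with attributes `affine` (4x4 sform or
#'   pixdim-scaled identity) and `pixdim`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  con <- open_read(path)
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348)
  if (length(hdr_raw) < 348) stop_arg("truncated NIfTI header in %s", path)
  rd <- function(off, what, n, size, endian) {
    readBin(hdr_raw[(off + 1):length(hdr_raw)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4, endian) != 348L) {
    endian <- "big"
    if (rd(0, "integer", 1, 4, endian) != 348L)
      stop_arg("%s is not a NIfTI-1 file (bad sizeof_hdr)", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop_arg("%s lacks NIfTI magic", path)
  dim0 <- rd(40, "integer", 8, 2, endian)
  ndim <- dim0[1]
  if (ndim < 3 || ndim > 4)
    stop_arg("%s: only 3-D/4-D volumes supported (dim[0] = %d)", path, ndim)
  dims <- dim0[2:(1 + ndim)]
  datatype <- rd(70, "integer", 1, 2, endian)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop_arg("%s: unsupported NIfTI datatype %d", path, datatype)
  pixdim <- rd(76, "numeric", 8, 4, endian)[2:4]
  vox_offset <- rd(108, "numeric", 1, 4, endian)
  scl_slope <- rd(112, "numeric", 1, 4, endian)
  scl_inter <- rd(116, "numeric", 1, 4, endian)
  sform_code <- rd(254, "integer", 1, 2, endian)
  srow <- matrix(rd(280, "numeric", 12, 4, endian), 3, 4, byrow = TRUE)
  nvals <- prod(dims)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  data <- readBin(con, dt$what, n = nvals, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(data) < nvals) stop_arg("%s: truncated data section", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1)) else
    diag(c(pixdim, 1))
  structure(array(as.numeric(data), dims), affine = affine, pixdim = pixdim)
}

#' Write a NIfTI-1 volume
#'
#' Data are stored as float64, little-endian, with the affine in the sform.
#'
#' @param volume 3-D or 4-D numeric array.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param affine 4x4 (or 3x4) voxel-to-world matrix.
#' @param pixdim Voxel sizes (mm), length 3.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, affine = diag(4), pixdim = c(1, 1, 1)) {
  dims <- dim(volume)
  if (is.null(dims) || !length(dims) %in% 3:4)
    stop_arg("volume must be a 3-D or 4-D array")
  A <- as.matrix(affine)
  if (all(dim(A) == c(3, 4))) A <- rbind(A, c(0, 0, 0, 1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348)                                  # sizeof_hdr
  w_raw(35)                                   # data_type..regular, dim_info
  w_raw(1)
  dim8 <- c(length(dims), dims, rep(1L, 7 - length(dims)))
  w_i16(dim8)                                 # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0)                 # intent_p1-3, intent_code
  w_i16(64); w_i16(64); w_i16(0)              # datatype float64, bitpix, slice_start
  w_f32(c(0, pixdim, rep(1, 4)))              # pixdim[8] (qfac 0)
  w_f32(352)                                  # vox_offset
  w_f32(1); w_f32(0)                          # scl_slope, scl_inter
  w_i16(0); w_raw(2)                          # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                        # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0, 0))                              # glmax, glmin
  w_raw(80); w_raw(24)                        # descrip, aux_file
  w_i16(0); w_i16(1)                          # qform_code 0, sform_code 1
  w_f32(rep(0, 6))                            # quatern_b/c/d, qoffset_x/y/z
  w_f32(t(A[1:3, ]))                          # srow_x/y/z (row-major)
  w_raw(16)                                   # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1)   # magic
  w_raw(4)                                    # extension indicator
  writeBin(as.numeric(volume), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a covariate table
#'
#' Expects a CSV with header `subject_id,pma_weeks,ga_weeks,sex[,timepoint]`.
#' Sex accepted as 0/1 or M/F (mapped M -> 1, F -> 0 with a message). Rows
#' violating `20 <= ga_weeks <= pma_weeks <= 46` raise an error naming the
#' line.
#'
#' @param path CSV path.
#' @return Validated covariate `data.frame`.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "pma_weeks", "ga_weeks", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_arg("covariate file %s missing column(s): %s", path,
             paste(miss, collapse = ", "))
  if (is.character(df$sex)) {
    if (!all(df$sex %in% c("M", "F")))
      stop_arg("sex column must be 0/1 or M/F")
    message("mapping sex M -> 1, F -> 0")
    df$sex <- ifelse(df$sex == "M", 1L, 0L)
  }
  if (!"timepoint" %in% names(df)) df$timepoint <- 1L
  bad <- which(!(df$ga_weeks >= 20 & df$ga_weeks <= df$pma_weeks & df$pma_weeks <= 46))
  if (length(bad))
    stop_arg("%s line %d: requires 20 <= ga_weeks <= pma_weeks <= 46 (ga=%g, pma=%g)",
             path, bad[1] + 1L, df$ga_weeks[bad[1]], df$pma_weeks[bad[1]])
  if (!all(df$sex %in% c(0, 1))) stop_arg("sex must be coded 0/1")
  df
}

#' Write a covariate table
#' @param covariates Covariate `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to disk (NIfTI volumes + covariate CSV)
#'
#' One NIfTI file per subject and channel (`<id>_<channel>.nii`), the shared
#' brain mask, the label map, per-subject affines (JSON) and `covariates.csv`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(cohort$covariates)
  for (s in seq_len(n)) {
    id <- cohort$covariates$subject_id[s]
    for (c in 1:5) {
      vol <- array(cohort$images[s, c, , , ], cohort$grid_shape)
      write_volume(vol, file.path(dir, sprintf("%s_%s.nii", id,
                                               cohort$channel_names[c])))
    }
  }
  write_volume(array(as.numeric(cohort$mask), cohort$grid_shape),
               file.path(dir, "mask.nii"))
  write_volume(array(as.numeric(cohort$labels), cohort$grid_shape),
               file.path(dir, "labels.nii"))
  jsonlite::write_json(lapply(cohort$affines, function(a) unclass(a)),
                       file.path(dir, "affines.json"), digits = NA)
  write_covariates(cohort$covariates, file.path(dir, "covariates.csv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Grid consistency is enforced across all volumes; a mismatching file is
#' named in the error.
#'
#' @param dir Directory produced by [write_cohort()] (or CLI `simulate`).
#' @return A `cohort` (without hidden effects, which exist only in memory).
#' @export
read_cohort <- function(dir) {
  cov <- read_covariates(file.path(dir, "covariates.csv"))
  mask_vol <- read_volume(file.path(dir, "mask.nii"))
  gs <- dim(mask_vol)
  vals <- unique(as.numeric(mask_vol))
  if (!all(vals %in% c(0, 1)))
    warning("mask contains non-{0,1} values; coercing > 0 to TRUE", call. = FALSE)
  mask <- array(mask_vol > 0, gs)
  labels_path <- file.path(dir, "labels.nii")
  labels <- if (file.exists(labels_path))
    array(as.integer(round(read_volume(labels_path))), gs) else array(as.integer(mask), gs)
  n <- nrow(cov)
  images <- array(0, c(n, 5, gs))
  for (s in seq_len(n)) {
    id <- cov$subject_id[s]
    for (c in seq_along(channel_names())) {
      f <- file.path(dir, sprintf("%s_%s.nii", id, channel_names()[c]))
      v <- read_volume(f)
      if (!all(dim(v) == gs))
        stop_arg("grid mismatch in %s: %s vs mask %s", f,
                 paste(dim(v), collapse = "x"), paste(gs, collapse = "x"))
      images[s, c, , , ] <- v
    }
  }
  aff_path <- file.path(dir, "affines.json")
  affines <- if (file.exists(aff_path))
    lapply(jsonlite::read_json(aff_path, simplifyVector = FALSE), function(a)
      matrix(unlist(a), 3, 4, byrow = TRUE)) else rep(list(cbind(diag(3), 0)), n)
  vox <- which(mask)
  structure(list(covariates = cov, images = images, mask = mask,
                 labels = structure(labels, class = c("tissue_label_map", "array")),
                 affines = affines, channel_names = channel_names(),
                 noise_sd = NA_real_, subject_effect_sd = NA_real_, spec = NULL,
                 grid_shape = gs, effects = NULL, voxel_index = vox, seed = NA),
            class = "cohort")
}
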