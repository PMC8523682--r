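#' Construct a 4D fMRI image
#'
#' Container for a subject's resting-state time series: an X x Y x Z x T
#' numeric array plus voxel geometry and repetition time. Voxel indices are
#' 1-based, axis order X, Y, Z, T (see the package help page).
#'
#' @param data numeric 4D array (X x Y x Z x T), finite values, T >= 2.
#' @param voxel_size_mm numeric length-3 voxel dimensions in mm.
#' @param tr_s repetition time in seconds.
#' @return an object of class `image_4d` with elements `data`,
#'   `voxel_size_mm`, `tr_s`.
#' @export
image_4d <- function(data, voxel_size_mm = c(1.2, 1.2, 1.5), tr_s = 2.8) {
  data <- unclass(as.array(data))
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 4L) {
    stop("image_4d requires a 4D array (X,Y,Z,T); got ",
         length(dim(data)), " dimensions", call. = FALSE)
  }
  if (dim(data)[4] < 2L) stop("image_4d requires T >= 2", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all image dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(data))) stop("image_4d values must be finite", call. = FALSE)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be 3 positive values", call. = FALSE)
  }
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0) {
    stop("tr_s must be a single positive number", call. = FALSE)
  }
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_s = as.numeric(tr_s)),
            class = "image_4d")
}

#' @export
print.image_4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_4d> %d x %d x %d voxels, %d timepoints; voxel %s mm; TR %.3g s\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size_mm), collapse = " x "), x$tr_s))
  invisible(x)
}

#' Construct a 3D statistic map
#'
#' A voxelwise statistic over a brain mask, tagged with its kind. Off-mask
#' voxels are stored as `NA` once a mask has been applied.
#'
#' @param data numeric 3D array.
#' @param kind one of `"r"`, `"t"`, `"z"`, `"mean_z"`, `"diff_z"`.
#' @param mask_applied logical; `TRUE` if off-mask voxels are `NA`.
#' @return an object of class `stat_map`.
#' @export
stat_map <- function(data, kind, mask_applied = FALSE) {
  kind <- match.arg(kind, c("r", "t", "z", "mean_z", "diff_z"))
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("stat_map requires a 3D array", call. = FALSE)
  v <- data[!is.na(data)]
  if (kind == "r" && length(v) && (min(v) < -1 - 1e-12 || max(v) > 1 + 1e-12)) {
    stop("r-kind stat_map values must lie in [-1, 1]", call. = FALSE)
  }
  if (kind == "z" && mask_applied && length(v) >= 2) {
    m <- mean(v)
    va_pop <- mean((v - m)^2)
    va_smp <- va_pop * length(v) / (length(v) - 1)
    if (abs(m) > 1e-6 || min(abs(va_pop - 1), abs(va_smp - 1)) > 1e-6) {
      stop(sprintf(
        "z-kind stat_map must have in-mask mean 0 and variance 1 (got mean %.3g, var %.3g)",
        m, va_pop), call. = FALSE)
    }
  }
  structure(list(data = data, kind = kind, mask_applied = isTRUE(mask_applied)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<stat_map kind=%s> %d x %d x %d; %d non-NA voxels\n",
              x$kind, d[1], d[2], d[3], sum(!is.na(x$data))))
  invisible(x)
}

#' Read a 4D NIfTI image
#'
#' Loads a 4D NIfTI-1 file, reorients it to canonical (RAS) axes, and reads
#' voxel size and TR from the header. Inputs are assumed to be already on a
#' common (e.g. stereotaxic) grid; only axis conventions are fixed here.
#'
#' @param path path to a `.nii` or `.nii.gz` file with 4 dimensions.
#' @param tr_s optional TR override in seconds; if `NULL` the header value is
#'   used.
#' @return an [image_4d].
#' @export
read_image_4d <- function(path, tr_s = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  nim <- RNifti::readNifti(path)
  if (!identical(RNifti::orientation(nim), "RAS")) {
    RNifti::orientation(nim) <- "RAS"
  }
  if (length(dim(nim)) != 4L) {
    stop("expected a 4D image, got ", length(dim(nim)),
         " dimensions: ", path, call. = FALSE)
  }
  pd <- RNifti::pixdim(nim)
  header_tr <- if (length(pd) >= 4) pd[4] else NA_real_
  tr <- tr_s %||% header_tr
  if (!is.finite(tr) || tr <= 0) {
    stop("no usable TR in header of ", path, "; pass tr_s explicitly",
         call. = FALSE)
  }
  image_4d(as.array(nim)[, , , , drop = FALSE], voxel_size_mm = pd[1:3], tr_s = tr)
}

#' Write a 4D image as NIfTI
#'
#' @param img an [image_4d].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_image_4d <- function(img, path) {
  stopifnot(inherits(img, "image_4d"))
  nim <- RNifti::asNifti(img$data)
  RNifti::pixdim(nim) <- c(img$voxel_size_mm, img$tr_s)
  RNifti::pixunits(nim) <- c("mm", "s")
  RNifti::writeNifti(nim, path)
  invisible(path)
}

# Drop NIfTI pointer/class attributes, keeping a plain array.
strip_array <- function(x) {
  x <- as.array(x)
  attributes(x) <- list(dim = dim(x))
  x
}

stat_map_sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0(".json")
}

#' Write a statistic map with a JSON sidecar
#'
#' The voxel values go to a NIfTI file (64-bit float storage, so round trips
#' are lossless); the map kind, mask flag and any extra provenance go to a
#' JSON sidecar next to it (`<stem>.json`), since NIfTI-1 has no standard
#' slot for them. `NA` voxels are stored as NaN and restored as `NA`.
#'
#' @param map a [stat_map].
#' @param path output NIfTI path.
#' @param extra optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path, extra = NULL) {
  stopifnot(inherits(map, "stat_map"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  nim <- RNifti::asNifti(map$data, datatype = "double")
  RNifti::writeNifti(nim, path)
  side <- c(list(kind = map$kind, mask_applied = map$mask_applied), extra)
  jsonlite::write_json(side, stat_map_sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a statistic map written by [write_stat_map()]
#'
#' @param path NIfTI path; the JSON sidecar is looked up next to it.
#' @return a [stat_map]; the full sidecar is attached as attribute `sidecar`.
#' @export
read_stat_map <- function(path) {
  side_path <- stat_map_sidecar_path(path)
  if (!file.exists(side_path)) {
    stop("missing sidecar for stat map: ", side_path, call. = FALSE)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  arr <- strip_array(RNifti::readNifti(path))
  arr[is.nan(arr)] <- NA_real_
  out <- stat_map(arr, kind = side$kind, mask_applied = isTRUE(side$mask_applied))
  attr(out, "sidecar") <- side
  out
}

#' Read or write a brain mask
#'
#' Masks are stored as 8-bit NIfTI volumes; any nonzero voxel is inside the
#' mask. A mask in memory is a 3D logical array on the image grid.
#'
#' @param path NIfTI path.
#' @return `read_brain_mask`: a 3D logical array with at least one `TRUE`
#'   voxel.
#' @export
read_brain_mask <- function(path) {
  arr <- strip_array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stop("brain mask must be 3D", call. = FALSE)
  m <- arr != 0
  if (!any(m)) stop("brain mask has no in-mask voxels", call. = FALSE)
  m
}

#' @rdname read_brain_mask
#' @param mask 3D logical array.
#' @export
write_brain_mask <- function(mask, path) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim = dim(mask)),
                                     datatype = "uint8"), path)
  invisible(path)
}

check_mask <- function(mask, dims3) {
  if (!is.logical(mask) || length(dim(mask)) != 3L) {
    stop("mask must be a 3D logical array", call. = FALSE)
  }
  if (!identical(dim(mask), as.integer(dims3))) {
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match image grid ", paste(dims3, collapse = "x"),
         call. = FALSE)
  }
  if (!any(mask)) stop("mask has no in-mask voxels", call. = FALSE)
  invisible(TRUE)
}

#' Construct an ROI definition
#'
#' A labeled region map: integer labels on the image grid (0 = background)
#' plus a name per nonzero label, e.g. `"Left posterior cingulate cortex"`.
#'
#' @param label_map 3D integer array, 0 = background.
#' @param names named character vector mapping label (as name) to region name.
#' @return an object of class `roi_definition`.
#' @export
roi_definition <- function(label_map, names) {
  label_map <- as.array(label_map)
  if (length(dim(label_map)) != 3L) stop("label_map must be 3D", call. = FALSE)
  labs <- sort(unique(as.vector(label_map)))
  labs <- labs[labs != 0]
  missing <- setdiff(as.character(labs), base::names(names))
  if (length(missing)) {
    stop("no name for ROI label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(label_map = label_map, names = names), class = "roi_definition")
}

#' Read an ROI label map from NIfTI plus a JSON name table
#'
#' @param path NIfTI label map (integers, 0 background).
#' @param names_path JSON file of `{"label": "Region name", ...}`; defaults to
#'   the sidecar `<stem>.json`.
#' @return a [roi_definition].
#' @export
read_roi_definition <- function(path, names_path = NULL) {
  names_path <- names_path %||% stat_map_sidecar_path(path)
  arr <- round(strip_array(RNifti::readNifti(path)))
  storage.mode(arr) <- "integer"
  nm <- unlist(jsonlite::read_json(names_path, simplifyVector = TRUE))
  roi_definition(arr, nm)
}

#' @rdname read_roi_definition
#' @param rois a [roi_definition] to write.
#' @export
write_roi_definition <- function(rois, path) {
  stopifnot(inherits(rois, "roi_definition"))
  RNifti::writeNifti(RNifti::asNifti(rois$label_map, datatype = "int16"), path)
  jsonlite::write_json(as.list(rois$names), stat_map_sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

manifest_columns <- c("subject_id", "group", "image_path", "physio_path", "rng_seed")

#' Read a cohort manifest
#'
#' The manifest is a TSV with header columns `subject_id`, `group`,
#' `image_path`, `physio_path`, `rng_seed`, one row per subject.
#'
#' @param path TSV path.
#' @param require_two_groups if `TRUE`, validate that exactly two distinct
#'   group labels are present (required before a group contrast).
#' @return a data.frame of validated rows.
#' @export
read_manifest <- function(path, require_two_groups = FALSE) {
  if (!file.exists(path)) stop("cannot read manifest: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicated subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (require_two_groups && length(unique(df$group)) != 2L) {
    stop("group contrast requires exactly 2 distinct group labels; found ",
         length(unique(df$group)), call. = FALSE)
  }
  df$rng_seed <- as.integer(df$rng_seed)
  df[manifest_columns]
}

#' @rdname read_manifest
#' @param manifest data.frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(manifest_columns %in% names(manifest)))
  write.table(manifest[manifest_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read or write per-volume physiological phase traces
#'
#' Plain-text, whitespace-delimited, two columns per volume:
#' `cardiac_phase resp_phase`, both in radians in `[0, 2*pi)`.
#'
#' @param path text file path.
#' @return `read_physio_trace`: a `physio_trace` (list with `cardiac_phase`,
#'   `resp_phase`).
#' @export
read_physio_trace <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 2L) stop("physio trace must have 2 columns", call. = FALSE)
  physio_trace(m[, 1], m[, 2])
}

#' @rdname read_physio_trace
#' @param physio a `physio_trace`.
#' @export
write_physio_trace <- function(physio, path) {
  stopifnot(inherits(physio, "physio_trace"))
  write.table(data.frame(physio$cardiac_phase, physio$resp_phase), path,
              sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a physiological phase trace
#'
#' @param cardiac_phase,resp_phase numeric vectors of equal length, radians in
#'   `[0, 2*pi)`, one value per fMRI volume.
#' @return an object of class `physio_trace`.
#' @export
physio_trace <- function(cardiac_phase, resp_phase) {
  if (length(cardiac_phase) != length(resp_phase)) {
    stop("cardiac and respiratory phase series must have equal length",
         call. = FALSE)
  }
  if (!all(is.finite(cardiac_phase)) || !all(is.finite(resp_phase))) {
    stop("phase series must be finite", call. = FALSE)
  }
  structure(list(cardiac_phase = as.numeric(cardiac_phase) %% (2 * pi),
                 resp_phase = as.numeric(resp_phase) %% (2 * pi)),
            class = "physio_trace")
}
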