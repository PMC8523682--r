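#' Define a 9-voxel seed region
#'
#' The seed is the 3x3 in-plane (single axial slice) block of voxels centered
#' on `center`. Every block voxel must lie inside the grid and inside the
#' brain mask.
#'
#' @param center integer voxel coordinate `c(x, y, z)` (1-based).
#' @param mask 3D logical array.
#' @param hemisphere_tag free label, e.g. `"L-PCC"`.
#' @return an object of class `seed_region` with `voxel_indices` (9 x 3
#'   matrix), `center`, `hemisphere_tag`.
#' @export
define_seed <- function(center, mask, hemisphere_tag = "") {
  if (length(center) != 3L) stop("seed center must be c(x, y, z)", call. = FALSE)
  center <- as.integer(center)
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be 3D", call. = FALSE)
  if (center[1] < 2L || center[1] > d[1] - 1L ||
      center[2] < 2L || center[2] > d[2] - 1L ||
      center[3] < 1L || center[3] > d[3]) {
    stop("3x3 seed block around (", paste(center, collapse = ","),
         ") exits the grid ", paste(d, collapse = "x"), call. = FALSE)
  }
  block <- as.matrix(expand.grid(x = center[1] + (-1:1),
                                 y = center[2] + (-1:1),
                                 z = center[3]))
  inside <- mask[block]
  if (!all(inside)) {
    bad <- block[!inside, , drop = FALSE]
    stop("seed block voxel(s) outside the brain mask: ",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "),
         call. = FALSE)
  }
  structure(list(voxel_indices = block, center = center,
                 hemisphere_tag = hemisphere_tag),
            class = "seed_region")
}

#' Seed reference time series
#'
#' The linearly detrended arithmetic average of the nine seed voxel time
#' series. The result has zero mean and zero linear trend (orthogonal to the
#' constant and linear terms).
#'
#' @param img an [image_4d].
#' @param seed a [seed_region].
#' @return an object of class `reference_timeseries` with `values` (length-T
#'   numeric) and `source_seed`.
#' @export
reference_timeseries <- function(img, seed) {
  stopifnot(inherits(img, "image_4d"), inherits(seed, "seed_region"))
  d <- dim(img$data)
  if (any(seed$voxel_indices[, 1] > d[1] | seed$voxel_indices[, 2] > d[2] |
          seed$voxel_indices[, 3] > d[3])) {
    stop("seed voxels outside the image grid", call. = FALSE)
  }
  ts_mat <- vapply(seq_len(d[4]), function(tt) {
    mean(img$data[cbind(seed$voxel_indices, tt)])
  }, numeric(1))
  structure(list(values = linear_detrend(ts_mat), source_seed = seed),
            class = "reference_timeseries")
}

#' Voxelwise correlation with the seed reference
#'
#' Zero-lag Pearson correlation between the reference time series and every
#' in-mask voxel time series. Off-mask voxels are `NA`. In-mask voxels with
#' zero temporal variance get `r = 0` and are counted in the `n_zero_variance`
#' attribute (QC) rather than failing the run.
#'
#' @param img an [image_4d] with T >= 4.
#' @param ref a [reference_timeseries] with positive variance.
#' @param mask 3D logical array.
#' @return a [stat_map] of kind `"r"` with attribute `n_zero_variance`.
#' @export
correlation_map <- function(img, ref, mask) {
  stopifnot(inherits(img, "image_4d"), inherits(ref, "reference_timeseries"))
  d <- dim(img$data)
  if (d[4] < 4L) stop("correlation requires T >= 4", call. = FALSE)
  check_mask(mask, d[1:3])
  rv <- ref$values
  if (length(rv) != d[4]) stop("reference length does not match image T", call. = FALSE)
  rc <- rv - mean(rv)
  ref_ss <- sum(rc^2)
  if (ref_ss <= 0) stop("reference time series has zero variance", call. = FALSE)
  idx <- which(as.vector(mask))
  mat <- matrix(img$data, nrow = prod(d[1:3]))[idx, , drop = FALSE]
  mat <- mat - rowMeans(mat)
  vox_ss <- rowSums(mat^2)
  num <- as.vector(mat %*% rc)
  r <- numeric(length(idx))
  ok <- vox_ss > 0
  r[ok] <- num[ok] / sqrt(vox_ss[ok] * ref_ss)
  r <- pmin(1, pmax(-1, r))
  out <- array(NA_real_, dim = d[1:3])
  out[idx] <- r
  n_zero <- sum(!ok)
  if (n_zero > 0) {
    warning(n_zero, " in-mask voxel(s) had zero temporal variance; r set to 0",
            call. = FALSE)
  }
  sm <- stat_map(out, kind = "r", mask_applied = TRUE)
  attr(sm, "n_zero_variance") <- n_zero
  sm
}

#' Degrees-of-freedom policy for the t conversion
#'
#' `nominal` uses `T - 2` degrees of freedom (the default; for a 132-volume
#' series this is 130). Temporal filtering reduces the effective degrees of
#' freedom, so `fixed` lets the user supply a value directly.
#'
#' @param mode `"nominal"` or `"fixed"`.
#' @param dof required when `mode = "fixed"`; must be >= 1.
#' @return an object of class `dof_policy`.
#' @export
dof_policy <- function(mode = c("nominal", "fixed"), dof = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(dof) || !is.numeric(dof) || dof < 1) {
      stop("fixed dof_policy requires dof >= 1", call. = FALSE)
    }
  } else {
    dof <- NULL
  }
  structure(list(mode = mode, dof = dof), class = "dof_policy")
}

resolve_dof <- function(policy, n_timepoints) {
  stopifnot(inherits(policy, "dof_policy"))
  dof <- if (policy$mode == "nominal") n_timepoints - 2 else policy$dof
  if (dof < 1) stop("resolved dof must be >= 1", call. = FALSE)
  dof
}

#' Convert a correlation map to a Student's t map
#'
#' `t = r * sqrt(dof / (1 - r^2))`, with `r` symmetrically clipped to
#' `+/-(1 - 1e-12)` first so perfect correlations yield huge but finite t.
#' The conversion is odd and strictly increasing in r.
#'
#' @param rmap a [stat_map] of kind `"r"`.
#' @param dof a [dof_policy] or a single number of degrees of freedom.
#' @param n_timepoints needed to resolve a `nominal` policy.
#' @return a [stat_map] of kind `"t"`.
#' @export
r_to_t <- function(rmap, dof, n_timepoints = NULL) {
  stopifnot(inherits(rmap, "stat_map"))
  if (rmap$kind != "r") stop("r_to_t expects a stat_map of kind 'r'", call. = FALSE)
  if (inherits(dof, "dof_policy")) {
    if (dof$mode == "nominal" && is.null(n_timepoints)) {
      stop("nominal dof policy needs n_timepoints", call. = FALSE)
    }
    dof <- resolve_dof(dof, n_timepoints %||% 0)
  }
  if (!is.numeric(dof) || length(dof) != 1L || dof < 1) {
    stop("dof must be a single value >= 1", call. = FALSE)
  }
  r <- rmap$data
  lim <- 1 - 1e-12
  r <- pmin(lim, pmax(-lim, r))
  t_vals <- r * sqrt(dof / (1 - r^2))
  stat_map(array(t_vals, dim = dim(rmap$data)), kind = "t",
           mask_applied = rmap$mask_applied)
}

#' Standardize a statistic map over the whole-brain mask
#'
#' Normalizes the in-mask (whole-brain) distribution to zero mean and unit
#' variance: `z = (t - mean) / sd`, where mean and sd are taken over in-mask
#' voxels. The default sd convention is the population SD (divide by N),
#' treating the in-mask values as the full distribution of interest; the
#' sample convention (N-1) is available. The transform is affine, so voxel
#' rank order is preserved, and it is idempotent.
#'
#' @param tmap a [stat_map] (typically kind `"t"`).
#' @param mask 3D logical array.
#' @param sd_convention `"population"` (default) or `"sample"`.
#' @return a [stat_map] of kind `"z"` with attribute `standardization`
#'   recording the mean, sd and convention used.
#' @export
standardize_whole_brain <- function(tmap, mask, sd_convention = c("population", "sample")) {
  stopifnot(inherits(tmap, "stat_map"))
  sd_convention <- match.arg(sd_convention)
  d <- dim(tmap$data)
  check_mask(mask, d)
  vals <- tmap$data[mask]
  if (any(is.na(vals))) stop("NA values inside the mask", call. = FALSE)
  if (length(vals) < 2L) stop("need >= 2 in-mask voxels", call. = FALSE)
  m <- mean(vals)
  s <- if (sd_convention == "population") {
    sqrt(mean((vals - m)^2))
  } else {
    stats::sd(vals)
  }
  if (s == 0) stop("zero in-mask variance; cannot standardize", call. = FALSE)
  out <- array(NA_real_, dim = d)
  out[mask] <- (vals - m) / s
  z <- stat_map(out, kind = "z", mask_applied = TRUE)
  attr(z, "standardization") <- list(mean = m, sd = s, convention = sd_convention)
  z
}

#' Compute one subject's seed-connectivity z-map
#'
#' Full single-subject chain: nuisance regression, 2D Hamming spatial filter
#' (if enabled), temporal low-pass, 9-voxel seed definition, reference time
#' series, voxelwise correlation, Student's t conversion, and whole-brain z
#' standardization.
#'
#' @param img an [image_4d].
#' @param physio a [physio_trace].
#' @param seed_center voxel coordinate `c(x, y, z)` of the seed block center.
#' @param mask 3D logical array.
#' @param cfg a [filter_config]; defaults to 0.08 Hz low-pass at the image TR
#'   with the Hamming filter enabled.
#' @param dof a [dof_policy]; default nominal (`T - 2`).
#' @param harmonics_m RETROICOR harmonics per physiological signal.
#' @param sd_convention passed to [standardize_whole_brain()].
#' @param hemisphere_tag label stored with the seed.
#' @return a [stat_map] of kind `"z"` with attribute `provenance` (seed
#'   voxels, dof, filter settings, sd convention, QC counts).
#' @export
subject_zmap <- function(img, physio, seed_center, mask, cfg = NULL,
                         dof = dof_policy("nominal"), harmonics_m = 2,
                         sd_convention = "population", hemisphere_tag = "") {
  stopifnot(inherits(img, "image_4d"))
  cfg <- cfg %||% filter_config(tr_s = img$tr_s)
  if (abs(cfg$tr_s - img$tr_s) > 1e-9) {
    stop("filter_config tr_s does not match the image TR", call. = FALSE)
  }
  pre <- preprocess_subject(img, physio, mask, cfg, harmonics_m)
  seed <- define_seed(seed_center, mask, hemisphere_tag)
  ref <- reference_timeseries(pre, seed)
  rmap <- correlation_map(pre, ref, mask)
  n_t <- dim(img$data)[4]
  tmap <- r_to_t(rmap, dof, n_timepoints = n_t)
  z <- standardize_whole_brain(tmap, mask, sd_convention)
  attr(z, "provenance") <- list(
    seed_voxels = seed$voxel_indices,
    seed_center = seed$center,
    hemisphere_tag = hemisphere_tag,
    dof = if (inherits(dof, "dof_policy")) resolve_dof(dof, n_t) else dof,
    lowpass_hz = cfg$lowpass_hz,
    hamming_enabled = cfg$hamming_enabled,
    harmonics_m = harmonics_m,
    sd_convention = sd_convention,
    n_zero_variance = attr(rmap, "n_zero_variance"),
    standardization = attr(z, "standardization")
  )
  z
}
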