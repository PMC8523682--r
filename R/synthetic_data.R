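#' Configuration for the synthetic fMRI cohort generator
#'
#' Defines a two-group resting-state cohort with known connectivity ground
#' truth. The acquisition envelope defaults to a 132-volume series at
#' TR 2.8 s. A small set of spherical "network nodes" (the first is the seed
#' node) share a single low-frequency latent source; the group label controls
#' the planted signal amplitude, so any downstream group contrast is
#' attributable to connectivity strength alone.
#'
#' @param grid_dims voxels per axis (default `c(24, 24, 16)`, a desk-scale
#'   grid rather than a full brain).
#' @param voxel_size_mm voxel dimensions in mm (default 1.2 x 1.2 x 1.5).
#' @param n_timepoints number of volumes (default 132, >= 8).
#' @param tr_s repetition time in seconds (default 2.8).
#' @param node_centers list of 1-based voxel coordinates: the seed node first,
#'   then at least two remote network nodes. All centers must lie at least
#'   `node_radius_vox` inside the grid.
#' @param node_radius_vox radius (in voxels) of the spherical nodes.
#' @param amp_by_group named numeric: planted network amplitude `a` per group
#'   label (exactly two distinct labels; amplitudes >= 0). Defaults to 0.3
#'   for `"head-trauma"` and 0.8 for `"no-head-trauma"`.
#' @param noise_sd white-noise standard deviation `s` (> 0, default 1).
#' @param drift_slope linear drift in signal units per volume (default 0.01).
#' @param cardiac_hz,resp_hz nominal physiological frequencies (defaults 1.0
#'   and 0.3 Hz).
#' @param physio_amp amplitude of the phase-locked physiological confound
#'   (default 0.5).
#' @param phase_jitter_sd per-volume phase-increment jitter SD in radians
#'   (default 0.1).
#' @param rng_seed default base seed for generation.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(grid_dims = c(24, 24, 16),
                              voxel_size_mm = c(1.2, 1.2, 1.5),
                              n_timepoints = 132,
                              tr_s = 2.8,
                              node_centers = list(c(12, 12, 8),
                                                  c(6, 6, 5),
                                                  c(18, 17, 11)),
                              node_radius_vox = 2,
                              amp_by_group = c("head-trauma" = 0.3,
                                               "no-head-trauma" = 0.8),
                              noise_sd = 1,
                              drift_slope = 0.01,
                              cardiac_hz = 1.0,
                              resp_hz = 0.3,
                              physio_amp = 0.5,
                              phase_jitter_sd = 0.1,
                              rng_seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 4L)) {
    stop("grid_dims must be 3 values >= 4", call. = FALSE)
  }
  if (n_timepoints < 8) stop("n_timepoints must be >= 8", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (any(amp_by_group < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (length(amp_by_group) != 2L || is.null(names(amp_by_group)) ||
      anyDuplicated(names(amp_by_group)) || any(names(amp_by_group) == "")) {
    stop("amp_by_group must name exactly two distinct group labels", call. = FALSE)
  }
  if (cardiac_hz <= 0 || resp_hz <= 0) {
    stop("physiological frequencies must be > 0", call. = FALSE)
  }
  if (!is.list(node_centers) || length(node_centers) < 3L) {
    stop("node_centers must list the seed node plus >= 2 remote nodes",
         call. = FALSE)
  }
  r <- as.integer(node_radius_vox)
  if (r < 1L) stop("node_radius_vox must be >= 1", call. = FALSE)
  for (ctr in node_centers) {
    if (length(ctr) != 3L) stop("node centers must be c(x, y, z)", call. = FALSE)
    if (any(ctr - r < 1L) || any(ctr + r > grid_dims)) {
      stop("node center (", paste(ctr, collapse = ","), ") lies closer than ",
           r, " voxels to the grid boundary", call. = FALSE)
    }
  }
  structure(list(grid_dims = grid_dims,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 n_timepoints = as.integer(n_timepoints), tr_s = tr_s,
                 node_centers = lapply(node_centers, as.integer),
                 node_radius_vox = r, amp_by_group = amp_by_group,
                 noise_sd = noise_sd, drift_slope = drift_slope,
                 cardiac_hz = cardiac_hz, resp_hz = resp_hz,
                 physio_amp = physio_amp, phase_jitter_sd = phase_jitter_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

# Per-volume phase series advancing at 2*pi*f*tr per volume plus Gaussian
# jitter on each increment; first volume at phase 0. Draws from the current
# RNG stream.
physio_phases_impl <- function(n, tr_s, freq_hz, jitter_sd) {
  inc <- rep(2 * pi * freq_hz * tr_s, n - 1)
  if (jitter_sd > 0) inc <- inc + rnorm(n - 1, 0, jitter_sd)
  c(0, cumsum(inc)) %% (2 * pi)
}

#' Simulate per-volume cardiac and respiratory phase traces
#'
#' Each phase advances by its nominal increment `2*pi*f*TR` per volume plus
#' small Gaussian jitter, starting at phase 0, reported modulo `2*pi`.
#' Deterministic for a fixed seed.
#'
#' @param n_timepoints number of volumes (>= 2).
#' @param tr_s repetition time in seconds.
#' @param cardiac_hz,resp_hz nominal frequencies (> 0).
#' @param rng_seed integer seed.
#' @param jitter_sd per-increment jitter SD in radians (0 disables jitter).
#' @return a [physio_trace].
#' @export
make_physio_traces <- function(n_timepoints, tr_s, cardiac_hz = 1.0,
                               resp_hz = 0.3, rng_seed = 1L, jitter_sd = 0.1) {
  if (!is.numeric(n_timepoints) || n_timepoints < 2) {
    stop("invalid config: n_timepoints must be >= 2", call. = FALSE)
  }
  if (cardiac_hz <= 0 || resp_hz <= 0 || tr_s <= 0) {
    stop("invalid config: tr and frequencies must be > 0", call. = FALSE)
  }
  with_rng_seed(rng_seed, {
    physio_trace(
      physio_phases_impl(n_timepoints, tr_s, cardiac_hz, jitter_sd),
      physio_phases_impl(n_timepoints, tr_s, resp_hz, jitter_sd)
    )
  })
}

# Unit-variance low-frequency latent source: random-phase sum over DFT bins
# 2..28 of a length-n grid at spacing tr_s (all below the 0.08 Hz cutoff for
# n = 132, tr = 2.8), standardized to zero mean and unit population variance.
# Draws from the current RNG stream.
make_shared_source <- function(n, tr_s, cutoff_hz = 0.08) {
  freqs <- (seq_len(n) - 1) / (n * tr_s)
  bins <- which(freqs > 0 & freqs < cutoff_hz & seq_len(n) - 1 <= n / 2)
  bins <- bins[bins >= 3]                 # skip DC and the slowest bin
  if (length(bins) < 2L) bins <- 2:3      # degenerate short series
  t_idx <- seq_len(n) - 1
  amp <- runif(length(bins), 0.5, 1)
  ph <- runif(length(bins), 0, 2 * pi)
  src <- rep(0, n)
  for (i in seq_along(bins)) {
    f <- (bins[i] - 1) / (n * tr_s)
    src <- src + amp[i] * cos(2 * pi * f * t_idx * tr_s + ph[i])
  }
  src <- src - mean(src)
  src / sqrt(mean(src^2))
}

node_label_array <- function(config) {
  d <- config$grid_dims
  lab <- array(0L, dim = d)
  r <- config$node_radius_vox
  off <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  off <- off[rowSums(off^2) <= r^2, , drop = FALSE]
  for (i in seq_along(config$node_centers)) {
    ctr <- config$node_centers[[i]]
    vox <- sweep(off, 2, ctr, "+")
    lab[vox] <- i
  }
  lab
}

#' Generate one synthetic subject
#'
#' Voxel time series model:
#' `a * n(t) * [voxel in a node] + physio_amp * (sin(phi_c) + sin(phi_r)) +
#' drift_slope * t + s * eps(t)`, where `n(t)` is a unit-variance latent
#' source band-limited below 0.08 Hz shared by all node voxels, `eps` is
#' white Gaussian noise, and `t` is the 0-based volume index. The theoretical
#' correlation of a node voxel's signal-plus-noise component with the source
#' is `a / sqrt(a^2 + s^2)`; it is 0 outside the nodes.
#'
#' @param config a [simulation_config].
#' @param group one of the two group labels in `config$amp_by_group`.
#' @param rng_seed integer seed; the whole subject is a pure function of
#'   `(config, group, rng_seed)`.
#' @return a list with `image` ([image_4d]), `physio` ([physio_trace]) and
#'   `truth` (list: `true_r_map` 3D array, `node_labels` integer 3D array,
#'   `node_masks` list of logical arrays, `shared_source` length-T vector,
#'   `group`, `amplitude`).
#' @export
generate_subject <- function(config, group, rng_seed = config$rng_seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (!group %in% names(config$amp_by_group)) {
    stop("unknown group label '", group, "'; expected one of: ",
         paste(names(config$amp_by_group), collapse = ", "), call. = FALSE)
  }
  a <- unname(config$amp_by_group[[group]])
  s <- config$noise_sd
  d <- config$grid_dims
  n <- config$n_timepoints
  with_rng_seed(rng_seed, {
    physio <- physio_trace(
      physio_phases_impl(n, config$tr_s, config$cardiac_hz, config$phase_jitter_sd),
      physio_phases_impl(n, config$tr_s, config$resp_hz, config$phase_jitter_sd)
    )
    src <- make_shared_source(n, config$tr_s)
    labels <- node_label_array(config)
    in_node <- as.vector(labels > 0)
    t_idx <- seq_len(n) - 1
    confound <- config$physio_amp * (sin(physio$cardiac_phase) + sin(physio$resp_phase)) +
      config$drift_slope * t_idx
    nv <- prod(d)
    mat <- matrix(rnorm(nv * n, sd = s), nrow = nv, ncol = n)
    mat <- sweep(mat, 2, confound, "+")
    if (a > 0 && any(in_node)) {
      mat[in_node, ] <- mat[in_node, ] + rep(a * src, each = sum(in_node))
    }
    true_r <- array(0, dim = d)
    true_r[labels > 0] <- a / sqrt(a^2 + s^2)
    node_masks <- lapply(seq_along(config$node_centers), function(i) labels == i)
    names(node_masks) <- paste0("node", seq_along(node_masks))
    list(
      image = image_4d(array(mat, dim = c(d, n)), config$voxel_size_mm, config$tr_s),
      physio = physio,
      truth = list(true_r_map = true_r, node_labels = labels,
                   node_masks = node_masks, shared_source = src,
                   group = group, amplitude = a)
    )
  })
}

#' Generate and write a two-group synthetic cohort
#'
#' Writes one 4D NIfTI image and one physio text file per subject, a TSV
#' manifest, and the ground truth (true-r NIfTI plus a JSON file with node
#' definitions). Per-subject seeds are derived deterministically from
#' `base_seed`.
#'
#' @param config a [simulation_config].
#' @param n_per_group subjects per group (>= 1; default 3).
#' @param base_seed integer base seed.
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame (columns `subject_id`, `group`,
#'   `image_path`, `physio_path`, `rng_seed`), invisibly also written to
#'   `manifest.tsv` in `out_dir`.
#' @export
generate_cohort <- function(config, n_per_group = 3, base_seed = config$rng_seed,
                            out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  groups <- names(config$amp_by_group)
  rows <- list()
  k <- 0L
  for (g in groups) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      seed_i <- derive_seed(base_seed, k)
      sid <- sprintf("sub-%s-%02d", gsub("[^A-Za-z0-9]+", "", g), i)
      sub <- generate_subject(config, g, seed_i)
      img_path <- file.path(out_dir, paste0(sid, ".nii.gz"))
      phys_path <- file.path(out_dir, paste0(sid, "_physio.txt"))
      write_image_4d(sub$image, img_path)
      write_physio_trace(sub$physio, phys_path)
      rows[[k]] <- data.frame(subject_id = sid, group = g,
                              image_path = img_path, physio_path = phys_path,
                              rng_seed = seed_i, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  # ground truth is group-independent up to amplitude; store geometry + both
  truth <- generate_subject(config, groups[1], derive_seed(base_seed, 1L))$truth
  RNifti::writeNifti(RNifti::asNifti(truth$true_r_map, datatype = "double"),
                     file.path(out_dir, "true_r.nii.gz"))
  jsonlite::write_json(
    list(node_centers = config$node_centers,
         node_radius_vox = config$node_radius_vox,
         amp_by_group = as.list(config$amp_by_group),
         noise_sd = config$noise_sd,
         true_r_by_group = as.list(config$amp_by_group /
                                     sqrt(config$amp_by_group^2 + config$noise_sd^2))),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
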