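#' Load a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file containing one) with
#' any of the fields below; unspecified fields take the documented defaults.
#'
#' * `out_dir` (required): output directory.
#' * `manifest`: path to a cohort manifest TSV (not needed for `run_simulate`).
#' * `mask`: brain mask NIfTI path; default: whole grid in-mask.
#' * `rois`: ROI label map NIfTI path (with JSON names sidecar); optional.
#' * `seed_center`: 1-based voxel coordinate of the seed block center;
#'   default: the first simulation node center.
#' * `lowpass_hz` (0.08), `hamming_enabled` (true), `harmonics_m` (2),
#'   `dof` (`"nominal"` or a number), `sd_convention` (`"population"`),
#'   `z_floor` (2.3), `alpha` (0.05), `two_sided` (true),
#'   `min_cluster_vox` (31), `connectivity` (`"faces"`),
#'   `diff_mode` (`"standardized_diff"`), `rng_seed` (1),
#'   `n_per_group` (3), `simulation`: named list of [simulation_config()]
#'   overrides.
#'
#' @param config named list or path to a YAML file.
#' @return validated config list of class `run_config`.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  defaults <- list(manifest = NULL, mask = NULL, rois = NULL,
                   seed_center = NULL, lowpass_hz = 0.08,
                   hamming_enabled = TRUE, harmonics_m = 2, dof = "nominal",
                   sd_convention = "population", z_floor = 2.3, alpha = 0.05,
                   two_sided = TRUE, min_cluster_vox = 31,
                   connectivity = "faces", diff_mode = "standardized_diff",
                   rng_seed = 1L, n_per_group = 3, simulation = list())
  unknown <- setdiff(names(config), c(names(defaults), "out_dir"))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$out_dir)) stop("config requires out_dir", call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  structure(cfg, class = "run_config")
}

run_dof_policy <- function(dof) {
  if (identical(dof, "nominal")) dof_policy("nominal") else
    dof_policy("fixed", dof = as.numeric(dof))
}

sim_config_from_run <- function(cfg) {
  do.call(simulation_config, cfg$simulation)
}

write_provenance <- function(path, stage, cfg, files, extra = NULL) {
  rec <- c(list(
    tool = "seedconn",
    version = as.character(utils::packageVersion("seedconn")),
    stage = stage,
    config = unclass(cfg),
    outputs = files,
    file_md5 = as.list(tools::md5sum(files[file.exists(files)])),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Simulate a synthetic cohort from a run configuration
#'
#' Calls [generate_cohort()] with the configured simulation parameters and
#' writes the images, physio traces, manifest and a provenance record under
#' `out_dir`.
#'
#' @param config run configuration (list or YAML path; see
#'   [load_run_config()]).
#' @return the manifest data.frame, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- load_run_config(config)
  sim <- sim_config_from_run(cfg)
  manifest <- generate_cohort(sim, n_per_group = cfg$n_per_group,
                              base_seed = cfg$rng_seed, out_dir = cfg$out_dir)
  files <- c(file.path(cfg$out_dir, "manifest.tsv"),
             manifest$image_path, manifest$physio_path,
             file.path(cfg$out_dir, c("true_r.nii.gz", "ground_truth.json")))
  write_provenance(file.path(cfg$out_dir, "provenance_simulate.json"),
                   "simulate", cfg, files)
  invisible(manifest)
}

default_roi_definition <- function(sim) {
  lab <- node_label_array(sim)
  nm <- paste0("node", seq_along(sim$node_centers))
  nm[1] <- "seed node"
  names(nm) <- as.character(seq_along(sim$node_centers))
  roi_definition(lab, nm)
}

#' Run the full pipeline on a cohort
#'
#' For every subject in the manifest: load the image and physio trace,
#' compute the seed-connectivity z-map, and write it (with sidecar). Then
#' compute the two group mean maps, the group difference map (first group
#' label in the manifest minus the second), voxel + cluster thresholding,
#' per-subject ROI summaries and the report tables, plus a provenance record.
#'
#' @param config run configuration (list or YAML path). `manifest` is
#'   required; `mask` defaults to the whole grid; `seed_center` defaults to
#'   the first simulation node center; `rois` defaults (when the cohort was
#'   simulated) to the simulation node label map.
#' @return a list with `manifest`, `zmap_paths`, `group_means`, `difference`,
#'   `thresholded`, `clusters`, `roi_rows`, `report_files`, invisibly.
#' @export
run_full <- function(config) {
  cfg <- load_run_config(config)
  if (is.null(cfg$manifest)) stop("run_full requires config$manifest", call. = FALSE)
  manifest <- read_manifest(cfg$manifest, require_two_groups = TRUE)
  missing <- manifest$image_path[!file.exists(manifest$image_path)]
  if (length(missing)) {
    stop("manifest image(s) not readable: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  first <- read_image_4d(manifest$image_path[1])
  d3 <- dim(first$data)[1:3]
  mask <- if (is.null(cfg$mask)) array(TRUE, dim = d3) else read_brain_mask(cfg$mask)
  sim <- sim_config_from_run(cfg)
  seed_center <- cfg$seed_center %||% sim$node_centers[[1]]
  fcfg <- filter_config(tr_s = first$tr_s, lowpass_hz = cfg$lowpass_hz,
                        hamming_enabled = cfg$hamming_enabled)
  dofp <- run_dof_policy(cfg$dof)
  rois <- if (!is.null(cfg$rois)) read_roi_definition(cfg$rois) else
    if (identical(d3, sim$grid_dims)) default_roi_definition(sim) else NULL

  zmaps <- list()
  zmap_paths <- character(0)
  roi_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    img <- tryCatch(read_image_4d(manifest$image_path[i]),
                    error = function(e) stop("stage zmap, subject ", sid, ": ",
                                             conditionMessage(e), call. = FALSE))
    physio <- read_physio_trace(manifest$physio_path[i])
    z <- tryCatch(
      subject_zmap(img, physio, seed_center, mask, fcfg, dofp,
                   harmonics_m = cfg$harmonics_m,
                   sd_convention = cfg$sd_convention),
      error = function(e) stop("stage zmap, subject ", sid, ": ",
                               conditionMessage(e), call. = FALSE))
    zp <- file.path(cfg$out_dir, paste0(sid, "_z.nii.gz"))
    write_stat_map(z, zp, extra = attr(z, "provenance"))
    zmaps[[sid]] <- z
    zmap_paths <- c(zmap_paths, zp)
    if (!is.null(rois)) {
      rs <- roi_summary(z, rois, z_floor = cfg$z_floor)
      rs$subject_id <- sid
      rs$group <- manifest$group[i]
      roi_rows[[sid]] <- rs
    }
  }

  groups <- unique(manifest$group)
  by_group <- split(seq_len(nrow(manifest)), manifest$group)[groups]
  means <- lapply(by_group, function(ix) group_mean_map(zmaps[ix], mask))
  gcc <- group_contrast_config(alpha = cfg$alpha, two_sided = cfg$two_sided,
                               min_cluster_vox = cfg$min_cluster_vox,
                               connectivity = cfg$connectivity,
                               diff_mode = cfg$diff_mode)
  diff <- difference_map(means[[1]], means[[2]], gcc,
                         n_a = length(by_group[[1]]), n_b = length(by_group[[2]]))
  thr <- threshold_clusters(diff, gcc, mask)

  mean_paths <- file.path(cfg$out_dir,
                          paste0("group_mean_", gsub("[^A-Za-z0-9]+", "", groups), "_z.nii.gz"))
  for (i in seq_along(means)) write_stat_map(means[[i]], mean_paths[i])
  diff_path <- file.path(cfg$out_dir, "group_diff_z.nii.gz")
  thr_path <- file.path(cfg$out_dir, "group_diff_thresholded_z.nii.gz")
  write_stat_map(diff, diff_path,
                 extra = list(contrast = paste(groups[1], "minus", groups[2]),
                              diff_mode = gcc$diff_mode))
  write_stat_map(thr$map, thr_path,
                 extra = list(alpha = gcc$alpha, two_sided = gcc$two_sided,
                              min_cluster_vox = gcc$min_cluster_vox,
                              connectivity = gcc$connectivity))
  roi_df <- if (length(roi_rows)) do.call(rbind, c(roi_rows, make.row.names = FALSE)) else
    data.frame(subject_id = character(0), group = character(0),
               region = character(0), mean_z = numeric(0), sd_z = numeric(0),
               n_voxels = integer(0))
  report_files <- render_report(thr$clusters, roi_df, cfg$out_dir)

  files <- c(zmap_paths, mean_paths, diff_path, thr_path, report_files)
  write_provenance(file.path(cfg$out_dir, "provenance_run.json"), "run_full",
                   cfg, files,
                   extra = list(groups = groups,
                                n_per_group = vapply(by_group, length, integer(1)),
                                n_clusters = nrow(thr$clusters)))
  invisible(list(manifest = manifest, zmap_paths = zmap_paths,
                 group_means = means, difference = diff, thresholded = thr$map,
                 clusters = thr$clusters, roi_rows = roi_df,
                 report_files = report_files))
}

#' In-memory contrast recovery experiment
#'
#' Repeatedly simulates a two-group cohort, computes per-subject z-maps and
#' the thresholded group contrast, and reports (per replicate) the number of
#' surviving clusters and whether any surviving cluster overlaps a planted
#' network node. With equal group amplitudes this measures the false-positive
#' rate of the voxel + cluster-extent threshold; with unequal amplitudes it
#' measures recovery of the planted group difference. No files are written.
#'
#' @param n_replicates number of simulated cohorts.
#' @param config a [simulation_config] (its `amp_by_group` defines the planted
#'   difference; pass equal amplitudes for a null experiment).
#' @param n_per_group subjects per group (default 3).
#' @param base_seed integer; replicate r uses seeds derived from
#'   `base_seed + r`.
#' @param contrast a [group_contrast_config].
#' @param dof a [dof_policy].
#' @return data.frame with one row per replicate: `replicate`, `n_clusters`,
#'   `overlaps_node` (any surviving cluster voxel inside a planted node),
#'   `max_cluster_vox`.
#' @export
contrast_recovery_experiment <- function(n_replicates, config,
                                         n_per_group = 3, base_seed = 1L,
                                         contrast = group_contrast_config(),
                                         dof = dof_policy("nominal")) {
  stopifnot(inherits(config, "simulation_config"))
  mask <- array(TRUE, dim = config$grid_dims)
  node_mask <- node_label_array(config) > 0L
  seed_center <- config$node_centers[[1]]
  fcfg <- filter_config(tr_s = config$tr_s)
  groups <- names(config$amp_by_group)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    zmaps <- list(list(), list())
    k <- 0L
    for (gi in seq_along(groups)) {
      for (i in seq_len(n_per_group)) {
        k <- k + 1L
        sub <- generate_subject(config, groups[gi],
                                derive_seed(base_seed + r, k))
        zmaps[[gi]][[i]] <- subject_zmap(sub$image, sub$physio, seed_center,
                                         mask, fcfg, dof)
      }
    }
    means <- lapply(zmaps, group_mean_map, mask = mask)
    diff <- difference_map(means[[1]], means[[2]], contrast,
                           n_a = n_per_group, n_b = n_per_group)
    thr <- threshold_clusters(diff, contrast, mask)
    surv <- !is.na(thr$map$data) & thr$map$data != 0
    out[[r]] <- data.frame(
      replicate = r, n_clusters = nrow(thr$clusters),
      overlaps_node = any(surv & node_mask),
      max_cluster_vox = if (nrow(thr$clusters)) max(thr$clusters$size_vox) else 0L)
  }
  do.call(rbind, out)
}
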