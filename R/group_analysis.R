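#' Group contrast configuration
#'
#' Thresholding follows the single-voxel-plus-cluster-extent recipe: voxels
#' pass if their statistic exceeds the normal critical value for `alpha`
#' (two-sided by default), and surviving voxels must form connected
#' components strictly larger than 30 voxels (default `min_cluster_vox = 31`).
#'
#' @param alpha single-voxel p threshold (default 0.05).
#' @param two_sided logical; two-sided thresholding by default.
#' @param min_cluster_vox minimum surviving cluster size in voxels
#'   (default 31, i.e. strictly greater than 30).
#' @param connectivity `"faces"` (6-neighborhood, default), `"faces+edges"`
#'   (18) or `"faces+edges+corners"` (26).
#' @param diff_mode `"standardized_diff"` (default): the difference of group
#'   mean z-maps divided by `sqrt(1/n_a + 1/n_b)`, its null SD when subject
#'   maps are unit-variance; or `"naive_diff"`: the raw difference.
#' @return an object of class `group_contrast_config`.
#' @export
group_contrast_config <- function(alpha = 0.05, two_sided = TRUE,
                                  min_cluster_vox = 31,
                                  connectivity = c("faces", "faces+edges",
                                                   "faces+edges+corners"),
                                  diff_mode = c("standardized_diff", "naive_diff")) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  if (min_cluster_vox < 1) stop("min_cluster_vox must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, two_sided = isTRUE(two_sided),
                 min_cluster_vox = as.integer(min_cluster_vox),
                 connectivity = match.arg(connectivity),
                 diff_mode = match.arg(diff_mode)),
            class = "group_contrast_config")
}

#' Voxelwise mean of subject z-maps
#'
#' @param zmaps list of [stat_map]s (kind `"z"`) on identical grids.
#' @param mask 3D logical array.
#' @return a [stat_map] of kind `"mean_z"` (off-mask `NA`).
#' @export
group_mean_map <- function(zmaps, mask) {
  if (!length(zmaps)) stop("need at least one z-map", call. = FALSE)
  lapply(zmaps, function(z) stopifnot(inherits(z, "stat_map")))
  d <- dim(zmaps[[1]]$data)
  check_mask(mask, d)
  for (z in zmaps) {
    if (!identical(dim(z$data), d)) {
      stop("z-maps are not on identical grids", call. = FALSE)
    }
  }
  acc <- Reduce(`+`, lapply(zmaps, function(z) z$data[mask]))
  out <- array(NA_real_, dim = d)
  out[mask] <- acc / length(zmaps)
  stat_map(out, kind = "mean_z", mask_applied = TRUE)
}

#' Group difference map
#'
#' `naive_diff`: voxelwise `mean_a - mean_b`. `standardized_diff`: the same
#' difference divided by `sqrt(1/n_a + 1/n_b)`, which is its standard
#' deviation under the null when the per-subject maps are unit-variance, so
#' the result is on a z scale.
#'
#' @param mean_a,mean_b [stat_map]s of kind `"mean_z"` on the same grid/mask.
#' @param cfg a [group_contrast_config].
#' @param n_a,n_b group sizes (required for `standardized_diff`).
#' @return a [stat_map] of kind `"diff_z"`.
#' @export
difference_map <- function(mean_a, mean_b, cfg = group_contrast_config(),
                           n_a = NULL, n_b = NULL) {
  stopifnot(inherits(mean_a, "stat_map"), inherits(mean_b, "stat_map"))
  if (!identical(dim(mean_a$data), dim(mean_b$data))) {
    stop("group mean maps are not on the same grid", call. = FALSE)
  }
  if (!identical(is.na(mean_a$data), is.na(mean_b$data))) {
    stop("group mean maps have different masks", call. = FALSE)
  }
  diff <- mean_a$data - mean_b$data
  if (cfg$diff_mode == "standardized_diff") {
    if (is.null(n_a) || is.null(n_b) || n_a < 1 || n_b < 1) {
      stop("standardized_diff requires group sizes n_a and n_b", call. = FALSE)
    }
    diff <- diff / sqrt(1 / n_a + 1 / n_b)
  }
  stat_map(diff, kind = "diff_z", mask_applied = mean_a$mask_applied)
}

connectivity_offsets <- function(connectivity) {
  faces <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  edges <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                 c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
  corners <- rbind(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  switch(connectivity,
         "faces" = faces,
         "faces+edges" = rbind(faces, edges),
         "faces+edges+corners" = rbind(faces, edges, corners))
}

# Label connected components of a 3D logical array. Returns an integer array
# (0 = background) and the number of components. Adjacency is resolved with
# igraph over the voxel adjacency graph.
label_components <- function(flag, connectivity = "faces") {
  d <- dim(flag)
  idx <- which(flag)
  lab <- array(0L, dim = d)
  if (!length(idx)) return(list(labels = lab, n = 0L))
  vid <- array(0L, dim = d)
  vid[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  edges <- list()
  for (k in seq_len(nrow(connectivity_offsets(connectivity)))) {
    off <- connectivity_offsets(connectivity)[k, ]
    nb <- sweep(coords, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_id <- vid[nb[ok, , drop = FALSE]]
    src <- seq_along(idx)[ok]
    hit <- nb_id > 0L
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(src[hit], nb_id[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  list(labels = lab, n = comp$no)
}

#' Threshold a difference map at voxel and cluster level
#'
#' Voxels pass if `|value| >= z_crit` where `z_crit` is the standard-normal
#' critical value for `alpha` (`qnorm(1 - alpha/2)` two-sided, about 1.96 for
#' alpha 0.05; `qnorm(1 - alpha)` one-sided). Connected components are then
#' computed separately for positive and negative suprathreshold voxels under
#' the configured neighborhood, and only components with at least
#' `min_cluster_vox` voxels (default: strictly more than 30) are retained;
#' every other voxel is zeroed.
#'
#' @param diff a [stat_map] of kind `"diff_z"`, finite in mask.
#' @param cfg a [group_contrast_config].
#' @param mask 3D logical array.
#' @return a list with `map` (thresholded [stat_map], kind `"diff_z"`) and
#'   `clusters` (data.frame: `cluster_id`, `size_vox`, `peak_value`,
#'   `peak_x/y/z`, `centroid_x/y/z`, `sign`).
#' @export
threshold_clusters <- function(diff, cfg = group_contrast_config(), mask) {
  stopifnot(inherits(diff, "stat_map"), inherits(cfg, "group_contrast_config"))
  d <- dim(diff$data)
  check_mask(mask, d)
  vals <- diff$data
  if (any(!is.finite(vals[mask]))) {
    stop("difference map must be finite inside the mask", call. = FALSE)
  }
  z_crit <- if (cfg$two_sided) qnorm(1 - cfg$alpha / 2) else qnorm(1 - cfg$alpha)
  out <- array(0, dim = d)
  rows <- list()
  cid <- 0L
  for (sgn in c(1, -1)) {
    pass <- array(FALSE, dim = d)
    pass[mask] <- (sgn * vals[mask]) >= z_crit
    if (sgn == -1 && !cfg$two_sided) next
    lab <- label_components(pass, cfg$connectivity)
    if (lab$n == 0L) next
    sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
    for (comp in which(sizes >= cfg$min_cluster_vox)) {
      cid <- cid + 1L
      vox <- which(lab$labels == comp)
      coords <- arrayInd(vox, d)
      v <- vals[vox]
      pk <- which.max(sgn * v)
      out[vox] <- v
      rows[[cid]] <- data.frame(
        cluster_id = cid, size_vox = length(vox),
        peak_value = v[pk],
        peak_x = coords[pk, 1], peak_y = coords[pk, 2], peak_z = coords[pk, 3],
        centroid_x = mean(coords[, 1]), centroid_y = mean(coords[, 2]),
        centroid_z = mean(coords[, 3]),
        sign = if (sgn > 0) "positive" else "negative",
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else data.frame(
    cluster_id = integer(0), size_vox = integer(0), peak_value = numeric(0),
    peak_x = integer(0), peak_y = integer(0), peak_z = integer(0),
    centroid_x = numeric(0), centroid_y = numeric(0), centroid_z = numeric(0),
    sign = character(0), stringsAsFactors = FALSE)
  if (nrow(clusters)) {
    ord <- order(-clusters$size_vox, clusters$cluster_id)
    clusters <- clusters[ord, , drop = FALSE]
    clusters$cluster_id <- seq_len(nrow(clusters))
    rownames(clusters) <- NULL
  }
  out[!mask] <- NA_real_
  list(map = stat_map(out, kind = "diff_z", mask_applied = TRUE),
       clusters = clusters)
}

#' Per-subject ROI summary of a z-map
#'
#' For each labeled region, summarizes the voxels with that label whose z
#' value is at least `z_floor`: mean, sample SD (n-1) and voxel count. A
#' region with no qualifying voxel gets count 0 and missing mean/SD.
#'
#' @param zmap a [stat_map] of kind `"z"`.
#' @param rois a [roi_definition] on the same grid.
#' @param z_floor minimum z for a voxel to qualify (default 2.3).
#' @return data.frame with one row per region: `region`, `mean_z`, `sd_z`,
#'   `n_voxels`.
#' @export
roi_summary <- function(zmap, rois, z_floor = 2.3) {
  stopifnot(inherits(zmap, "stat_map"), inherits(rois, "roi_definition"))
  if (!identical(dim(zmap$data), dim(rois$label_map))) {
    stop("ROI label map is not on the z-map grid", call. = FALSE)
  }
  labs <- sort(as.integer(names(rois$names)))
  rows <- lapply(labs, function(lb) {
    v <- zmap$data[rois$label_map == lb]
    v <- v[!is.na(v) & v >= z_floor]
    data.frame(region = unname(rois$names[[as.character(lb)]]),
               mean_z = if (length(v)) mean(v) else NA_real_,
               sd_z = if (length(v) >= 2) stats::sd(v) else
                 if (length(v) == 1) 0 else NA_real_,
               n_voxels = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group summary of per-subject scalars
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of one
#' scalar per subject, as printed in group summary tables. Use
#' [format_report_value()] for the half-up 2-decimal report rounding.
#'
#' @param values numeric vector of per-subject values (n >= 1; SD needs
#'   n >= 2).
#' @param group group label.
#' @return an object of class `group_summary`: list with `group`, `values`,
#'   `mean`, `sd`, `n`.
#' @export
group_summary <- function(values, group = "") {
  values <- as.numeric(values)
  if (!length(values)) stop("group_summary requires n >= 1 values", call. = FALSE)
  structure(list(group = group, values = values, mean = mean(values),
                 sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
                 n = length(values)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary '%s'> n=%d mean=%s sd=%s\n", x$group, x$n,
              format_report_value(x$mean), format_report_value(x$sd)))
  invisible(x)
}

#' Format a value for report tables
#'
#' Rounds half away from zero to 2 decimals, the convention used in the
#' printed summary tables.
#'
#' @param x numeric.
#' @param digits decimals (default 2).
#' @return character vector.
#' @export
format_report_value <- function(x, digits = 2) {
  ifelse(is.na(x), "", formatC(round_half_up(x, digits), format = "f",
                               digits = digits))
}

#' Write report tables
#'
#' Writes `clusters.tsv` (one row per surviving cluster) and `roi_table.tsv`
#' mirroring the per-participant layout of published ROI summary tables:
#' within each group block, one row per subject with mean/SD/voxel-count
#' triplets per region, followed by group `Mean` and `SD` rows computed over
#' the subjects' per-ROI means with the sample (n-1) SD convention. Output is
#' deterministic: subjects ordered as given, regions in label order, values
#' printed with half-up 2-decimal rounding.
#'
#' @param clusters cluster data.frame from [threshold_clusters()].
#' @param roi_rows data.frame with columns `subject_id`, `group`, `region`,
#'   `mean_z`, `sd_z`, `n_voxels` (one row per subject x region, e.g. stacked
#'   [roi_summary()] outputs).
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
render_report <- function(clusters, roi_rows, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  cl_path <- file.path(out_dir, "clusters.tsv")
  cl <- clusters
  num <- vapply(cl, is.numeric, logical(1)) & names(cl) != "cluster_id" &
    !names(cl) %in% c("size_vox", "peak_x", "peak_y", "peak_z")
  cl[num] <- lapply(cl[num], function(v) format_report_value(v))
  write.table(cl, cl_path, sep = "\t", quote = FALSE, row.names = FALSE)

  roi_path <- file.path(out_dir, "roi_table.tsv")
  need <- c("subject_id", "group", "region", "mean_z", "sd_z", "n_voxels")
  missing <- setdiff(need, names(roi_rows))
  if (length(missing)) {
    stop("roi_rows missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  regions <- unique(roi_rows$region)
  groups <- unique(roi_rows$group)
  header <- c("participant",
              unlist(lapply(regions, function(r) paste0(r, c(" M", " SD", " V")))))
  lines <- list()
  fmt_row <- function(label, cells) paste(c(label, cells), collapse = "\t")
  for (g in groups) {
    gb <- roi_rows[roi_rows$group == g, , drop = FALSE]
    subjects <- unique(gb$subject_id)
    for (s in subjects) {
      cells <- unlist(lapply(regions, function(r) {
        row <- gb[gb$subject_id == s & gb$region == r, , drop = FALSE]
        if (!nrow(row)) return(c("", "", "0"))
        c(format_report_value(row$mean_z), format_report_value(row$sd_z),
          as.character(row$n_voxels))
      }))
      lines[[length(lines) + 1L]] <- fmt_row(s, cells)
    }
    # group Mean / SD rows over the subjects' per-ROI means
    for (stat in c("Mean", "SD")) {
      cells <- unlist(lapply(regions, function(r) {
        m <- gb$mean_z[gb$region == r]
        m <- m[!is.na(m)]
        gs <- if (length(m)) group_summary(m, g) else NULL
        val <- if (is.null(gs)) NA_real_ else if (stat == "Mean") gs$mean else gs$sd
        c(format_report_value(val), "", "")
      }))
      lines[[length(lines) + 1L]] <- fmt_row(paste(g, stat), cells)
    }
  }
  con <- file(roi_path, "w")
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(unlist(lines), con)
  close(con)
  invisible(c(cl_path, roi_path))
}
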