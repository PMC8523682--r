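make_z_like <- function(arr, mask) {
  v <- arr[mask]
  arr[mask] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  stat_map(arr, kind = "z", mask_applied = TRUE)
}

test_that("group mean map averages voxelwise and validates grids", {
  d <- c(6, 6, 4)
  mask <- array(TRUE, dim = d); mask[1, 1, ] <- FALSE
  set.seed(41)
  maps <- lapply(1:3, function(i) {
    arr <- array(rnorm(prod(d)), dim = d); arr[!mask] <- NA
    make_z_like(arr, mask)
  })
  gm <- group_mean_map(maps, mask)
  # elementwise naive oracle
  oracle <- (maps[[1]]$data + maps[[2]]$data + maps[[3]]$data) / 3
  expect_equal(gm$data[mask], oracle[mask], tolerance = 1e-12)
  expect_identical(gm$kind, "mean_z")
  # identical maps: mean equals any input; z and -z cancel
  expect_equal(group_mean_map(maps[c(1, 1)], mask)$data, maps[[1]]$data,
               tolerance = 1e-12)
  neg <- maps[[1]]; neg$data <- -neg$data
  zero <- group_mean_map(list(maps[[1]], neg), mask)
  expect_equal(zero$data[mask], rep(0, sum(mask)), tolerance = 1e-12)
  small <- stat_map(array(0, dim = c(2, 2, 2)), "z")
  expect_error(group_mean_map(list(maps[[1]], small), mask), "grids")
})

test_that("difference map supports naive and standardized modes", {
  d <- c(4, 4, 2)
  mask <- array(TRUE, dim = d)
  a <- stat_map(array(1.0, dim = d), "mean_z", mask_applied = TRUE)
  b <- stat_map(array(0.4, dim = d), "mean_z", mask_applied = TRUE)
  naive <- difference_map(a, b, group_contrast_config(diff_mode = "naive_diff"))
  expect_equal(unique(as.vector(naive$data)), 0.6, tolerance = 1e-12)
  std <- difference_map(a, b, group_contrast_config(), n_a = 3, n_b = 3)
  expect_equal(unique(as.vector(std$data)), 0.6 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(unique(as.vector(std$data)), 0.7348469, tolerance = 1e-6)
  # equal maps difference is zero
  expect_true(all(difference_map(a, a, group_contrast_config(), 3, 3)$data == 0))
  expect_error(difference_map(a, b, group_contrast_config()), "group sizes")
})

test_that("cluster thresholding retains only suprathreshold components above the size floor", {
  d <- c(12, 40, 10)
  mask <- array(TRUE, dim = d)
  arr <- array(0, dim = d)
  # a 40-voxel face-connected blob at +3 and a 10-voxel blob at +3
  arr[3:6, 3:7, 3:4] <- 3.0       # 4*5*2 = 40 voxels
  arr[9:10, 30:34, 8] <- 3.0      # 2*5   = 10 voxels
  diff <- stat_map(arr, kind = "diff_z", mask_applied = TRUE)
  res <- threshold_clusters(diff, group_contrast_config(), mask)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$size_vox, 40)
  expect_equal(res$clusters$sign, "positive")
  expect_equal(res$clusters$peak_value, 3.0)
  expect_equal(sum(res$map$data != 0, na.rm = TRUE), 40)

  # oppositely signed adjacent blobs stay separate clusters
  arr2 <- array(0, dim = d)
  arr2[2:6, 2:5, 3:4] <- 3.0      # 5*4*2 = 40
  arr2[7, 2:8, 3:8] <- -3.0       # 7*6 = 42, wait: 1*7*6 = 42
  arr2[7, 8, 8] <- 0              # trim to 41; still > 30
  diff2 <- stat_map(arr2, kind = "diff_z", mask_applied = TRUE)
  res2 <- threshold_clusters(diff2, group_contrast_config(), mask)
  expect_equal(nrow(res2$clusters), 2)
  expect_setequal(res2$clusters$sign, c("positive", "negative"))

  # all-zero map: empty table
  res0 <- threshold_clusters(stat_map(array(0, dim = d), "diff_z", TRUE),
                             group_contrast_config(), mask)
  expect_equal(nrow(res0$clusters), 0)
})

test_that("voxel threshold uses the normal critical value and connectivity matters", {
  d <- c(10, 10, 4)
  mask <- array(TRUE, dim = d)
  arr <- array(0, dim = d)
  arr[2:9, 2:9, 2] <- 1.95   # below two-sided z_crit 1.960
  below <- threshold_clusters(stat_map(arr, "diff_z", TRUE),
                              group_contrast_config(min_cluster_vox = 1), mask)
  expect_equal(nrow(below$clusters), 0)
  arr[2:9, 2:9, 2] <- 1.97   # above
  above <- threshold_clusters(stat_map(arr, "diff_z", TRUE),
                              group_contrast_config(min_cluster_vox = 1), mask)
  expect_equal(nrow(above$clusters), 1)
  # one-sided threshold qnorm(0.95) = 1.645 passes a 1.7 blob
  one <- threshold_clusters(stat_map(array(1.7 * (arr > 0), dim = d), "diff_z", TRUE),
                            group_contrast_config(two_sided = FALSE,
                                                  min_cluster_vox = 1), mask)
  expect_equal(nrow(one$clusters), 1)

  # diagonal pair: separate under faces, joined under corners
  arr2 <- array(0, dim = d)
  arr2[3, 3, 2] <- 3; arr2[4, 4, 3] <- 3
  cfgf <- group_contrast_config(min_cluster_vox = 1)
  cfgc <- group_contrast_config(min_cluster_vox = 1,
                                connectivity = "faces+edges+corners")
  expect_equal(nrow(threshold_clusters(stat_map(arr2, "diff_z", TRUE), cfgf, mask)$clusters), 2)
  expect_equal(nrow(threshold_clusters(stat_map(arr2, "diff_z", TRUE), cfgc, mask)$clusters), 1)

  # alpha = 1 with min cluster 1 returns every in-mask voxel
  set.seed(5)
  rnd <- array(rnorm(prod(d)), dim = d)
  all_cfg <- group_contrast_config(alpha = 1, min_cluster_vox = 1)
  res_all <- threshold_clusters(stat_map(rnd, "diff_z", TRUE), all_cfg, mask)
  expect_equal(sum(res_all$map$data != 0, na.rm = TRUE), sum(rnd != 0))

  # cluster sizes invariant under positive rescaling of values and threshold
  arr3 <- array(0, dim = d); arr3[2:8, 2:8, 2] <- 2.5
  r1 <- threshold_clusters(stat_map(arr3, "diff_z", TRUE),
                           group_contrast_config(min_cluster_vox = 10), mask)
  r2 <- threshold_clusters(stat_map(10 * arr3, "diff_z", TRUE),
                           group_contrast_config(min_cluster_vox = 10), mask)
  expect_equal(r1$clusters$size_vox, r2$clusters$size_vox)
})

test_that("roi_summary reports mean/SD/count over qualifying voxels", {
  d <- c(8, 8, 4)
  lab <- array(0L, dim = d)
  lab[1:5, 1, 1] <- 1L          # 5 voxels, known values
  lab[1:10 + 20] <- 2L          # 10 voxels all at 3.0
  lab[6:8, 8, 4] <- 3L          # below floor
  rois <- roi_definition(lab, c(`1` = "mixed region", `2` = "flat region",
                                `3` = "subthreshold region"))
  arr <- array(0, dim = d)
  arr[1:5, 1, 1] <- c(2.5, 3.5, 1.0, 4.0, 2.2)  # 1.0 fails the 2.3 floor
  arr[lab == 2L] <- 3.0
  arr[lab == 3L] <- 1.5
  zmap <- stat_map(arr, kind = "z", mask_applied = FALSE)
  got <- roi_summary(zmap, rois, z_floor = 2.3)
  mixed <- got[got$region == "mixed region", ]
  qual <- c(2.5, 3.5, 4.0)  # >= 2.3, enumerated by hand
  expect_equal(mixed$n_voxels, 3)
  expect_equal(mixed$mean_z, mean(qual), tolerance = 1e-12)
  expect_equal(mixed$sd_z, sd(qual), tolerance = 1e-12)
  flat <- got[got$region == "flat region", ]
  expect_equal(c(flat$mean_z, flat$sd_z, flat$n_voxels), c(3, 0, 10))
  sub <- got[got$region == "subthreshold region", ]
  expect_equal(sub$n_voxels, 0)
  expect_true(is.na(sub$mean_z) && is.na(sub$sd_z))
})

test_that("group_summary uses mean and sample SD with half-up report rounding", {
  # worked values from a published per-participant ROI table
  gs1 <- group_summary(c(2.62, 2.83, 3.00), "patient")
  expect_identical(format_report_value(gs1$mean), "2.82")
  expect_identical(format_report_value(gs1$sd), "0.19")
  gs2 <- group_summary(c(2.82, 2.84, 3.60), "patient")
  expect_identical(format_report_value(gs2$sd), "0.44")
  gs3 <- group_summary(c(3.66, 3.86, 3.12), "control")
  expect_identical(format_report_value(gs3$mean), "3.55")
  # constants have zero SD; single value has undefined SD
  expect_equal(group_summary(c(4, 4, 4))$sd, 0)
  expect_true(is.na(group_summary(5)$sd))
  expect_error(group_summary(numeric(0)), "n >= 1")
  # half-up rounding at the .005 boundary (banker's rounding would give 0.12)
  expect_identical(format_report_value(0.125), "0.13")
  expect_identical(format_report_value(-0.125), "-0.13")
})

test_that("sample (n-1) SD matches the printed value where population SD would not", {
  v <- c(2.62, 2.83, 3.00)
  sample_sd <- sd(v)
  population_sd <- sqrt(mean((v - mean(v))^2))
  expect_identical(format_report_value(sample_sd), "0.19")
  expect_identical(format_report_value(population_sd), "0.16")
})

test_that("render_report writes deterministic cluster and ROI tables", {
  roi_rows <- expand.grid(subject_id = sprintf("s%d", 1:6),
                          region = c("region A", "region B"),
                          stringsAsFactors = FALSE)
  roi_rows$group <- rep(rep(c("head-trauma", "no-head-trauma"), each = 3), 2)
  set.seed(2)
  roi_rows$mean_z <- round(runif(12, 2.4, 4), 2)
  roi_rows$sd_z <- round(runif(12, 0.1, 1), 2)
  roi_rows$n_voxels <- sample(10:500, 12)
  clusters <- data.frame(cluster_id = 1L, size_vox = 40L, peak_value = 3.21,
                         peak_x = 4L, peak_y = 5L, peak_z = 3L,
                         centroid_x = 4.5, centroid_y = 5.2, centroid_z = 3.1,
                         sign = "positive")
  dir <- withr::local_tempdir()
  files <- render_report(clusters, roi_rows, dir)
  expect_true(all(file.exists(files)))
  tab <- readLines(file.path(dir, "roi_table.tsv"))
  # 1 header + per group: 3 subjects + Mean + SD = 1 + 2*5
  expect_length(tab, 11)
  expect_match(tab[1], "region A M\tregion A SD\tregion A V")
  expect_match(tab[5], "^head-trauma Mean\t")
  # group Mean cell equals the half-up rounded mean of the subject means
  m <- mean(roi_rows$mean_z[roi_rows$group == "head-trauma" &
                              roi_rows$region == "region A"])
  expect_identical(strsplit(tab[5], "\t")[[1]][2], format_report_value(m))
  # byte-identical rerun
  dir2 <- withr::local_tempdir()
  render_report(clusters, roi_rows, dir2)
  expect_identical(readLines(file.path(dir2, "roi_table.tsv")), tab)
  expect_identical(readLines(file.path(dir2, "clusters.tsv")),
                   readLines(file.path(dir, "clusters.tsv")))
  # empty cluster table: header-only TSV
  dir3 <- withr::local_tempdir()
  empty <- clusters[0, ]
  render_report(empty, roi_rows, dir3)
  expect_length(readLines(file.path(dir3, "clusters.tsv")), 1)
})
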