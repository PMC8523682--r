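#' Remove a least-squares linear trend from a time series
#'
#' Fits intercept + slope over time index `0..T-1` by ordinary least squares
#' and returns the residual, which is exactly orthogonal to both the constant
#' and the linear term.
#'
#' @param ts numeric vector, length >= 3.
#' @return numeric vector of the same length.
#' @export
linear_detrend <- function(ts) {
  n <- length(ts)
  if (n < 3L) stop("linear_detrend requires at least 3 timepoints", call. = FALSE)
  if (!all(is.finite(ts))) stop("time series must be finite", call. = FALSE)
  t_idx <- seq_len(n) - 1
  tc <- t_idx - mean(t_idx)
  slope <- sum(tc * ts) / sum(tc^2)
  ts - mean(ts) - slope * tc
}

#' Build a Fourier nuisance design from physiological phases
#'
#' RETROICOR-style design matrix: an intercept plus `m` sine/cosine harmonic
#' pairs of the cardiac phase and of the respiratory phase, evaluated at each
#' volume's phase. Column order is
#' `[1, sin(k*phi_c), cos(k*phi_c), sin(k*phi_r), cos(k*phi_r)]` for
#' `k = 1..m`, so `K = 1 + 4*m` columns.
#'
#' @param physio a [physio_trace].
#' @param harmonics_m number of harmonics per signal (default 2).
#' @return a `T x K` numeric matrix with class `nuisance_design` and
#'   attribute `harmonics_m`; column names document the basis.
#' @export
build_retroicor_design <- function(physio, harmonics_m = 2) {
  stopifnot(inherits(physio, "physio_trace"))
  if (harmonics_m < 1) stop("harmonics_m must be >= 1", call. = FALSE)
  m <- as.integer(harmonics_m)
  n <- length(physio$cardiac_phase)
  cols <- list(intercept = rep(1, n))
  for (k in seq_len(m)) {
    cols[[paste0("card_sin", k)]] <- sin(k * physio$cardiac_phase)
    cols[[paste0("card_cos", k)]] <- cos(k * physio$cardiac_phase)
    cols[[paste0("resp_sin", k)]] <- sin(k * physio$resp_phase)
    cols[[paste0("resp_cos", k)]] <- cos(k * physio$resp_phase)
  }
  # order: intercept, then for k=1..m the cardiac pair, then the resp pair
  ord <- c("intercept",
           unlist(lapply(seq_len(m), function(k)
             paste0(c("card_sin", "card_cos", "resp_sin", "resp_cos"), k))))
  X <- do.call(cbind, cols[ord])
  structure(X, class = c("nuisance_design", class(X)), harmonics_m = m)
}

# Name the columns of X that are linearly dependent on earlier ones.
dependent_columns <- function(X) {
  dep <- character(0)
  r_prev <- 0L
  for (j in seq_len(ncol(X))) {
    r <- qr(X[, seq_len(j), drop = FALSE])$rank
    if (r == r_prev) dep <- c(dep, colnames(X)[j] %||% paste0("col", j))
    r_prev <- r
  }
  dep
}

#' Regress a nuisance design out of every in-mask voxel
#'
#' Each in-mask voxel time series is replaced by its ordinary least-squares
#' residual against the design; the residual is orthogonal to every design
#' column. Off-mask voxels are left untouched.
#'
#' @param img an [image_4d].
#' @param design `T x K` design matrix (e.g. from [build_retroicor_design()]),
#'   full column rank.
#' @param mask 3D logical array on the image grid.
#' @return an [image_4d] of residuals.
#' @export
regress_nuisance <- function(img, design, mask) {
  stopifnot(inherits(img, "image_4d"))
  d <- dim(img$data)
  check_mask(mask, d[1:3])
  design <- as.matrix(design)
  if (nrow(design) != d[4]) {
    stop("design has ", nrow(design), " rows but image has ", d[4],
         " timepoints", call. = FALSE)
  }
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    stop("rank-deficient nuisance design; dependent column(s): ",
         paste(dependent_columns(design), collapse = ", "), call. = FALSE)
  }
  mat <- matrix(aperm(img$data, c(4, 1, 2, 3)), nrow = d[4])
  idx <- which(as.vector(mask))
  mat[, idx] <- qr.resid(qr_x, mat[, idx, drop = FALSE])
  out <- aperm(array(mat, dim = d[c(4, 1, 2, 3)]), c(2, 3, 4, 1))
  image_4d(out, img$voxel_size_mm, img$tr_s)
}

#' Temporal filter configuration
#'
#' @param tr_s repetition time in seconds.
#' @param lowpass_hz cutoff frequency; fluctuations above it are removed
#'   (default 0.08 Hz). Must lie strictly below the Nyquist frequency
#'   `1/(2*tr_s)`.
#' @param hamming_enabled whether the 2D in-plane Hamming spatial filter is
#'   applied in pipeline compositions.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(tr_s, lowpass_hz = 0.08, hamming_enabled = TRUE) {
  if (!is.numeric(tr_s) || tr_s <= 0) stop("tr_s must be positive", call. = FALSE)
  nyquist <- 1 / (2 * tr_s)
  if (!is.numeric(lowpass_hz) || lowpass_hz <= 0 || lowpass_hz >= nyquist) {
    stop(sprintf("lowpass_hz must lie in (0, Nyquist = %.4g Hz)", nyquist),
         call. = FALSE)
  }
  structure(list(lowpass_hz = lowpass_hz, tr_s = tr_s,
                 hamming_enabled = isTRUE(hamming_enabled)),
            class = "filter_config")
}

# DFT-bin frequencies (Hz, absolute value) for T samples at spacing tr_s.
dft_bin_freqs <- function(n, tr_s) {
  j <- seq_len(n) - 1
  pmin(j, n - j) / (n * tr_s)
}

#' Low-pass filter voxel time series in the Fourier domain
#'
#' Removes all fluctuations above the cutoff by hard projection: the discrete
#' Fourier transform of each voxel series is masked to retain DC and every
#' bin with `|f| <= lowpass_hz`, all other bins are zeroed, and the series is
#' inverse-transformed. The projection is zero-phase and idempotent.
#'
#' @param img an [image_4d].
#' @param cfg a [filter_config] with `tr_s` matching the image.
#' @return filtered [image_4d].
#' @export
lowpass_temporal <- function(img, cfg) {
  stopifnot(inherits(img, "image_4d"), inherits(cfg, "filter_config"))
  d <- dim(img$data)
  n <- d[4]
  keep <- dft_bin_freqs(n, cfg$tr_s) <= cfg$lowpass_hz * (1 + 1e-12)
  mat <- matrix(img$data, nrow = prod(d[1:3]))
  ft <- mvfft(t(mat))
  ft[!keep, ] <- 0
  out <- Re(t(mvfft(ft, inverse = TRUE))) / n
  image_4d(array(out, dim = d), img$voxel_size_mm, img$tr_s)
}

# Separable DC-centered Hamming window values for one axis of length n:
# w(k) = 0.54 + 0.46*cos(pi*k/k_max), unity at DC (k = 0).
hamming_axis_window <- function(n) {
  k <- seq_len(n) - 1
  k <- ifelse(k > n / 2, k - n, k)
  k_max <- max(abs(k))
  if (k_max == 0) return(rep(1, n))
  0.54 + 0.46 * cos(pi * k / k_max)
}

#' 2D in-plane Hamming spatial filter
#'
#' For each axial slice and time point, the 2D spatial-frequency spectrum is
#' multiplied by a separable Hamming window (`0.54 + 0.46*cos(pi*k/k_max)`
#' along each in-plane frequency axis, unity at DC) and inverse-transformed.
#' This k-space apodization mildly smooths in-plane to improve functional
#' contrast-to-noise; the slice mean is preserved because the window is 1 at
#' DC. The filter acts on whole slices; the mask argument is accepted for
#' interface symmetry and validated but does not restrict the filter support.
#'
#' @param img an [image_4d] with in-plane dimensions >= 4.
#' @param mask optional 3D logical array on the image grid.
#' @return filtered [image_4d].
#' @export
hamming_spatial_2d <- function(img, mask = NULL) {
  stopifnot(inherits(img, "image_4d"))
  d <- dim(img$data)
  if (d[1] < 4L || d[2] < 4L) {
    stop("in-plane dimensions must be >= 4 for the Hamming filter", call. = FALSE)
  }
  if (!is.null(mask)) check_mask(mask, d[1:3])
  # The window is even in k along each axis, so the separable 2D filter can be
  # applied as two real 1D Fourier-domain filters, one per in-plane axis.
  filter_axis1 <- function(m, w) Re(mvfft(mvfft(m) * w, inverse = TRUE)) / nrow(m)
  out <- filter_axis1(matrix(img$data, nrow = d[1]), hamming_axis_window(d[1]))
  out <- array(out, dim = d)
  out <- aperm(out, c(2, 1, 3, 4))
  out <- filter_axis1(matrix(out, nrow = d[2]), hamming_axis_window(d[2]))
  out <- aperm(array(out, dim = d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  image_4d(out, img$voxel_size_mm, img$tr_s)
}

#' Run the preprocessing chain on one subject
#'
#' Fixed order: physiological nuisance regression, then 2D in-plane Hamming
#' spatial filtering (if enabled), then temporal low-pass filtering.
#'
#' @param img an [image_4d].
#' @param physio a [physio_trace] with one phase pair per volume.
#' @param mask 3D logical array.
#' @param cfg a [filter_config].
#' @param harmonics_m RETROICOR harmonics per physiological signal.
#' @return preprocessed [image_4d].
#' @export
preprocess_subject <- function(img, physio, mask, cfg, harmonics_m = 2) {
  if (length(physio$cardiac_phase) != dim(img$data)[4]) {
    stop("physio trace length does not match image timepoints", call. = FALSE)
  }
  design <- build_retroicor_design(physio, harmonics_m)
  out <- regress_nuisance(img, design, mask)
  if (cfg$hamming_enabled) out <- hamming_spatial_2d(out, mask)
  lowpass_temporal(out, cfg)
}
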