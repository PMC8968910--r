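# Fourier-spectrum directionality analysis of grayscale micrographs.
#
# The estimator mirrors the classical FFT-based directionality measurement:
# window the image, take the 2-D power spectrum, discard the DC neighborhood,
# and integrate spectral power over angular sectors. Spectral energy of a
# structure oriented at theta lies at theta +/- 90 in frequency space, so the
# sector angle is rotated back by 90 deg before binning. Orientation 0 deg is
# a transect across the image width (the x / column axis); angles grow toward
# the row axis and are folded into [0, 180).

#' Grayscale image container
#'
#' @param data Numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size_um Physical pixel size in micrometers per pixel.
#' @param bit_depth Nominal bit depth of the source (8 or 16); informational.
#' @return A `gray_image` (the matrix, with attributes).
#' @export
gray_image <- function(data, pixel_size_um = 1, bit_depth = 8) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  structure(data, pixel_size_um = pixel_size_um, bit_depth = bit_depth,
            class = c("gray_image", class(data)))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("gray_image %d x %d px, %.3g um/px, range [%.3g, %.3g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), min(x), max(x)))
  invisible(x)
}

pixel_size <- function(img) attr(img, "pixel_size_um") %||% 1

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

.fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n)
}

#' Directionality histogram from the 2-D Fourier power spectrum
#'
#' @param img A [gray_image()] (or plain matrix), at least 64 x 64 pixels.
#' @param bin_width Bin width in degrees; default 2 (90 bins over 0-180).
#' @param r_min Low-frequency exclusion radius in frequency pixels (default 3);
#'   removes illumination gradients and the windowing residue.
#' @param r_max High-frequency cutoff (default: Nyquist of the padded square).
#' @param on_constant `"error"` (default) to fail on a constant image, or
#'   `"uniform"` to return a flagged uniform histogram.
#' @return A `directionality_histogram`: data frame columns `bin_start_deg`,
#'   `bin_end_deg`, `amount` (normalized to sum 1), with attributes
#'   `bin_width` and `degenerate`.
#' @export
fourier_directionality <- function(img, bin_width = 2, r_min = 3,
                                   r_max = NULL,
                                   on_constant = c("error", "uniform")) {
  on_constant <- match.arg(on_constant)
  m <- unclass(img)
  if (nrow(m) < 64 || ncol(m) < 64)
    stop("image must be at least 64 x 64 pixels")
  nb <- round(180 / bin_width)
  if (abs(nb * bin_width - 180) > 1e-9) stop("bin_width must divide 180")
  if (max(m) == min(m)) {
    if (on_constant == "error") stop("constant image: no orientation content")
    return(.make_hist(rep(1 / nb, nb), bin_width, degenerate = TRUE))
  }
  m <- m - mean(m)
  m <- m * outer(.hann(nrow(m)), .hann(ncol(m)))
  N <- max(dim(m))
  if (nrow(m) < N || ncol(m) < N) {
    pad <- matrix(0, N, N)
    pad[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    m <- pad
  }
  P <- Mod(stats::fft(m))^2
  ky <- .fft_freqs(N) # rows
  kx <- .fft_freqs(N) # cols
  KY <- matrix(ky, N, N)
  KX <- matrix(kx, N, N, byrow = TRUE)
  r <- sqrt(KX^2 + KY^2)
  if (is.null(r_max)) r_max <- floor(N / 2) - 1
  keep <- r >= r_min & r <= r_max
  phi <- atan2(KY[keep], KX[keep]) * 180 / pi  # spectral angle
  theta <- (phi + 90) %% 180                    # structure orientation
  idx <- pmin(floor(theta / bin_width) + 1, nb)
  amounts <- vapply(seq_len(nb), function(b) sum(P[keep][idx == b]), 0)
  tot <- sum(amounts)
  if (tot <= 0) return(.make_hist(rep(1 / nb, nb), bin_width, degenerate = TRUE))
  .make_hist(amounts / tot, bin_width, degenerate = FALSE)
}

.make_hist <- function(amounts, bin_width, degenerate = FALSE) {
  nb <- length(amounts)
  structure(data.frame(bin_start_deg = (seq_len(nb) - 1) * bin_width,
                       bin_end_deg = seq_len(nb) * bin_width,
                       amount = amounts),
            bin_width = bin_width, degenerate = degenerate,
            class = c("directionality_histogram", "data.frame"))
}

hist_centers <- function(hist) (hist$bin_start_deg + hist$bin_end_deg) / 2

#' Fit a Gaussian peak to a directionality histogram
#'
#' Least-squares fit of `amount(theta) = baseline + amplitude *
#' exp(-(theta - center)^2 / (2 sd^2))`. The bins are circularly shifted so
#' the mode sits mid-range before fitting (orientation is periodic with
#' period 180), and the fitted center is mapped back to [0, 180).
#'
#' @param hist A `directionality_histogram`.
#' @return A `gaussian_fit`: `center` (deg), `sd` (deg), `amplitude`,
#'   `baseline`, `goodness` (R^2), `converged`.
#' @export
fit_gaussian <- function(hist) {
  y <- hist$amount
  nb <- length(y)
  bw <- attr(hist, "bin_width")
  centers <- hist_centers(hist)
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-16) { # flat histogram: nothing to fit
    return(structure(list(center = NA_real_, sd = NA_real_, amplitude = 0,
                          baseline = mean(y), goodness = 0,
                          converged = FALSE),
                     class = "gaussian_fit"))
  }
  mode_i <- which.max(y)
  shift <- (nb %/% 2) - mode_i            # bring mode to mid-range
  ys <- y[((seq_len(nb) - 1 - shift) %% nb) + 1]
  th <- centers                            # working coordinates after shift
  start <- list(b = min(ys), A = max(ys) - min(ys),
                c = centers[nb %/% 2], s = 5 * bw / 2)
  obj <- function(par) {
    mu <- par[1] + par[2] * exp(-(th - par[3])^2 / (2 * par[4]^2))
    sum((ys - mu)^2)
  }
  fit <- try(stats::optim(unlist(start), obj, method = "L-BFGS-B",
                          lower = c(-Inf, 0, 0, bw / 10),
                          upper = c(Inf, Inf, 180, 180)),
             silent = TRUE)
  if (inherits(fit, "try-error") || fit$convergence != 0) {
    return(structure(list(center = NA_real_, sd = NA_real_, amplitude = NA_real_,
                          baseline = NA_real_, goodness = 0, converged = FALSE),
                     class = "gaussian_fit"))
  }
  par <- fit$par
  r2 <- 1 - fit$value / sst
  center <- (par[3] - shift * bw) %% 180
  structure(list(center = center, sd = par[4], amplitude = par[2],
                 baseline = par[1], goodness = r2, converged = TRUE),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("gaussian_fit: center %.2f deg, sd %.2f deg, R2 %.3f\n",
                x$center, x$sd, x$goodness))
  else cat("gaussian_fit: did not converge / degenerate\n")
  invisible(x)
}

# Circular local maxima of a (smoothed) histogram; returns indices.
.circ_local_max <- function(y) {
  nb <- length(y)
  prev <- y[c(nb, seq_len(nb - 1))]
  nxt <- y[c(seq_len(nb)[-1], 1)]
  which(y > prev & y >= nxt)
}

.circ_smooth <- function(y, w = 5) {
  nb <- length(y)
  half <- w %/% 2
  yy <- c(y[(nb - half + 1):nb], y, y[1:half])
  stats::filter(yy, rep(1 / w, w))[(half + 1):(half + nb)]
}

#' Classify a histogram as anisotropic or isotropic
#'
#' Anisotropic means a single isolated orientation peak: the fitted amplitude
#' must exceed `k` times the fitted baseline, the fit must reach the goodness
#' cutoff, and no secondary local maximum (on a lightly smoothed histogram)
#' may rise above half the main peak height over baseline.
#'
#' @param fit A `gaussian_fit` for `hist`.
#' @param hist The `directionality_histogram` that was fitted.
#' @param k Amplitude-to-baseline ratio required (default 2).
#' @param goodness_min Minimum R^2 (default 0.5).
#' @param min_separation_deg Secondary maxima closer than this to the main
#'   peak are treated as the same peak (default 20).
#' @return An `anisotropy_call`: `is_anisotropic`, `peak_center` (deg, NA when
#'   isotropic).
#' @export
classify_anisotropy <- function(fit, hist, k = 2, goodness_min = 0.5,
                                min_separation_deg = 20) {
  iso <- structure(list(is_anisotropic = FALSE, peak_center = NA_real_),
                   class = "anisotropy_call")
  if (!isTRUE(fit$converged)) return(iso)
  base <- max(fit$baseline, 0)
  if (!(fit$amplitude > k * max(base, 1e-12))) return(iso)
  if (!(fit$goodness >= goodness_min)) return(iso)
  y <- as.numeric(.circ_smooth(hist$amount))
  centers <- hist_centers(hist)
  bw <- attr(hist, "bin_width")
  peaks <- .circ_local_max(y)
  if (length(peaks)) {
    main <- peaks[which.max(y[peaks])]
    h_main <- y[main] - base
    sep <- abs(centers[peaks] - centers[main])
    sep <- pmin(sep, 180 - sep) # circular distance
    rivals <- peaks[sep > min_separation_deg]
    if (any((y[rivals] - base) > 0.5 * h_main)) return(iso)
  }
  structure(list(is_anisotropic = TRUE, peak_center = fit$center),
            class = "anisotropy_call")
}

#' Otsu binarization of an f-actin (or any grayscale) image
#'
#' Thresholds at the gray level maximizing between-class variance over a
#' 256-level quantization of the intensity range; output is a 0/1 image that
#' feeds [fourier_directionality()] unchanged.
#'
#' @param img A [gray_image()].
#' @return A binary `gray_image` (values 0/1), same pixel size.
#' @export
binarize_actin <- function(img) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("single-valued image cannot be binarized")
  q <- pmin(floor((v - lo) / (hi - lo) * 256), 255)
  cnt <- tabulate(q + 1, nbins = 256)
  p <- cnt / sum(cnt)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  t_star <- which.max(sigma_b) - 1 # threshold: keep q > t_star
  b <- matrix(as.numeric(q > t_star), nrow(img), ncol(img))
  gray_image(b, pixel_size_um = pixel_size(img), bit_depth = 8)
}

#' Average directionality histograms over replicate gels
#'
#' Per-bin arithmetic mean, renormalized to sum 1.
#'
#' @param hists List of `directionality_histogram` with identical binning.
#' @return A `directionality_histogram`.
#' @export
average_histograms <- function(hists) {
  stopifnot(length(hists) >= 1)
  bw <- attr(hists[[1]], "bin_width")
  nb <- nrow(hists[[1]])
  for (h in hists)
    if (nrow(h) != nb || !isTRUE(all.equal(attr(h, "bin_width"), bw)))
      stop("histograms have mixed binning")
  m <- rowMeans(vapply(hists, function(h) h$amount, numeric(nb)))
  .make_hist(m / sum(m), bw)
}
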