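#' Luminance statistics of a greyscale image
#'
#' Mean luminance, RMS contrast (standard deviation of pixel values divided
#' by their mean) and skewness of the luminance histogram, all using
#' population (1/n) moments. A uniform image has contrast 0 and, by
#' convention, skewness 0 (the standardised third moment is 0/0 there).
#'
#' @param img numeric matrix of pixel values; values are used as given
#'   (typically in `[0, 1]`).
#' @return A one-row tibble: `mean`, `contrast`, `skewness`, `n_pixels`.
#' @export
#' @examples
#' image_stats(matrix(c(0, 0, 0, 1), 2))
image_stats <- function(img) {
  img <- as.matrix(img)
  if (!is.numeric(img) || !length(img)) abort("`img` must be a numeric matrix")
  if (anyNA(img)) abort("`img` contains missing values")
  v <- as.numeric(img)
  m <- mean(v)
  s2 <- mean((v - m)^2)
  s <- sqrt(s2)
  skew <- if (s == 0) 0 else mean((v - m)^3) / s^3
  if (m == 0)
    abort("image has zero mean luminance; contrast is undefined",
          class = "surfdecode_degenerate")
  tibble(mean = m, contrast = s / m, skewness = skew,
         n_pixels = length(v))
}

# internal: rotationally averaged log-amplitude spectrum of one image.
# Radius is the integer-rounded distance in cycles/image from DC, using the
# signed min-frequency convention of the DFT; the DC component (radius 0)
# is excluded.
radial_log_spectrum <- function(img) {
  img <- as.matrix(img)
  nr <- nrow(img); nc <- ncol(img)
  amp <- Mod(fft(img - mean(img)))
  fr <- ifelse(seq_len(nr) - 1 <= nr %/% 2, seq_len(nr) - 1,
               seq_len(nr) - 1 - nr)
  fc <- ifelse(seq_len(nc) - 1 <= nc %/% 2, seq_len(nc) - 1,
               seq_len(nc) - 1 - nc)
  rad <- round(sqrt(outer(fr^2, fc^2, `+`)))
  keep <- rad > 0 & rad <= min(nr, nc) %/% 2
  prof <- tapply(log10(amp[keep] + 1e-12), rad[keep], mean)
  tibble(frequency = as.integer(names(prof)),
         log_amplitude = as.numeric(prof))
}

#' Radial amplitude-spectrum profiles and their pairwise differences
#'
#' Each image's 2-D Fourier amplitude spectrum (DC removed) is log10
#' transformed and rotationally averaged into a 1-D profile over integer
#' spatial-frequency radii. The dissimilarity between two images is the root
#' mean square difference of their profiles; `spectrum_difference` returns
#' the mean over all unordered image pairs, quantifying how much a stimulus
#' set varies in spectral content.
#'
#' @param images a list of same-sized numeric matrices (>= 2 for
#'   differences).
#' @return `spectrum_profiles()`: a tibble with columns `image`, `frequency`,
#'   `log_amplitude`. `spectrum_difference()`: a list with the pairwise tibble
#'   (`image_1`, `image_2`, `rms_difference`) and the scalar
#'   `mean_difference`.
#' @export
spectrum_profiles <- function(images) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1)
  dims <- unique(lapply(images, dim))
  if (length(dims) > 1) abort("images must share dimensions")
  nm <- names(images) %||% as.character(seq_along(images))
  dplyr::bind_rows(lapply(seq_along(images), function(i) {
    dplyr::mutate(radial_log_spectrum(images[[i]]), image = nm[i],
                  .before = 1)
  }))
}

#' @rdname spectrum_profiles
#' @export
spectrum_difference <- function(images) {
  if (length(images) < 2)
    abort("need at least 2 images to compare spectra")
  prof <- spectrum_profiles(images)
  wide <- tidyr::pivot_wider(prof, names_from = "image",
                             values_from = "log_amplitude")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  nm <- colnames(mat)
  pairs <- utils::combn(seq_along(nm), 2)
  rms <- vapply(seq_len(ncol(pairs)), function(k) {
    d <- mat[, pairs[1, k]] - mat[, pairs[2, k]]
    sqrt(mean(d^2))
  }, numeric(1))
  pw <- tibble(image_1 = nm[pairs[1, ]], image_2 = nm[pairs[2, ]],
               rms_difference = rms)
  list(pairwise = pw, mean_difference = mean(rms))
}
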