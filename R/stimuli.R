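#' Render a synthetic surface stimulus
#'
#' Draws a diffusely shaded spherical object on a mid-grey background, then
#' applies one of four surface treatments at 5 strength levels:
#'
#' * `"matte"` — plain Lambertian shading (the `level` is ignored beyond
#'   bookkeeping); the baseline appearance.
#' * `"glossy"` — adds sparse, compact specular highlights whose intensity
#'   grows with `level`, producing the positive luminance-histogram skew
#'   characteristic of gloss.
#' * `"rough"` — multiplies the shading by band-limited surface-normal
#'   perturbations ("bumpiness") whose depth grows with `level`, raising RMS
#'   contrast and shifting spectral energy to higher frequencies.
#' * `"painted"` — multiplies the *reflectance* (not the shading) by a
#'   smooth random albedo texture of increasing strength, changing the
#'   luminance distribution without changing the implied relief.
#'
#' With `amplitude = 0` every treatment collapses to the uniform background,
#' which is useful as a degenerate test case. Pixel values are clipped to
#' `[0, 1]`.
#'
#' @param kind `"glossy"`, `"matte"`, `"rough"` or `"painted"`.
#' @param level integer strength level in 1..5.
#' @param size image side length in pixels.
#' @param amplitude overall strength of the rendered object against the
#'   0.5 background.
#' @param seed optional integer seed for the texture/highlight layout.
#' @return A `size` x `size` numeric matrix in `[0, 1]` with attributes
#'   `kind` and `level`.
#' @export
#' @examples
#' img <- generate_stimulus_image("glossy", level = 4, size = 64, seed = 1)
#' image_stats(img)
generate_stimulus_image <- function(kind = c("glossy", "matte", "rough",
                                             "painted"),
                                    level = 3, size = 128, amplitude = 1,
                                    seed = NULL) {
  kind <- match.arg(kind)
  if (!level %in% 1:5) abort("`level` must be an integer in 1..5")
  if (size < 8) abort("`size` must be at least 8 pixels")
  if (amplitude < 0) abort("`amplitude` must be >= 0")

  # normalised coordinates in [-1, 1] and the disk mask of the object
  u <- seq(-1, 1, length.out = size)
  X <- matrix(u, size, size)
  Y <- t(X)
  r2 <- X^2 + Y^2
  inside <- r2 < 0.8^2

  # Lambertian shading of a sphere of radius 0.8 lit from the upper left
  Z <- sqrt(pmax(0.8^2 - r2, 0))
  light <- c(-0.45, -0.45, 0.77)
  ndotl <- (X * light[1] + Y * light[2] + Z * light[3]) / 0.8
  shading <- pmax(ndotl, 0)

  with_seed_opt(seed, {
    strength <- level / 5
    reflectance <- matrix(0.8, size, size)
    if (kind == "painted") {
      reflectance <- reflectance *
        (1 + 0.5 * strength * smooth_field(size, wavelength = size / 6))
    }
    if (kind == "rough") {
      shading <- shading *
        pmax(1 + 0.9 * strength * smooth_field(size, wavelength = size / 16),
             0)
    }
    img <- matrix(0.5, size, size)
    img[inside] <- 0.5 + amplitude * (reflectance[inside] * shading[inside] -
                                        0.35)
    if (kind == "glossy") {
      n_spots <- 2 + level
      cx <- runif(n_spots, -0.5, 0.2)
      cy <- runif(n_spots, -0.5, 0.2)
      sigma <- 0.035
      for (s in seq_len(n_spots)) {
        spot <- exp(-((X - cx[s])^2 + (Y - cy[s])^2) / (2 * sigma^2))
        img <- img + amplitude * (0.4 + 0.25 * strength) * spot *
          as.numeric(inside)
      }
    }
  })
  img <- pmin(pmax(img, 0), 1)
  attr(img, "kind") <- kind
  attr(img, "level") <- as.integer(level)
  img
}

# internal: zero-mean, unit-SD band-limited random field (white noise
# blurred by a separable gaussian of the given wavelength)
smooth_field <- function(size, wavelength) {
  z <- matrix(rnorm(size^2), size, size)
  sd_px <- wavelength / 4
  half <- max(1L, ceiling(3 * sd_px))
  g <- dnorm(seq(-half, half), sd = sd_px)
  g <- g / sum(g)
  conv1 <- function(m) {
    apply(m, 2, function(col) {
      ext <- c(rev(col[seq_len(half)]), col, rev(col[size - half + seq_len(half)]))
      stats::filter(ext, g, sides = 2)[half + seq_len(size)]
    })
  }
  z <- conv1(z)
  z <- t(conv1(t(z)))
  (z - mean(z)) / sqrt(mean((z - mean(z))^2))
}

#' Render the stimulus set used in the decoding experiment
#'
#' One image per kind x level cell; the default grid covers the four surface
#' treatments at five strength levels.
#'
#' @param kinds,levels the grid to render.
#' @param size,amplitude passed to [generate_stimulus_image()].
#' @param seed master seed; each cell gets a derived sub-seed.
#' @return A named list of image matrices (`"<kind>_<level>"`).
#' @export
generate_stimulus_set <- function(kinds = c("glossy", "matte", "rough",
                                            "painted"),
                                  levels = 1:5, size = 128, amplitude = 1,
                                  seed = NULL) {
  grid <- expand.grid(level = levels, kind = kinds,
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  imgs <- lapply(seq_len(nrow(grid)), function(i) {
    generate_stimulus_image(grid$kind[i], grid$level[i], size, amplitude,
                            seed = seeds[i])
  })
  names(imgs) <- paste0(grid$kind, "_", grid$level)
  imgs
}

#' Write a stimulus image to a PNG file
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    abort("the 'png' package is required to write PNG files",
          class = "surfdecode_missing_package")
  png::writePNG(pmin(pmax(as.matrix(img), 0), 1), target = path)
  invisible(path)
}
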