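#' Noise model for synthetic screen data
#'
#' Bundles the stochastic components used by the simulators and the image
#' renderer. Well-level noise is additive Gaussian on the localization metric
#' (percent units) and multiplicative lognormal on luminescence readings
#' (`well_sd` is then the sdlog). Plate effects are multiplicative lognormal
#' factors shared by firefly and beta-galactosidase readings of a plate, so
#' that the beta-gal normalization cancels them.
#'
#' @param well_sd Additive Gaussian SD of the localization well metric
#'   (percent points), and sdlog of the lognormal luminescence noise.
#' @param plate_effect_sd sdlog of the per-plate multiplicative factor.
#' @param image_background Mean background intensity (camera counts) added to
#'   every pixel of rendered images.
#' @param image_noise_sd Per-pixel Gaussian SD (counts) of rendered images.
#' @param seed Integer seed; identical models give bit-identical output.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(well_sd = 1, seed = 42)
#' @export
noise_model <- function(well_sd = 1, plate_effect_sd = 0.1,
                        image_background = 0, image_noise_sd = 0,
                        seed = 1L) {
  for (nm in c("well_sd", "plate_effect_sd", "image_background",
               "image_noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("noise_model: '", nm, "' must be a single non-negative number",
           call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("noise_model: 'seed' must be an integer", call. = FALSE)
  structure(list(well_sd = well_sd, plate_effect_sd = plate_effect_sd,
                 image_background = image_background,
                 image_noise_sd = image_noise_sd, seed = seed),
            class = "noise_model")
}

# labels reserved for control/empty wells; everything else is library content
.control_labels <- c("siCTL", "siMARK4", "siYAP")
.non_library_labels <- c(.control_labels, "empty")

#' @export
print.noise_model <- function(x, ...) {
  cat("noise_model: well_sd=", x$well_sd,
      " plate_effect_sd=", x$plate_effect_sd,
      " image_background=", x$image_background,
      " image_noise_sd=", x$image_noise_sd,
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}
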