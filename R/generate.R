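#' Generate one animal's synthetic fluorescence field
#'
#' Draws a full-precision G-value field for one animal of a given stage.
#' The pixel model along the x (apex-to-root) axis is
#'
#' \deqn{pixel(x, y) = m + a (x - x_c) + \epsilon(x, y) - spot(x)}
#'
#' where the animal mean `m ~ N(mean_g, between_sd^2)` is the expected mean
#' over the measurement line, the realized slope `a ~ N(axial_slope,
#' slope_sd^2)` is centred on the line midpoint `x_c` so that it does not
#' shift the line mean, `epsilon` is i.i.d. Gaussian pixel noise whose SD is
#' derived from `within_sd` by variance decomposition (see
#' [pixel_noise_sd()]), and `spot(x)` is a field of top-hat dark-spot
#' depressions at Poisson-distributed x positions (full image height,
#' `spot_width` px wide, `spot_depth` deep), mean-compensated so the
#' expected line mean stays `m`. Fields are clipped to `[0, 255]`; 8-bit
#' quantization happens only at render time ([write_gvalue_image()]).
#'
#' @param params a [stage_params()] object.
#' @param animal_index index of the animal within its cohort (identifier).
#' @param seed integer seed; the same `(params, seed)` pair reproduces the
#'   field bit-exactly.
#' @param width image width in pixels; the measurement line spans it.
#' @param height image height in pixels.
#' @param spot_profile `"tophat"` (default) or `"gaussian"` spot shape.
#' @return a list with elements `image` (a [gvalue_image()], full precision)
#'   and `truth` (list: `animal_id`, `stage_label`, `animal_mean`,
#'   `realized_slope`, `spot_positions` (0-based x), `noise_sd`, `seed`).
#' @export
generate_animal_field <- function(params, animal_index, seed,
                                  width = 200L, height = 64L,
                                  spot_profile = c("tophat", "gaussian")) {
  stopifnot(inherits(params, "stage_params"))
  spot_profile <- match.arg(spot_profile)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 2L || height < 1L) stop("image dimensions must be positive (width >= 2)")
  noise_sd <- pixel_noise_sd(params, width)

  set.seed(as.integer(seed))
  animal_mean <- rnorm(1, params$mean_g, params$between_sd)
  if (animal_mean < 0 || animal_mean > 255) {
    stop("drawn animal mean outside [0, 255]; check mean_g/between_sd calibration")
  }
  a <- rnorm(1, params$axial_slope, params$slope_sd)

  x <- seq_len(width) - 1
  x_c <- (width - 1) / 2
  p_spot <- min(params$spot_rate * params$spot_width / 100, 1)
  baseline <- animal_mean + p_spot * params$spot_depth + a * (x - x_c)

  n_spots <- if (params$spot_rate > 0) rpois(1, params$spot_rate * width / 100) else 0L
  spot_positions <- integer(0)
  spot_drop <- numeric(width)
  if (n_spots > 0) {
    spot_positions <- sort(sample.int(width, n_spots, replace = TRUE) - 1L)
    half <- (params$spot_width - 1) / 2
    for (pos in spot_positions) {
      if (spot_profile == "tophat") {
        lo <- max(0L, as.integer(ceiling(pos - half)))
        hi <- min(width - 1L, as.integer(floor(pos + half)))
        idx <- (lo:hi) + 1L
        spot_drop[idx] <- pmax(spot_drop[idx], params$spot_depth)
      } else {
        prof <- params$spot_depth * exp(-((x - pos)^2) / (2 * (params$spot_width / 2)^2))
        spot_drop <- pmax(spot_drop, prof)
      }
    }
  }

  field <- matrix(rnorm(height * width, 0, noise_sd), nrow = height)
  field <- sweep(field, 2L, baseline - spot_drop, `+`)
  field <- pmin(pmax(field, 0), 255)

  truth <- list(
    animal_id = sprintf("%s_%02d", params$stage_label, animal_index),
    stage_label = params$stage_label,
    animal_mean = animal_mean,
    realized_slope = a,
    spot_positions = as.integer(spot_positions),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  list(image = gvalue_image(field), truth = truth)
}

#' Quantize a G-value field to 8 bits
#'
#' @param image a [gvalue_image()].
#' @return integer matrix of rounded G-values in `[0, 255]`.
#' @export
quantize_gvalues <- function(image) {
  stopifnot(inherits(image, "gvalue_image"))
  m <- round(image$pixels)
  storage.mode(m) <- "integer"
  pmin(pmax(m, 0L), 255L)
}

#' Render a G-value field to an RGB fluorescence image file
#'
#' The quantized field goes into the green channel; red and blue are set to
#' a fixed low backdrop, mimicking the pale-green emission recorded by the
#' visualization device.
#'
#' @param image a [gvalue_image()].
#' @param path output path; format chosen by extension (`.png` or `.tif`).
#' @param backdrop red/blue channel value (0-255), default 8.
#' @return `path`, invisibly.
#' @export
write_gvalue_image <- function(image, path, backdrop = 8L) {
  g <- quantize_gvalues(image)
  arr <- array(backdrop / 255, dim = c(nrow(g), ncol(g), 3L))
  arr[, , 2L] <- g / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, where = path, bits.per.sample = 8L)
  } else {
    stop("unsupported image format: .", ext, " (use png or tiff)")
  }
  invisible(path)
}

#' Generate a full synthetic cohort on disk
#'
#' Writes one RGB image per animal plus a single machine-readable ground
#' truth file (`truth.json`) per cohort. Per-animal seeds are derived
#' deterministically from the root seed, so the same `(config, seed)` pair
#' regenerates byte-identical truth metadata.
#'
#' @param config cohort configuration as returned by [read_stage_config()],
#'   [rat_stage_presets()] or [human_site_presets()]; it must contain at
#'   least one stage.
#' @param seed integer root seed.
#' @param dir output directory for images and `truth.json`.
#' @param force overwrite an existing non-empty cohort directory.
#' @param format `"png"` (default) or `"tiff"`.
#' @param spot_profile passed to [generate_animal_field()].
#' @return a data frame manifest (one row per animal: `file`, truth fields),
#'   invisibly.
#' @export
generate_cohort <- function(config, seed, dir, force = FALSE,
                            format = c("png", "tiff"),
                            spot_profile = "tophat") {
  format <- match.arg(format)
  if (is.null(config$stages) || length(config$stages) == 0) {
    stop("no stages configured")
  }
  if (dir.exists(dir) && length(list.files(dir)) > 0) {
    if (!force) stop("cohort directory ", dir, " exists and is not empty; use force = TRUE")
    unlink(file.path(dir, list.files(dir)), recursive = TRUE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  n_total <- sum(vapply(config$stages, function(p) p$n_animals, integer(1)))
  set.seed(as.integer(seed))
  animal_seeds <- sample.int(.Machine$integer.max - 1L, n_total)

  ext <- if (format == "png") "png" else "tif"
  records <- list()
  k <- 0L
  for (lab in names(config$stages)) {
    params <- config$stages[[lab]]
    for (i in seq_len(params$n_animals)) {
      k <- k + 1L
      gen <- generate_animal_field(
        params, i, animal_seeds[k],
        width = config$n_points, height = config$height,
        spot_profile = spot_profile
      )
      file <- sprintf("%s_%02d.%s", lab, i, ext)
      write_gvalue_image(gen$image, file.path(dir, file))
      records[[k]] <- c(list(file = file), gen$truth)
    }
  }
  jsonlite::write_json(
    list(model = config$model, seed = as.integer(seed),
         n_points = config$n_points, height = config$height,
         animals = records),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest <- do.call(rbind, lapply(records, function(r) {
    data.frame(file = r$file, animal_id = r$animal_id,
               stage_label = r$stage_label, animal_mean = r$animal_mean,
               realized_slope = r$realized_slope, noise_sd = r$noise_sd,
               n_spots = length(r$spot_positions), seed = r$seed,
               stringsAsFactors = FALSE)
  }))
  invisible(manifest)
}
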