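# Synthetic micrograph generation with exact per-object ground truth.
# Every object is a radial shape (r as a function of polar angle), so the
# "object + clearance" test used for non-overlap placement is exact.

shape_params <- function(shape_class, area_px) {
  # returns a radial-function description with analytic area -> base radius
  switch(shape_class,
    round = list(amp = 0, k = 0, phase = 0, q = 1, rot = 0,
                 r0 = sqrt(area_px / pi)),
    branched = {
      amp <- 0.5
      k <- sample(4:6, 1)
      list(amp = amp, k = k, phase = stats::runif(1, 0, 2 * pi), q = 1, rot = 0,
           r0 = sqrt(area_px / (pi * (1 + amp^2 / 2))))
    },
    spread = {
      amp <- 0.12
      list(amp = amp, k = 3, phase = stats::runif(1, 0, 2 * pi),
           q = stats::runif(1, 1, 1.15), rot = stats::runif(1, 0, pi),
           r0 = sqrt(area_px / (pi * (1 + amp^2 / 2))))
    },
    stop_voltphen(sprintf("unknown shape class `%s`.", shape_class))
  )
}

# mask of a radial shape on a local grid; `extra` grows the radius (clearance)
rasterize_radial <- function(sp, extra = 0) {
  rmax <- sp$r0 * (1 + sp$amp) * sp$q + extra
  half <- ceiling(rmax)
  g <- seq(-half, half)
  dx <- matrix(g, nrow = length(g), ncol = length(g), byrow = TRUE)
  dy <- matrix(g, nrow = length(g), ncol = length(g))
  if (sp$q != 1) {
    xr <- cos(sp$rot) * dx + sin(sp$rot) * dy
    yr <- -sin(sp$rot) * dx + cos(sp$rot) * dy
    dist <- sqrt((xr / sp$q)^2 + (yr * sp$q)^2)
  } else {
    dist <- sqrt(dx^2 + dy^2)
  }
  theta <- atan2(dy, dx)
  rtheta <- sp$r0 * (1 + sp$amp * cos(sp$k * theta + sp$phase))
  list(mask = dist <= rtheta + extra, half = half)
}

#' Synthesize a micrograph-like image with exact ground truth
#'
#' Places non-overlapping cell-shaped objects (disks for round cells, star
#' polygons with radial arms for branched cells, larger low-eccentricity
#' blobs for spread cells) on a dark background, recording each object's
#' exact pixel area and type label. Per-cell target areas are drawn
#' log-normally around each profile's mean area. Foreground/background
#' contrast is set before optional Gaussian blur and noise, and ground truth
#' always refers to the pre-noise label mask.
#'
#' @param profiles Profiles tibble (see [default_cell_profiles()]).
#' @param counts Number of cells per type: a single number recycled over the
#'   profiles, or a vector named by cell type.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size Physical pixel size (um/px), > 0.
#' @param seed Integer seed; identical inputs give identical images.
#' @param background,foreground Background and foreground intensities; the
#'   contrast margin `foreground - background` must be positive.
#' @param noise_sd Intensity noise s.d. added after rasterisation (0 = none).
#' @param blur_sigma Gaussian blur sigma in px (0 = none).
#' @param min_gap Minimum clearance between objects (px).
#' @param max_tries Placement attempts per object before giving up.
#' @return An object of class `synthetic_image`: a list with `pixels`
#'   (intensity matrix), `truth_mask` (integer label matrix), `truth_areas`
#'   (tibble: `object`, `cell_type`, `pixels`, `area_um2`), `pixel_size`,
#'   `seed`.
#' @examples
#' img <- synthesize_micrograph(default_cell_profiles(), counts = 3,
#'                              image_shape = c(256, 256), pixel_size = 1, seed = 7)
#' img$truth_areas
#' @export
synthesize_micrograph <- function(profiles, counts, image_shape = c(768, 768),
                                  pixel_size = 0.5, seed = 1L,
                                  background = 0.1, foreground = 0.9,
                                  noise_sd = 0, blur_sigma = 0,
                                  min_gap = 2, max_tries = 500) {
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(blur_sigma, "blur_sigma", min = 0)
  if (foreground <= background) {
    stop_voltphen("`foreground` intensity must exceed `background`.")
  }
  if (length(counts) == 1 && is.null(names(counts))) {
    counts <- setNames(rep(counts, nrow(profiles)), profiles$name)
  }
  if (is.null(names(counts)) || !all(names(counts) %in% profiles$name)) {
    stop_voltphen("`counts` must be named by cell type (or be a single number).")
  }
  counts <- counts[counts > 0]

  nr <- image_shape[1]
  nc <- image_shape[2]
  expected_px <- sum(map_dbl(names(counts), function(ty) {
    counts[[ty]] * profiles$mean_area_um2[profiles$name == ty]
  })) / pixel_size^2
  if (expected_px > 0.45 * nr * nc) {
    stop_voltphen(sprintf(
      "requested objects would fill ~%.0f%% of the image; enlarge image_shape or reduce counts.",
      100 * expected_px / (nr * nc)
    ))
  }

  truth <- matrix(0L, nr, nc)
  rows <- list()

  withr::with_seed(as.integer(seed), {
    # place the largest types first: improves packing success
    type_order <- profiles$name[order(-profiles$mean_area_um2)]
    type_order <- type_order[type_order %in% names(counts)]
    obj <- 0L
    for (ty in type_order) {
      prof <- profiles[profiles$name == ty, ]
      for (ci in seq_len(counts[[ty]])) {
        target_um2 <- if (prof$area_cv == 0) {
          prof$mean_area_um2
        } else {
          p <- lognormal_params(prof$mean_area_um2, prof$area_cv)
          rlnorm(1, p$meanlog, p$sdlog)
        }
        sp <- shape_params(prof$shape_class, target_um2 / pixel_size^2)
        shp <- rasterize_radial(sp, extra = 0)
        gap <- rasterize_radial(sp, extra = min_gap)
        half <- gap$half
        if (2 * half + 1 >= min(nr, nc)) {
          stop_voltphen(sprintf(
            "a %s object (radius ~%d px) does not fit in a %dx%d image.",
            ty, half, nr, nc
          ))
        }
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          cy <- sample.int(nr - 2 * half, 1) + half
          cx <- sample.int(nc - 2 * half, 1) + half
          ry <- (cy - half):(cy + half)
          rx <- (cx - half):(cx + half)
          if (any(truth[ry, rx][gap$mask] != 0L)) next
          obj <- obj + 1L
          core <- shp$mask
          pad <- half - shp$half
          if (pad > 0) { # align core mask inside the (larger) gap window
            ry2 <- (cy - shp$half):(cy + shp$half)
            rx2 <- (cx - shp$half):(cx + shp$half)
          } else {
            ry2 <- ry; rx2 <- rx
          }
          block <- truth[ry2, rx2]
          block[core] <- obj
          truth[ry2, rx2] <- block
          rows[[obj]] <- tibble(
            object = obj, cell_type = ty,
            pixels = sum(core), area_um2 = sum(core) * pixel_size^2
          )
          placed <- TRUE
          break
        }
        if (!placed) {
          stop_voltphen(sprintf(
            "could not place %s object %d without overlap after %d tries; enlarge the image or reduce counts.",
            ty, ci, max_tries
          ))
        }
      }
    }

    pixels <- matrix(background, nr, nc)
    pixels[truth > 0L] <- foreground
    if (blur_sigma > 0) {
      pixels <- EBImage::imageData(EBImage::gblur(EBImage::Image(pixels), sigma = blur_sigma))
    }
    if (noise_sd > 0) {
      pixels <- pixels + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    }

    structure(
      list(
        pixels = pixels,
        truth_mask = truth,
        truth_areas = if (length(rows)) bind_rows(rows) else
          tibble(object = integer(), cell_type = character(),
                 pixels = integer(), area_um2 = double()),
        pixel_size = pixel_size,
        seed = as.integer(seed)
      ),
      class = "synthetic_image"
    )
  })
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf(
    "<synthetic_image> %d x %d px at %g um/px, %d objects (%s), seed %d\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size,
    nrow(x$truth_areas),
    paste(sprintf("%s=%d", names(table(x$truth_areas$cell_type)),
                  as.integer(table(x$truth_areas$cell_type))), collapse = ", "),
    x$seed
  ))
  invisible(x)
}

#' Write a synthetic micrograph as PNG plus a ground-truth sidecar
#'
#' Intensities are clamped to `[0, 1]` and written as a greyscale PNG; the
#' per-object truth areas and labels go to `<path>.truth.json`.
#'
#' @param image A `synthetic_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_micrograph_png <- function(image, path) {
  px <- pmin(pmax(image$pixels, 0), 1)
  png::writePNG(px, target = path)
  jsonlite::write_json(
    list(
      pixel_size_um = image$pixel_size,
      seed = image$seed,
      objects = image$truth_areas
    ),
    path = paste0(path, ".truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
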