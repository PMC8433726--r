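# Imaging arm: threshold segmentation and per-cell area measurement — the
# independent verification of the electrical size ordering.

# EBImage's bwlabel is 4-connected; merge labels that touch diagonally to get
# the 8-connected components this pipeline specifies.
label_8connected <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  nr <- nrow(lab)
  nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]  # down-left diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  edges <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(edges) == 0) return(lab)
  g <- igraph::make_empty_graph(n = nlab, directed = FALSE)
  g <- igraph::add_edges(g, t(unique(edges)))
  memb <- igraph::components(g)$membership
  new_id <- match(memb, sort(unique(memb)))
  out <- lab
  out[lab > 0L] <- new_id[lab[lab > 0L]]
  out
}

#' Segment cells in a micrograph by global thresholding
#'
#' Foreground by a global threshold (Otsu's method by default, or a fixed
#' value), objects by 8-connected component labelling, with components
#' smaller than `min_object_size` pixels removed and the remaining labels
#' renumbered contiguously from 1.
#'
#' @param image A numeric intensity matrix, or a `synthetic_image` from
#'   [synthesize_micrograph()] (its `pixels` are used).
#' @param threshold_policy `"otsu"` or `"fixed"`.
#' @param threshold_value Threshold intensity when `threshold_policy = "fixed"`.
#' @param min_object_size Minimum object area in pixels.
#' @return An object of class `segmentation_result`: `label_mask` (integer
#'   matrix), `areas` (tibble: `object`, `pixels`), `n_objects`, `threshold`,
#'   `settings`.
#' @examples
#' img <- synthesize_micrograph(default_cell_profiles(), counts = 2,
#'                              image_shape = c(256, 256), pixel_size = 1, seed = 2)
#' seg <- segment_cells(img)
#' seg$n_objects
#' @export
segment_cells <- function(image, threshold_policy = c("otsu", "fixed"),
                          threshold_value = NULL, min_object_size = 30) {
  threshold_policy <- match.arg(threshold_policy)
  check_number(min_object_size, "min_object_size", min = 0)
  px <- if (inherits(image, "synthetic_image")) image$pixels else image
  if (!is.matrix(px) || !is.numeric(px)) {
    stop_voltphen("`image` must be a numeric matrix (or a synthetic_image).")
  }

  if (threshold_policy == "otsu") {
    rng <- range(px)
    if (rng[1] == rng[2]) {
      stop_voltphen("blank image (single intensity): Otsu thresholding is undefined; use a fixed threshold.")
    }
    thr <- EBImage::otsu(EBImage::Image(px), range = rng)
  } else {
    if (is.null(threshold_value)) {
      stop_voltphen("`threshold_value` is required with threshold_policy = \"fixed\".")
    }
    thr <- threshold_value
  }

  mask <- px > thr
  if (!any(mask)) {
    lab <- matrix(0L, nrow(px), ncol(px))
  } else {
    lab <- label_8connected(mask)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_size)
    relabel <- integer(length(sizes))
    relabel[keep] <- seq_along(keep)
    lab[lab > 0L] <- relabel[lab[lab > 0L]]
  }
  sizes <- if (max(lab) > 0) tabulate(lab[lab > 0L]) else integer(0)

  structure(
    list(
      label_mask = lab,
      areas = tibble(object = seq_along(sizes), pixels = sizes),
      n_objects = length(sizes),
      threshold = as.numeric(thr),
      settings = list(
        threshold_policy = threshold_policy,
        min_object_size = min_object_size
      )
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d objects, threshold %.4g (%s), min size %g px\n",
    x$n_objects, x$threshold, x$settings$threshold_policy,
    x$settings$min_object_size
  ))
  invisible(x)
}

#' Convert segmented object areas to physical units
#'
#' @param seg A [segment_cells()] result.
#' @param pixel_size Pixel size (um/px), > 0.
#' @return A tibble: `object`, `pixels`, `area_um2 = pixels * pixel_size^2`.
#' @export
measure_areas <- function(seg, pixel_size = 1) {
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  mutate(seg$areas, area_um2 = .data$pixels * pixel_size^2)
}

#' Assign segmented objects their ground-truth cell type
#'
#' Maps each segmented object to the truth object it overlaps most, and
#' takes that object's type label. Objects with no truth overlap get `NA`.
#'
#' @param seg A [segment_cells()] result.
#' @param image The `synthetic_image` the segmentation came from.
#' @return [measure_areas()] output (at the image's pixel size) plus a
#'   `cell_type` column.
#' @export
label_objects_by_truth <- function(seg, image) {
  if (!inherits(image, "synthetic_image")) {
    stop_voltphen("`image` must be a synthetic_image with a truth mask.")
  }
  areas <- measure_areas(seg, image$pixel_size)
  fg <- seg$label_mask > 0L
  overlap <- tibble(
    object = seg$label_mask[fg],
    truth = image$truth_mask[fg]
  )
  best <- overlap |>
    filter(.data$truth > 0L) |>
    count(.data$object, .data$truth) |>
    group_by(.data$object) |>
    slice_max(.data$n, n = 1, with_ties = FALSE) |>
    ungroup() |>
    left_join(
      select(image$truth_areas, truth = "object", "cell_type"),
      by = "truth"
    ) |>
    select("object", "cell_type")
  left_join(areas, best, by = "object")
}

#' Compare mean cell areas across types
#'
#' Per-type mean area, SEM and n, ordered by descending mean, with pairwise
#' two-tailed Student's t-tests (pooled variance, shared with the
#' electrical arm).
#'
#' @param areas A tibble with columns `cell_type` and `area_um2` (>= 2 cells
#'   per type), or a named list of per-type area vectors.
#' @param alpha Significance level.
#' @return An object of class `area_comparison`: `summary` tibble
#'   (`cell_type`, `mean_um2`, `sem_um2`, `n`, `rank`), `pairwise` tibble of
#'   t-test results, `ordering` (types by descending mean), `alpha`.
#' @export
compare_type_areas <- function(areas, alpha = 0.05) {
  if (is.list(areas) && !is.data.frame(areas)) {
    areas <- bind_rows(imap(areas, ~ tibble(cell_type = .y, area_um2 = .x)))
  }
  if (!all(c("cell_type", "area_um2") %in% names(areas))) {
    stop_voltphen("`areas` needs columns `cell_type` and `area_um2`.")
  }
  counts <- table(areas$cell_type)
  if (any(counts < 2)) {
    stop_voltphen(sprintf(
      "every type needs >= 2 cells (short: %s).",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  summ <- areas |>
    group_by(.data$cell_type) |>
    summarise(
      mean_um2 = mean(.data$area_um2),
      sem_um2 = sd(.data$area_um2) / sqrt(n()),
      n = n(),
      .groups = "drop"
    ) |>
    arrange(desc(.data$mean_um2), .data$cell_type) |>
    mutate(rank = row_number())

  types <- summ$cell_type
  pairs <- utils::combn(types, 2, simplify = FALSE)
  pairwise <- bind_rows(map(pairs, function(p) {
    res <- student_t_two_tailed(
      areas$area_um2[areas$cell_type == p[1]],
      areas$area_um2[areas$cell_type == p[2]],
      alpha = alpha
    )
    mutate(res, type_a = p[1], type_b = p[2], .before = 1)
  }))

  structure(
    list(summary = summ, pairwise = pairwise, ordering = types, alpha = alpha),
    class = "area_comparison"
  )
}

#' @export
print.area_comparison <- function(x, ...) {
  cat("<area_comparison> ordering:", paste(x$ordering, collapse = " > "), "\n")
  print(x$summary)
  invisible(x)
}
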