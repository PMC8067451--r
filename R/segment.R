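#' Segment a canopy image into projected canopy size
#'
#' Thresholds a top-down intensity image into plant (foreground) and
#' background, removes connected components smaller than `min_object_px`
#' (8-connectivity), and converts the foreground pixel count to area:
#' `total_area = foreground_pixels * pixel_scale^2`, `pcs_per_plant =
#' total_area / n_plants`. This is the digital replacement for interactive
#' area measurement: plants are not individually delineated; per-plant PCS
#' is the group mean.
#'
#' @param image A [canopy_image()].
#' @param method `"otsu"` (default; Otsu's threshold on the intensity
#'   histogram, via [EBImage::otsu()]) or `"fixed"`.
#' @param fixed_threshold Intensity threshold when `method = "fixed"`;
#'   pixels strictly above it are foreground.
#' @param min_object_px Minimum connected-component size kept (default 25
#'   px, removes speckle noise).
#' @param n_plants Number of plants in the frame; defaults to the image
#'   metadata, else 9.
#' @return An object of class `canopy_segmentation`: `mask` (logical
#'   matrix), `foreground_pixels`, `total_area_cm2`, `pcs_per_plant_cm2`,
#'   `threshold_used`, `method`, `n_plants`, `pixel_scale` and the image
#'   metadata. `tidy()` turns it into a one-row tibble.
#' @section Errors:
#' A blank image (zero intensity range) under Otsu raises a
#' "no bimodality" error rather than silently returning zero area.
#' @export
segment_canopy <- function(image, method = c("otsu", "fixed"),
                           fixed_threshold = NULL, min_object_px = 25L,
                           n_plants = NULL) {
  if (!inherits(image, "canopy_image")) abort("`image` must be a canopy_image")
  method <- match.arg(method)
  px <- image$pixels
  n_plants <- n_plants %||% image$meta$n_plants %||% 9L

  if (method == "otsu") {
    if (diff(range(px)) == 0) {
      abort("no bimodality: image has zero intensity range")
    }
    thr <- EBImage::otsu(EBImage::Image(pmin(pmax(px, 0), 1)))
  } else {
    if (is.null(fixed_threshold)) {
      abort("`fixed_threshold` is required when method = \"fixed\"")
    }
    thr <- fixed_threshold
  }

  mask <- px > thr
  if (min_object_px > 0 && any(mask)) {
    mask <- drop_small_objects(mask, min_object_px)
  }

  fg <- sum(mask)
  total_area <- fg * image$pixel_scale^2
  structure(
    list(
      mask = mask,
      foreground_pixels = fg,
      total_area_cm2 = total_area,
      pcs_per_plant_cm2 = total_area / n_plants,
      threshold_used = as.numeric(thr),
      method = method,
      n_plants = n_plants,
      pixel_scale = image$pixel_scale,
      capture_day = image$capture_day,
      meta = image$meta
    ),
    class = "canopy_segmentation"
  )
}

## remove 8-connected components below min_px. EBImage::bwlabel() labels
## 4-connected components; diagonal-adjacent labels are merged with a small
## union-find over the label adjacency pairs to obtain 8-connectivity.
drop_small_objects <- function(mask, min_px) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab == 0L) return(mask)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) unite(pairs[k, 1], pairs[k, 2])
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  sizes <- tapply(tabulate(lab[lab > 0], nbins = nlab), root, sum)
  keep_roots <- as.integer(names(sizes))[sizes >= min_px]
  keep <- root[lab[lab > 0]] %in% keep_roots
  out <- mask
  out[lab > 0] <- keep
  out
}

#' @export
print.canopy_segmentation <- function(x, ...) {
  cat(sprintf(
    "<canopy_segmentation> %s threshold %.4g: %d fg px, %.1f cm^2 total, %.1f cm^2/plant\n",
    x$method, x$threshold_used, x$foreground_pixels, x$total_area_cm2,
    x$pcs_per_plant_cm2))
  invisible(x)
}

#' @rdname segment_canopy
#' @param x A `canopy_segmentation`.
#' @param ... Unused.
#' @export
tidy.canopy_segmentation <- function(x, ...) {
  tibble::tibble(
    species = x$meta$species %||% NA_character_,
    ppfd = x$meta$ppfd %||% NA_real_,
    block = x$meta$block %||% NA_integer_,
    day = x$capture_day,
    foreground_pixels = x$foreground_pixels,
    total_area_cm2 = x$total_area_cm2,
    pcs_cm2_per_plant = x$pcs_per_plant_cm2,
    threshold_used = x$threshold_used,
    method = x$method,
    n_plants = x$n_plants
  )
}

#' Segment every image in a manifest
#'
#' @param manifest Tibble with columns `path`, `species`, `ppfd`, `block`,
#'   `day`, `pixel_scale`, `n_plants` (as written by
#'   [generate_experiment()]).
#' @param base_dir Directory that `path` entries are relative to.
#' @inheritParams segment_canopy
#' @return Long tibble, one row per image (see [tidy.canopy_segmentation()]).
#' @export
segment_images <- function(manifest, base_dir = ".",
                           method = c("otsu", "fixed"),
                           fixed_threshold = NULL, min_object_px = 25L) {
  method <- match.arg(method)
  purrr::pmap(manifest, function(path, species, ppfd, block, day,
                                 pixel_scale, n_plants, ...) {
    img <- read_canopy_image(file.path(base_dir, path),
                             pixel_scale = pixel_scale)
    img$capture_day <- day
    img$meta <- list(species = species, ppfd = ppfd, block = block,
                     n_plants = n_plants)
    tidy(segment_canopy(img, method = method,
                        fixed_threshold = fixed_threshold,
                        min_object_px = min_object_px))
  }) |>
    dplyr::bind_rows()
}

#' Assemble per-unit PCS trajectories from segmentation results
#'
#' Groups per-image PCS values by experimental unit, sorts by day, and
#' validates the grouping (at least one image per unit, no duplicate days
#' within a unit).
#'
#' @param results A list of `canopy_segmentation` objects, or a tidy tibble
#'   as returned by [segment_images()].
#' @return Tibble `species`, `ppfd`, `block`, `day`, `pcs_cm2_per_plant`,
#'   `threshold_used`, sorted by unit and day.
#' @export
build_trajectories <- function(results) {
  df <- if (is.data.frame(results)) {
    tibble::as_tibble(results)
  } else {
    dplyr::bind_rows(purrr::map(results, tidy))
  }
  need <- c("species", "ppfd", "block", "day", "pcs_cm2_per_plant")
  if (!all(need %in% names(df))) {
    abort(paste("results must provide columns", paste(need, collapse = ", ")))
  }
  dup <- df |>
    dplyr::count(species, ppfd, block, day) |>
    dplyr::filter(n > 1)
  if (nrow(dup)) {
    abort("duplicate (species, ppfd, block, day) observations in input")
  }
  df |>
    dplyr::select(dplyr::all_of(need),
                  dplyr::any_of("threshold_used")) |>
    dplyr::arrange(species, ppfd, block, day)
}
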