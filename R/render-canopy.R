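#' Construct a canopy image object
#'
#' Wraps a single-channel intensity grid with the metadata the segmentation
#' stage needs: isotropic pixel scale, capture day and group membership.
#'
#' @param pixels Numeric matrix of non-negative intensities in `[0, 1]`.
#' @param pixel_scale Pixel edge length, cm per pixel (> 0).
#' @param capture_day Days after seeding (>= 0), or `NA`.
#' @param meta Named list of group metadata (`species`, `ppfd`, `block`,
#'   `n_plants`).
#' @return An object of class `canopy_image`.
#' @export
canopy_image <- function(pixels, pixel_scale, capture_day = NA_integer_,
                         meta = list()) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    abort("`pixels` must be a non-empty matrix")
  }
  if (any(pixels < 0)) abort("intensities must be non-negative")
  stopifnot_scalar_number(pixel_scale, "pixel_scale")
  if (pixel_scale <= 0) abort("`pixel_scale` must be > 0")
  if (!is.na(capture_day) && capture_day < 0) {
    abort("`capture_day` must be >= 0")
  }
  structure(
    list(pixels = pixels, pixel_scale = pixel_scale,
         capture_day = capture_day, meta = meta, ground_truth = NULL),
    class = "canopy_image"
  )
}

#' @export
print.canopy_image <- function(x, ...) {
  cat(sprintf("<canopy_image> %d x %d px, %.3g cm/px",
              nrow(x$pixels), ncol(x$pixels), x$pixel_scale))
  if (!is.na(x$capture_day)) cat(", day", x$capture_day)
  if (!is.null(x$ground_truth)) {
    cat(sprintf(", truth %d fg px", x$ground_truth$foreground_px))
  }
  cat("\n")
  invisible(x)
}

## rasterise one rosette: union mask over leaf ellipses + central crown.
## geom: list(n_leaves, anchor_frac, width_frac, crown_frac, len_jit, angles)
## L: leaf length scale in pixels. Returns union/drawn pixel counts + mask.
rosette_raster <- function(L, geom) {
  rmax <- ceiling(L * (geom$anchor_frac + 0.6 * max(geom$len_jit)) + 2)
  n <- 2L * rmax + 1L
  ax <- seq(-rmax, rmax)
  X <- matrix(ax, n, n)            # x varies along rows
  Y <- matrix(ax, n, n, byrow = TRUE)
  mask <- matrix(FALSE, n, n)
  drawn <- 0L

  paint <- function(cx, cy, s1, s2, theta) {
    # bounding box of the rotated ellipse
    ex <- sqrt((s1 * cos(theta))^2 + (s2 * sin(theta))^2)
    ey <- sqrt((s1 * sin(theta))^2 + (s2 * cos(theta))^2)
    ri <- which(ax >= cx - ex - 1 & ax <= cx + ex + 1)
    ci <- which(ax >= cy - ey - 1 & ax <= cy + ey + 1)
    if (!length(ri) || !length(ci)) return(invisible())
    xs <- X[ri, ci, drop = FALSE] - cx
    ys <- Y[ri, ci, drop = FALSE] - cy
    u <- cos(theta) * xs + sin(theta) * ys
    v <- -sin(theta) * xs + cos(theta) * ys
    inside <- (u / s1)^2 + (v / s2)^2 <= 1
    drawn <<- drawn + sum(inside)
    mask[ri, ci] <<- mask[ri, ci] | inside
    invisible()
  }

  # central crown keeps the rosette simply connected and star-shaped
  cr <- geom$crown_frac * L
  if (cr >= 0.5) paint(0, 0, cr, cr, 0)
  for (i in seq_len(geom$n_leaves)) {
    s1 <- 0.5 * L * geom$len_jit[i]
    s2 <- 0.5 * geom$width_frac * L
    th <- geom$angles[i]
    d <- geom$anchor_frac * L
    paint(d * cos(th), d * sin(th), s1, s2, th)
  }
  list(union_px = sum(mask), drawn_px = drawn, mask = mask)
}

## find the leaf scale L whose union area hits target_px (multiplicative
## iteration, then bisection on the pixel count)
calibrate_scale <- function(target_px, geom, tol_frac = 0.004) {
  L <- sqrt(target_px / pi)
  r <- rosette_raster(L, geom)
  for (k in 1:10) {
    if (r$union_px == 0) L <- 2 * L
    else L <- L * sqrt(target_px / r$union_px)
    r <- rosette_raster(L, geom)
    if (abs(r$union_px - target_px) <= 0.02 * target_px) break
  }
  lo <- 0.9 * L; hi <- 1.1 * L
  rlo <- rosette_raster(lo, geom); rhi <- rosette_raster(hi, geom)
  for (k in 1:6) {
    if (rlo$union_px <= target_px) break
    lo <- 0.9 * lo; rlo <- rosette_raster(lo, geom)
  }
  for (k in 1:6) {
    if (rhi$union_px >= target_px) break
    hi <- 1.1 * hi; rhi <- rosette_raster(hi, geom)
  }
  best <- r
  tol <- max(1, tol_frac * target_px)
  for (k in 1:30) {
    mid <- (lo + hi) / 2
    r <- rosette_raster(mid, geom)
    if (abs(r$union_px - target_px) < abs(best$union_px - target_px)) best <- r
    if (abs(r$union_px - target_px) <= tol) { best <- r; break }
    if (r$union_px < target_px) lo <- mid else hi <- mid
  }
  best
}

#' Render a synthetic top-down canopy image
#'
#' Stands in for a chlorophyll-fluorescence imaging rig: bright rosettes of
#' overlapping ellipse "leaves" on a dark background. The renderer
#' calibrates the leaf scale so the total foreground (union) area matches
#' `n_plants * pcs_per_plant` within 1%, and chooses the leaf count/anchor
#' so the total drawn leaf area (counting occluded leaf parts) approximates
#' `overlap_ratio` times the projected area. The exact rendered foreground
#' pixel count is returned as ground truth for segmentation benchmarks.
#'
#' @param pcs_per_plant Target projected canopy size per plant, cm² (> 0).
#' @param overlap_ratio Target leaf-area / projected-area ratio (>= 1).
#' @param n_plants Number of rosettes (default 9, one imaging group).
#' @param pixel_scale cm per pixel (default 0.05).
#' @param seed Integer seed for leaf jitter, rosette orientation and image
#'   noise.
#' @param fg,bg Foreground/background mean intensities in `[0, 1]`
#'   (separation is kept >= 50/255).
#' @param noise_sd SD of additive Gaussian pixel noise (0 disables).
#' @param canvas_px Optional `c(rows, cols)` canvas size; an error is
#'   raised if the plants cannot fit without touching the border.
#' @return A [canopy_image()] whose `ground_truth` element holds
#'   `foreground_px`, `projected_area_cm2`, `drawn_area_cm2` and the
#'   requested inputs.
#' @export
render_canopy_image <- function(pcs_per_plant, overlap_ratio = 1.5,
                                n_plants = 9L, pixel_scale = 0.05,
                                seed = 1L, fg = 0.8, bg = 0.06,
                                noise_sd = 0.02, canvas_px = NULL) {
  stopifnot_scalar_number(pcs_per_plant, "pcs_per_plant")
  if (pcs_per_plant <= 0) abort("`pcs_per_plant` must be > 0")
  if (overlap_ratio < 1) abort("`overlap_ratio` must be >= 1")
  if (n_plants < 1) abort("`n_plants` must be >= 1")
  if (fg - bg < 50 / 255) abort("foreground/background separation must be >= 50 grey levels")

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  target_px <- pcs_per_plant / pixel_scale^2
  if (target_px < 20) {
    abort("requested area is below the resolvable size at this pixel scale")
  }

  geom <- list(
    n_leaves = max(4L, min(90L, round(5 + 10.5 * (overlap_ratio - 1)))),
    anchor_frac = min(0.8, max(0.3, 0.8 - 0.12 * (overlap_ratio - 1))),
    width_frac = 0.35,
    crown_frac = 0.22
  )
  refresh_leaves <- function(g) {
    g$len_jit <- stats::runif(g$n_leaves, 0.88, 1.12)
    g$angles <- (seq_len(g$n_leaves) - 1) * 137.508 * pi / 180 +
      stats::runif(1, 0, 2 * pi)
    g
  }
  geom <- refresh_leaves(geom)

  ros <- calibrate_scale(target_px, geom)
  for (k in 1:4) {
    ratio <- ros$drawn_px / ros$union_px
    if (abs(ratio - overlap_ratio) <= 0.07 * overlap_ratio) break
    adj <- (overlap_ratio / ratio)^1.3
    new_n <- max(4L, min(140L, round(geom$n_leaves * adj)))
    if (new_n == geom$n_leaves) {
      # leaf count pinned: shift the anchor instead
      geom$anchor_frac <- min(0.85, max(0.22,
        geom$anchor_frac * (ratio / overlap_ratio)^0.5))
    }
    geom$n_leaves <- new_n
    geom <- refresh_leaves(geom)
    ros <- calibrate_scale(target_px, geom)
  }

  # lay the rosettes on a square grid of non-touching cells; dihedral
  # transforms vary orientation without changing the pixel count
  wr <- nrow(ros$mask)
  ncell <- ceiling(sqrt(n_plants))
  cell <- wr + 4L
  rows <- cols <- ncell * cell
  if (!is.null(canvas_px)) {
    if (canvas_px[1] < rows || canvas_px[2] < cols) {
      abort("requested area exceeds canvas capacity")
    }
    rows <- canvas_px[1]; cols <- canvas_px[2]
  }
  canvas <- matrix(FALSE, rows, cols)
  variants <- sample.int(8L, n_plants, replace = TRUE)
  for (p in seq_len(n_plants)) {
    m <- ros$mask
    v <- variants[p]
    if (v > 4L) { m <- t(m); v <- v - 4L }
    for (r in seq_len(v - 1L)) m <- t(apply(m, 2L, rev))
    r0 <- ((p - 1L) %/% ncell) * cell + 2L
    c0 <- ((p - 1L) %% ncell) * cell + 2L
    canvas[r0 + seq_len(wr) - 1L, c0 + seq_len(wr) - 1L] <- m
  }

  fg_px <- sum(canvas)
  px <- bg + (fg - bg) * canvas
  if (noise_sd > 0) px <- px + rnorm(length(px), 0, noise_sd)
  px <- matrix(pmin(pmax(px, 0), 1), rows, cols)

  img <- canopy_image(px, pixel_scale)
  img$ground_truth <- list(
    foreground_px = fg_px,
    projected_area_cm2 = fg_px * pixel_scale^2,
    drawn_area_cm2 = n_plants * ros$drawn_px * pixel_scale^2,
    requested_pcs_cm2 = pcs_per_plant,
    requested_overlap_ratio = overlap_ratio,
    n_plants = as.integer(n_plants)
  )
  img
}

#' Write / read canopy images
#'
#' Images are stored as single-channel PNG (or TIFF, by file extension)
#' with a JSON sidecar (`<path>.json`) carrying pixel scale, capture day,
#' group metadata and the rendered ground truth.
#'
#' @param img A [canopy_image()].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `write_canopy_image()` returns `path` invisibly;
#'   `read_canopy_image()` returns a [canopy_image()].
#' @export
write_canopy_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img$pixels, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img$pixels, where = path)
  } else {
    abort("`path` must end in .png, .tif or .tiff")
  }
  side <- list(pixel_scale = img$pixel_scale, capture_day = img$capture_day,
               meta = img$meta, ground_truth = img$ground_truth)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_canopy_image
#' @param pixel_scale Pixel scale override (cm/px); defaults to the sidecar
#'   value when one exists.
#' @export
read_canopy_image <- function(path, pixel_scale = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") png::readPNG(path)
        else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
        else abort("`path` must end in .png, .tif or .tiff")
  if (length(dim(px)) == 3L) px <- px[, , 1]
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  ps <- pixel_scale %||% side$pixel_scale
  if (is.null(ps)) abort("no pixel scale: pass `pixel_scale` or provide a sidecar")
  img <- canopy_image(px, as.numeric(ps),
                      capture_day = side$capture_day %||% NA_integer_,
                      meta = side$meta %||% list())
  if (!is.null(side$ground_truth)) img$ground_truth <- side$ground_truth
  img
}
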