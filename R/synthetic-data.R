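#' Generate one synthetic PCS trajectory
#'
#' Projected canopy size at each imaging day is the species sigmoid
#' evaluated at that day times multiplicative lognormal noise with mean 1
#' and fractional SD `noise$pcs_cv`. The true generating parameters travel
#' with the result so recovery can be tested downstream.
#'
#' @param params A [species_params()] object.
#' @param treatment A one-row treatment data frame (with a `ppfd` column) or
#'   a single PPFD (µmol m⁻² s⁻¹).
#' @param noise A [noise_model()].
#' @param days Strictly increasing imaging days within
#'   `[0, params$harvest_day]`.
#' @param block Optional block label stored with the trajectory.
#' @return Tibble with columns `species`, `ppfd`, `block`, `day`,
#'   `pcs_true` and `pcs` (cm² per plant), plus a `true_params` attribute
#'   `c(a, x0, b)`.
#' @export
generate_pcs_trajectory <- function(params, treatment, noise = noise_model(),
                                    days, block = 1L) {
  ppfd <- if (is.data.frame(treatment)) treatment$ppfd[1] else treatment
  stopifnot_scalar_number(ppfd, "ppfd")
  if (length(days) == 0L) abort("`days` must not be empty")
  if (any(diff(days) <= 0)) abort("`days` must be strictly increasing")
  if (any(days < 0) || any(days > params$harvest_day)) {
    abort("`days` must lie within [0, harvest_day]")
  }
  a <- ppfd_lookup(params$pcs_asymptote_by_ppfd, ppfd)
  truth <- sigmoid(days, a, params$midpoint_day, params$shape_b)
  out <- tibble::tibble(
    species = params$name,
    ppfd = ppfd,
    block = block,
    day = days,
    pcs_true = truth,
    pcs = truth * rlnorm_unit_mean(length(days), noise$pcs_cv)
  )
  attr(out, "true_params") <- c(a = a, x0 = params$midpoint_day,
                                b = params$shape_b)
  out
}

#' Generate synthetic physiology records
#'
#' CCI, ACI, Φ_PSII and net CO₂ assimilation are drawn from the species'
#' linear PPFD responses plus additive Gaussian noise; Φ_PSII is clamped to
#' [0, 0.85] (a physical bound on the quantum yield of photosystem II).
#'
#' @inheritParams generate_pcs_trajectory
#' @param treatment One-row treatment data frame or a vector of PPFDs
#'   (each must lie in [50, 425], the calibrated range of the responses).
#' @return Tibble with one row per PPFD: `species`, `ppfd`, `cci`, `aci`,
#'   `phipsii`, `assim`.
#' @export
generate_physiology <- function(params, treatment, noise = noise_model()) {
  ppfd <- if (is.data.frame(treatment)) treatment$ppfd else treatment
  if (any(ppfd < 50) || any(ppfd > 425)) {
    abort("physiology responses are calibrated for PPFD in [50, 425]")
  }
  n <- length(ppfd)
  s <- noise$physiology_sd
  draw <- function(slope, intercept, sd) {
    intercept + slope * ppfd + (if (sd > 0) rnorm(n, 0, sd) else 0)
  }
  tibble::tibble(
    species = params$name,
    ppfd = ppfd,
    cci = draw(params$cci_slope, params$cci_intercept, s[["cci"]]),
    aci = draw(params$aci_slope, params$aci_intercept, s[["aci"]]),
    phipsii = pmin(pmax(
      draw(params$phipsii_slope, params$phipsii_intercept, s[["phipsii"]]),
      0), 0.85),
    assim = draw(params$assim_slope, params$assim_intercept, s[["assim"]])
  )
}

#' Configuration of a synthetic experiment
#'
#' Defaults mirror the study design this package emulates: 6 PPFD levels,
#' 2 species, 3 replicate blocks (36 nine-plant experimental units),
#' twice-weekly imaging (days 4, 7, 11, 14, 18, 21, 25 plus the day before
#' each species' harvest) over a 27--28 day cycle.
#'
#' @param treatments Treatment table, default [default_treatments()].
#' @param species List of [species_params()], default
#'   [default_species_params()].
#' @param blocks Number of replicate blocks (default 3).
#' @param imaging_days Base imaging days; the day before harvest is
#'   appended per species.
#' @param noise A [noise_model()].
#' @param seed Integer seed governing every random draw (defaults to the
#'   noise model's seed).
#' @param images If `TRUE`, [generate_experiment()] also renders canopy
#'   images (requires `out_dir`).
#' @param pixel_scale Image resolution, cm per pixel (default 0.05).
#' @param n_plants Plants per experimental unit (default 9).
#' @param out_dir Output directory for on-disk datasets, or `NULL` for an
#'   in-memory dataset.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(treatments = default_treatments(),
                              species = default_species_params(),
                              blocks = 3L,
                              imaging_days = c(4, 7, 11, 14, 18, 21, 25),
                              noise = noise_model(),
                              seed = noise$seed,
                              images = FALSE,
                              pixel_scale = 0.05,
                              n_plants = 9L,
                              out_dir = NULL) {
  if (blocks < 1) abort("`blocks` must be >= 1")
  if (images && is.null(out_dir)) {
    abort("rendering images requires `out_dir`")
  }
  for (sp in species) {
    days_sp <- sort(unique(c(imaging_days, sp$harvest_day - 1L)))
    if (length(days_sp) < 5L) {
      abort("each unit needs at least 5 imaging days for a stable sigmoid fit")
    }
    if (sp$harvest_day > max(days_sp) + 7) {
      abort("harvest day is more than a week past the last imaging day")
    }
  }
  structure(
    list(treatments = treatments, species = species, blocks = as.integer(blocks),
         imaging_days = imaging_days, noise = noise, seed = as.integer(seed),
         images = images, pixel_scale = pixel_scale,
         n_plants = as.integer(n_plants), out_dir = out_dir),
    class = "experiment_config"
  )
}

#' Generate a complete synthetic experiment
#'
#' Produces, for every species x PPFD x block unit: a noisy PCS trajectory,
#' a physiology record, a harvest record, and a ground-truth sidecar.
#' Before noise, harvest dry weight is exactly `lue * total incident light`
#' where the total is the daily sum of the true sigmoid (days 0..harvest)
#' times the treatment DLI, and leaf area is `overlap_ratio * PCS at
#' harvest`, so the generator's targets are recoverable by the analysis
#' pipeline. With `images = TRUE`, top-down canopy images (PNG, plus a
#' manifest CSV and JSON sidecars with the rendered ground truth) are also
#' written.
#'
#' The same seed and configuration reproduce the dataset bit-for-bit.
#'
#' @param config An [experiment_config()].
#' @return A list of class `synthetic_experiment` with tibbles
#'   `treatments`, `pcs_long`, `physiology`, `harvest`, `truth`, and (when
#'   images are rendered) `manifest`. Written to `config$out_dir` as CSV
#'   files when that is set.
#' @export
generate_experiment <- function(config = experiment_config()) {
  if (!inherits(config, "experiment_config")) {
    abort("`config` must be an experiment_config()")
  }
  set.seed(config$seed)
  tr <- config$treatments
  noise <- config$noise

  units <- tidyr::expand_grid(
    species = names(config$species),
    ppfd = tr$ppfd,
    block = seq_len(config$blocks)
  )

  pcs_long <- list(); truth <- list(); harvest <- list(); phys <- list()
  for (i in seq_len(nrow(units))) {
    sp <- config$species[[units$species[i]]]
    ppfd_i <- units$ppfd[i]
    block_i <- units$block[i]
    days_i <- sort(unique(c(config$imaging_days, sp$harvest_day - 1L)))

    traj <- generate_pcs_trajectory(sp, ppfd_i, noise, days_i, block_i)
    tp <- attr(traj, "true_params")

    daily_true <- predict_daily(tp, sp$harvest_day)
    dli_i <- tr$dli_mol_m2_d[match(ppfd_i, tr$ppfd)]
    total_true <- sum(daily_true$pcs * 1e-4 * dli_i)

    lue_i <- ppfd_lookup(sp$lue_by_ppfd, ppfd_i)
    ov_i <- ppfd_lookup(sp$overlap_ratio_by_ppfd, ppfd_i)
    pcs_h <- sigmoid(sp$harvest_day, tp[["a"]], tp[["x0"]], tp[["b"]])
    dw <- lue_i * total_true * rlnorm_unit_mean(1, noise$dw_cv)
    la <- ov_i * pcs_h

    ph <- generate_physiology(sp, ppfd_i, noise)
    ph$block <- block_i

    pcs_long[[i]] <- traj
    phys[[i]] <- ph
    harvest[[i]] <- tibble::tibble(
      species = sp$name, ppfd = ppfd_i, block = block_i,
      leaf_area_cm2 = la, dry_weight_g = dw, n_plants = config$n_plants
    )
    truth[[i]] <- tibble::tibble(
      species = sp$name, ppfd = ppfd_i, block = block_i,
      a_true = tp[["a"]], x0_true = tp[["x0"]], b_true = tp[["b"]],
      pcs_at_harvest_true_cm2 = pcs_h,
      total_incident_true_mol = total_true,
      lue_true_g_mol = lue_i,
      overlap_ratio_true = ov_i,
      harvest_day = sp$harvest_day
    )
  }

  out <- structure(
    list(
      treatments = tr,
      pcs_long = dplyr::bind_rows(pcs_long) |>
        dplyr::rename(pcs_cm2_per_plant = pcs),
      physiology = dplyr::bind_rows(phys) |>
        dplyr::relocate(block, .after = ppfd),
      harvest = dplyr::bind_rows(harvest),
      truth = dplyr::bind_rows(truth),
      config = config
    ),
    class = "synthetic_experiment"
  )

  if (config$images) {
    out$manifest <- render_experiment_images(out)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) readr::write_csv(x, file.path(config$out_dir, f))
    wr(tr, "treatments.csv")
    wr(out$pcs_long, "pcs_long.csv")
    wr(out$physiology, "physiology.csv")
    wr(out$harvest, "harvest.csv")
    wr(out$truth, "truth.csv")
    if (!is.null(out$manifest)) wr(out$manifest, "manifest.csv")
  }
  out
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment>\n")
  cat("  units:", nrow(x$truth), " (",
      length(unique(x$truth$species)), "species x",
      length(unique(x$truth$ppfd)), "PPFDs x",
      max(x$truth$block), "blocks )\n")
  cat("  PCS observations:", nrow(x$pcs_long), "\n")
  if (!is.null(x$manifest)) cat("  images:", nrow(x$manifest), "\n")
  invisible(x)
}

## render one PNG per (species, ppfd, block, day); returns manifest tibble
render_experiment_images <- function(exp) {
  config <- exp$config
  dir.create(file.path(config$out_dir, "images"),
             recursive = TRUE, showWarnings = FALSE)
  df <- exp$pcs_long
  seeds <- derive_seeds(config$seed + 1L, nrow(df))
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    sp <- config$species[[df$species[i]]]
    ov <- ppfd_lookup(sp$overlap_ratio_by_ppfd, df$ppfd[i])
    img <- render_canopy_image(
      pcs_per_plant = df$pcs_cm2_per_plant[i],
      overlap_ratio = ov,
      n_plants = config$n_plants,
      pixel_scale = config$pixel_scale,
      seed = seeds[i]
    )
    img$capture_day <- df$day[i]
    img$meta <- list(species = df$species[i], ppfd = df$ppfd[i],
                     block = df$block[i], n_plants = config$n_plants)
    fname <- sprintf("%s_%d_%d_d%d.png", df$species[i], round(df$ppfd[i]),
                     df$block[i], df$day[i])
    path <- file.path(config$out_dir, "images", fname)
    write_canopy_image(img, path)
    rows[[i]] <- tibble::tibble(
      path = file.path("images", fname),
      species = df$species[i], ppfd = df$ppfd[i], block = df$block[i],
      day = df$day[i], pixel_scale = config$pixel_scale,
      n_plants = config$n_plants,
      truth_foreground_px = img$ground_truth$foreground_px
    )
  }
  dplyr::bind_rows(rows)
}
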