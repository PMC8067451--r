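#' Light use efficiency
#'
#' Shoot dry weight divided by the total incident light the plant received
#' over the growing period.
#'
#' @param dry_weight Shoot dry weight, g per plant (>= 0).
#' @param total_incident Total incident light, mol per plant (> 0).
#' @return LUE in g mol⁻¹.
#' @export
compute_lue <- function(dry_weight, total_incident) {
  if (any(total_incident <= 0)) abort("`total_incident` must be > 0")
  if (any(dry_weight < 0)) abort("`dry_weight` must be >= 0")
  dry_weight / total_incident
}

#' Specific leaf area
#'
#' Leaf area of a plant divided by its shoot dry weight; higher values mean
#' thinner leaves.
#'
#' @param leaf_area Leaf area, cm² per plant (>= 0).
#' @param dry_weight Shoot dry weight, g per plant (> 0).
#' @return SLA in cm² g⁻¹.
#' @export
compute_sla <- function(leaf_area, dry_weight) {
  if (any(dry_weight <= 0)) abort("`dry_weight` must be > 0")
  if (any(leaf_area < 0)) abort("`leaf_area` must be >= 0")
  leaf_area / dry_weight
}

#' Canopy overlap ratio
#'
#' Leaf area divided by the projected canopy size at harvest; quantifies
#' intra-canopy self-shading. Values below 1 (leaf area smaller than the
#' canopy silhouette) are physically suspect and trigger a warning, not an
#' error.
#'
#' @param leaf_area Leaf area, cm² per plant (>= 0).
#' @param pcs_at_harvest Projected canopy size at harvest, cm² (> 0).
#' @return Dimensionless ratio.
#' @export
compute_overlap_ratio <- function(leaf_area, pcs_at_harvest) {
  if (any(pcs_at_harvest <= 0)) abort("`pcs_at_harvest` must be > 0")
  if (any(leaf_area < 0)) abort("`leaf_area` must be >= 0")
  out <- leaf_area / pcs_at_harvest
  if (any(out < 1)) {
    warn("overlap ratio < 1: leaf area smaller than projected canopy size")
  }
  out
}

#' Harvest-derived trait table
#'
#' Joins harvest records with per-unit incident-light totals and fitted
#' growth curves, and computes LUE, SLA and the canopy overlap ratio per
#' experimental unit (the nine-plant group, never individual plants).
#' PCS at harvest is by default the sigmoid prediction at the species'
#' harvest day (consistent with the daily series used for light
#' integration); `pcs_source = "image"` uses the last raw observation
#' instead.
#'
#' @param harvest Tibble `species`, `ppfd`, `block`, `leaf_area_cm2`,
#'   `dry_weight_g`.
#' @param light Tibble from [incident_light()] (`species`, `ppfd`, `block`,
#'   `total_incident_mol`).
#' @param fits Tibble from [fit_sigmoids()].
#' @param harvest_days Named vector of harvest days per species.
#' @param pcs_source `"fit"` (default) or `"image"`; with `"image"`,
#'   supply `pcs_long` too.
#' @param pcs_long Long PCS table (needed for `pcs_source = "image"`).
#' @return Tibble with group keys, inputs and `pcs_at_harvest_cm2`,
#'   `lue_g_mol`, `sla_cm2_g`, `overlap_ratio`.
#' @export
compute_traits <- function(harvest, light, fits,
                           harvest_days = c(mizuna = 27, lettuce = 28),
                           pcs_source = c("fit", "image"),
                           pcs_long = NULL) {
  pcs_source <- match.arg(pcs_source)
  keys <- c("species", "ppfd", "block")

  pcs_h <- if (pcs_source == "fit") {
    fits |>
      dplyr::mutate(pcs_at_harvest_cm2 = purrr::pmap_dbl(
        list(a, x0, b, species),
        function(a, x0, b, sp) sigmoid(harvest_days[[sp]], a, x0, b))) |>
      dplyr::select(dplyr::all_of(keys), pcs_at_harvest_cm2)
  } else {
    if (is.null(pcs_long)) abort("`pcs_long` is required for pcs_source = \"image\"")
    pcs_long |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::slice_max(day, n = 1) |>
      dplyr::ungroup() |>
      dplyr::transmute(species, ppfd, block,
                       pcs_at_harvest_cm2 = pcs_cm2_per_plant)
  }

  tibble::as_tibble(harvest) |>
    dplyr::inner_join(dplyr::select(light, dplyr::all_of(keys),
                                    total_incident_mol), by = keys) |>
    dplyr::inner_join(pcs_h, by = keys) |>
    dplyr::mutate(
      lue_g_mol = compute_lue(dry_weight_g, total_incident_mol),
      sla_cm2_g = compute_sla(leaf_area_cm2, dry_weight_g),
      overlap_ratio = compute_overlap_ratio(leaf_area_cm2, pcs_at_harvest_cm2)
    )
}
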