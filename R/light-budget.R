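#' Daily light integral from PPFD and photoperiod
#'
#' Converts a photosynthetic photon flux density (PPFD, µmol m⁻² s⁻¹) and a
#' photoperiod (hours per day) into the daily light integral
#' (DLI, mol m⁻² d⁻¹): `dli = ppfd * photoperiod * 3600 / 1e6`.
#'
#' @param ppfd Numeric vector of PPFDs (µmol m⁻² s⁻¹), non-negative.
#' @param photoperiod Photoperiod in hours per day, in `(0, 24]`.
#'   Default 16 h, the usual leafy-green schedule in vertical farms.
#' @return Numeric vector of DLIs (mol m⁻² d⁻¹).
#' @examples
#' compute_dli(210, 16) # 12.096 mol m-2 d-1
#' @export
compute_dli <- function(ppfd, photoperiod = 16) {
  if (!is.numeric(ppfd) || any(!is.finite(ppfd)) || any(ppfd < 0)) {
    abort("`ppfd` must be finite and non-negative")
  }
  stopifnot_scalar_number(photoperiod, "photoperiod")
  if (photoperiod <= 0 || photoperiod > 24) {
    abort("`photoperiod` must be in (0, 24] hours")
  }
  ppfd * photoperiod * 3600 / 1e6
}

#' Default light treatments
#'
#' The six-PPFD treatment ladder used throughout the package: nominal levels
#' 50--425 µmol m⁻² s⁻¹, measured tray-center means 53, 128, 210, 281, 345 and
#' 410 µmol m⁻² s⁻¹, 16-h photoperiod. Calculations use the measured means
#' (the DLIs derive from them); the nominal labels are display-only.
#'
#' @param photoperiod Photoperiod in hours per day (default 16).
#' @return A tibble with columns `ppfd_nominal`, `ppfd`, `photoperiod_h`
#'   and `dli_mol_m2_d`.
#' @export
default_treatments <- function(photoperiod = 16) {
  ppfd <- c(53, 128, 210, 281, 345, 410)
  tibble::tibble(
    ppfd_nominal = c(50, 125, 200, 275, 350, 425),
    ppfd = ppfd,
    photoperiod_h = photoperiod,
    dli_mol_m2_d = compute_dli(ppfd, photoperiod)
  )
}

#' Integrate per-plant incident light over a daily PCS series
#'
#' Each day's projected canopy size (cm² per plant) is multiplied by the
#' treatment DLI to give the incident light intercepted by the canopy
#' footprint that day: `daily_incident = pcs * 1e-4 * dli` (mol plant⁻¹ d⁻¹).
#' Summing over the daily series gives the total incident light per plant for
#' the growing period. The discrete daily sum (not continuous quadrature) is
#' the definition of the total.
#'
#' @param daily A data frame with columns `day` and `pcs` (cm² per plant),
#'   e.g. from [predict_daily()].
#' @param dli Daily light integral (mol m⁻² d⁻¹), a single non-negative
#'   number, or a one-row data frame carrying a `dli_mol_m2_d` column.
#' @return The input tibble with an added `daily_incident_mol` column and a
#'   `total_incident_mol` attribute (also reported by
#'   [total_incident_light()]).
#' @seealso [compute_dli()], [incident_light()]
#' @export
integrate_incident_light <- function(daily, dli) {
  if (is.data.frame(dli)) {
    if (nrow(dli) != 1L || is.null(dli$dli_mol_m2_d)) {
      abort("`dli` data frame must have one row and a `dli_mol_m2_d` column")
    }
    dli <- dli$dli_mol_m2_d
  }
  stopifnot_scalar_number(dli, "dli")
  if (dli < 0) abort("`dli` must be non-negative")
  if (!is.data.frame(daily) || is.null(daily$day) || is.null(daily$pcs)) {
    abort("`daily` must be a data frame with `day` and `pcs` columns")
  }
  if (any(daily$pcs < 0)) abort("`pcs` must be non-negative (cm^2 per plant)")
  out <- dplyr::mutate(tibble::as_tibble(daily),
                       daily_incident_mol = pcs * 1e-4 * dli)
  attr(out, "total_incident_mol") <- sum(out$daily_incident_mol)
  out
}

#' Total incident light of an integrated series
#'
#' @param x Result of [integrate_incident_light()].
#' @return Total incident light, mol plant⁻¹.
#' @export
total_incident_light <- function(x) {
  tot <- attr(x, "total_incident_mol")
  if (is.null(tot)) {
    if (is.data.frame(x) && !is.null(x$daily_incident_mol)) {
      return(sum(x$daily_incident_mol))
    }
    abort("`x` is not an integrated incident-light series")
  }
  tot
}

#' Per-unit incident light totals
#'
#' Table-level wrapper: joins a daily PCS table (one row per
#' species/PPFD/block/day) with a treatment table and returns the total
#' incident light per experimental unit.
#'
#' @param pcs_daily Tibble with columns `species`, `ppfd`, `block`, `day`,
#'   `pcs` as produced by [predict_daily_all()].
#' @param treatments Treatment table with `ppfd` and `dli_mol_m2_d`
#'   (default [default_treatments()]).
#' @return Tibble with `species`, `ppfd`, `block`, `harvest_day` and
#'   `total_incident_mol`.
#' @export
incident_light <- function(pcs_daily, treatments = default_treatments()) {
  need <- c("species", "ppfd", "block", "day", "pcs")
  if (!all(need %in% names(pcs_daily))) {
    abort(paste("`pcs_daily` must have columns", paste(need, collapse = ", ")))
  }
  if (any(pcs_daily$pcs < 0)) abort("`pcs` must be non-negative")
  dplyr::inner_join(tibble::as_tibble(pcs_daily),
                    dplyr::select(treatments, ppfd, dli_mol_m2_d),
                    by = "ppfd") |>
    dplyr::group_by(species, ppfd, block) |>
    dplyr::summarise(
      harvest_day = max(day),
      total_incident_mol = sum(pcs * 1e-4 * dli_mol_m2_d),
      .groups = "drop"
    )
}
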