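#' Species-by-PPFD multiple regression with interaction pruning
#'
#' Ordinary least squares of a trait on PPFD (continuous) and species
#' (two-level class variable, dummy-coded with lettuce = 0, mizuna = 1 by
#' default). The full model includes the species × PPFD interaction; when
#' the interaction is not significant at `alpha` it is removed and the
#' main-effects model is reported (`interaction_dropped = TRUE`), the
#' standard treatment for testing whether two species share a common slope.
#'
#' Two degenerate cases are handled explicitly rather than erroring:
#' a constant response returns zero slope and offset with `r_squared = 0`
#' and `NA` p-values; and noise-free data (residual SD numerically zero,
#' where t-based p-values are undefined) drop the interaction exactly when
#' its coefficient is numerically zero relative to the PPFD slope.
#'
#' @param data Data frame with columns `ppfd`, `species` and the response.
#' @param response Response column (tidy-evaluated, e.g. `lue_g_mol`).
#' @param alpha Significance level for interaction pruning (default 0.05).
#' @param include_block Add `block` as a fixed covariate (default `FALSE`).
#' @param reference Reference species for dummy coding (default
#'   `"lettuce"`).
#' @return Object of class `species_ppfd_fit`, with `tidy()` and
#'   `glance()` methods. Key fields: `coefficients` (tibble), `slopes`
#'   (per-species PPFD slope, from the interaction model when retained),
#'   `species_offset`, `interaction_dropped`, `interaction_p`,
#'   `r_squared`, `n`, and the underlying `lm` objects (`model`,
#'   `full_model`).
#' @examples
#' sp <- default_species_params()
#' d <- dplyr::bind_rows(
#'   generate_physiology(sp$mizuna, c(53, 128, 210, 281, 345, 410),
#'                       noise_model(physiology_sd = c(cci = 0, aci = 0,
#'                                                     phipsii = 0, assim = 0))),
#'   generate_physiology(sp$lettuce, c(53, 128, 210, 281, 345, 410),
#'                       noise_model(physiology_sd = c(cci = 0, aci = 0,
#'                                                     phipsii = 0, assim = 0)))
#' )
#' fit <- fit_species_ppfd_model(d, phipsii)
#' fit$interaction_dropped # TRUE: common slope -3e-4
#' @export
fit_species_ppfd_model <- function(data, response, alpha = 0.05,
                                   include_block = FALSE,
                                   reference = "lettuce") {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  d <- dplyr::mutate(tibble::as_tibble(data), .y = {{ response }})
  resp_name <- rlang::as_label(rlang::enquo(response))
  if (!all(c("ppfd", "species") %in% names(d))) {
    abort("`data` must have `ppfd` and `species` columns")
  }
  lev <- unique(as.character(d$species))
  if (length(lev) != 2L) abort("exactly two species levels are required")
  if (!reference %in% lev) abort("`reference` is not a species level")
  if (length(unique(d$ppfd)) < 3L) abort("need at least 3 PPFD levels")
  counts <- table(d$species)
  if (any(counts < 2L)) abort("need at least 2 observations per species")
  other <- setdiff(lev, reference)
  d$species <- factor(d$species, levels = c(reference, other))
  if (include_block) {
    if (is.null(d$block)) abort("`include_block = TRUE` needs a `block` column")
    d$block <- factor(d$block)
  }

  new_fit <- function(model, full_model, dropped, p_int, coef_tab, slopes,
                      offset, r2) {
    structure(
      list(model = model, full_model = full_model, response = resp_name,
           alpha = alpha, interaction_dropped = dropped,
           interaction_p = p_int, coefficients = coef_tab, slopes = slopes,
           species_offset = offset, reference = reference,
           r_squared = r2, n = nrow(d)),
      class = "species_ppfd_fit")
  }

  ## degenerate: constant response
  if (sd(d$.y) == 0) {
    coef_tab <- tibble::tibble(
      term = c("(Intercept)", "ppfd", paste0("species", other)),
      estimate = c(d$.y[1], 0, 0),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_)
    slopes <- tibble::tibble(species = c(reference, other), slope = c(0, 0))
    return(new_fit(NULL, NULL, dropped = TRUE, p_int = NA_real_,
                   coef_tab, slopes, offset = 0, r2 = 0))
  }

  ## zero-noise data trips lm's perfect-fit warning; that case is handled
  ## explicitly below, so the warning is muffled here
  quiet_summary <- function(m) {
    withCallingHandlers(summary(m), warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }

  rhs <- "ppfd * species"
  if (include_block) rhs <- paste(rhs, "+ block")
  full <- lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  sfull <- quiet_summary(full)
  ctab <- sfull$coefficients
  int_term <- grep(":", rownames(ctab), value = TRUE)
  b_int <- ctab[int_term, "Estimate"]
  b_ppfd <- ctab["ppfd", "Estimate"]

  exact <- sfull$sigma < 1e-8 * max(abs(d$.y), .Machine$double.eps)
  p_int <- if (exact) {
    # t statistics are undefined at zero residual; prune on the coefficient
    if (abs(b_int) <= 1e-8 * (abs(b_ppfd) + 1e-12)) 1 else 0
  } else {
    ctab[int_term, "Pr(>|t|)"]
  }

  dropped <- p_int >= alpha
  model <- if (dropped) {
    rhs2 <- "ppfd + species"
    if (include_block) rhs2 <- paste(rhs2, "+ block")
    lm(stats::as.formula(paste(".y ~", rhs2)), data = d)
  } else {
    full
  }
  sm <- quiet_summary(model)
  cm <- sm$coefficients
  pvals <- cm[, "Pr(>|t|)"]
  if (exact) pvals[] <- NA_real_
  coef_tab <- tibble::tibble(
    term = rownames(cm), estimate = cm[, "Estimate"],
    std.error = if (exact) NA_real_ else cm[, "Std. Error"],
    statistic = if (exact) NA_real_ else cm[, "t value"],
    p.value = pvals)

  slope_ref <- coef(model)[["ppfd"]]
  slope_other <- if (dropped) slope_ref else slope_ref + b_int
  slopes <- tibble::tibble(species = c(reference, other),
                           slope = c(slope_ref, slope_other))
  offset <- coef(model)[[paste0("species", other)]]
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0

  new_fit(model, full, dropped, p_int, coef_tab, slopes, offset, r2)
}

#' @export
print.species_ppfd_fit <- function(x, ...) {
  cat(sprintf("<species_ppfd_fit> %s ~ ppfd %s species (n = %d, R^2 = %.3f)\n",
              x$response,
              if (x$interaction_dropped) "+" else "*",
              x$n, x$r_squared))
  cat(sprintf("  interaction p = %s -> %s\n",
              format(x$interaction_p, digits = 3),
              if (x$interaction_dropped) "dropped" else "retained"))
  print(x$slopes)
  invisible(x)
}

#' @rdname fit_species_ppfd_model
#' @param x,object A `species_ppfd_fit`.
#' @param ... Unused.
#' @export
tidy.species_ppfd_fit <- function(x, ...) x$coefficients

#' @rdname fit_species_ppfd_model
#' @export
glance.species_ppfd_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    r.squared = x$r_squared,
    interaction_dropped = x$interaction_dropped,
    interaction_p = x$interaction_p,
    alpha = x$alpha,
    nobs = x$n
  )
}

#' Univariate PPFD-response curve fits
#'
#' Least-squares fit of a trait against PPFD with one of the standard
#' response forms: `linear`, `quadratic`, `exponential_rise`
#' (`y = A (1 - exp(-k x))`, `A` the fitted plateau) or `sigmoid`
#' (three-parameter logistic). Nonlinear forms use Levenberg--Marquardt
#' with analytic starts and up to five deterministic jittered restarts;
#' non-convergence raises an error (no silent fallback).
#'
#' @param x Predictor values (typically PPFD, µmol m⁻² s⁻¹).
#' @param y Response values.
#' @param form One of `"linear"`, `"quadratic"`, `"exponential_rise"`,
#'   `"sigmoid"`.
#' @return Object of class `response_curve` with `parameters` (tibble of
#'   `term`, `estimate`), `r_squared`, `form`, `n`, and the underlying fit.
#' @examples
#' x <- c(53, 128, 210, 281, 345, 410)
#' fit <- fit_response_curve(x, 340 * (1 - exp(-0.015 * x)), "exponential_rise")
#' fit$parameters
#' @export
fit_response_curve <- function(x, y,
                               form = c("linear", "quadratic",
                                        "exponential_rise", "sigmoid")) {
  form <- match.arg(form)
  n_par <- switch(form, linear = 2L, quadratic = 3L,
                  exponential_rise = 2L, sigmoid = 3L)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ## saturated fits (n == n_par) are allowed: a two-point line is the
  ## standard way to quote a slope from published endpoints
  if (length(x) < n_par) {
    abort(sprintf("form \"%s\" needs at least %d points", form, n_par))
  }
  d <- data.frame(x = x, y = y)
  sst <- sum((y - mean(y))^2)

  if (form %in% c("linear", "quadratic")) {
    fit <- if (form == "linear") lm(y ~ x, data = d)
           else lm(y ~ x + I(x^2), data = d)
    est <- coef(fit)
    terms <- if (form == "linear") c("intercept", "slope")
             else c("intercept", "slope", "quadratic")
    sse <- sum(stats::residuals(fit)^2)
  } else {
    formula <- if (form == "exponential_rise") y ~ A * (1 - exp(-k * x))
               else y ~ a / (1 + exp(-(x - x0) / b))
    starts <- if (form == "exponential_rise") {
      list(A = 1.05 * max(y), k = 1 / stats::median(x))
    } else {
      list(a = 1.05 * max(y), x0 = stats::median(x),
           b = (max(x) - min(x)) / 6)
    }
    lower <- setNames(rep(1e-12, length(starts)), names(starts))
    if (form == "sigmoid") lower["x0"] <- -Inf
    jit <- list(1, 0.5, 2, 0.2, 5, 1.5)
    fit <- NULL
    for (j in jit) {
      st <- purrr::map(starts, ~ .x * j)
      res <- tryCatch(
        minpack.lm::nlsLM(formula, data = d, start = st, lower = lower,
                          control = nls.control(maxiter = 200)),
        error = function(e) e)
      if (!inherits(res, "error")) { fit <- res; break }
    }
    if (is.null(fit)) {
      abort(sprintf("\"%s\" fit did not converge after bounded restarts", form),
            class = "canolux_fit_error")
    }
    est <- coef(fit)
    terms <- names(est)
    sse <- sum(stats::residuals(fit)^2)
  }

  r2 <- if (sst == 0) as.numeric(sse <= 1e-12) else 1 - sse / sst
  structure(
    list(form = form,
         parameters = tibble::tibble(term = terms, estimate = unname(est)),
         r_squared = r2, n = length(x), fit = fit),
    class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> form = %s (R^2 = %.4f, n = %d)\n",
              x$form, x$r_squared, x$n))
  print(x$parameters)
  invisible(x)
}

#' @export
coef.response_curve <- function(object, ...) {
  setNames(object$parameters$estimate, object$parameters$term)
}

#' @rdname fit_response_curve
#' @param x,object A `response_curve`.
#' @param ... Unused.
#' @export
tidy.response_curve <- function(x, ...) x$parameters

#' @rdname fit_response_curve
#' @export
glance.response_curve <- function(x, ...) {
  tibble::tibble(form = x$form, r.squared = x$r_squared, nobs = x$n)
}

#' Early-PCS vs final-dry-weight correlation
#'
#' Pearson correlation between projected canopy size early in the cycle and
#' dry weight at harvest, the basis for early growth screening.
#'
#' @param early Early-cycle PCS values (cm² per plant), one per unit.
#' @param final_dw Final dry weights (g per plant), paired with `early`.
#' @return One-row tibble `estimate` (R), `statistic`, `p.value`, `n`.
#' @export
early_pcs_correlation <- function(early, final_dw) {
  if (length(early) != length(final_dw)) abort("inputs must be paired")
  if (length(early) < 3L) abort("need at least 3 paired observations")
  if (sd(early) == 0 || sd(final_dw) == 0) {
    abort("zero variance: correlation undefined")
  }
  ct <- cor.test(early, final_dw, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 p.value = ct$p.value, n = length(early))
}

#' Per-species early-PCS screening correlation
#'
#' Looks up the fitted daily PCS at a species-specific early day (defaults:
#' mizuna day 8, lettuce day 10 after seeding) and correlates it with the
#' harvested dry weight across the units of each species.
#'
#' @param pcs_daily Daily PCS table from [predict_daily_all()].
#' @param harvest Harvest table with `species`, `ppfd`, `block`,
#'   `dry_weight_g`.
#' @param early_days Named vector of early days per species.
#' @return Tibble with one row per species: `species`, `early_day`,
#'   `estimate`, `p.value`, `n`.
#' @export
correlate_early_pcs <- function(pcs_daily, harvest,
                                early_days = c(mizuna = 8, lettuce = 10)) {
  keys <- c("species", "ppfd", "block")
  purrr::imap(early_days, function(ed, sp) {
    early <- pcs_daily |>
      dplyr::filter(species == sp, day == ed) |>
      dplyr::select(dplyr::all_of(keys), early_pcs_cm2 = pcs)
    joined <- dplyr::inner_join(early,
                                dplyr::filter(harvest, species == sp),
                                by = keys)
    if (nrow(joined) < 3L || sd(joined$early_pcs_cm2) == 0 ||
        sd(joined$dry_weight_g) == 0) {
      return(NULL)
    }
    res <- early_pcs_correlation(joined$early_pcs_cm2, joined$dry_weight_g)
    dplyr::mutate(res, species = sp, early_day = ed, .before = 1)
  }) |>
    dplyr::bind_rows()
}
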