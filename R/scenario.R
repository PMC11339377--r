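#' Catalogue of the seven counterfactual scenarios
#'
#' S1 baseline (2010 landscape, no loss applied); S2/S3 proactive new
#' reserves (redistributing vs retaining the existing estate); S4/S5
#' expedient new reserves (redistributing vs retaining); S6 existing
#' protected areas only, assumed fully effective; S7 business-as-usual
#' (existing estate present but ineffective -- modelled loss applies
#' everywhere).
#'
#' @return data.frame with one row per scenario: `id`, `label`, `mode`
#'   (`proactive`/`expedient`/`none`), `retain_existing_pas`,
#'   `add_new_reserves`, `pas_effective`.
#' @export
scenario_catalog <- function() {
  data.frame(
    id = 1:7,
    label = c("Baseline",
              "Proactive conservation redistributing PAs",
              "Proactive conservation maintaining PAs",
              "Expedient conservation redistributing PAs",
              "Expedient conservation maintaining PAs",
              "Existing PAs effective",
              "Business-as-usual"),
    mode = c("none", "proactive", "proactive", "expedient", "expedient",
             "none", "none"),
    retain_existing_pas = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
    add_new_reserves = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    pas_effective = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' Cells shielded from modelled forest loss under a scenario
#'
#' Baseline (S1) shields everything (no loss is applied at all);
#' business-as-usual (S7) shields nothing; S6 shields the existing estate;
#' redistribute scenarios (S2/S4) shield only the new reserves -- an
#' existing PA cell outside them is unprotected; retain scenarios (S3/S5)
#' shield the union of estate and new reserves.
#'
#' @param spec one row of [scenario_catalog()] (or a scenario id 1-7).
#' @param pa_mask 0/1 `grid_raster` of the existing estate.
#' @param new_reserves 0/1 `grid_raster` of newly selected reserves
#'   (required for S2-S5).
#' @return 0/1 `grid_raster` (1 = effectively protected).
#' @export
effective_protection_mask <- function(spec, pa_mask, new_reserves = NULL) {
  if (is.numeric(spec) && length(spec) == 1L)
    spec <- scenario_catalog()[spec, ]
  stopifnot(is.data.frame(spec), nrow(spec) == 1L, is_grid_raster(pa_mask))
  if (spec$add_new_reserves) {
    if (is.null(new_reserves))
      stop("scenario ", spec$id, " requires a new_reserves mask")
    check_aligned(pa_mask, new_reserves)
  }
  id <- spec$id
  vals <- if (id == 1L) {
    rep(1, length(pa_mask$values))
  } else if (id == 7L) {
    rep(0, length(pa_mask$values))
  } else if (id == 6L) {
    as.numeric(pa_mask$values > 0)
  } else if (spec$retain_existing_pas) {
    as.numeric(pa_mask$values > 0 | new_reserves$values > 0)
  } else {
    as.numeric(new_reserves$values > 0)
  }
  raster_like(pa_mask, vals)
}

#' Project landscape resistance under forest loss
#'
#' Unprotected cells gain the expected resistance increase of conversion to
#' the plantation/regrowth class: `r' = r + p * r_plantation`, the loss
#' probability times that class's resistance.  Protected cells keep their
#' baseline resistance.
#'
#' @param resistance baseline resistance `grid_raster` (>= 1).
#' @param risk loss-probability `grid_raster` in \[0, 1\].
#' @param plantation_resistance resistance of the conversion class.
#' @param protection_mask 0/1 `grid_raster` from
#'   [effective_protection_mask()].
#' @return projected resistance `grid_raster`.
#' @export
update_resistance <- function(resistance, risk, plantation_resistance,
                              protection_mask) {
  check_aligned(resistance, risk, protection_mask)
  if (any(raster_values(resistance) < 0)) stop("negative resistance")
  p <- raster_values(risk)
  if (any(p < 0 | p > 1)) stop("risk must lie in [0, 1]")
  unprot <- protection_mask$values == 0
  out <- resistance
  out$values <- resistance$values +
    risk$values * plantation_resistance * unprot
  out
}

#' Project carbon stocks under forest loss
#'
#' Expected remaining above-ground biomass: unprotected cells keep the
#' retained fraction `c' = c * (1 - p)`; protected cells keep their full
#' baseline stock.  `loss_model = "literal"` instead removes `c * (1 - p)`
#' (i.e. keeps `c * p`); it inverts the meaning of risk, rewarding
#' high-risk cells, and exists only to make the reading of the update rule
#' explicit and auditable -- the default is the expected-loss form.
#'
#' @param carbon baseline AGB `grid_raster` (Mg per cell, >= 0).
#' @param risk loss-probability `grid_raster` in \[0, 1\].
#' @param protection_mask 0/1 `grid_raster`.
#' @param loss_model `"expected"` (default) or `"literal"`.
#' @return projected carbon `grid_raster`.
#' @export
update_carbon <- function(carbon, risk, protection_mask,
                          loss_model = c("expected", "literal")) {
  loss_model <- match.arg(loss_model)
  check_aligned(carbon, risk, protection_mask)
  if (any(raster_values(carbon) < 0)) stop("negative carbon")
  p <- raster_values(risk)
  if (any(p < 0 | p > 1)) stop("risk must lie in [0, 1]")
  retained <- if (loss_model == "expected") 1 - risk$values else risk$values
  prot <- protection_mask$values > 0
  out <- carbon
  out$values <- carbon$values * ifelse(prot, 1, retained)
  out
}

#' Total carbon stock in gigatons
#'
#' @param carbon AGB `grid_raster` in Mg per cell.
#' @return total stock in Gt (1 Gt = 1e9 Mg).
#' @export
total_carbon <- function(carbon) {
  stopifnot(is_grid_raster(carbon))
  sum(raster_values(carbon)) / 1e9
}
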