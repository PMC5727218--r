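#' Per-cell Shannon diversity map over suitability surfaces
#'
#' For each cell, the K input surfaces' values s_i are turned into
#' proportions p_i = s_i / sum(s_j) (when `normalize_per_cell` is on; else
#' the s_i are used as given) and the Shannon index
#' H' = -sum(p_i * ln(p_i)), with 0 * ln 0 := 0, is computed. Cells where
#' the surfaces sum to less than `min_total` carry no usable signal and are
#' masked, as are cells masked in the inputs.
#'
#' @param surfaces list of >= 2 `suitability_map` objects on a common grid.
#' @param normalize_per_cell normalize p_i per cell so they sum to 1
#'   (default TRUE; with it H' is a true Shannon index bounded by ln K).
#' @param min_total cells whose total suitability falls below this are
#'   masked (default 1e-12).
#' @return a `diversity_map`: `values` matrix of H' (NA where masked),
#'   `taxa`, `normalized`, `min_total`, grid geometry.
#' @export
shannon_map <- function(surfaces, normalize_per_cell = TRUE,
                        min_total = 1e-12) {
  if (length(surfaces) < 2L)
    stop("Shannon diversity requires >= 2 surfaces")
  dims <- lapply(surfaces, function(s) dim(s$values))
  if (!all(vapply(dims, function(d) identical(d, dims[[1L]]), logical(1L))))
    stop("surfaces are on different grids")
  base_mask <- Reduce("&", lapply(surfaces, function(s) s$mask))
  S <- vapply(surfaces, function(s) as.vector(s$values),
              numeric(length(surfaces[[1L]]$values)))
  S[is.na(S)] <- 0
  tot <- rowSums(S)
  usable <- as.vector(base_mask) & tot >= min_total
  H <- rep(NA_real_, nrow(S))
  if (any(usable)) {
    P <- S[usable, , drop = FALSE]
    if (normalize_per_cell) P <- P / rowSums(P)
    Plog <- P * log(P)
    Plog[P == 0] <- 0
    H[usable] <- -rowSums(Plog)
  }
  taxa <- names(surfaces)
  if (is.null(taxa)) taxa <- paste0("surface", seq_along(surfaces))
  g <- surfaces[[1L]]
  structure(
    list(values = matrix(H, g$n_rows, g$n_cols), taxa = taxa,
         normalized = normalize_per_cell, min_total = min_total,
         mask = matrix(usable, g$n_rows, g$n_cols),
         n_rows = g$n_rows, n_cols = g$n_cols, xll = g$xll, yll = g$yll,
         cellsize = g$cellsize),
    class = "diversity_map")
}

#' Difference between two diversity maps (scenario minus current)
#'
#' Cellwise `scenario - current` wherever both maps carry signal, plus a
#' summary: the fraction of jointly unmasked cells where the scenario is
#' less diverse ("impoverished"), the fraction where it is more diverse, and
#' a tally of cells that lost all signal in the scenario ("lost cells").
#' The two maps must share grid, taxa list and normalization mode.
#'
#' @param current,scenario `diversity_map` objects.
#' @return list with `difference` (matrix), `impoverished_fraction`,
#'   `enriched_fraction`, `lost_cells`, `gained_cells`.
#' @export
diversity_difference <- function(current, scenario) {
  if (!identical(dim(current$values), dim(scenario$values)))
    stop("diversity maps are on different grids")
  if (!identical(sort(current$taxa), sort(scenario$taxa)))
    stop("diversity maps use different taxa lists")
  if (!identical(current$normalized, scenario$normalized))
    stop("diversity maps use different normalization modes")
  both <- current$mask & scenario$mask
  diff <- matrix(NA_real_, nrow(current$values), ncol(current$values))
  diff[both] <- scenario$values[both] - current$values[both]
  n_both <- sum(both)
  list(difference = diff,
       impoverished_fraction = if (n_both) sum(diff[both] < 0) / n_both else NA_real_,
       enriched_fraction = if (n_both) sum(diff[both] > 0) / n_both else NA_real_,
       lost_cells = sum(current$mask & !scenario$mask),
       gained_cells = sum(!current$mask & scenario$mask))
}

#' Write a diversity map as an ESRI ASCII grid with a JSON settings sidecar
#'
#' @param dmap a `diversity_map`.
#' @param path output `.asc` path; the sidecar is written at `<path>.json`.
#' @export
write_diversity <- function(dmap, path) {
  g <- env_grid(list(H = dmap$values), xll = dmap$xll, yll = dmap$yll,
                cellsize = dmap$cellsize, mask = dmap$mask)
  write_ascii_grid(g, "H", path)
  jsonlite::write_json(
    list(taxa = dmap$taxa, normalized = dmap$normalized,
         min_total = dmap$min_total),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
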