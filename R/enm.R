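#' Clean an occurrence table
#'
#' Collapses exact duplicate coordinates (one kept per taxon), removes
#' invalid coordinates, and — when reference points are supplied — removes
#' points farther than `max_km` from their reference (the georeferencing
#' plausibility screen: an occurrence must lie within `max_km`, default
#' 50 km, of its independently recorded reference location). Every rejection
#' is listed in the report; cleaning never errors.
#'
#' @param occ data.frame with `taxon`, `lon`, `lat`.
#' @param reference_points optional data.frame with `lon`, `lat`, one row per
#'   occurrence row, giving each point's reference location.
#' @param max_km maximum accepted distance to the reference (km).
#' @return list with `occurrences` (cleaned data.frame) and `report`
#'   (data.frame `taxon,lon,lat,reason` for every rejected row).
#' @export
clean_occurrences <- function(occ, reference_points = NULL, max_km = 50) {
  rej <- occ[0, c("taxon", "lon", "lat")]
  rej$reason <- character(0)
  keep <- rep(TRUE, nrow(occ))
  bad_coord <- !is.finite(occ$lon) | !is.finite(occ$lat) |
    abs(occ$lon) > 180 | abs(occ$lat) > 90
  if (any(bad_coord)) {
    rej <- rbind(rej, cbind(occ[bad_coord, c("taxon", "lon", "lat")],
                            reason = "invalid coordinate"))
    keep[bad_coord] <- FALSE
  }
  if (!is.null(reference_points)) {
    if (nrow(reference_points) != nrow(occ))
      stop("reference_points must have one row per occurrence")
    ok <- which(keep)
    d <- haversine_km(occ$lon[ok], occ$lat[ok],
                      reference_points$lon[ok], reference_points$lat[ok])
    far <- ok[d > max_km]
    if (length(far)) {
      rej <- rbind(rej, cbind(occ[far, c("taxon", "lon", "lat")],
                              reason = sprintf("farther than %g km from reference", max_km)))
      keep[far] <- FALSE
    }
  }
  kept <- occ[keep, , drop = FALSE]
  dup <- duplicated(kept[, c("taxon", "lon", "lat")])
  if (any(dup))
    rej <- rbind(rej, cbind(kept[dup, c("taxon", "lon", "lat")],
                            reason = "duplicate coordinate"))
  kept <- kept[!dup, , drop = FALSE]
  rownames(kept) <- NULL; rownames(rej) <- NULL
  list(occurrences = kept, report = rej)
}

#' Solve the penalized maximum-entropy fit on an explicit feature matrix
#'
#' Core convex solver behind [fit_maxent()]. Maximizes the penalized
#' presence log-likelihood of the Gibbs distribution q(x) proportional to
#' exp(w . f(x)) over a background sample:
#' mean presence score - log sum(exp(w . f)) over background - sum(beta_j |w_j|).
#' The L1 penalty is handled exactly by splitting w = u - v with u, v >= 0
#' and running L-BFGS-B on the smooth objective plus the linear penalty.
#' Convergence is verified against the KKT conditions
#' |presence mean_j - model expectation_j| <= beta_j + tol for every feature.
#'
#' @param F_bg background feature matrix (cells x features).
#' @param presence_means empirical mean of each feature over presences.
#' @param beta non-negative penalty per feature (recycled).
#' @param tol KKT tolerance (default 1e-6).
#' @param max_restarts optimizer restarts before declaring non-convergence.
#' @return list with `weights`, `kkt_gap` (per-feature |gap| - beta, capped
#'   at 0 from below), `log_normalizer`.
#' @export
maxent_solve <- function(F_bg, presence_means, beta = 0, tol = 1e-6,
                         max_restarts = 5L) {
  F_bg <- as.matrix(F_bg)
  p <- ncol(F_bg)
  stopifnot(length(presence_means) == p)
  beta <- rep_len(beta, p)
  if (any(beta < 0)) stop("beta must be non-negative")
  obj <- function(uv) {
    w <- uv[1:p] - uv[(p + 1):(2 * p)]
    s <- drop(F_bg %*% w)
    m <- max(s)
    lz <- m + log(sum(exp(s - m)))
    -sum(presence_means * w) + lz + sum(beta * uv)
  }
  grad <- function(uv) {
    w <- uv[1:p] - uv[(p + 1):(2 * p)]
    s <- drop(F_bg %*% w)
    m <- max(s)
    q <- exp(s - m); q <- q / sum(q)
    eq <- drop(crossprod(F_bg, q))
    g <- eq - presence_means
    c(g + beta, -g + beta)
  }
  start <- rep(0, 2 * p)
  for (r in seq_len(max_restarts)) {
    fit <- stats::optim(start, obj, grad, method = "L-BFGS-B",
                        lower = rep(0, 2 * p),
                        control = list(maxit = 2000L, factr = 1e1, pgtol = 0))
    uv <- fit$par
    w <- uv[1:p] - uv[(p + 1):(2 * p)]
    s <- drop(F_bg %*% w)
    m <- max(s)
    q <- exp(s - m); q <- q / sum(q)
    eq <- drop(crossprod(F_bg, q))
    gap <- abs(presence_means - eq) - beta
    # active weights must satisfy the moment condition to tol; inactive ones
    # may sit strictly inside the subgradient interval
    viol <- pmax(gap, 0)
    viol[w == 0] <- pmax(gap[w == 0], 0)
    if (max(viol) <= tol) {
      lz <- m + log(sum(exp(s - m)))
      return(list(weights = w, kkt_gap = viol, log_normalizer = lz))
    }
    start <- uv + stats::runif(2 * p, 0, 1e-3)
  }
  stop(sprintf("maxent solver failed to reach KKT tolerance %g (last gap %g)",
               tol, max(pmax(gap, 0))))
}

# standardized linear + quadratic features from raw layer values. Layers are
# standardized first and the quadratic term is the square of the standardized
# value (itself re-standardized), so the feature basis — and hence the L1
# penalty — is invariant to positive affine rescaling of the inputs.
maxent_features <- function(raw, constants = NULL) {
  raw <- as.matrix(raw)
  if (is.null(constants)) {
    mu <- colMeans(raw)
    sdv <- apply(raw, 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    z <- sweep(sweep(raw, 2L, mu), 2L, sdv, "/")
    q <- z^2
    qmu <- colMeans(q)
    qsd <- apply(q, 2L, stats::sd)
    qsd[qsd == 0 | !is.finite(qsd)] <- 1
    constants <- list(mean = mu, sd = sdv, qmean = qmu, qsd = qsd)
  }
  z <- sweep(sweep(raw, 2L, constants$mean), 2L, constants$sd, "/")
  q <- sweep(sweep(z^2, 2L, constants$qmean), 2L, constants$qsd, "/")
  list(features = cbind(z, q), constants = constants)
}

#' Fit a maximum-entropy presence-background niche model
#'
#' Features are linear and quadratic terms per layer, standardized with
#' constants computed on the training background (stored in the model so
#' projection is reproducible). Regularization is
#' `beta_j = reg_multiplier * sd(feature_j over background) / sqrt(n_presences)`;
#' on standardized features the background sd is 1, so the penalty reduces to
#' `reg_multiplier / sqrt(n)`. The background is a seeded uniform sample of
#' unmasked cells without replacement (all cells when fewer than
#' `background_size`).
#'
#' @param env training `env_grid`.
#' @param presences occurrence data.frame (`lon`, `lat`), already cleaned.
#' @param background_size background sample size (default 10000, capped at
#'   the number of unmasked cells).
#' @param reg_multiplier L1 regularization multiplier (default 1).
#' @param seed integer seed for the background sample.
#' @return a `maxent_model`: layer names, standardization constants, weights,
#'   per-feature beta, background cell indices and the training grid
#'   signature.
#' @export
fit_maxent <- function(env, presences, background_size = 10000L,
                       reg_multiplier = 1, seed = 1L) {
  stopifnot(inherits(env, "env_grid"))
  n_pres <- nrow(presences)
  if (n_pres < 5L) stop("need >= 5 presence points")
  ext <- extract_cell_values(env, presences$lon, presences$lat)
  if (any(ext$masked)) stop("presence point(s) fall in masked cells")
  cell_id <- (ext$cell$col - 1L) * env$n_rows + ext$cell$row
  if (length(unique(cell_id)) < 2L)
    stop("degenerate likelihood: all presences in one cell")
  land <- which(env$mask)
  bg_size <- min(background_size, length(land))
  if (background_size > length(land))
    bg_size <- length(land)
  set.seed(as.integer(seed))
  bg_cells <- if (bg_size == length(land)) land else
    sort(sample(land, bg_size))
  raw_bg <- vapply(env$layers, function(m) m[bg_cells], numeric(bg_size))
  mf <- maxent_features(raw_bg)
  pres_feat <- maxent_features(ext$values, mf$constants)$features
  presence_means <- colMeans(pres_feat)
  beta <- reg_multiplier * apply(mf$features, 2L, stats::sd) / sqrt(n_pres)
  sol <- maxent_solve(mf$features, presence_means, beta)
  feat_names <- c(names(env$layers), paste0(names(env$layers), "^2"))
  structure(
    list(layer_names = names(env$layers), feature_names = feat_names,
         constants = mf$constants, weights = sol$weights, beta = beta,
         kkt_gap = sol$kkt_gap, background_cells = bg_cells,
         n_presences = n_pres, reg_multiplier = reg_multiplier,
         seed = as.integer(seed)),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d layers, %d features, %d presences, %d background cells\n",
              length(x$layer_names), length(x$weights), x$n_presences,
              length(x$background_cells)))
  nz <- sum(x$weights != 0)
  cat(sprintf("  %d non-zero weights, max KKT gap %.2e\n", nz, max(x$kkt_gap)))
  invisible(x)
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model a `maxent_model`.
#' @param path JSON file path.
#' @export
write_maxent_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$constants <- list(mean = as.numeric(m$constants$mean),
                      sd = as.numeric(m$constants$sd),
                      qmean = as.numeric(m$constants$qmean),
                      qsd = as.numeric(m$constants$qsd))
  class(m) <- "maxent_model"
  m
}

#' Project a fitted model onto an environmental grid
#'
#' Applies the stored standardization and weights to the target grid's
#' layers. Raw mode renormalizes the exponential scores over the target
#' grid's unmasked cells, so the map sums to one there. Layers present in
#' the target but unused by the model are ignored with a warning; a missing
#' model layer is an error naming it.
#'
#' @param model a `maxent_model`.
#' @param env target `env_grid` (must supply every model layer).
#' @param mode `"raw"` (sums to 1 over unmasked cells) or `"minmax"` (simple
#'   min-max display rescale of the raw map to \[0, 1\]; a display transform,
#'   not a probability of presence).
#' @return a `suitability_map`: list with `values` matrix, `mode`, `mask`,
#'   and grid geometry fields.
#' @export
project_model <- function(model, env, mode = c("raw", "minmax")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "maxent_model"), inherits(env, "env_grid"))
  missing_layers <- setdiff(model$layer_names, names(env$layers))
  if (length(missing_layers))
    stop("target grid is missing model layer(s): ",
         paste(missing_layers, collapse = ", "))
  extra <- setdiff(names(env$layers), model$layer_names)
  if (length(extra))
    warning("ignoring layer(s) not used by the model: ",
            paste(extra, collapse = ", "))
  land <- which(env$mask)
  raw <- vapply(model$layer_names, function(nm) env$layers[[nm]][land],
                numeric(length(land)))
  if (length(land) == 1L) raw <- matrix(raw, nrow = 1L)
  Fs <- maxent_features(raw, model$constants)$features
  s <- drop(Fs %*% model$weights)
  s <- s - max(s)
  q <- exp(s)
  vals <- matrix(NA_real_, env$n_rows, env$n_cols)
  if (mode == "raw") {
    vals[land] <- q / sum(q)
  } else {
    rng <- range(q)
    vals[land] <- if (rng[2] > rng[1]) (q - rng[1]) / (rng[2] - rng[1]) else 1
  }
  structure(list(values = vals, mode = mode, mask = env$mask,
                 n_rows = env$n_rows, n_cols = env$n_cols, xll = env$xll,
                 yll = env$yll, cellsize = env$cellsize),
            class = "suitability_map")
}

# per-point model score (unnormalized log-suitability) at lon/lat locations
model_scores <- function(model, env, lon, lat) {
  ext <- extract_cell_values(env, lon, lat)
  Fs <- maxent_features(ext$values, model$constants)$features
  drop(Fs %*% model$weights)
}

#' Rank-based AUC of presence vs background scores
#'
#' Mann-Whitney probability that a random presence outscores a random
#' background point, ties counted 0.5.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_scores <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n0 <- length(background_scores)
  if (n1 == 0L || n0 == 0L) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Training AUC of a fitted model
#'
#' Scores the presences and the model's background sample on the training
#' grid and applies [auc_scores()].
#'
#' @param model a `maxent_model`.
#' @param env the training `env_grid`.
#' @param presences data.frame with `lon`, `lat`.
#' @return AUC in \[0, 1\].
#' @export
auc_maxent <- function(model, env, presences) {
  ps <- model_scores(model, env, presences$lon, presences$lat)
  land_raw <- vapply(model$layer_names,
                     function(nm) env$layers[[nm]][model$background_cells],
                     numeric(length(model$background_cells)))
  Fs <- maxent_features(land_raw, model$constants)$features
  bs <- drop(Fs %*% model$weights)
  auc_scores(ps, bs)
}

#' Permutation importance of each layer
#'
#' For each layer, its values are permuted jointly across the presence and
#' background evaluation points, the fixed model is re-scored and the AUC
#' drop recorded; the importance is the mean drop over `n_reps`, floored at
#' zero, then normalized so the importances sum to 100 (an all-zero vector
#' is returned when no layer produces a positive drop).
#'
#' @param model a `maxent_model`.
#' @param env the evaluation `env_grid`.
#' @param presences data.frame with `lon`, `lat`.
#' @param n_reps permutation replicates per layer (default 10).
#' @param seed integer seed.
#' @return named numeric vector of percentages summing to 100 (or all 0).
#' @export
permutation_importance <- function(model, env, presences, n_reps = 10L,
                                   seed = 1L) {
  stopifnot(n_reps >= 1L)
  ext_p <- extract_cell_values(env, presences$lon, presences$lat)
  raw_p <- ext_p$values[, model$layer_names, drop = FALSE]
  raw_b <- vapply(model$layer_names,
                  function(nm) env$layers[[nm]][model$background_cells],
                  numeric(length(model$background_cells)))
  raw_all <- rbind(raw_p, raw_b)
  n_p <- nrow(raw_p)
  idx_p <- seq_len(n_p)
  score_all <- function(raw) {
    Fs <- maxent_features(raw, model$constants)$features
    drop(Fs %*% model$weights)
  }
  s0 <- score_all(raw_all)
  auc0 <- auc_scores(s0[idx_p], s0[-idx_p])
  set.seed(as.integer(seed))
  drops <- numeric(length(model$layer_names))
  names(drops) <- model$layer_names
  for (l in seq_along(model$layer_names)) {
    d <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      perm <- raw_all
      perm[, l] <- perm[sample(nrow(perm)), l]
      s <- score_all(perm)
      d[r] <- auc0 - auc_scores(s[idx_p], s[-idx_p])
    }
    drops[l] <- max(mean(d), 0)
  }
  tot <- sum(drops)
  if (tot == 0) return(drops)
  100 * drops / tot
}

#' Write a suitability map as an ESRI ASCII grid
#'
#' @param map a `suitability_map`.
#' @param path output path.
#' @export
write_suitability <- function(map, path) {
  g <- env_grid(list(suitability = map$values), xll = map$xll, yll = map$yll,
                cellsize = map$cellsize, mask = map$mask)
  write_ascii_grid(g, "suitability", path)
}
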