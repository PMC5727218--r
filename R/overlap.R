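# shared guard: two raw suitability maps on the same grid/mask
check_pair <- function(qA, qB) {
  if (!identical(dim(qA$values), dim(qB$values)))
    stop("suitability maps are on different grids")
  if (!identical(qA$mask, qB$mask))
    stop("suitability maps have different masks")
  if (!identical(qA$mode, "raw") || !identical(qB$mode, "raw"))
    stop("overlap metrics require raw-normalized maps")
  invisible(TRUE)
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|qA - qB|)` over unmasked cells of two raw-normalized
#' suitability maps. Symmetric; 1 for identical maps, 0 for disjoint
#' supports.
#'
#' @param qA,qB `suitability_map` objects in raw mode on the same grid.
#' @return D in \[0, 1\].
#' @export
schoener_D <- function(qA, qB) {
  check_pair(qA, qB)
  land <- which(qA$mask)
  d <- 1 - 0.5 * sum(abs(qA$values[land] - qB$values[land]))
  min(max(d, 0), 1)
}

#' Hellinger-based I niche overlap
#'
#' `I = 1 - 0.5 * sum((sqrt(qA) - sqrt(qB))^2)` over unmasked cells.
#' Symmetric; 1 for identical maps, 0 for disjoint supports.
#'
#' @inheritParams schoener_D
#' @return I in \[0, 1\].
#' @export
hellinger_I <- function(qA, qB) {
  check_pair(qA, qB)
  land <- which(qA$mask)
  i <- 1 - 0.5 * sum((sqrt(qA$values[land]) - sqrt(qB$values[land]))^2)
  min(max(i, 0), 1)
}

#' Gaussian-filtered background density from occurrence points
#'
#' Kernel-density surface over unmasked cells: each cell's density is the
#' sum of Gaussian kernels (in great-circle distance) centred on the
#' occurrence points, normalized to sum to 1. This is the sampling density
#' used to draw pseudo-occurrences in the background similarity test.
#'
#' @param points data.frame with `lon`, `lat` (>= 1 row).
#' @param env an `env_grid`.
#' @param bandwidth_km Gaussian kernel bandwidth in km (default 200).
#' @return matrix of per-cell densities (NA on masked cells) summing to 1.
#' @export
gaussian_background <- function(points, env, bandwidth_km = 200) {
  if (nrow(points) < 1L) stop("need >= 1 occurrence point")
  if (bandwidth_km <= 0) stop("bandwidth must be > 0")
  land <- which(env$mask)
  rc <- arrayInd(land, dim(env$mask))
  cc <- cell_centers(env)
  cl <- cc$lon[rc[, 2L]]
  ct <- cc$lat[rc[, 1L]]
  d <- haversine_matrix(cl, ct, points$lon, points$lat)
  dens <- rowSums(exp(-(d / bandwidth_km)^2 / 2))
  tot <- sum(dens)
  if (tot == 0 || !is.finite(tot))
    stop("background density has no mass on unmasked cells")
  out <- matrix(NA_real_, env$n_rows, env$n_cols)
  out[land] <- dens / tot
  out
}

# draw n pseudo-occurrence points from a per-cell density, jittered in-cell
sample_from_density <- function(density, env, n) {
  land <- which(env$mask & !is.na(density))
  cells <- sample(land, n, replace = TRUE, prob = density[land])
  rc <- arrayInd(cells, dim(density))
  u <- stats::runif(n); v <- stats::runif(n)
  data.frame(
    lon = env$xll + (rc[, 2L] - 1L + u) * env$cellsize,
    lat = pmin(env$yll + (env$n_rows - rc[, 1L] + v) * env$cellsize,
               env$yll + env$n_rows * env$cellsize - 1e-9))
}

#' Background-randomization niche similarity test
#'
#' Compares the observed overlap (D and I) of two taxa's fitted niche models
#' with null distributions built by replacing one taxon's occurrences with
#' the same number of points drawn from its Gaussian-filtered background
#' density, refitting, and recomputing the overlap against the other taxon's
#' observed model. Both directions are always run. The verdict per metric
#' and direction is two-sided at level `alpha`: "similar" when the observed
#' value exceeds the upper `1 - alpha/2` null quantile, "divergent" below
#' the `alpha/2` quantile, otherwise "ns". A refit failure within an
#' iteration is retried with a fresh draw up to 3 times, then recorded as
#' `NA` and counted in the report.
#'
#' @param occA,occB occurrence data.frames (`lon`, `lat`) for taxa A and B.
#' @param env the `env_grid` both models are fitted on.
#' @param n_iterations null draws per direction (default 100).
#' @param alpha two-sided test level (default 0.05).
#' @param seed integer seed.
#' @param bandwidth_km background kernel bandwidth (default 200 km).
#' @param background_size,reg_multiplier passed to [fit_maxent()].
#' @return an `overlap_result` list: observed `D` and `I`, `null` (named list
#'   per direction with `D` and `I` vectors of length `n_iterations`),
#'   `verdict` (data.frame), `n_failed` per direction, and the settings used.
#' @export
background_similarity_test <- function(occA, occB, env, n_iterations = 100L,
                                       alpha = 0.05, seed = 1L,
                                       bandwidth_km = 200,
                                       background_size = 10000L,
                                       reg_multiplier = 1) {
  fit_map <- function(occ, fit_seed) {
    m <- fit_maxent(env, occ, background_size = background_size,
                    reg_multiplier = reg_multiplier, seed = fit_seed)
    project_model(m, env)
  }
  mapA <- fit_map(occA, seed)
  mapB <- fit_map(occB, seed)
  D_obs <- schoener_D(mapA, mapB)
  I_obs <- hellinger_I(mapA, mapB)
  bgA <- gaussian_background(occA, env, bandwidth_km)
  bgB <- gaussian_background(occB, env, bandwidth_km)
  set.seed(as.integer(seed))
  run_direction <- function(obs_map, null_bg, n_null) {
    D0 <- rep(NA_real_, n_iterations); I0 <- rep(NA_real_, n_iterations)
    failed <- 0L
    for (it in seq_len(n_iterations)) {
      ok <- FALSE
      for (try in 1:3) {
        pts <- sample_from_density(null_bg, env, n_null)
        res <- tryCatch({
          nm <- fit_map(pts, sample.int(.Machine$integer.max, 1L))
          list(D = schoener_D(obs_map, nm), I = hellinger_I(obs_map, nm))
        }, error = function(e) NULL)
        if (!is.null(res)) { ok <- TRUE; break }
      }
      if (ok) { D0[it] <- res$D; I0[it] <- res$I } else failed <- failed + 1L
    }
    list(D = D0, I = I0, failed = failed)
  }
  # direction 1: B's occurrences replaced by draws from B's background,
  # compared against A's observed model; direction 2 mirrors it
  dir1 <- run_direction(mapA, bgB, nrow(occB))
  dir2 <- run_direction(mapB, bgA, nrow(occA))
  verdict_of <- function(obs, null_vec) {
    nv <- null_vec[!is.na(null_vec)]
    if (!length(nv)) return("ns")
    lo <- stats::quantile(nv, alpha / 2, names = FALSE)
    hi <- stats::quantile(nv, 1 - alpha / 2, names = FALSE)
    if (obs > hi) "similar" else if (obs < lo) "divergent" else "ns"
  }
  verdict <- data.frame(
    direction = rep(c("A_vs_B_background", "B_vs_A_background"), each = 2L),
    metric = rep(c("D", "I"), 2L),
    observed = c(D_obs, I_obs, D_obs, I_obs),
    verdict = c(verdict_of(D_obs, dir1$D), verdict_of(I_obs, dir1$I),
                verdict_of(D_obs, dir2$D), verdict_of(I_obs, dir2$I)),
    stringsAsFactors = FALSE)
  structure(
    list(D = D_obs, I = I_obs,
         null = list(A_vs_B_background = list(D = dir1$D, I = dir1$I),
                     B_vs_A_background = list(D = dir2$D, I = dir2$I)),
         verdict = verdict,
         n_failed = c(A_vs_B_background = dir1$failed,
                      B_vs_A_background = dir2$failed),
         settings = list(n_iterations = n_iterations, alpha = alpha,
                         seed = as.integer(seed), bandwidth_km = bandwidth_km,
                         background_size = background_size,
                         reg_multiplier = reg_multiplier)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: D = %.4f, I = %.4f (%d null iterations/direction)\n",
              x$D, x$I, x$settings$n_iterations))
  print(x$verdict)
  invisible(x)
}
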