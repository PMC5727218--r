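make_env <- function(seed = 1, nr = 20, nc = 20, n_layers = 3,
                     autocorr = 3) {
  gen_env_layers(sim_config(seed = seed, grid_rows = nr, grid_cols = nc,
                            n_layers = n_layers, autocorr_range = autocorr))
}

test_that("occurrence cleaning collapses duplicates and reports every rejection", {
  occ <- data.frame(taxon = "t", lon = c(10, 10, 11, 12, 200),
                    lat = c(40, 40, 41, 95, 42))
  out <- clean_occurrences(occ)
  expect_equal(nrow(out$occurrences), 2)   # dup collapsed, 2 invalid dropped
  expect_setequal(out$report$reason,
                  c("invalid coordinate", "duplicate coordinate"))
  expect_equal(nrow(out$report), 3)
})

test_that("cleaning enforces the maximum distance to reference points", {
  # ~0.54 km per 0.01 deg lat at the equator: build 40 km and 60 km offsets
  d40 <- 40 / 111.19
  d60 <- 60 / 111.19
  occ <- data.frame(taxon = "t", lon = c(0, 0), lat = c(d40, d60))
  ref <- data.frame(lon = c(0, 0), lat = c(0, 0))
  expect_equal(haversine_km(0, 0, 0, d40), 40, tolerance = 0.01)
  out <- clean_occurrences(occ, reference_points = ref, max_km = 50)
  expect_equal(nrow(out$occurrences), 1)
  expect_equal(out$occurrences$lat, d40)
  expect_match(out$report$reason, "50")
})

test_that("single binary feature fit matches the analytic moment condition", {
  # presence mean 0.8; background has the feature in exactly half its cells:
  # e^w / (e^w + 1) = 0.8  =>  w = ln 4
  F_bg <- matrix(c(rep(1, 100), rep(0, 100)), ncol = 1)
  sol <- maxent_solve(F_bg, presence_means = 0.8, beta = 0)
  expect_equal(sol$weights, log(4), tolerance = 1e-6)
  expect_lte(max(sol$kkt_gap), 1e-6)
})

test_that("all-zero weights give a uniform raw map", {
  env <- make_env(2)
  o <- gen_occurrences(env$current, c(1, 0, 0), 100, seed = 3)
  m <- fit_maxent(env$current, o$occurrences, seed = 4)
  m$weights[] <- 0
  map <- project_model(m, env$current)
  N <- sum(env$current$mask)
  expect_equal(unique(round(map$values[env$current$mask], 15)), 1 / N)
  expect_equal(sum(map$values, na.rm = TRUE), 1, tolerance = 1e-9)
})

test_that("fitted models satisfy the KKT moment conditions within beta + tolerance", {
  for (s in 1:3) {
    env <- make_env(s, n_layers = 2)
    o <- gen_occurrences(env$current, rnorm(2), 80, seed = s + 10)
    m <- fit_maxent(env$current, o$occurrences, seed = s)
    expect_lte(max(m$kkt_gap), 1e-6)
    map <- project_model(m, env$current)
    expect_equal(sum(map$values, na.rm = TRUE), 1, tolerance = 1e-9)
  }
})

test_that("coefficient signs are recovered on synthetic occurrences (50 seeds)", {
  env <- make_env(7, nr = 25, nc = 25, n_layers = 2)
  hits <- 0
  for (s in 1:50) {
    beta_true <- sample(c(-1.5, 1.5), 2, replace = TRUE) *
      runif(2, 1, 2)  # |beta| >= 1 throughout
    o <- gen_occurrences(env$current, beta_true, 200, seed = 1000 + s)
    m <- fit_maxent(env$current, o$occurrences, seed = s)
    w_lin <- m$weights[1:2]
    if (all(sign(w_lin) == sign(beta_true))) hits <- hits + 1
  }
  expect_gte(hits, 45)  # >= 90% of 50 seeds
})

test_that("fit is invariant to affine rescaling of input layers", {
  env <- make_env(5, n_layers = 2)
  o <- gen_occurrences(env$current, c(2, -1), 120, seed = 6)
  m1 <- fit_maxent(env$current, o$occurrences, seed = 7)
  env2 <- env$current
  env2$layers[[1]] <- env2$layers[[1]] * 37 + 5
  env2$layers[[2]] <- env2$layers[[2]] * 0.01 - 42
  m2 <- fit_maxent(env2, o$occurrences, seed = 7)
  expect_equal(m1$weights, m2$weights, tolerance = 1e-4)
})

test_that("degenerate fits are rejected", {
  env <- make_env(8, n_layers = 1)
  occ1 <- data.frame(taxon = "t", lon = rep(20.1, 6), lat = rep(30.1, 6))
  expect_error(fit_maxent(env$current, occ1, seed = 1), "one cell")
  expect_error(fit_maxent(env$current, occ1[1:3, ], seed = 1), ">= 5")
})

test_that("projection reproduces training suitability and reacts to shifted layers", {
  env <- make_env(9, n_layers = 2)
  o <- gen_occurrences(env$current, c(2, 0), 150, seed = 10)
  m <- fit_maxent(env$current, o$occurrences, background_size = 1e6, seed = 11)
  map1 <- project_model(m, env$current)
  map2 <- project_model(m, env$current)
  expect_identical(map1$values, map2$values)
  # analytic direction check: keep only the linear weight on layer 1 and
  # raise layer 1 in a single cell; that cell's renormalized suitability
  # must move with the weight's sign while all other cells move against it
  m_lin <- m
  m_lin$weights[] <- 0
  m_lin$weights[1] <- 1.2
  base <- project_model(m_lin, env$current)
  env_up <- env$current
  cell <- c(5, 5)
  env_up$layers[[1]][cell[1], cell[2]] <-
    env_up$layers[[1]][cell[1], cell[2]] + 1
  up <- project_model(m_lin, env_up)
  expect_gt(up$values[cell[1], cell[2]], base$values[cell[1], cell[2]])
  expect_true(all(up$values[-((cell[2] - 1) * nrow(base$values) + cell[1])] <=
                  base$values[-((cell[2] - 1) * nrow(base$values) + cell[1])]))
  m_neg <- m_lin
  m_neg$weights[1] <- -1.2
  base_n <- project_model(m_neg, env$current)
  up_n <- project_model(m_neg, env_up)
  expect_lt(up_n$values[cell[1], cell[2]], base_n$values[cell[1], cell[2]])
  # missing layer errors by name; extra layers warn and are ignored
  env_missing <- env$current
  env_missing$layers[["BIO2"]] <- NULL
  expect_error(project_model(m, env_missing), "BIO2")
  env_extra <- env$current
  env_extra$layers[["JUNK"]] <- env_extra$layers[[1]]
  expect_warning(mapx <- project_model(m, env_extra), "JUNK")
  expect_equal(mapx$values, map1$values)
})

test_that("model JSON serialization round-trips projection exactly", {
  env <- make_env(12, n_layers = 2)
  o <- gen_occurrences(env$current, c(1, -1), 80, seed = 13)
  m <- fit_maxent(env$current, o$occurrences, seed = 14)
  f <- withr::local_tempfile(fileext = ".json")
  write_maxent_model(m, f)
  m2 <- read_maxent_model(f)
  expect_equal(project_model(m2, env$current)$values,
               project_model(m, env$current)$values)
})

test_that("AUC is the tie-aware Mann-Whitney probability", {
  # brute force over all 6 presence/background pairs: wins 5, ties 1
  expect_equal(auc_scores(c(0.9, 0.8), c(0.7, 0.8, 0.1)), 5.5 / 6)
  expect_equal(auc_scores(c(3, 4), c(1, 2)), 1.0)
  expect_equal(auc_scores(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_error(auc_scores(numeric(0), 1), "non-empty")
})

test_that("permutation importance isolates the informative layer and sums to 100", {
  env <- make_env(15, nr = 25, nc = 25, n_layers = 2)
  hits <- 0
  for (s in 1:20) {
    o <- gen_occurrences(env$current, c(2.5, 0), 250, seed = 2000 + s)
    m <- fit_maxent(env$current, o$occurrences, seed = s)
    imp <- permutation_importance(m, env$current, o$occurrences,
                                  n_reps = 10, seed = s)
    expect_equal(sum(imp), 100, tolerance = 1e-6)
    if (imp[1] > 90 && imp[2] < 10) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of 20 seeds
})

test_that("permuting a constant layer produces zero drop", {
  env <- make_env(16, n_layers = 2)
  env$current$layers[[2]][] <- 1.7
  o <- gen_occurrences(env$current, c(2, 0), 100, seed = 17)
  m <- fit_maxent(env$current, o$occurrences, seed = 18)
  imp <- permutation_importance(m, env$current, o$occurrences,
                                n_reps = 5, seed = 19)
  expect_equal(unname(imp[2]), 0)
})
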