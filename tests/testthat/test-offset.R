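test_that("I-spline basis is monotone between 0 and 1", {
  kn <- c(0, 0.4, 1)
  expect_equal(unname(ispline_basis(0, kn)), matrix(0, 1, 3),
               ignore_attr = TRUE)
  expect_equal(unname(ispline_basis(1, kn)[1, ]), c(1, 1, 1))
  xs <- seq(0, 1, length.out = 400)
  B <- ispline_basis(xs, kn)
  expect_true(all(B >= -1e-12 & B <= 1 + 1e-12))
  # numeric derivative non-negative everywhere
  expect_true(all(diff(B[, 1]) >= -1e-10))
  expect_true(all(diff(B[, 2]) >= -1e-10))
  expect_true(all(diff(B[, 3]) >= -1e-10))
  # continuity across the middle knot
  eps <- 1e-9
  expect_equal(ispline_basis(0.4 - eps, kn)[1, ],
               ispline_basis(0.4 + eps, kn)[1, ], tolerance = 1e-6)
  expect_warning(ispline_basis(2, kn), "clamped")
  expect_error(ispline_basis(0.5, c(0, 0, 1)), "strictly increasing")
})

test_that("GDM fitting recovers a known monotone model", {
  set.seed(5)
  n_sites <- 10
  x1 <- runif(2 * n_sites); x2 <- runif(2 * n_sites)
  pr <- t(combn(2 * n_sites, 2))[sample(choose(2 * n_sites, 2), 45), ]
  kn1 <- c(0, 0.5, 1)
  f1 <- function(x) ispline_basis(x, kn1) %*% c(0.8, 0.5, 0.3)
  f2 <- function(x) ispline_basis(x, kn1) %*% c(0.2, 0.4, 0.1)
  eta <- abs(f1(x1[pr[, 1]]) - f1(x1[pr[, 2]])) +
    abs(f2(x2[pr[, 1]]) - f2(x2[pr[, 2]]))
  d <- pmin(pmax(1 - exp(-eta) + rnorm(45, 0, 0.02), 0), 0.97)
  env_i <- cbind(p1 = x1[pr[, 1]], p2 = x2[pr[, 1]])
  env_j <- cbind(p1 = x1[pr[, 2]], p2 = x2[pr[, 2]])
  m <- gdm_fit(d, env_i, env_j)
  expect_true(all(coef(m) >= 0))
  # fitted eta tracks the generating eta
  expect_gte(cor(m$fitted_eta, as.numeric(eta)), 0.98)
  # recovered f1 close to truth over the training range (sup norm)
  xs <- seq(min(x1), max(x1), length.out = 50)
  f1_hat <- suppressWarnings(
    ispline_basis(xs, m$knots[["p1"]]) %*% m$coef[["p1"]])
  shift <- function(v) v - v[1]
  expect_lt(max(abs(shift(as.numeric(f1_hat)) -
                      shift(as.numeric(f1(xs))))), 0.05 + m$intercept)
  # zero response gives the null model
  m0 <- gdm_fit(rep(0, 45), env_i, env_j)
  expect_equal(unname(coef(m0)), rep(0, length(coef(m0))))
  # permuting pair order leaves coefficients unchanged
  pm <- sample(45)
  m2 <- gdm_fit(d[pm], env_i[pm, ], env_j[pm, ])
  expect_equal(coef(m2), coef(m), tolerance = 1e-8)
  expect_error(gdm_fit(c(d[-1], 1), env_i, env_j), "0, 1")
})

test_that("predictions follow the negative-exponential link exactly", {
  # two-coefficient toy model checked by hand
  env_i <- cbind(p = c(0, 1, 0.5))
  env_j <- cbind(p = c(0, 0, 0.5))
  d_train <- c(0, 0.6, 0)
  m <- gdm_fit(d_train, env_i, env_j)
  # hand-computed eta for a fresh pair
  a <- 0.9; b <- 0.1
  WA <- relictpop:::.gdm_transform(m, cbind(p = a))
  WB <- relictpop:::.gdm_transform(m, cbind(p = b))
  eta_hand <- m$intercept + sum(abs(WA - WB))
  expect_equal(predict(m, cbind(p = a), cbind(p = b)),
               1 - exp(-eta_hand), tolerance = 1e-12)
  # identical environments, zero intercept -> 0
  m$intercept <- 0
  expect_equal(predict(m, cbind(p = 0.3), cbind(p = 0.3)), 0)
  # monotone in the predictor gap
  gaps <- seq(0, 1, by = 0.1)
  preds <- vapply(gaps, function(g)
    predict(m, cbind(p = 0), cbind(p = g)), numeric(1))
  expect_true(all(diff(preds) >= -1e-12))
  expect_true(all(preds >= 0 & preds < 1))
})

test_that("pairwise dissimilarity table is symmetric and FST-based", {
  sim <- small_sim(seed = 10)
  pops <- sim$meta$pop
  env_pop <- aggregate_by_pop(matrix(rnorm(nrow(sim$gm) * 3),
                                     ncol = 3), pops)
  xy <- aggregate_by_pop(sim$meta[, c("lat", "lon")], pops)
  pd <- suppressWarnings(pairwise_dissimilarity(sim$gm, pops, env_pop, xy))
  expect_true(all(pd$d >= 0 & pd$d < 1))
  # equals the Hudson FST oracle, linearized and rescaled
  fm <- suppressWarnings(linearized_fst_matrix(sim$gm, pops))
  lv <- unique(pops)
  k <- which(pd$pairs[, 1] == lv[1] & pd$pairs[, 2] == lv[2])
  raw <- pmax(fm[lv[1], lv[2]], 0)
  expect_equal(pd$d[k], raw / (max(pmax(fm[upper.tri(fm)], 0)) * 1.05))
  expect_error(pairwise_dissimilarity(sim$gm, rep("p1", nrow(sim$gm)),
                                      env_pop, xy), "3 populations")
})

# shared toy grid for the offset family
make_toy_model <- function() {
  set.seed(77)
  x <- runif(40); y <- runif(40)
  pr <- t(combn(10, 2))
  env_i <- cbind(a = x[pr[, 1]], b = y[pr[, 1]])
  env_j <- cbind(a = x[pr[, 2]], b = y[pr[, 2]])
  eta <- 2 * abs(env_i[, 1] - env_j[, 1]) + abs(env_i[, 2] - env_j[, 2])
  gdm_fit(pmin(1 - exp(-eta), 0.95), env_i, env_j)
}

test_that("local offset is zero without climate change and monotone", {
  m <- make_toy_model()
  grid <- data.frame(lat = runif(20, 20, 25), lon = runif(20, 100, 110),
                     a = runif(20), b = runif(20))
  expect_equal(local_offset(m, grid, grid), rep(0, 20))
  # per-cell equality with the brute-force prediction loop
  fut <- grid; fut$a <- pmin(grid$a + runif(20, 0, 0.3), 1)
  off <- local_offset(m, grid, fut)
  for (s in seq_len(20))
    expect_equal(off[s],
                 predict(m, grid[s, c("a", "b")], fut[s, c("a", "b")]),
                 tolerance = 1e-12)
  # a larger single-predictor shift cannot reduce the offset
  fut_big <- grid; fut_big$a <- pmin(grid$a + 0.4, 1)
  fut_small <- grid; fut_small$a <- pmin(grid$a + 0.1, 1)
  expect_true(all(local_offset(m, grid, fut_big) >=
                    local_offset(m, grid, fut_small) - 1e-12))
  expect_error(local_offset(m, grid, NULL), "future")
})

test_that("forward/reverse offsets equal the exhaustive double loop", {
  m <- make_toy_model()
  set.seed(9)
  grid <- data.frame(lat = runif(20, 20, 25), lon = runif(20, 100, 110),
                     a = runif(20), b = runif(20))
  fut <- grid; fut$a <- grid$a + runif(20, -0.2, 0.4)
  fr <- forward_reverse_offset(m, grid, fut)
  o_loc <- local_offset(m, grid, fut)
  brute_f <- vapply(1:20, function(s)
    min(vapply(1:20, function(c2)
      predict(m, grid[s, c("a", "b")], fut[c2, c("a", "b")]),
      numeric(1))), numeric(1))
  brute_r <- vapply(1:20, function(s)
    min(vapply(1:20, function(c2)
      predict(m, grid[c2, c("a", "b")], fut[s, c("a", "b")]),
      numeric(1))), numeric(1))
  expect_equal(fr$forward, brute_f, tolerance = 1e-12)
  expect_equal(fr$reverse, brute_r, tolerance = 1e-12)
  # staying put is always an option
  expect_true(all(fr$forward <= o_loc + 1e-12))
  expect_true(all(fr$reverse >= 0))
  # a single-cell grid collapses all three offsets
  fr1 <- forward_reverse_offset(m, grid[1, ], fut[1, ])
  expect_equal(fr1$forward, o_loc[1])
  expect_equal(fr1$reverse, o_loc[1])
})

test_that("migration distance finds the nearest tolerable cell", {
  m <- make_toy_model()
  set.seed(19)
  grid <- data.frame(lat = runif(15, 20, 25), lon = runif(15, 100, 110),
                     a = runif(15), b = runif(15))
  fut <- grid; fut$a <- grid$a + runif(15, 0, 0.5)
  tau <- 0.15
  mig <- migration_distance(m, grid, fut, tau)
  # brute force
  for (s in 1:15) {
    off <- vapply(1:15, function(c2)
      predict(m, grid[s, c("a", "b")], fut[c2, c("a", "b")]), numeric(1))
    ok <- which(off < tau)
    if (!length(ok)) {
      expect_true(is.na(mig$distance_km[s]))
    } else if (s %in% ok) {
      expect_equal(mig$distance_km[s], 0)
    } else {
      dd <- geosphere::distHaversine(
        cbind(grid$lon[s], grid$lat[s]),
        cbind(grid$lon[ok], grid$lat[ok]), r = 6371008.8) / 1000
      expect_equal(mig$distance_km[s], min(dd), tolerance = 1e-9)
      expect_gte(mig$bearing[s], 0)
      expect_lt(mig$bearing[s], 360)
    }
  }
  # tau above the attainable offsets: distance 0 everywhere
  mig0 <- migration_distance(m, grid, grid, 0.9)
  expect_true(all(mig0$distance_km == 0))
  # tighter tau can only increase the distance
  mig2 <- migration_distance(m, grid, fut, 0.05)
  both <- !is.na(mig$distance_km) & !is.na(mig2$distance_km)
  expect_true(all(mig2$distance_km[both] >= mig$distance_km[both]))
})

test_that("RGB channels are min-max normalized per offset", {
  o1 <- c(0, 0.5, 1); o2 <- c(0.2, 0.2, 0.6); o3 <- c(3, 1, 2)
  rgb <- rgb_map(o1, o2, o3)
  expect_equal(rgb$r, c(0, 0.5, 1))
  expect_equal(rgb$g, c(0, 0, 1))
  expect_equal(rgb$b, c(1, 0, 0.5))
  # the grid-max cell in all three channels is white
  expect_equal(unlist(rgb[3, c("r", "g")]), c(r = 1, g = 1))
  # affine rescaling of a channel does not change its normalization
  rgb2 <- rgb_map(o1 * 7 + 2, o2, o3)
  expect_equal(rgb2$r, rgb$r)
  expect_warning(out <- rgb_map(rep(0.3, 3), o2, o3), "constant")
  expect_equal(out$r, c(0, 0, 0))
})

test_that("polar summaries compute circular statistics", {
  mig <- data.frame(distance_km = c(10, 20, 30),
                    bearing = c(90, 90, 90), target = 1:3)
  ps <- polar_summary(mig)
  expect_equal(ps$mean_direction, 90)
  expect_equal(ps$resultant, 1)
  expect_equal(nrow(ps$table), 3)
  # uniform bearings: resultant near zero
  n <- 360
  migu <- data.frame(distance_km = rep(1, n),
                     bearing = seq(0, 359), target = 1)
  expect_lt(polar_summary(migu)$resultant, 1e-10)
  # undefined direction when nothing needs to move
  mig0 <- data.frame(distance_km = c(0, 0, NA), bearing = NA, target = NA)
  ps0 <- polar_summary(mig0)
  expect_true(is.na(ps0$mean_direction))
  expect_equal(nrow(ps0$table), 2)     # only cells with defined distance
})
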