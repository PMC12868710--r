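#' Order-2 I-spline basis
#'
#' Monotone (integrated M-spline) basis with three functions on knots
#' (min, mid, max): each basis function is non-decreasing, 0 at the lowest
#' knot and 1 at the highest. Values outside the knot range are clamped
#' with a warning. These are the standard monotone basis functions of
#' generalized dissimilarity modelling.
#'
#' @param x numeric vector.
#' @param knots strictly increasing vector of 3 knots.
#' @return length(x) x 3 matrix of basis values.
#' @export
ispline_basis <- function(x, knots) {
  stopifnot(length(knots) == 3)
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  k1 <- knots[1]; k2 <- knots[2]; k3 <- knots[3]
  if (any(x < k1 - 1e-12 | x > k3 + 1e-12, na.rm = TRUE))
    warning("values outside the knot range were clamped")
  x <- pmin(pmax(x, k1), k3)
  b1 <- ifelse(x <= k2, 1 - ((k2 - x) / (k2 - k1))^2, 1)
  b2 <- ifelse(x <= k2,
               (x - k1)^2 / ((k3 - k1) * (k2 - k1)),
               1 - (k3 - x)^2 / ((k3 - k1) * (k3 - k2)))
  b3 <- ifelse(x <= k2, 0, ((x - k2) / (k3 - k2))^2)
  cbind(b1, b2, b3)
}

#' Pairwise dissimilarity table for GDM fitting
#'
#' Builds the response and predictor structure for a generalized
#' dissimilarity model from adaptive-locus genotypes: population-pair
#' genetic distance `FST / (1 - FST)` (Hudson estimator, ratio of sums)
#' rescaled into [0, 1) by the observed maximum times (1 + 1e-6), paired
#' with the two populations' environmental values and their great-circle
#' distance.
#'
#' @param gm samples x sites dosage matrix restricted to the adaptive loci.
#' @param pops population label per sample (>= 3 populations).
#' @param env_pop matrix of environmental values, one row per population
#'   (rownames = population labels).
#' @param coords_pop matrix/data frame with `lat`, `lon` per population.
#' @param headroom factor (> 1) applied to the observed maximum before
#'   rescaling. The default 1.05 keeps the largest pair's transformed
#'   response `-log(1 - d)` finite and moderate (about 3) so the
#'   negative-exponential fit is not dominated by a single saturated pair.
#' @return list with `d` (response), `env_i`, `env_j` (pair predictor
#'   matrices), `geo` (km), `pairs` (labels).
#' @export
pairwise_dissimilarity <- function(gm, pops, env_pop, coords_pop,
                                   headroom = 1.05) {
  pops <- as.character(pops)
  lv <- unique(pops)
  if (length(lv) < 3) stop("need at least 3 populations")
  fm <- linearized_fst_matrix(gm, pops)
  pr <- t(utils::combn(length(lv), 2))
  d_raw <- pmax(fm[pr], 0)
  dmax <- max(d_raw)
  stopifnot(headroom > 1)
  d <- if (dmax > 0) d_raw / (dmax * headroom) else d_raw
  E <- as.matrix(env_pop)[lv, , drop = FALSE]
  cp <- as.matrix(coords_pop)[lv, c("lat", "lon"), drop = FALSE]
  geo <- vapply(seq_len(nrow(pr)), function(k)
    geosphere::distHaversine(c(cp[pr[k, 1], "lon"], cp[pr[k, 1], "lat"]),
                             c(cp[pr[k, 2], "lon"], cp[pr[k, 2], "lat"]),
                             r = 6371008.8) / 1000, numeric(1))
  list(d = d, env_i = E[pr[, 1], , drop = FALSE],
       env_j = E[pr[, 2], , drop = FALSE], geo = geo,
       pairs = cbind(lv[pr[, 1]], lv[pr[, 2]]))
}

#' Fit a generalized dissimilarity model
#'
#' Monotone regression of pairwise dissimilarity on predictor differences:
#' each predictor enters through a non-decreasing function
#' `f_p(x) = sum_k w_pk I_pk(x)` built from order-2 I-splines (knots at
#' min/median/max of the pooled predictor values), the linear predictor is
#' `eta = a0 + sum_p |f_p(x_i) - f_p(x_j)| (+ f_geo(distance))`, and the
#' response link is `d = 1 - exp(-eta)`. Because all basis functions are
#' monotone, `|f_p(x_i) - f_p(x_j)| = sum_k w_pk |I_pk(x_i) - I_pk(x_j)|`,
#' so the model is linear in the coefficients and is fitted by non-negative
#' least squares on the transformed response `-log(1 - d)` (d clamped at
#' 1 - 1e-6). The NNLS constraint guarantees non-negative coefficients and
#' hence monotone fitted predictor functions and predictions in [0, 1).
#'
#' @param d pairwise dissimilarities in [0, 1) (e.g. from
#'   [pairwise_dissimilarity()]).
#' @param env_i,env_j pair predictor matrices (n_pairs x P).
#' @param geo optional pairwise geographic distances (km); include as a
#'   monotone predictor of its own.
#' @return object of class `gdm`: `intercept`, `coef` (list of 3-vectors
#'   per predictor), `knots` (list), `predictors`, `fitted`, `response`,
#'   `explained` (fraction of response variance explained on the
#'   dissimilarity scale).
#' @export
gdm_fit <- function(d, env_i, env_j, geo = NULL) {
  d <- as.numeric(d)
  env_i <- as.matrix(env_i); env_j <- as.matrix(env_j)
  stopifnot(nrow(env_i) == length(d), nrow(env_j) == length(d))
  if (any(d < 0 | d >= 1)) stop("response must lie in [0, 1)")
  P <- ncol(env_i)
  nm <- colnames(env_i)
  if (is.null(nm)) nm <- paste0("pred", seq_len(P))
  if (!is.null(geo)) nm <- c(nm, "geo")
  knots <- vector("list", length(nm)); names(knots) <- nm
  blocks <- vector("list", length(nm))
  for (p in seq_len(P)) {
    pooled <- c(env_i[, p], env_j[, p])
    kn <- c(min(pooled), stats::median(pooled), max(pooled))
    if (diff(range(kn)) <= 0) {              # constant predictor
      knots[[p]] <- kn
      blocks[[p]] <- matrix(0, length(d), 3)
      next
    }
    if (kn[2] <= kn[1] || kn[2] >= kn[3]) kn[2] <- (kn[1] + kn[3]) / 2
    knots[[p]] <- kn
    blocks[[p]] <- abs(ispline_basis(env_i[, p], kn) -
                         ispline_basis(env_j[, p], kn))
  }
  if (!is.null(geo)) {
    kn <- c(min(geo), stats::median(geo), max(geo))
    if (diff(range(kn)) <= 0) {
      knots[["geo"]] <- kn
      blocks[[length(nm)]] <- matrix(0, length(d), 3)
    } else {
      if (kn[2] <= kn[1] || kn[2] >= kn[3]) kn[2] <- (kn[1] + kn[3]) / 2
      knots[["geo"]] <- kn
      blocks[[length(nm)]] <- ispline_basis(geo, kn)
    }
  }
  X <- cbind(1, do.call(cbind, blocks))
  eta <- as.numeric(-log(1 - pmin(d, 1 - 1e-6)))
  w <- pracma::lsqnonneg(X, eta)$x
  intercept <- w[1]
  coefs <- split(w[-1], rep(seq_along(nm), each = 3))
  names(coefs) <- nm
  eta_fit <- as.numeric(X %*% w)
  d_fit <- 1 - exp(-eta_fit)
  ssr <- sum((d - d_fit)^2)
  sst <- sum((d - mean(d))^2)
  out <- list(intercept = intercept, coef = coefs, knots = knots,
              predictors = nm, has_geo = !is.null(geo),
              fitted = d_fit, fitted_eta = eta_fit, response = d,
              explained = if (sst > 0) 1 - ssr / sst else NA_real_)
  class(out) <- "gdm"
  out
}

#' @export
print.gdm <- function(x, ...) {
  cat("Generalized dissimilarity model\n")
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat(sprintf("  intercept: %.4g;  pairs: %d;  variance explained: %.3f\n",
              x$intercept, length(x$response), x$explained))
  tot <- vapply(x$coef, sum, numeric(1))
  cat("  total spline height per predictor:\n")
  for (p in x$predictors)
    cat(sprintf("    %-10s %.4g\n", p, tot[[p]]))
  invisible(x)
}

#' @export
coef.gdm <- function(object, ...) {
  c(intercept = object$intercept,
    unlist(lapply(object$coef, function(w)
      stats::setNames(w, paste0("k", seq_along(w))))))
}

#' @export
residuals.gdm <- function(object, ...) object$response - object$fitted

#' @export
summary.gdm <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Plot fitted GDM predictor functions
#'
#' Draws each fitted monotone function `f_p` over its knot range; the curve
#' height is the predictor's importance.
#' @param x a `gdm` model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gdm <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$predictors)))
  on.exit(graphics::par(old))
  for (p in x$predictors) {
    kn <- x$knots[[p]]
    if (diff(range(kn)) <= 0) next
    xs <- seq(kn[1], kn[3], length.out = 100)
    fs <- ispline_basis(xs, kn) %*% x$coef[[p]]
    graphics::plot(xs, fs, type = "l", xlab = p, ylab = "f(x)", ...)
  }
  invisible(x)
}

# eta contribution machinery: weighted I-spline transforms of a matrix of
# predictor values (cells x P), stacked so that
# eta(a, b) = a0 + sum_k |WA[a, k] - WB[b, k]|  (env part)
.gdm_transform <- function(model, env) {
  env <- as.matrix(env)
  pn <- setdiff(model$predictors, "geo")
  cols <- lapply(pn, function(p) {
    kn <- model$knots[[p]]
    if (diff(range(kn)) <= 0)
      return(matrix(0, nrow(env), 3))
    suppressWarnings(ispline_basis(env[, p], kn)) %*%
      diag(model$coef[[p]], 3)
  })
  do.call(cbind, cols)
}

.gdm_geo_eta <- function(model, geo) {
  if (!model$has_geo) return(rep(0, length(geo)))
  kn <- model$knots[["geo"]]
  if (diff(range(kn)) <= 0) return(rep(0, length(geo)))
  as.numeric(suppressWarnings(ispline_basis(geo, kn)) %*%
               model$coef[["geo"]])
}

#' Predict dissimilarity between environment pairs
#'
#' @param object a fitted `gdm`.
#' @param env_a,env_b matrices (rows = pairs) of predictor values.
#' @param geo geographic distance per pair in km (default 0; clamped into
#'   the fitted knot range, so 0 contributes nothing).
#' @param ... unused.
#' @return predicted dissimilarities in [0, 1).
#' @export
predict.gdm <- function(object, env_a, env_b, geo = 0, ...) {
  env_a <- as.matrix(env_a); env_b <- as.matrix(env_b)
  WA <- .gdm_transform(object, env_a)
  WB <- .gdm_transform(object, env_b)
  eta <- object$intercept + unname(rowSums(abs(WA - WB))) +
    .gdm_geo_eta(object, rep_len(geo, nrow(env_a)))
  as.numeric(1 - exp(-eta))
}

#' @rdname predict.gdm
#' @param model a fitted `gdm`.
#' @export
predict_dissimilarity <- function(model, env_a, env_b, geo = 0)
  predict(model, env_a, env_b, geo)

#' Local genetic offset
#'
#' Predicted dissimilarity between each grid cell's current and future
#' environment (geographic distance 0): the expected maladaptation of a
#' population that stays in place.
#'
#' @param model a fitted `gdm`.
#' @param grid_current,grid_future data frames with the model's predictor
#'   columns (plus `lat`/`lon`, ignored here), aligned by row.
#' @return numeric vector of offsets, one per cell.
#' @export
local_offset <- function(model, grid_current, grid_future) {
  if (is.null(grid_future)) stop("future environmental layer is missing")
  pn <- setdiff(model$predictors, "geo")
  predict(model, grid_current[, pn, drop = FALSE],
          grid_future[, pn, drop = FALSE], geo = 0)
}

#' Forward and reverse genetic offsets
#'
#' Climate-only migration optima: the forward offset of cell `s` is the
#' minimum predicted dissimilarity between `s`'s current environment and
#' the *future* environment of any cell (where could its population go);
#' the reverse offset is the minimum dissimilarity between any cell's
#' current environment and `s`'s future environment (who could come). The
#' geographic term is zeroed: offsets measure climate mismatch, not travel
#' cost.
#'
#' @inheritParams local_offset
#' @return list with `forward` and `reverse` numeric vectors.
#' @export
forward_reverse_offset <- function(model, grid_current, grid_future) {
  pn <- setdiff(model$predictors, "geo")
  WA <- .gdm_transform(model, grid_current[, pn, drop = FALSE])
  WB <- .gdm_transform(model, grid_future[, pn, drop = FALSE])
  n <- nrow(WA)
  fwd <- numeric(n); rev_ <- numeric(n)
  for (s in seq_len(n)) {
    eta_f <- model$intercept +
      rowSums(abs(sweep(WB, 2, WA[s, ], "-")))
    fwd[s] <- min(1 - exp(-eta_f))
    eta_r <- model$intercept +
      rowSums(abs(sweep(WA, 2, WB[s, ], "-")))
    rev_[s] <- min(1 - exp(-eta_r))
  }
  list(forward = fwd, reverse = rev_)
}

#' Migration distance to the nearest climatically suitable cell
#'
#' For each cell `s`, the haversine distance (km) to the nearest cell `c`
#' whose future environment keeps the predicted offset below `tau`
#' (0 when `s` itself qualifies; `NA` when no cell does), plus the initial
#' great-circle bearing toward that cell in [0, 360).
#'
#' @inheritParams local_offset
#' @param tau offset threshold (e.g. 0.15 for high, 0.05 for moderate).
#' @return data frame `distance_km`, `bearing`, `target` (cell index).
#' @export
migration_distance <- function(model, grid_current, grid_future, tau) {
  pn <- setdiff(model$predictors, "geo")
  WA <- .gdm_transform(model, grid_current[, pn, drop = FALSE])
  WB <- .gdm_transform(model, grid_future[, pn, drop = FALSE])
  n <- nrow(WA)
  lat <- grid_current$lat; lon <- grid_current$lon
  dist_km <- rep(NA_real_, n); bearing <- rep(NA_real_, n)
  target <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    off <- 1 - exp(-(model$intercept +
                       rowSums(abs(sweep(WB, 2, WA[s, ], "-")))))
    ok <- which(off < tau)
    if (!length(ok)) next
    if (s %in% ok) { dist_km[s] <- 0; target[s] <- s; next }
    dd <- geosphere::distHaversine(cbind(lon[s], lat[s]),
                                   cbind(lon[ok], lat[ok]),
                                   r = 6371008.8) / 1000
    j <- ok[which.min(dd)]
    dist_km[s] <- min(dd)
    b <- geosphere::bearing(c(lon[s], lat[s]), c(lon[j], lat[j]))
    bearing[s] <- (b + 360) %% 360
    target[s] <- j
  }
  data.frame(distance_km = dist_km, bearing = bearing, target = target)
}

#' RGB vulnerability channels from the three offsets
#'
#' Min-max normalizes each offset over the grid into [0, 1] and maps local,
#' forward and reverse offsets to the red, green and blue channels. A
#' constant channel becomes all zeros with a warning.
#'
#' @param o_local,o_forward,o_reverse offset vectors over the same grid.
#' @return data frame `r`, `g`, `b`.
#' @export
rgb_map <- function(o_local, o_forward, o_reverse) {
  norm <- function(x, label) {
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) <= 0) {
      warning("constant ", label, " channel normalized to 0")
      return(rep(0, length(x)))
    }
    (x - rng[1]) / diff(rng)
  }
  data.frame(r = norm(o_local, "local"), g = norm(o_forward, "forward"),
             b = norm(o_reverse, "reverse"))
}

#' Polar summary of migration requirements
#'
#' Collects the cells with a defined migration distance and reduces their
#' bearings to a circular mean direction and resultant length
#' (1 = perfectly concentrated, 0 = no directional trend). Cells that
#' qualify in place (distance 0) carry no direction and are excluded from
#' the circular statistics.
#'
#' @param mig output of [migration_distance()].
#' @return list with `table` (cell, distance_km, bearing),
#'   `mean_direction` (degrees, `NA` if undefined) and `resultant`.
#' @export
polar_summary <- function(mig) {
  def <- which(!is.na(mig$distance_km))
  tab <- data.frame(cell = def, distance_km = mig$distance_km[def],
                    bearing = mig$bearing[def])
  moving <- def[mig$distance_km[def] > 0 & !is.na(mig$bearing[def])]
  if (!length(moving))
    return(list(table = tab, mean_direction = NA_real_, resultant = NA_real_))
  th <- mig$bearing[moving] * pi / 180
  s <- mean(sin(th)); c <- mean(cos(th))
  list(table = tab,
       mean_direction = (atan2(s, c) * 180 / pi + 360) %% 360,
       resultant = sqrt(s^2 + c^2))
}
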