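#' Population-pair distance matrices for IBD/IBE testing
#'
#' `linearized_fst_matrix()` computes Hudson FST for every population pair
#' and returns `FST / (1 - FST)`; estimates at or above 1 are clamped to
#' `1 - 1e-6` with a warning so entries stay finite. Negative FST estimates
#' are kept as computed (small negative distances are possible).
#' `geo_distance_matrix()` is great-circle (haversine) distance in km on the
#' WGS84 mean radius; `env_distance_matrix()` is Euclidean distance on
#' standardized environmental variables.
#'
#' @param gm samples x sites dosage matrix.
#' @param pops factor/character of population labels per sample.
#' @return symmetric matrix with zero diagonal, labelled by population.
#' @export
linearized_fst_matrix <- function(gm, pops) {
  pops <- as.character(pops)
  lv <- unique(pops)
  k <- length(lv)
  m <- matrix(0, k, k, dimnames = list(lv, lv))
  clamped <- FALSE
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    f <- hudson_fst(gm, which(pops == lv[i]), which(pops == lv[j]))
    if (is.na(f)) f <- 0
    if (f >= 1 - 1e-6) { f <- 1 - 1e-6; clamped <- TRUE }
    m[i, j] <- m[j, i] <- f / (1 - f)
  }
  if (clamped) warning("FST clamped at 1 - 1e-6 for at least one pair")
  m
}

#' @rdname linearized_fst_matrix
#' @param lat,lon coordinates (decimal degrees), one per population.
#' @param labels optional dimnames.
#' @export
geo_distance_matrix <- function(lat, lon, labels = NULL) {
  k <- length(lat)
  m <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) {
      d <- geosphere::distHaversine(c(lon[i], lat[i]), c(lon[j], lat[j]),
                                    r = 6371008.8) / 1000
      m[i, j] <- m[j, i] <- d
    }
  }
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' @rdname linearized_fst_matrix
#' @param env matrix/data frame of environmental variables per population
#'   (standardized before the distance is taken).
#' @export
env_distance_matrix <- function(env) {
  z <- scale(as.matrix(env))
  z[!is.finite(z)] <- 0        # constant variables contribute nothing
  as.matrix(stats::dist(z))
}

#' Aggregate sample-level data to population level
#'
#' Means of coordinates / environmental variables by population label.
#' @param x data frame or matrix of sample-level values.
#' @param pops population label per sample.
#' @return matrix with one row per population (order of first appearance).
#' @export
aggregate_by_pop <- function(x, pops) {
  pops <- as.character(pops)
  lv <- unique(pops)
  out <- t(vapply(lv, function(p)
    colMeans(as.matrix(x)[pops == p, , drop = FALSE]),
    numeric(ncol(as.matrix(x)))))
  rownames(out) <- lv
  out
}
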