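#' Plant runs of homozygosity into a simulated panel
#'
#' Forces known autozygous tracts: inside each planted tract every
#' heterozygous genotype of that individual is collapsed to a homozygote
#' (one of its two alleles, chosen at random per site), emulating a
#' recently inbred segment. Overlapping tracts for one individual are
#' merged before being applied and reported merged.
#'
#' @param sim a `relict_sim` object.
#' @param n_tracts tracts per selected sample: scalar, or a named vector
#'   keyed by sample id (samples absent from the vector get none).
#' @param length_range length-2 bp range; tract lengths are drawn uniformly.
#' @param samples sample ids to receive tracts (default: all).
#' @param seed optional integer seed.
#' @return the `relict_sim` with modified genotypes and a
#'   `truth$planted_roh` table (sample, chrom, start, end; 0-based
#'   half-open).
#' @export
plant_roh <- function(sim, n_tracts = 2, length_range = c(3e5, 8e5),
                      samples = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(sim$gm)
  if (is.null(samples)) samples <- ids
  nt <- if (!is.null(names(n_tracts))) n_tracts else
    stats::setNames(rep(n_tracts[1], length(samples)), samples)
  cl <- sim$chrom_lengths
  if (max(length_range) > max(cl))
    stop("tract length range exceeds the longest chromosome")
  rows <- list()
  for (sid in names(nt)) {
    k <- nt[[sid]]
    if (k < 1) next
    fits <- cl >= max(length_range)
    cn <- names(cl)[fits][sample.int(sum(fits), k, replace = TRUE)]
    len <- round(stats::runif(k, length_range[1], length_range[2]))
    start <- vapply(seq_len(k), function(i)
      sample.int(cl[[cn[i]]] - len[i] + 1L, 1) - 1L, numeric(1))
    d <- data.frame(sample = sid, chrom = cn, start = start,
                    end = start + len, stringsAsFactors = FALSE)
    # merge overlaps within sample/chromosome
    merged <- do.call(rbind, lapply(split(d, d$chrom), function(dd) {
      ir <- IRanges::reduce(IRanges::IRanges(dd$start + 1L, dd$end))
      data.frame(sample = sid, chrom = dd$chrom[1],
                 start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
                 stringsAsFactors = FALSE)
    }))
    rows[[sid]] <- merged
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  # apply homozygosity
  for (i in seq_len(nrow(truth))) {
    sidx <- match(truth$sample[i], ids)
    in_tract <- sim$vt$chrom == truth$chrom[i] &
      sim$vt$pos >= truth$start[i] & sim$vt$pos < truth$end[i]
    g <- sim$gm[sidx, in_tract]
    hets <- which(!is.na(g) & g == 1L)
    if (length(hets))
      g[hets] <- 2L * stats::rbinom(length(hets), 1L, 0.5)
    sim$gm[sidx, in_tract] <- g
  }
  sim$truth$planted_roh <- truth[order(truth$sample, truth$chrom,
                                       truth$start), ]
  rownames(sim$truth$planted_roh) <- NULL
  sim
}

#' Simulate correlated-but-prunable environmental layers and adaptive loci
#'
#' Builds `n_vars` smooth environmental surfaces (deterministic functions of
#' latitude and longitude with randomized weights), evaluated at the
#' sampling sites and on a regular grid covering the sampled region, and
#' standardized to the site mean/sd. Weights are redrawn until the maximum
#' pairwise |r| across sites is below `r_max`, matching the variable-pruning
#' convention used for bioclimatic predictors. A "future" grid equals the
#' current grid plus a per-variable shift (in site-sd units) scaled by
#' `shift_scale`, emulating a climate-change scenario ladder.
#'
#' Selected loci receive logistic allele-frequency clines along their
#' assigned variable's climate syndrome: the effective gradient blends the
#' variable with the mean of its correlation block
#' (`(1 - gradient_blend) * var + gradient_blend * block mean`,
#' restandardized), reflecting that plants respond to integrated climate
#' regimes rather than to a single bioclim summary in isolation. The
#' individual derived-allele probability is `p = plogis(effect * gradient)`
#' and genotypes are redrawn as Binomial(2, p).
#'
#' @param sim a `relict_sim` object.
#' @param n_vars number of environmental variables (default 7).
#' @param n_adaptive number of loci to make clinal (0 for a pure null);
#'   the default plants adaptive variation at about 1.4% of segregating
#'   sites, matching the adaptive fraction reported for range-wide plant
#'   resequencing panels.
#' @param effect_size logistic slope per sd of environment (default 3, a
#'   steep cline: derived-allele frequency rises from ~0.05 to ~0.95
#'   across two sd of the gradient).
#' @param grid_dim c(n_lat, n_lon) grid resolution.
#' @param future_shift per-variable climate shift in sd units (recycled).
#' @param shift_scale multiplier on `future_shift` (scenario severity).
#' @param r_max maximum tolerated pairwise |r| among site values.
#' @param gradient_blend weight of the block-mean component in the
#'   effective selection gradient (default 0.5).
#' @param seed optional integer seed.
#' @return the `relict_sim` with an `env` element (`sites`, `grid`,
#'   `grid_future`, `var_names`) and `truth$adaptive`
#'   (chrom, pos, var, effect).
#' @export
simulate_environment <- function(sim, n_vars = 7, n_adaptive = 120,
                                 effect_size = 3, grid_dim = c(12, 12),
                                 future_shift = c(1.5, 0.5, 0.5, 1.0,
                                                  -0.8, -0.3, 0.4),
                                 shift_scale = 1, r_max = 0.7,
                                 gradient_blend = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meta <- sim$meta
  sites_xy <- unique(meta[, c("lat", "lon")])
  if (nrow(sites_xy) < 3) stop("need at least 3 distinct sampling sites")
  lat_r <- range(meta$lat) + c(-1, 1)
  lon_r <- range(meta$lon) + c(-1, 1)
  glat <- seq(lat_r[1], lat_r[2], length.out = grid_dim[1])
  glon <- seq(lon_r[1], lon_r[2], length.out = grid_dim[2])
  grid_xy <- expand.grid(lat = glat, lon = glon)

  # coarse (regional) plus fine (topographic) surface components; the fine
  # terms guarantee environmental heterogeneity within each lineage's
  # cluster of sites, as mountainous terrain produces in real bioclim layers
  surf <- function(w, lat, lon) {
    latz <- (lat - mean(lat_r)) / diff(lat_r) * 2
    lonz <- (lon - mean(lon_r)) / diff(lon_r) * 2
    0.4 * (w[1] * latz + w[2] * lonz + w[3] * latz * lonz) +
      w[4] * sin(2.5 * pi * latz) + w[5] * cos(2.5 * pi * lonz) +
      w[6] * sin(2.5 * pi * lonz) + w[7] * cos(2.5 * pi * latz)
  }
  basis <- function(lat, lon) sapply(seq_len(7), function(b) {
    w <- numeric(7); w[b] <- 1
    surf(w, lat, lon)
  })
  B_site <- basis(meta$lat, meta$lon)
  # target correlation structure mirroring bioclim sets pruned at |r|<0.7:
  # a temperature-like and a precipitation-like block, correlated within
  # block, weakly across
  n_blk1 <- ceiling(n_vars / 2)
  blk <- rep(c(1, 2), c(n_blk1, n_vars - n_blk1))
  R <- outer(blk, blk, function(a, b) ifelse(a == b, 0.68, 0.2))
  diag(R) <- 1
  # within-lineage (residual) basis: the correlation target is imposed on
  # the fine-scale structure shared inside each lineage's range, the part
  # of real bioclim layers that survives correction for population
  # structure
  lin_f <- factor(meta$lineage)
  one_lineage <- nlevels(lin_f) < 2
  ok <- FALSE
  for (attempt in seq_len(400)) {
    # whiten random weights against the site covariance, impose the target
    # correlation, and keep the draw only if the correlation structure
    # also holds within lineages (where structure-corrected association
    # tests must find their signal)
    W0 <- matrix(stats::rnorm(7 * n_vars), nrow = 7)
    S <- stats::cov(B_site %*% W0)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) next
    W <- W0 %*% backsolve(ch, diag(n_vars)) %*% chol(R)
    site_env <- B_site %*% W
    cc <- suppressWarnings(stats::cor(site_env))
    sd_tot <- apply(site_env, 2, stats::sd)
    sd_within <- if (one_lineage) sd_tot else
      vapply(seq_len(n_vars), function(k)
        mean(tapply(site_env[, k], lin_f, stats::sd)), numeric(1))
    rw <- suppressWarnings(stats::cor(if (one_lineage) site_env else
      stats::resid(stats::lm(site_env ~ lin_f))))
    blk_ok <- all(vapply(seq_len(n_vars), function(k) {
      partners <- which(blk == blk[k] & seq_len(n_vars) != k)
      sum(rw[k, partners] >= 0.62) >= 2
    }, logical(1)))
    if (max(abs(cc[upper.tri(cc)])) < r_max && all(sd_tot > 0) &&
        all(sd_within / sd_tot >= 0.55) && blk_ok) { ok <- TRUE; break }
  }
  if (!ok) stop("could not generate variables with max |r| < ", r_max)
  mu <- colMeans(site_env); sdv <- apply(site_env, 2, stats::sd)
  site_env <- scale(site_env, center = mu, scale = sdv)
  grid_env <- sweep(sweep(basis(grid_xy$lat, grid_xy$lon) %*% W, 2, mu),
                    2, sdv, "/")

  var_names <- if (n_vars == 7)
    c("bio1", "bio2", "bio3", "bio7", "bio12", "bio14", "bio15") else
      paste0("env", seq_len(n_vars))
  colnames(site_env) <- var_names
  rownames(site_env) <- meta$sample_id
  shift <- rep_len(future_shift, n_vars) * shift_scale
  grid <- cbind(grid_xy, as.data.frame(grid_env))
  names(grid)[-(1:2)] <- var_names
  grid_future <- grid
  grid_future[var_names] <- sweep(as.matrix(grid[var_names]), 2, shift, "+")

  adaptive <- NULL
  if (n_adaptive > 0) {
    p_alt <- colMeans(sim$gm, na.rm = TRUE) / 2
    pool <- which(p_alt > 0.1 & p_alt < 0.9)
    if (length(pool) < n_adaptive)
      stop("not enough polymorphic loci to plant ", n_adaptive,
           " adaptive sites")
    loci <- sort(pool[sample.int(length(pool), n_adaptive)])
    vars <- sample.int(n_vars, n_adaptive, replace = TRUE)
    for (j in seq_len(n_adaptive)) {
      peers <- which(blk == blk[vars[j]])
      grad <- (1 - gradient_blend) * site_env[, vars[j]] +
        gradient_blend * rowMeans(site_env[, peers, drop = FALSE])
      grad <- as.numeric(scale(grad))
      p <- stats::plogis(effect_size * grad)
      sim$gm[, loci[j]] <- stats::rbinom(nrow(sim$gm), 2L, p)
    }
    adaptive <- data.frame(chrom = sim$vt$chrom[loci],
                           pos = sim$vt$pos[loci],
                           var = var_names[vars], effect = effect_size,
                           stringsAsFactors = FALSE)
  }
  sim$env <- list(sites = site_env, grid = grid, grid_future = grid_future,
                  var_names = var_names, shift = shift)
  sim$truth$adaptive <- adaptive
  sim
}
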