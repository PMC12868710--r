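#' Tile a genome into analysis windows
#'
#' 0-based half-open windows; the terminal window of each chromosome may be
#' shorter. A `step` smaller than `window` yields overlapping (sliding)
#' windows.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window window size in bp.
#' @param step step in bp (default: non-overlapping).
#' @return data frame `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, window = 1e5, step = window) {
  stopifnot(window > 0, step > 0)
  do.call(rbind, lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    start <- seq(0, max(0, len - 1), by = step)
    start <- start[start < len]
    data.frame(chrom = cn, start = start, end = pmin(start + window, len),
               stringsAsFactors = FALSE)
  }))
}

# per-site unbiased heterozygosity terms for a sample subset:
# pi_site = 2 p (1-p) n/(n-1) with n the non-missing allele count
.site_pi_terms <- function(gm) {
  n <- 2 * colSums(!is.na(gm))
  ac <- colSums(gm, na.rm = TRUE)
  p <- ac / n
  list(n = n, p = p,
       pi = ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_))
}

#' Windowed nucleotide diversity (pi)
#'
#' pixy-style estimator: the window numerator sums per-site unbiased
#' heterozygosity `2p(1-p) n/(n-1)` over variant sites; the denominator is
#' the callable window length, i.e. the window size scaled by the mean
#' non-missing genotype fraction at its variant sites (positions without a
#' variant record are assumed invariant and callable at the same rate).
#' Windows with no usable site in a polymorphic panel report pi = 0;
#' windows with no callable genotypes report `NA`.
#'
#' @param gm samples x sites dosage matrix.
#' @param vt variant table aligned to `gm`.
#' @param chrom_lengths named chromosome lengths.
#' @param pop sample ids (or indices) defining the population; default all.
#' @param window,step window geometry in bp.
#' @return data frame `chrom`, `start`, `end`, `n_sites_used`, `pi`.
#' @export
window_pi <- function(gm, vt, chrom_lengths, pop = NULL, window = 1e5,
                      step = window) {
  g <- .subset_pop(gm, pop)
  st <- .site_pi_terms(g)
  win <- make_windows(chrom_lengths, window, step)
  frac_ok <- colMeans(!is.na(g))
  out <- win
  out$n_sites_used <- 0L
  out$pi <- NA_real_
  for (i in seq_len(nrow(win))) {
    in_w <- which(vt$chrom == win$chrom[i] & vt$pos >= win$start[i] &
                    vt$pos < win$end[i] & !is.na(st$pi))
    wbp <- win$end[i] - win$start[i]
    if (!length(in_w)) {
      out$pi[i] <- if (nrow(g) > 0) 0 else NA_real_
      next
    }
    callable <- wbp * mean(frac_ok[in_w])
    out$n_sites_used[i] <- length(in_w)
    out$pi[i] <- if (callable > 0) sum(st$pi[in_w]) / callable else NA_real_
  }
  out
}

#' Windowed Hudson FST (ratio of sums)
#'
#' Per usable site (at least two sampled alleles in each population):
#' `num = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `den = p1(1-p2) + p2(1-p1)`; the window estimate is
#' `sum(num)/sum(den)`. Negative estimates are reported as computed; a
#' window whose denominator sums to zero is `NA`.
#'
#' @inheritParams window_pi
#' @param popA,popB sample ids (or indices) of the two populations.
#' @return data frame `chrom`, `start`, `end`, `n_sites_used`, `fst`.
#' @export
window_fst <- function(gm, vt, chrom_lengths, popA, popB, window = 1e5,
                       step = window) {
  h <- .hudson_site_terms(.subset_pop(gm, popA), .subset_pop(gm, popB))
  win <- make_windows(chrom_lengths, window, step)
  out <- win
  out$n_sites_used <- 0L
  out$fst <- NA_real_
  for (i in seq_len(nrow(win))) {
    in_w <- which(vt$chrom == win$chrom[i] & vt$pos >= win$start[i] &
                    vt$pos < win$end[i] & h$usable)
    out$n_sites_used[i] <- length(in_w)
    den <- sum(h$den[in_w])
    if (length(in_w) && den > 0)
      out$fst[i] <- sum(h$num[in_w]) / den
  }
  out
}

.hudson_site_terms <- function(gA, gB) {
  nA <- 2 * colSums(!is.na(gA)); nB <- 2 * colSums(!is.na(gB))
  pA <- colSums(gA, na.rm = TRUE) / nA
  pB <- colSums(gB, na.rm = TRUE) / nB
  usable <- nA >= 2 & nB >= 2
  num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  num[!usable] <- NA_real_; den[!usable] <- NA_real_
  list(num = num, den = den, usable = usable)
}

#' Genome-wide Hudson FST between two populations
#'
#' Ratio-of-sums across all usable sites (see [window_fst()]).
#' @inheritParams window_fst
#' @return a single numeric value.
#' @export
hudson_fst <- function(gm, popA, popB) {
  h <- .hudson_site_terms(.subset_pop(gm, popA), .subset_pop(gm, popB))
  den <- sum(h$den[h$usable])
  if (!is.finite(den) || den <= 0) return(NA_real_)
  sum(h$num[h$usable]) / den
}

#' Windowed Tajima's D
#'
#' Standard formulation: `D = (pi_hat - S/a1) / sqrt(e1 S + e2 S (S-1))`
#' with the usual coefficients computed from the haplotype sample size
#' `n = 2 x` number of diploids in `pop`. `pi_hat` is the sum of per-site
#' unbiased heterozygosities (mean pairwise differences) and `S` the number
#' of segregating sites in the window. Windows with `S = 0` are `NA`, not
#' zero.
#'
#' @inheritParams window_pi
#' @return data frame `chrom`, `start`, `end`, `n_sites_used`, `tajima_d`.
#' @export
window_tajima_d <- function(gm, vt, chrom_lengths, pop = NULL,
                            window = 1e5, step = window) {
  g <- .subset_pop(gm, pop)
  n <- 2 * nrow(g)
  if (n < 4) stop("Tajima's D needs at least 4 haplotypes")
  cst <- .tajima_constants(n)
  st <- .site_pi_terms(g)
  seg <- !is.na(st$p) & st$p > 0 & st$p < 1
  win <- make_windows(chrom_lengths, window, step)
  out <- win
  out$n_sites_used <- 0L
  out$tajima_d <- NA_real_
  for (i in seq_len(nrow(win))) {
    in_w <- which(vt$chrom == win$chrom[i] & vt$pos >= win$start[i] &
                    vt$pos < win$end[i] & seg)
    S <- length(in_w)
    out$n_sites_used[i] <- S
    if (S == 0) next
    pihat <- sum(st$pi[in_w])
    vr <- cst$e1 * S + cst$e2 * S * (S - 1)
    if (vr > 0) out$tajima_d[i] <- (pihat - S / cst$a1) / sqrt(vr)
  }
  out
}

.tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Individual heterozygosity
#'
#' Heterozygous calls divided by the callable denominator. With
#' `genome_bp = NULL` the denominator is the individual's non-missing
#' variant-site count; given a genome size, it is `genome_bp` scaled by the
#' individual's non-missing fraction (variant plus assumed-invariant
#' callable sites), putting the estimate on a per-bp scale comparable with
#' pi.
#'
#' @param gm samples x sites dosage matrix.
#' @param genome_bp optional genome length in bp.
#' @return named numeric vector per sample (`NA` if nothing is callable).
#' @export
individual_heterozygosity <- function(gm, genome_bp = NULL) {
  n_ok <- rowSums(!is.na(gm))
  n_het <- rowSums(gm == 1L, na.rm = TRUE)
  denom <- if (is.null(genome_bp)) n_ok else
    genome_bp * n_ok / ncol(gm)
  ifelse(denom > 0, n_het / denom, NA_real_)
}

#' LD decay: mean r-squared by physical distance
#'
#' Pairwise squared dosage correlation (pairwise-complete) for all
#' within-chromosome site pairs separated by at most `max_dist` bp, binned
#' by distance.
#'
#' @inheritParams window_pi
#' @param max_dist maximum pair separation in bp.
#' @param bins number of equal-width distance bins.
#' @return data frame `dist_lo`, `dist_hi`, `n_pairs`, `mean_r2`
#'   (`NA` for empty bins).
#' @export
ld_decay <- function(gm, vt, max_dist = 1e5, bins = 20) {
  breaks <- seq(0, max_dist, length.out = bins + 1)
  sums <- numeric(bins); counts <- integer(bins)
  for (cn in unique(vt$chrom)) {
    idx <- which(vt$chrom == cn)
    pos <- vt$pos[idx]
    for (a in seq_along(idx)) {
      b <- a + 1
      while (b <= length(idx) && pos[b] - pos[a] <= max_dist) {
        r <- suppressWarnings(stats::cor(gm[, idx[a]], gm[, idx[b]],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r)) {
          bin <- min(bins, max(1L, ceiling((pos[b] - pos[a]) /
                                             (max_dist / bins))))
          sums[bin] <- sums[bin] + r * r
          counts[bin] <- counts[bin] + 1L
        }
        b <- b + 1
      }
    }
  }
  data.frame(dist_lo = breaks[-(bins + 1)], dist_hi = breaks[-1],
             n_pairs = counts,
             mean_r2 = ifelse(counts > 0, sums / counts, NA_real_))
}

#' Principal components of the genotype matrix
#'
#' Sites are mean-imputed, centered, and optionally scaled by
#' `sqrt(p(1-p))` (Patterson scaling); coordinates come from the SVD. The
#' sign convention makes the largest-magnitude coordinate on each axis
#' positive, so results are reproducible across platforms.
#'
#' @param gm samples x sites dosage matrix.
#' @param scale one of "patterson" or "none".
#' @param n_pc number of components to return.
#' @return list with `coords` (samples x n_pc), `explained` (fraction of
#'   total variance per axis).
#' @export
pca_genotypes <- function(gm, scale = c("patterson", "none"), n_pc = 10) {
  scale <- match.arg(scale)
  if (nrow(gm) < 2 || ncol(gm) < 2) stop("need >= 2 samples and >= 2 sites")
  X <- gm
  cm <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- cm[j]
  X <- sweep(X, 2, cm)
  if (scale == "patterson") {
    p <- cm / 2
    s <- sqrt(pmax(p * (1 - p), 0))
    ok <- s > 0
    X <- sweep(X[, ok, drop = FALSE], 2, s[ok], "/")
  }
  X <- X[, apply(X, 2, function(x) any(x != 0)), drop = FALSE]
  if (ncol(X) == 0) stop("genotype matrix has no variance")
  sv <- svd(X)
  n_pc <- min(n_pc, length(sv$d))
  coords <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)
  for (k in seq_len(n_pc)) {
    j <- which.max(abs(coords[, k]))
    if (coords[j, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(gm)
  colnames(coords) <- paste0("PC", seq_len(n_pc))
  list(coords = coords, explained = sv$d^2 / sum(sv$d^2))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()]; negative branch lengths are
#' clamped to zero with a warning.
#'
#' @param d symmetric non-negative distance matrix (or `dist`).
#' @return an [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(m < 0)) stop("distance matrix must be non-negative")
  tr <- ape::nj(m)
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Mantel and partial Mantel tests
#'
#' Pearson correlation of the condensed (lower-triangle) entries of two
#' distance matrices, with a one-sided upper-tail permutation p-value
#' `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`; permutations shuffle rows
#' and columns of the first matrix jointly. The partial variant correlates
#' the residuals of both matrices after regressing each on a third
#' (control) matrix; a constant control reduces to the plain test, and a
#' control identical to the second matrix leaves no variation, reported as
#' r = 0.
#'
#' @param dA,dB distance matrices (same taxa, same order).
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed for the permutations.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(dA, dB, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- as.matrix(dA); B <- as.matrix(dB)
  stopifnot(all(dim(A) == dim(B)))
  lt <- lower.tri(A)
  a <- A[lt]; b <- B[lt]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm))
  r <- stats::cor(a, b)
  n <- nrow(A)
  rp <- vapply(seq_len(n_perm), function(k) {
    pm <- sample.int(n)
    stats::cor(A[pm, pm][lt], b)
  }, numeric(1))
  list(r = r, p = (1 + sum(rp >= r)) / (n_perm + 1), n_perm = n_perm)
}

#' @rdname mantel_test
#' @param dC control distance matrix for the partial test.
#' @export
partial_mantel_test <- function(dA, dB, dC, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- as.matrix(dA); B <- as.matrix(dB); C <- as.matrix(dC)
  lt <- lower.tri(A)
  cvec <- C[lt]
  if (stats::sd(cvec) == 0) return(mantel_test(A, B, n_perm))
  res_on_c <- function(x) stats::resid(stats::lm(x ~ cvec))
  a <- A[lt]; b <- B[lt]
  rb <- res_on_c(b)
  if (stats::sd(a) == 0 || stats::sd(rb) < 1e-12) {
    warning("no residual variation after controlling; partial r set to 0")
    return(list(r = 0, p = NA_real_, n_perm = n_perm))
  }
  ra <- res_on_c(a)
  if (stats::sd(ra) < 1e-12)
    return(list(r = 0, p = NA_real_, n_perm = n_perm))
  r <- stats::cor(ra, rb)
  n <- nrow(A)
  rp <- vapply(seq_len(n_perm), function(k) {
    pm <- sample.int(n)
    ap <- A[pm, pm][lt]
    if (stats::sd(ap) == 0) return(-Inf)
    stats::cor(res_on_c(ap), rb)
  }, numeric(1))
  list(r = r, p = (1 + sum(rp >= r)) / (n_perm + 1), n_perm = n_perm)
}

#' Intersect FST outlier windows with a within-lineage sweep score
#'
#' Candidate selective sweeps are windows in the upper `top_quantile` tail
#' of FST that are also flagged by a supplied within-lineage score (any
#' sweep statistic computed externally: reduced pi, composite likelihood,
#' ...). The within-score is pluggable: a logical vector aligned to the
#' windows, or a function mapping the window table to one.
#'
#' @param fst_windows window table from [window_fst()] (columns incl. `fst`).
#' @param within_score logical vector or `function(windows) -> logical`.
#' @param top_quantile FST quantile defining outliers (default 0.95).
#' @return the window table with logical columns `fst_outlier`,
#'   `within_flag`, `candidate`.
#' @export
sweep_scan <- function(fst_windows, within_score, top_quantile = 0.95) {
  if (nrow(fst_windows) < 20)
    warning("fewer than 20 windows: the FST quantile is unstable")
  flag <- if (is.function(within_score)) within_score(fst_windows) else
    as.logical(within_score)
  stopifnot(length(flag) == nrow(fst_windows))
  cut <- stats::quantile(fst_windows$fst, top_quantile, na.rm = TRUE,
                         names = FALSE)
  out <- fst_windows
  out$fst_outlier <- !is.na(out$fst) & out$fst >= cut
  out$within_flag <- flag %in% TRUE
  out$candidate <- out$fst_outlier & out$within_flag
  out
}

# resolve a population specification (ids, logical, or indices) to rows
.subset_pop <- function(gm, pop) {
  if (is.null(pop)) return(gm)
  if (is.character(pop)) {
    idx <- match(pop, rownames(gm))
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(pop[is.na(idx)], collapse = ", "))
    return(gm[idx, , drop = FALSE])
  }
  gm[pop, , drop = FALSE]
}
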