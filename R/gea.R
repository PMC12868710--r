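#' Prune correlated environmental variables
#'
#' Greedy removal: while any pair of variables has |Pearson r| at or above
#' `r_max`, drop the variable with the highest mean absolute correlation to
#' the others (ties broken by column order). Retained variables are
#' standardized to mean 0, sd 1.
#'
#' @param raw_env matrix/data frame, samples (or sites) x variables.
#' @param r_max correlation threshold (default 0.7; the result satisfies
#'   max pairwise |r| < `r_max`).
#' @return standardized matrix of the retained variables.
#' @export
prune_env <- function(raw_env, r_max = 0.7) {
  E <- as.matrix(raw_env)
  if (ncol(E) < 2) return(scale(E))
  keep <- seq_len(ncol(E))
  repeat {
    cc <- abs(suppressWarnings(stats::cor(E[, keep, drop = FALSE])))
    cc[is.na(cc)] <- 1          # constant columns count as redundant
    diag(cc) <- 0
    if (length(keep) < 2 || max(cc) < r_max) break
    worst <- which.max(colMeans(cc))
    keep <- keep[-worst]
  }
  out <- scale(E[, keep, drop = FALSE])
  out[!is.finite(out)] <- 0
  out
}

#' Latent-factor genotype-environment association
#'
#' Deterministic latent-factor regression in the LFMM spirit: the top `K`
#' left singular vectors of the centered, scaled genotype matrix serve as
#' structure covariates, and each locus is regressed on each environmental
#' variable plus the factors. Squared t-statistics are rescaled by the
#' genomic inflation factor (median chi-squared calibration) before
#' per-variable Benjamini-Hochberg adjustment. A locus is an outlier when
#' it is significant (q < `fdr`) for at least `min_vars` variables.
#'
#' @param gm samples x sites dosage matrix (MAF-filtered loci).
#' @param env samples x variables matrix (standardized; see [prune_env()]).
#' @param K number of latent factors (default 3); `K = 0` gives plain
#'   per-variable regression.
#' @param fdr per-variable FDR threshold (default 0.05).
#' @param min_vars variables required for outlier status (default 3).
#' @param gif apply genomic-inflation calibration (default TRUE).
#' @return object of class `gea_result`: `p`, `q` (loci x variables),
#'   `n_significant`, `outlier` (logical per locus), `lambda` per variable,
#'   `method = "lfmm"`.
#' @export
lfmm_assoc <- function(gm, env, K = 3, fdr = 0.05, min_vars = 3,
                       gif = TRUE) {
  E <- as.matrix(env)
  n <- nrow(gm)
  if (K >= n) stop("K must be smaller than the number of samples")
  Y <- .impute_center(gm)
  sds <- apply(Y, 2, stats::sd)
  ok <- sds > 0
  Ys <- sweep(Y[, ok, drop = FALSE], 2, sds[ok], "/")
  U <- NULL
  if (K > 0) {
    sv <- svd(Ys, nu = K, nv = 0)
    U <- sv$u
  }
  S <- ncol(gm)
  nv <- ncol(E)
  P <- matrix(NA_real_, S, nv)
  lambda <- numeric(nv)
  for (v in seq_len(nv)) {
    X <- cbind(1, E[, v], U)
    p_x <- ncol(X)
    qrX <- qr(X)
    coefs <- qr.coef(qrX, Y)
    fit <- qr.fitted(qrX, Y)
    rss <- colSums((Y - fit)^2)
    df <- n - p_x
    XtXinv22 <- solve(crossprod(X))[2, 2]
    se <- sqrt(rss / df * XtXinv22)
    tstat <- coefs[2, ] / se
    # exact small-sample p, then squared-normal scale for the median-chi2
    # genomic-inflation calibration
    p_raw <- 2 * stats::pt(-abs(tstat), df = df)
    chi2 <- stats::qnorm(pmax(p_raw / 2, 1e-300))^2
    lam <- 1
    if (gif) {
      lam <- stats::median(chi2, na.rm = TRUE) / stats::qchisq(0.5, 1)
      if (!is.finite(lam) || lam <= 0) lam <- 1
    }
    lambda[v] <- lam
    P[, v] <- stats::pchisq(chi2 / lam, df = 1, lower.tail = FALSE)
  }
  Q <- apply(P, 2, stats::p.adjust, method = "BH")
  n_sig <- rowSums(Q < fdr, na.rm = TRUE)
  res <- list(p = P, q = Q, n_significant = n_sig,
              outlier = n_sig >= min_vars, lambda = lambda,
              method = "lfmm", K = K, fdr = fdr, min_vars = min_vars)
  class(res) <- "gea_result"
  res
}

#' Redundancy-analysis outlier detection
#'
#' Constrained ordination computed directly: centered (mean-imputed)
#' dosages are regressed on the environmental matrix, and the SVD of the
#' fitted-value matrix gives the RDA axes. Locus loadings (right singular
#' vectors) are standardized per axis; a locus is an outlier when |z|
#' exceeds `sd_mult` (default 3.5, a two-tailed normal tail of about
#' 4.65e-4) on at least one of the first `n_axes` axes. Collinear
#' environmental columns are dropped with a warning.
#'
#' With several weakly correlated predictors, adaptive signal spreads over
#' all constrained axes while the leading axes are dominated by neutral
#' population structure, so the default examines every constrained axis;
#' set `n_axes = 3` to restrict attention to the leading ordination.
#'
#' @inheritParams lfmm_assoc
#' @param n_axes number of constrained axes examined (default: all, i.e.
#'   the number of independent environmental predictors).
#' @param sd_mult loading z-score cutoff (default 3.5).
#' @return object of class `gea_result`: `loadings` (loci x axes `z`
#'   scores), `outlier`, `eig`, `method = "rda"`.
#' @export
rda_outliers <- function(gm, env, n_axes = NULL, sd_mult = 3.5) {
  E <- as.matrix(env)
  if (nrow(gm) <= ncol(E))
    stop("need more samples than environmental variables")
  qrE <- qr(scale(E))
  if (qrE$rank < ncol(E)) {
    warning("dropping ", ncol(E) - qrE$rank,
            " collinear environmental column(s)")
    E <- E[, qrE$pivot[seq_len(qrE$rank)], drop = FALSE]
  }
  E <- scale(E)
  Y <- .impute_center(gm)
  fit <- qr.fitted(qr(cbind(1, E)), Y)
  n_axes <- if (is.null(n_axes)) ncol(E) else min(n_axes, ncol(E))
  sv <- svd(fit, nu = 0, nv = n_axes)
  V <- sv$v[, seq_len(n_axes), drop = FALSE]
  for (k in seq_len(n_axes)) {        # fixed sign convention
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  Z <- scale(V)
  out <- rowSums(abs(Z) > sd_mult) > 0
  res <- list(loadings = Z, outlier = out,
              eig = sv$d[seq_len(n_axes)]^2, method = "rda",
              n_axes = n_axes, sd_mult = sd_mult)
  class(res) <- "gea_result"
  res
}

#' @export
print.gea_result <- function(x, ...) {
  cat("GEA result (", x$method, "): ", length(x$outlier), " loci, ",
      sum(x$outlier), " outlier(s)\n", sep = "")
  invisible(x)
}

#' Core adaptive locus set
#'
#' Intersection of the outlier sets of two association methods (typically
#' latent-factor regression and RDA) over the same locus universe.
#'
#' @param lfmm,rda `gea_result` objects of equal length.
#' @return integer vector of locus indices in both outlier sets.
#' @export
core_adaptive_set <- function(lfmm, rda) {
  stopifnot(length(lfmm$outlier) == length(rda$outlier))
  core <- which(lfmm$outlier & rda$outlier)
  if (!length(core)) warning("no loci shared between the outlier sets")
  core
}

.impute_center <- function(gm) {
  X <- gm
  cm <- colMeans(X, na.rm = TRUE)
  nas <- which(colSums(is.na(X)) > 0)
  for (j in nas) X[is.na(X[, j]), j] <- cm[j]
  sweep(X, 2, cm)
}
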