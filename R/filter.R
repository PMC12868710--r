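#' Per-site summaries from a genotype matrix
#'
#' `site_maf()` is the minor-allele frequency computed on non-missing
#' alleles; `site_missing_rate()` the fraction of missing genotypes.
#'
#' @param gm samples x sites dosage matrix.
#' @return numeric vector, one entry per site (`NaN` for all-missing sites).
#' @export
site_maf <- function(gm) {
  n <- 2 * colSums(!is.na(gm))
  p <- colSums(gm, na.rm = TRUE) / n
  pmin(p, 1 - p)
}

#' @rdname site_maf
#' @export
site_missing_rate <- function(gm) colMeans(is.na(gm))

#' Apply GATK-style hard filters to a variant table
#'
#' A site is removed when any of the following holds (strict inequalities;
#' sites exactly at a threshold are retained): QD < 2.0, MQ < 40.0,
#' FS > 60.0, SOR > 3.0, MQRankSum < -12.5, ReadPosRankSum < -8.0.
#' Absent annotations (e.g. on simulated data that does not model caller
#' statistics) are treated as passing.
#'
#' @param vt variant table, optionally carrying QC annotation columns.
#' @param thresholds named list overriding any of the defaults
#'   `QD`, `MQ`, `FS`, `SOR`, `MQRankSum`, `ReadPosRankSum`.
#' @return the filtered variant table; `attr(, "idx")` holds the retained
#'   row indices of the input (use it to subset the genotype matrix).
#' @export
apply_hard_filters <- function(vt, thresholds = list()) {
  th <- utils::modifyList(list(QD = 2.0, MQ = 40.0, FS = 60.0, SOR = 3.0,
                               MQRankSum = -12.5, ReadPosRankSum = -8.0),
                          thresholds)
  fail <- rep(FALSE, nrow(vt))
  lt <- function(col, cut) !is.na(col) & col < cut
  gt <- function(col, cut) !is.na(col) & col > cut
  if (!is.null(vt$QD)) fail <- fail | lt(vt$QD, th$QD)
  if (!is.null(vt$MQ)) fail <- fail | lt(vt$MQ, th$MQ)
  if (!is.null(vt$FS)) fail <- fail | gt(vt$FS, th$FS)
  if (!is.null(vt$SOR)) fail <- fail | gt(vt$SOR, th$SOR)
  if (!is.null(vt$MQRankSum)) fail <- fail | lt(vt$MQRankSum, th$MQRankSum)
  if (!is.null(vt$ReadPosRankSum))
    fail <- fail | lt(vt$ReadPosRankSum, th$ReadPosRankSum)
  out <- vt[!fail, , drop = FALSE]
  attr(out, "idx") <- which(!fail)
  out
}

#' Select the core-variant set
#'
#' Retains biallelic SNPs with per-site missingness at or below
#' `max_missing`. Hard filters are expected to have been applied upstream.
#'
#' @param vt variant table (aligned to `gm` columns).
#' @param gm samples x sites dosage matrix.
#' @param max_missing maximum tolerated per-site missing fraction.
#' @return filtered variant table with retained indices in `attr(, "idx")`.
#' @export
select_core_variants <- function(vt, gm, max_missing = 0.2) {
  stopifnot(nrow(vt) == ncol(gm))
  keep <- vt$biallelic & vt$is_snp &
    site_missing_rate(gm) <= max_missing
  if (!any(keep)) warning("core-variant selection removed every site")
  out <- vt[keep, , drop = FALSE]
  attr(out, "idx") <- which(keep)
  out
}

#' Minor-allele-frequency filter
#'
#' Retains sites with MAF strictly greater than `min_maf`, computed on
#' non-missing alleles. All-missing sites are removed with a warning.
#'
#' @inheritParams select_core_variants
#' @param min_maf MAF cutoff (default 0.05; strict `>`).
#' @return filtered variant table with retained indices in `attr(, "idx")`.
#' @export
maf_filter <- function(gm, vt, min_maf = 0.05) {
  stopifnot(nrow(vt) == ncol(gm))
  maf <- site_maf(gm)
  if (anyNA(maf) || any(is.nan(maf)))
    warning("all-missing site(s) removed by MAF filter")
  keep <- !is.nan(maf) & !is.na(maf) & maf > min_maf
  out <- vt[keep, , drop = FALSE]
  attr(out, "idx") <- which(keep)
  out
}

#' Windowed greedy LD pruning
#'
#' PLINK-style pruning: within sliding windows of `window_snps` SNPs
#' (advanced by `step`), any retained pair with squared dosage correlation
#' above `r2_max` has its right-hand (downstream) member removed. r-squared
#' is composite LD on dosages, pairwise-complete over missing genotypes.
#' Pairs are only considered within a chromosome; the result is
#' deterministic (keep-left rule).
#'
#' @inheritParams select_core_variants
#' @param window_snps window size in SNPs (default 50).
#' @param step window step in SNPs (default 10).
#' @param r2_max r-squared above which the right-hand SNP is removed.
#' @return filtered variant table with retained indices in `attr(, "idx")`.
#' @export
ld_prune <- function(gm, vt, window_snps = 50, step = 10, r2_max = 0.2) {
  stopifnot(nrow(vt) == ncol(gm))
  S <- nrow(vt)
  keep <- rep(TRUE, S)
  if (S >= 2) {
    for (start in seq(1, S, by = step)) {
      idx <- start:min(start + window_snps - 1, S)
      idx <- idx[vt$chrom[idx] == vt$chrom[start]]
      for (a in seq_along(idx)) {
        i <- idx[a]
        if (!keep[i]) next
        for (b in seq_along(idx)) {
          if (b <= a) next
          j <- idx[b]
          if (!keep[j]) next
          r <- suppressWarnings(stats::cor(gm[, i], gm[, j],
                                           use = "pairwise.complete.obs"))
          if (!is.na(r) && r * r > r2_max) keep[j] <- FALSE
        }
      }
      if (max(idx) >= S) break
    }
  }
  out <- vt[keep, , drop = FALSE]
  attr(out, "idx") <- which(keep)
  out
}
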