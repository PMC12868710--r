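# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles with different code paths than the
# package implementation.

# mean pairwise difference per bp over all haplotype pairs
oracle_pi_haplotypes <- function(hap, len_bp) {
  n <- nrow(hap)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(hap[i, ] != hap[j, ])
  tot / choose(n, 2) / len_bp
}

# Hudson per-site terms evaluated literally
oracle_fst_sites <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# textbook Tajima's D from a 0/1 haplotype matrix (rows = haplotypes)
oracle_tajima_d <- function(hap) {
  n <- nrow(hap)
  seg <- which(colSums(hap) > 0 & colSums(hap) < n)
  S <- length(seg)
  if (S == 0) return(NA_real_)
  k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    k <- k + sum(hap[i, seg] != hap[j, seg])
  k <- k / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# all-pairs mean r^2 within a distance bin
oracle_ld_mean_r2 <- function(gm, pos, lo, hi) {
  vals <- c()
  for (i in seq_along(pos)) for (j in seq_along(pos)) {
    if (j <= i) next
    d <- abs(pos[j] - pos[i])
    if (d > lo && d <= hi) {
      r <- suppressWarnings(cor(gm[, i], gm[, j],
                                use = "pairwise.complete.obs"))
      if (!is.na(r)) vals <- c(vals, r^2)
    }
  }
  if (length(vals)) mean(vals) else NA_real_
}

# single-pass ROH scan for clean fixtures: maximal runs of non-het calls
oracle_roh_simple <- function(geno, pos, min_snps, min_len,
                              max_het_run = 0) {
  is_hom <- is.na(geno) | geno != 1L
  r <- rle(is_hom)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- data.frame(lo = starts[r$values], hi = ends[r$values])
  segs$n <- segs$hi - segs$lo + 1L
  segs$len <- pos[segs$hi] + 1L - pos[segs$lo]
  segs[segs$n >= min_snps & segs$len >= min_len, , drop = FALSE]
}

# degeneracy of one codon position by explicit enumeration through
# Biostrings translation (independent of the package's codon helpers)
oracle_fold <- function(codon, pos_in_codon) {
  bases <- c("A", "C", "G", "T")
  tr <- function(x) as.character(
    Biostrings::translate(Biostrings::DNAString(x), no.init.codon = TRUE))
  aa0 <- tr(codon)
  refb <- substr(codon, pos_in_codon, pos_in_codon)
  n_syn <- 0
  for (b in setdiff(bases, refb)) {
    alt <- codon
    substr(alt, pos_in_codon, pos_in_codon) <- b
    if (tr(alt) == aa0) n_syn <- n_syn + 1
  }
  if (n_syn == 0) "0-fold" else if (n_syn == 3) "4-fold" else "other"
}

# distances on a 4-taxon additive tree ((A:a,B:b):m,(C:c,D:d))
oracle_additive_dist <- function(a, b, c, d, m) {
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- a + b
  dm["C", "D"] <- dm["D", "C"] <- c + d
  dm["A", "C"] <- dm["C", "A"] <- a + m + c
  dm["A", "D"] <- dm["D", "A"] <- a + m + d
  dm["B", "C"] <- dm["C", "B"] <- b + m + c
  dm["B", "D"] <- dm["D", "B"] <- b + m + d
  dm
}

# closed-form expected Hudson FST for a clean two-population split
# (no migration, constant sizes): 1 - mean within / between coalescence
oracle_split_fst <- function(T_split, N1, N2, N_anc) {
  e_tw <- function(N) {
    e <- exp(-T_split / (2 * N))
    2 * N * (1 - e) + 2 * N_anc * e
  }
  e_tb <- T_split + 2 * N_anc
  1 - (e_tw(N1) + e_tw(N2)) / (2 * e_tb)
}

# small helper: dosage matrix -> haplotype expansion is not unique, so
# clean fixtures are built directly from haplotypes
hap_to_gm <- function(hap) {
  odd <- seq(1, nrow(hap), by = 2)
  hap[odd, , drop = FALSE] + hap[odd + 1, , drop = FALSE]
}

make_vt <- function(pos, chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             ref = "A", alt = "T", biallelic = TRUE, is_snp = TRUE,
             stringsAsFactors = FALSE)
}

small_sim <- function(seed = 1, ...) {
  cfg <- demography_config(samples_per_lineage = c(6, 4, 6),
                           genome_length = 2e5, seed = seed, ...)
  simulate_genotypes(cfg)
}
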