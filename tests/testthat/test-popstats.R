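test_that("windowed pi matches the mean-pairwise-difference oracle", {
  # 4 diploids, one segregating site at p = 0.5 in a 1000-bp window:
  # haplotype-pair average = 0.5 * 8/7 / 1000
  hap <- matrix(0L, 8, 1)
  hap[1:4, 1] <- 1L
  gm <- hap_to_gm(hap)
  vt <- make_vt(500)
  out <- window_pi(gm, vt, c(chr1 = 1000))
  expect_equal(out$pi, 0.5 * 8 / 7 / 1000, tolerance = 1e-12)
  expect_equal(out$pi, oracle_pi_haplotypes(hap, 1000), tolerance = 1e-12)
  # multi-site fixture against the oracle
  set.seed(4)
  hap2 <- matrix(rbinom(8 * 30, 1, 0.3), 8, 30)
  gm2 <- hap_to_gm(hap2)
  out2 <- window_pi(gm2, make_vt(seq_len(30) * 10), c(chr1 = 1000))
  expect_equal(out2$pi, oracle_pi_haplotypes(hap2, 1000),
               tolerance = 1e-12)
  # monomorphic window
  gm3 <- matrix(0L, 4, 2)
  expect_equal(window_pi(gm3, make_vt(c(1, 2)), c(chr1 = 1000))$pi, 0)
})

test_that("Hudson FST follows the ratio-of-sums formula", {
  # fixed difference
  gmA <- matrix(2L, 5, 1); gmB <- matrix(0L, 5, 1)
  gm <- rbind(gmA, gmB)
  expect_equal(hudson_fst(gm, 1:5, 6:10), 1)
  # p1 = p2 = 0.5 with 20 alleles each: small negative value
  set.seed(2)
  gmA <- matrix(rep(c(0L, 2L), 5), 10, 1)
  gmB <- matrix(rep(c(2L, 0L), 5), 10, 1)
  gm <- rbind(gmA, gmB)
  got <- hudson_fst(gm, 1:10, 11:20)
  expect_equal(got, oracle_fst_sites(0.5, 20, 0.5, 20), tolerance = 1e-12)
  expect_lt(got, 0)
  # multi-site window equals the oracle on the same frequencies
  set.seed(9)
  g1 <- matrix(rbinom(10 * 40, 2, 0.3), 10, 40)
  g2 <- matrix(rbinom(10 * 40, 2, 0.6), 10, 40)
  gm <- rbind(g1, g2)
  p1 <- colMeans(g1) / 2; p2 <- colMeans(g2) / 2
  keep <- TRUE
  expect_equal(hudson_fst(gm, 1:10, 11:20),
               oracle_fst_sites(p1, 20, p2, 20), tolerance = 1e-12)
  # FST is invariant to permuting samples within populations
  pm <- c(sample(1:10), sample(11:20))
  expect_equal(hudson_fst(gm[pm, ], 1:10, 11:20),
               hudson_fst(gm, 1:10, 11:20))
})

test_that("Tajima's D equals the textbook formula and is NA when S = 0", {
  set.seed(11)
  hap <- matrix(rbinom(10 * 5, 1, 0.4), 10, 5)
  hap[, 3] <- c(rep(1, 4), rep(0, 6))
  gm <- hap_to_gm(hap)
  out <- window_tajima_d(gm, make_vt(1:5 * 100), c(chr1 = 1000))
  expect_equal(out$tajima_d, oracle_tajima_d(hap), tolerance = 1e-10)
  # no segregating sites -> missing, not zero
  gm0 <- matrix(2L, 5, 3)
  out0 <- window_tajima_d(gm0, make_vt(1:3), c(chr1 = 1000))
  expect_true(is.na(out0$tajima_d))
  expect_error(window_tajima_d(gm0[1, , drop = FALSE], make_vt(1:3),
                               c(chr1 = 1000)), "4 haplotypes")
})

test_that("individual heterozygosity counts het calls over callable sites", {
  gm <- matrix(0L, 2, 1000)
  gm[1, 1:10] <- 1L
  expect_equal(unname(individual_heterozygosity(gm, genome_bp = 1000)[1]),
               0.01)
  expect_equal(unname(individual_heterozygosity(gm)[2]), 0)
  # planting ROH can only reduce heterozygosity
  sim <- small_sim(seed = 23)
  before <- individual_heterozygosity(sim$gm)
  planted <- plant_roh(sim, n_tracts = 2, length_range = c(4e4, 6e4),
                       samples = rownames(sim$gm)[1], seed = 1)
  after <- individual_heterozygosity(planted$gm)
  expect_lte(after[1], before[1])
  expect_equal(after[-1], before[-1])
})

test_that("LD decay matches the exhaustive pair average", {
  set.seed(31)
  n <- 20; S <- 40
  gm <- matrix(rbinom(n * S, 2, 0.5), n, S)
  pos <- sort(sample(1:5000, S))
  gm[, 2] <- gm[, 1]                # duplicated column
  vt <- make_vt(pos)
  out <- ld_decay(gm, vt, max_dist = 5000, bins = 5)
  for (b in seq_len(5)) {
    want <- oracle_ld_mean_r2(gm, pos, out$dist_lo[b], out$dist_hi[b])
    expect_equal(out$mean_r2[b], want, tolerance = 1e-12)
  }
  # the duplicated pair contributes r2 = 1
  d <- pos[2] - pos[1]
  r <- cor(gm[, 1], gm[, 2])
  expect_equal(r^2, 1)
})

test_that("PCA separates planted clusters with fixed sign convention", {
  set.seed(41)
  gA <- matrix(rbinom(10 * 200, 2, 0.15), 10, 200)
  gB <- matrix(rbinom(10 * 200, 2, 0.85), 10, 200)
  gm <- rbind(gA, gB)
  rownames(gm) <- paste0("s", 1:20)
  pc <- pca_genotypes(gm)
  labels <- rep(c(0, 1), each = 10)
  # PC1 linearly separates the clusters
  expect_true(max(pc$coords[labels == 0, 1]) <
                min(pc$coords[labels == 1, 1]) ||
                min(pc$coords[labels == 0, 1]) >
                max(pc$coords[labels == 1, 1]))
  expect_lte(sum(pc$explained), 1 + 1e-8)
  # duplicated sample lands on identical coordinates
  gm2 <- rbind(gm, gm[1, , drop = FALSE])
  pc2 <- pca_genotypes(gm2)
  expect_equal(unname(pc2$coords[21, ]), unname(pc2$coords[1, ]),
               tolerance = 1e-8)
  expect_error(pca_genotypes(matrix(1L, 4, 5)), "variance")
})

test_that("neighbor joining recovers additive trees", {
  dm <- oracle_additive_dist(2, 3, 4, 5, 6)
  tr <- nj_tree(dm)
  expect_true(ape::is.binary(tr))
  # recovered tree reproduces the additive distances exactly
  ct <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(unname(ct), unname(dm), tolerance = 1e-10)
  # AB vs CD split recovered
  expect_true(ape::is.monophyletic(ape::root(tr, "A"), c("C", "D")))
  # permuted label order gives an isomorphic tree
  pm <- c(3, 1, 4, 2)
  tr2 <- nj_tree(dm[pm, pm])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  # ultrametric 3-taxon matrix pairs the close pair
  d3 <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  expect_equal(sort(t3$tip.label), c("x", "y", "z"))
  asym <- dm; asym[1, 2] <- 99
  expect_error(nj_tree(asym), "symmetric")
})

test_that("Mantel tests agree with vegan and respect permutation bounds", {
  set.seed(51)
  xy <- cbind(runif(8), runif(8))
  dA <- as.matrix(dist(xy))
  dB <- dA + matrix(runif(64, 0, 0.1), 8)
  dB <- (dB + t(dB)) / 2; diag(dB) <- 0
  got <- mantel_test(dA, dB, n_perm = 199, seed = 1)
  ref <- vegan::mantel(as.dist(dA), as.dist(dB), permutations = 199)
  expect_equal(got$r, unname(ref$statistic), tolerance = 1e-10)
  expect_gte(got$p, 1 / 200)
  # identity case
  expect_equal(mantel_test(dA, dA, n_perm = 99, seed = 2)$r, 1)
  # constant matrix -> NA
  expect_true(is.na(mantel_test(matrix(1, 8, 8) - diag(8) * 0, dB,
                                n_perm = 9)$r))
})

test_that("partial Mantel equals brute-force residual correlation", {
  set.seed(61)
  n <- 6
  mk <- function() {
    m <- matrix(runif(n * n), n); m <- m + t(m); diag(m) <- 0; m
  }
  dA <- mk(); dB <- mk(); dC <- mk()
  got <- partial_mantel_test(dA, dB, dC, n_perm = 99, seed = 3)
  lt <- lower.tri(dA)
  ra <- resid(lm(dA[lt] ~ dC[lt]))
  rb <- resid(lm(dB[lt] ~ dC[lt]))
  expect_equal(got$r, cor(ra, rb), tolerance = 1e-12)
  # matches vegan's partial-correlation formulation
  ref <- vegan::mantel.partial(as.dist(dA), as.dist(dB), as.dist(dC),
                               permutations = 99)
  expect_equal(got$r, unname(ref$statistic), tolerance = 1e-10)
  # constant control degenerates to the plain test
  dCc <- matrix(1, n, n); diag(dCc) <- 0
  expect_equal(partial_mantel_test(dA, dB, dCc, n_perm = 99, seed = 4)$r,
               mantel_test(dA, dB, n_perm = 99, seed = 4)$r)
  # controlling for the second matrix itself leaves nothing
  expect_warning(
    out <- partial_mantel_test(dA, dB, dB, n_perm = 9, seed = 5),
    "no residual variation")
  expect_equal(out$r, 0)
})

test_that("sweep candidates are the FST tail intersected with the score", {
  win <- data.frame(chrom = "chr1", start = 0:99 * 5000,
                    end = 0:99 * 5000 + 5e5,
                    n_sites_used = 10, fst = seq(0.01, 1, length.out = 100))
  out <- sweep_scan(win, within_score = rep(TRUE, 100))
  expect_equal(sum(out$fst_outlier), ceiling(0.05 * 100))
  expect_equal(sum(out$candidate), ceiling(0.05 * 100))
  # empty within-lineage score kills all candidates
  out0 <- sweep_scan(win, within_score = rep(FALSE, 100))
  expect_equal(sum(out0$candidate), 0)
  expect_warning(sweep_scan(win[1:10, ], rep(TRUE, 10)), "20 windows")
})

test_that("distance matrices are symmetric with zero diagonals", {
  sim <- small_sim(seed = 81)
  m <- linearized_fst_matrix(sim$gm, sim$meta$lineage)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
  g <- geo_distance_matrix(c(0, 0), c(0, 1))
  # one degree of longitude at the equator on the mean radius
  expect_equal(g[1, 2], 6371.0088 * pi / 180, tolerance = 1e-6)
  e <- env_distance_matrix(matrix(rnorm(12), 4))
  expect_true(isSymmetric(e))
})

test_that("window statistics are invariant to sample order", {
  sim <- small_sim(seed = 91)
  pm <- sample(nrow(sim$gm))
  gmp <- sim$gm[pm, , drop = FALSE]
  p1 <- window_pi(sim$gm, sim$vt, sim$chrom_lengths)
  p2 <- window_pi(gmp, sim$vt, sim$chrom_lengths)
  expect_equal(p1$pi, p2$pi)
  d1 <- window_tajima_d(sim$gm, sim$vt, sim$chrom_lengths)
  d2 <- window_tajima_d(gmp, sim$vt, sim$chrom_lengths)
  expect_equal(d1$tajima_d, d2$tajima_d)
})
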