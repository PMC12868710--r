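test_that("derived alleles follow the majority-homozygote rule", {
  # 6/10 individuals hom-ref -> alt derived
  gm <- matrix(c(rep(0L, 6), 1L, 1L, 2L, 2L), 10, 1)
  vt <- polarize_derived(gm, make_vt(10))
  expect_equal(vt$derived_allele, "alt")
  # 5/10 hom-ref, 5/10 het: exactly 50% -> excluded
  gm2 <- matrix(c(rep(0L, 5), rep(1L, 5)), 10, 1)
  expect_true(is.na(polarize_derived(gm2, make_vt(10))$derived_allele))
  # all het -> excluded
  gm3 <- matrix(1L, 10, 1)
  expect_false(polarize_derived(gm3, make_vt(10))$polarized)
  # majority hom-alt -> ref is derived, dosages flip
  gm4 <- matrix(c(rep(2L, 7), 0L, 1L, 1L), 10, 1)
  vt4 <- polarize_derived(gm4, make_vt(10))
  expect_equal(vt4$derived_allele, "ref")
  dd <- derived_dosage(gm4, vt4)
  expect_equal(dd[8, 1], 2L)
  expect_equal(dd[1, 1], 0L)
  # missing genotypes are excluded from the denominator
  gm5 <- matrix(c(rep(0L, 3), 1L, 1L, rep(NA, 5)), 10, 1)
  expect_equal(polarize_derived(gm5, make_vt(10))$derived_allele, "alt")
})

test_that("codon classifier agrees with the genetic code, both strands", {
  ref <- Biostrings::DNAStringSet(c(
    chr1 = paste0("AAAA", "ATG", "TGG", "GGA", "TAA", "TTTT")))
  gff <- data.frame(seqid = "chr1", source = "t", type = c("gene", "CDS"),
                    start = 5L, end = 16L, score = ".", strand = "+",
                    phase = c(".", "0"), attributes = c("ID=g1", "ID=c1"),
                    stringsAsFactors = FALSE)
  # TGG -> TGA (stop gained): position of third base of codon 2
  vt <- make_vt(c(10 - 1, 15 - 1, 2))       # 0-based: TGG G>A, GGA A>G
  vt$ref <- c("G", "A", "A"); vt$alt <- c("A", "G", "C")
  ann <- classify_effects(vt, ref, gff)
  expect_equal(ann$class, c("stop_gained", "synonymous", "other"))
  expect_true(ann$lof[1])
  # reverse-strand gene: same coding change classified identically
  refm <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "AAAA",
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("ATGTGGGGATAA"))),
    "TTTT")))
  gffm <- gff; gffm$strand <- "-"
  # coding TGG G>A maps to genomic position of the complementary base
  # coding pos 6 (third base of codon 2, 1-based) -> genomic end - 6 + 1
  gpos <- 16 - 6 + 1
  vtm <- make_vt(gpos - 1)
  vtm$ref <- "C"; vtm$alt <- "T"            # complement of G>A
  annm <- classify_effects(vtm, refm, gffm)
  expect_equal(annm$class, "stop_gained")
  # frame inconsistency is a hard error naming the feature
  gbad <- gff; gbad$end <- 15L
  expect_error(classify_effects(vt, ref, gbad), "c1|frame")
})

test_that("single-base codon changes match direct translation everywhere", {
  # every codon x position x alternative base, against Biostrings
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  bases <- c("A", "C", "G", "T")
  set.seed(1)
  pick <- sample(length(codons) * 9, 150)   # subsample for speed
  k <- 0
  for (codon in codons) for (cp in 1:3) for (b in setdiff(bases, substr(codon, cp, cp))) {
    k <- k + 1
    if (!(k %in% pick)) next
    ef <- relictpop:::.codon_effect(codon, cp, b)
    alt <- codon; substr(alt, cp, cp) <- b
    aa0 <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                              no.init.codon = TRUE))
    aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(alt),
                                              no.init.codon = TRUE))
    want <- if (aa0 == aa1) "synonymous" else if (aa1 == "*")
      "stop_gained" else if (aa0 == "*") "stop_lost" else "missense"
    expect_equal(ef$class, want, info = paste(codon, cp, b))
  }
})

test_that("Grantham lookups reproduce the published matrix", {
  expect_equal(grantham_score("L", "I"), 5)
  expect_equal(grantham_score("C", "W"), 215)
  expect_equal(grantham_score("S", "R"), 110)
  expect_equal(grantham_score("D", "E"), 45)
  expect_equal(grantham_score("G", "W"), 184)
  expect_equal(grantham_score("A", "A"), 0)
  expect_false(grantham_deleterious(grantham_score("L", "I")))
  expect_true(grantham_deleterious(grantham_score("C", "W")))
  expect_error(grantham_score("B", "A"), "non-standard")
  # full symmetry over all 190 pairs
  aa <- rownames(relictpop:::.grantham_matrix)
  for (i in seq_along(aa)) for (j in seq_along(aa))
    if (i < j)
      expect_equal(grantham_score(aa[i], aa[j]),
                   grantham_score(aa[j], aa[i]))
})

test_that("load ratios implement both stated formulas", {
  # one individual with hom = 3, het = 4 over 7 deleterious sites
  gm <- matrix(c(2L, 2L, 2L, 1L, 1L, 1L, 1L), 1, 7)
  gm <- rbind(gm, matrix(0L, 9, 7))        # background keeps alt derived
  rownames(gm) <- paste0("s", 1:10)
  vt <- make_vt(1:7 * 10)
  vt <- polarize_derived(gm, vt)
  ann <- data.frame(chrom = "chr1", pos = 1:7 * 10, class = "missense",
                    deleterious = TRUE, lof = FALSE)
  af <- load_ratio(gm, vt, ann, "DEL", "allele_fraction")
  lit <- load_ratio(gm, vt, ann, "DEL", "literal")
  expect_equal(af$ratio[1], 6 / 10)
  expect_equal(lit$ratio[1], 6 / 7)
  # het only -> 0 under both
  expect_equal(af$ratio[af$n_hom == 0 & af$n_het > 0], numeric(0))
  gm2 <- rbind(matrix(1L, 1, 7), matrix(0L, 9, 7))
  rownames(gm2) <- paste0("t", 1:10)
  vt2 <- polarize_derived(gm2, make_vt(1:7 * 10))
  af2 <- load_ratio(gm2, vt2, ann, "DEL", "allele_fraction")
  expect_equal(af2$ratio[1], 0)
  expect_equal(load_ratio(gm2, vt2, ann, "DEL", "literal")$ratio[1], 0)
  # allele-fraction ratio is invariant to duplicating every individual
  gmd <- rbind(gm, gm)
  rownames(gmd) <- paste0("d", 1:20)
  vtd <- polarize_derived(gmd, make_vt(1:7 * 10))
  afd <- load_ratio(gmd, vtd, ann, "DEL", "allele_fraction")
  expect_equal(afd$ratio[1], af$ratio[1])
  # zero-denominator individuals are NA
  expect_true(all(is.na(af$ratio[af$n_hom + af$n_het == 0])))
})

test_that("LOF density in vs out of ROH is compared by rank-sum", {
  set.seed(3)
  n <- 8; S <- 30
  gm <- matrix(rbinom(n * S, 2, 0.2), n, S)
  rownames(gm) <- paste0("s", 1:n)
  vt <- polarize_derived(rbind(gm, matrix(0L, 20, S)), make_vt(1:S * 100))
  ann <- data.frame(chrom = "chr1", pos = 1:S * 100, class = "stop_gained",
                    deleterious = FALSE, lof = TRUE)
  segs <- data.frame(sample = paste0("s", 1:n), chrom = "chr1",
                     start = 0L, end = 1500L)
  out <- roh_lof_enrichment(gm, vt[1:S, ], ann, segs, genome_bp = 3000)
  expect_equal(nrow(out$per_sample), n)
  # counts partition hom-LOF calls
  dd <- derived_dosage(rbind(gm, matrix(0L, 20, S)), vt)[1:n, , drop = FALSE]
  expect_equal(out$per_sample$n_in + out$per_sample$n_out,
               unname(rowSums(dd == 2, na.rm = TRUE)))
  # all LOF inside ROH -> zero outside density
  segs_all <- data.frame(sample = paste0("s", 1:n), chrom = "chr1",
                         start = 0L, end = 3000L + 1L)
  out2 <- roh_lof_enrichment(gm, vt[1:S, ], ann, segs_all, 3001)
  expect_true(all(out2$per_sample$n_out == 0))
  # identical densities -> p = 1
  out3 <- roh_lof_enrichment(gm, vt[1:S, ], ann,
                             data.frame(sample = paste0("s", 1:n),
                                        chrom = "chr1", start = 0L,
                                        end = 1500L), 3000)
  dens <- out3$per_sample
  sym <- suppressWarnings(stats::wilcox.test(dens$dens_in,
                                             dens$dens_in))
  expect_equal(sym$p.value, 1)
  # samples without ROH have NA inside density
  out4 <- roh_lof_enrichment(gm, vt[1:S, ], ann, segs[0, ], 3000)
  expect_true(all(is.na(out4$per_sample$dens_in)))
})

test_that("degeneracy classes equal brute-force codon enumeration", {
  rc <- simulate_reference_and_cds(c(chr1 = 6e4, chr2 = 6e4),
                                   n_genes = 6, seed = 13)
  deg <- degeneracy_sites(rc$ref, rc$gff)
  cds <- rc$cds
  # spot-check: third base of a glycine codon is 4-fold, ATG/TGG 0-fold
  expect_equal(oracle_fold("GGA", 3), "4-fold")
  expect_equal(oracle_fold("ATG", 1), "0-fold")
  expect_equal(oracle_fold("ATG", 2), "0-fold")
  expect_equal(oracle_fold("ATG", 3), "0-fold")
  expect_equal(oracle_fold("TGG", 3), "0-fold")
  # exhaustive agreement on one full CDS, strand-aware
  i <- which(cds$strand == "-")[1]
  if (is.na(i)) i <- 1
  gseq <- Biostrings::subseq(rc$ref[[cds$chrom[i]]], cds$start[i],
                             cds$end[i])
  coding <- if (cds$strand[i] == "-")
    as.character(Biostrings::reverseComplement(gseq)) else
      as.character(gseq)
  key <- paste(deg$chrom, deg$pos)
  for (cpos in seq_len(nchar(coding))) {
    codon_i <- (cpos - 1) %/% 3 + 1
    codon <- substr(coding, (codon_i - 1) * 3 + 1, codon_i * 3)
    want <- oracle_fold(codon, (cpos - 1) %% 3 + 1)
    gpos1 <- if (cds$strand[i] == "+") cds$start[i] + cpos - 1 else
      cds$end[i] - cpos + 1
    got <- deg$fold[match(paste(cds$chrom[i], gpos1 - 1), key)]
    expect_equal(got, want, info = paste("cpos", cpos))
  }
})

test_that("pi0/pi4 uses class-specific callable denominators", {
  deg <- data.frame(chrom = "chr1", pos = c(0:9, 100:109),
                    fold = rep(c("0-fold", "4-fold"), each = 10))
  # identical planted diversity at both classes -> ratio 1
  hap <- matrix(rbinom(8 * 2, 1, 0.5), 8, 2)
  hap[, 2] <- hap[, 1]
  gm <- hap_to_gm(hap)
  vt <- make_vt(c(5, 105))
  out <- pi0_pi4(gm, vt, deg)
  expect_equal(out$ratio, 1)
  # thinned 0-fold diversity -> ratio < 1
  gm2 <- gm; gm2[, 1] <- 0L
  out2 <- pi0_pi4(gm2, vt, deg)
  expect_lt(out2$ratio, 1)
  expect_equal(out2$pi0, 0)
  # pi4 = 0 -> missing ratio
  gm3 <- gm; gm3[, 2] <- 0L
  expect_true(is.na(pi0_pi4(gm3, vt, deg)$ratio))
})
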