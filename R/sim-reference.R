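# codon helpers shared by the simulator and the effect classifier
.revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

.translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  out <- unname(gc[toupper(codon)])
  out[is.na(out)] <- "X"
  out
}

# Effect of substituting alt_base at codon position cpos (1..3), in coding
# orientation. Classes: synonymous / missense / stop_gained / stop_lost.
.codon_effect <- function(codon, cpos, alt_base) {
  alt_codon <- codon
  substr(alt_codon, cpos, cpos) <- alt_base
  aa1 <- .translate_codon(codon)
  aa2 <- .translate_codon(alt_codon)
  cls <- if (aa1 == aa2) "synonymous"
  else if (aa2 == "*") "stop_gained"
  else if (aa1 == "*") "stop_lost"
  else "missense"
  list(class = cls, aa_ref = aa1, aa_alt = aa2, alt_codon = alt_codon)
}

#' Simulate a toy reference genome with single-exon CDS features
#'
#' Generates random chromosome sequences and places non-overlapping
#' single-exon protein-coding CDS on random strands. Every CDS starts with
#' ATG, ends with a stop codon, contains no internal stop, and has length
#' divisible by three, so downstream effect and degeneracy annotation can
#' assume a clean reading frame.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param n_genes total number of CDS to place.
#' @param cds_codons length-2 range of body codons per CDS (start and stop
#'   codons are added on top).
#' @param seed optional integer seed.
#' @return list with `ref` (DNAStringSet), `gff` (GFF3 data frame with gene
#'   and CDS rows, 1-based inclusive coordinates) and `cds` (per-gene table:
#'   chrom, start, end, strand, protein).
#' @export
simulate_reference_and_cds <- function(chrom_lengths, n_genes = 20,
                                       cds_codons = c(60, 150),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  bases <- c("A", "C", "G", "T")
  gc <- Biostrings::GENETIC_CODE
  stops <- names(gc)[gc == "*"]
  nonstop <- setdiff(names(gc), stops)

  seqs <- lapply(chrom_lengths, function(len)
    paste(sample(bases, len, replace = TRUE), collapse = ""))

  slot_bp <- 3 * (max(cds_codons) + 2) + 500
  slots <- do.call(rbind, lapply(names(chrom_lengths), function(cn) {
    k <- floor(chrom_lengths[[cn]] / slot_bp)
    if (k < 1) return(NULL)
    data.frame(chrom = cn, slot = seq_len(k), stringsAsFactors = FALSE)
  }))
  if (is.null(slots) || nrow(slots) < n_genes)
    stop("genome too short to place ", n_genes, " CDS without overlap")
  pick <- slots[sample.int(nrow(slots), n_genes), , drop = FALSE]

  gene_rows <- vector("list", n_genes)
  cds_tab <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    n_body <- sample(seq(cds_codons[1], cds_codons[2]), 1)
    coding <- paste(c("ATG", sample(nonstop, n_body, replace = TRUE),
                      sample(stops, 1)), collapse = "")
    len <- nchar(coding)
    cn <- pick$chrom[g]
    start <- (pick$slot[g] - 1L) * slot_bp +
      sample.int(slot_bp - len - 1L, 1)          # 1-based
    end <- start + len - 1L
    if (end > chrom_lengths[[cn]])
      stop("CDS overlaps chromosome end on ", cn)
    strand <- sample(c("+", "-"), 1)
    genomic <- if (strand == "+") coding else .revcomp(coding)
    substr(seqs[[cn]], start, end) <- genomic
    prot <- paste(.translate_codon(substring(coding, seq(1, len - 3, 3),
                                             seq(3, len, 3) - 0)[1:(len / 3 - 1)]),
                  collapse = "")
    id <- sprintf("gene%02d", g)
    gene_rows[[g]] <- data.frame(
      seqid = cn, source = "relictpop", type = c("gene", "CDS"),
      start = start, end = end, score = ".", strand = strand,
      phase = c(".", "0"),
      attributes = c(sprintf("ID=%s", id),
                     sprintf("ID=cds.%s;Parent=%s", id, id)),
      stringsAsFactors = FALSE)
    cds_tab[[g]] <- data.frame(gene = id, chrom = cn, start = start,
                               end = end, strand = strand, protein = prot,
                               stringsAsFactors = FALSE)
  }
  ref <- Biostrings::DNAStringSet(unlist(seqs))
  names(ref) <- names(chrom_lengths)
  list(ref = ref, gff = do.call(rbind, gene_rows),
       cds = do.call(rbind, cds_tab))
}

#' Reconcile simulated variant alleles with a reference genome
#'
#' The coalescent simulator draws REF bases independently of any reference
#' sequence. Given a reference, this resets each variant's REF to the
#' actual base at its position (keeping ALT distinct), so that codon-level
#' annotation sees consistent alleles. Dosage semantics are unchanged: the
#' ALT allele remains the derived allele.
#'
#' @param sim a `relict_sim` object.
#' @param ref DNAStringSet covering the simulated chromosomes.
#' @return the modified `relict_sim`.
#' @export
harmonize_ref_alleles <- function(sim, ref) {
  vt <- sim$vt
  for (cn in unique(vt$chrom)) {
    idx <- which(vt$chrom == cn)
    s <- as.character(ref[[cn]])
    rb <- toupper(substring(s, vt$pos[idx] + 1L, vt$pos[idx] + 1L))
    swap <- vt$alt[idx] == rb
    vt$alt[idx][swap] <- vt$ref[idx][swap]
    vt$ref[idx] <- rb
    same <- vt$alt[idx] == vt$ref[idx]
    if (any(same)) {
      bases <- c("A", "C", "G", "T")
      vt$alt[idx][same] <- vapply(rb[same], function(b)
        sample(setdiff(bases, b), 1), character(1))
    }
  }
  sim$vt <- vt
  sim
}

#' Inject functional variants with known effects into a simulated panel
#'
#' Scans the CDS annotation for single-base substitutions realizing each
#' requested effect class (verified against the standard genetic code),
#' injects them as new biallelic sites, and draws genotypes per lineage with
#' controllable homozygous-derived and heterozygous frequencies. This
#' provides ground truth for genetic-load metrics: the derived (ALT) allele
#' frequency stays below 50% homozygous so the majority-homozygote
#' polarization rule recovers the planted ancestral state.
#'
#' @param sim a `relict_sim` object (already reference-harmonized).
#' @param ref DNAStringSet reference.
#' @param gff GFF data frame with CDS rows.
#' @param counts named vector: sites per class among
#'   `c(synonymous=, missense=, lof=)`.
#' @param del_fraction fraction of missense injections drawn from
#'   Grantham >= 150 candidate changes (radical substitutions).
#' @param hom_freq per-lineage probability an individual is
#'   homozygous-derived at an injected site (scalar or named by lineage).
#' @param het_freq per-lineage heterozygote probability (scalar or named).
#' @param seed optional integer seed.
#' @return the `relict_sim` with injected sites added to `gm`/`vt` and a
#'   `truth$effects` table (chrom, pos, class, aa_ref, aa_alt, gs,
#'   deleterious).
#' @export
inject_functional_variants <- function(sim, ref, gff,
                                       counts = c(synonymous = 100,
                                                  missense = 120,
                                                  lof = 40),
                                       del_fraction = 0.5,
                                       hom_freq = 0.1, het_freq = 0.2,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("no CDS features in GFF")
  taken <- paste0(sim$vt$chrom, ":", sim$vt$pos)

  cand <- .enumerate_coding_changes(ref, cds)
  cand <- cand[!(paste0(cand$chrom, ":", cand$pos) %in% taken), ,
               drop = FALSE]
  cand <- cand[!duplicated(paste0(cand$chrom, ":", cand$pos)), ,
               drop = FALSE]
  cand$gs <- NA_real_
  mis <- cand$class == "missense"
  cand$gs[mis] <- grantham_score(cand$aa_ref[mis], cand$aa_alt[mis])

  pick_rows <- integer(0)
  want <- function(rows, n, label) {
    if (length(rows) < n) {
      warning("only ", length(rows), " candidate sites for ", label,
              " (requested ", n, "); injecting all available")
      n <- length(rows)
    }
    rows[sample.int(length(rows), n)]
  }
  if (!is.na(counts["synonymous"]) && counts["synonymous"] > 0)
    pick_rows <- c(pick_rows, want(which(cand$class == "synonymous"),
                                   counts[["synonymous"]], "synonymous"))
  if (!is.na(counts["missense"]) && counts["missense"] > 0) {
    n_del <- round(del_fraction * counts[["missense"]])
    n_tol <- counts[["missense"]] - n_del
    pool_del <- setdiff(which(mis & cand$gs >= 150), pick_rows)
    pool_tol <- setdiff(which(mis & cand$gs < 150), pick_rows)
    pick_rows <- c(pick_rows, want(pool_del, n_del, "radical missense"),
                   want(pool_tol, n_tol, "tolerated missense"))
  }
  if (!is.na(counts["lof"]) && counts["lof"] > 0)
    pick_rows <- c(pick_rows, want(which(cand$class == "stop_gained"),
                                   counts[["lof"]], "lof"))
  inj <- cand[pick_rows, , drop = FALSE]
  if (!nrow(inj)) return(sim)

  lineages <- sim$meta$lineage
  hom <- if (length(hom_freq) == 1) stats::setNames(
    rep(hom_freq, length(unique(lineages))), unique(lineages)) else hom_freq
  het <- if (length(het_freq) == 1) stats::setNames(
    rep(het_freq, length(unique(lineages))), unique(lineages)) else het_freq
  n <- length(lineages)
  gm_new <- matrix(0L, nrow = n, ncol = nrow(inj))
  for (j in seq_len(nrow(inj))) {
    u <- stats::runif(n)
    gm_new[, j] <- ifelse(u < hom[lineages], 2L,
                          ifelse(u < hom[lineages] + het[lineages], 1L, 0L))
  }
  rownames(gm_new) <- rownames(sim$gm)

  vt_new <- data.frame(chrom = inj$chrom, pos = inj$pos, ref = inj$ref,
                       alt = inj$alt, biallelic = TRUE, is_snp = TRUE,
                       stringsAsFactors = FALSE)
  for (col in setdiff(names(sim$vt), names(vt_new))) vt_new[[col]] <- NA
  vt <- rbind(sim$vt, vt_new[names(sim$vt)])
  gm <- cbind(sim$gm, gm_new)
  o <- order(match(vt$chrom, unique(vt$chrom)), vt$pos)
  sim$vt <- vt[o, ]
  rownames(sim$vt) <- NULL
  sim$gm <- gm[, o, drop = FALSE]
  colnames(sim$gm) <- paste0(sim$vt$chrom, ":", sim$vt$pos + 1L)

  eff <- data.frame(chrom = inj$chrom, pos = inj$pos,
                    class = ifelse(inj$class == "stop_gained", "LOF",
                                   inj$class),
                    aa_ref = inj$aa_ref, aa_alt = inj$aa_alt, gs = inj$gs,
                    deleterious = inj$class == "stop_gained" |
                      (!is.na(inj$gs) & inj$gs >= 150),
                    stringsAsFactors = FALSE)
  sim$truth$effects <- eff[order(match(eff$chrom, unique(vt$chrom)),
                                 eff$pos), ]
  rownames(sim$truth$effects) <- NULL
  sim
}

# Enumerate all single-base coding changes over the CDS set, in genomic
# coordinates (0-based pos, genomic ref/alt), with coding-level class.
.enumerate_coding_changes <- function(ref, cds) {
  bases <- c("A", "C", "G", "T")
  out <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    cn <- cds$seqid[i] %||% cds$chrom[i]
    s <- toupper(as.character(ref[[cn]]))
    gseq <- substring(s, cds$start[i], cds$end[i])
    coding <- if (cds$strand[i] == "+") gseq else .revcomp(gseq)
    len <- nchar(coding)
    rows <- list()
    for (cpos in seq_len(len - 3)) {           # skip the stop codon
      codon_i <- (cpos - 1) %/% 3 + 1
      within <- (cpos - 1) %% 3 + 1
      codon <- substring(coding, (codon_i - 1) * 3 + 1, codon_i * 3)
      refb <- substring(coding, cpos, cpos)
      for (ab in setdiff(bases, refb)) {
        ef <- .codon_effect(codon, within, ab)
        gpos1 <- if (cds$strand[i] == "+") cds$start[i] + cpos - 1L else
          cds$end[i] - cpos + 1L
        gref <- if (cds$strand[i] == "+") refb else chartr("ACGT", "TGCA", refb)
        galt <- if (cds$strand[i] == "+") ab else chartr("ACGT", "TGCA", ab)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cn, pos = gpos1 - 1L, ref = gref, alt = galt,
          class = ef$class, aa_ref = ef$aa_ref, aa_alt = ef$aa_alt,
          stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thin diversity at 0-fold degenerate sites (purifying selection)
#'
#' Emulates purifying selection on coding sequence by removing a fraction
#' of the segregating (simulated, non-injected) variants that fall on
#' 0-fold degenerate positions: each such variant is kept with probability
#' `keep`. With class-specific denominators unchanged, the expected
#' pi0/pi4 ratio of an otherwise neutral simulation scales by `keep`.
#'
#' @param sim a `relict_sim` object.
#' @param ref DNAStringSet reference.
#' @param gff GFF data frame with CDS rows.
#' @param keep retention probability for 0-fold variants (default 0.45,
#'   in the regime reported for relict plants with relaxed selection).
#' @param seed optional integer seed.
#' @return the `relict_sim` with thinned variants removed from `gm`/`vt`.
#' @export
purify_zero_fold <- function(sim, ref, gff, keep = 0.45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  deg <- degeneracy_sites(ref, gff)
  zf <- deg[deg$fold == "0-fold", , drop = FALSE]
  idx <- which(paste(sim$vt$chrom, sim$vt$pos) %in%
                 paste(zf$chrom, zf$pos))
  drop <- idx[stats::runif(length(idx)) > keep]
  if (length(drop)) {
    sim$gm <- sim$gm[, -drop, drop = FALSE]
    sim$vt <- sim$vt[-drop, , drop = FALSE]
    rownames(sim$vt) <- NULL
  }
  sim
}
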