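#' Polarize derived alleles by the majority-homozygote rule
#'
#' At each biallelic site, if strictly more than 50% of the non-missing
#' individuals carry the same homozygous genotype, that allele is called
#' ancestral and the other derived. Sites failing the rule (including exact
#' 50% ties) are left unpolarized and are excluded from load metrics.
#'
#' @param gm samples x sites dosage matrix.
#' @param vt variant table aligned to `gm`.
#' @return `vt` with added columns `derived_allele` ("alt", "ref" or `NA`)
#'   and `polarized` (logical).
#' @export
polarize_derived <- function(gm, vt) {
  n_tot <- colSums(!is.na(gm))
  n_hom_ref <- colSums(gm == 0L, na.rm = TRUE)
  n_hom_alt <- colSums(gm == 2L, na.rm = TRUE)
  vt$derived_allele <- ifelse(n_hom_ref > n_tot / 2, "alt",
                              ifelse(n_hom_alt > n_tot / 2, "ref",
                                     NA_character_))
  vt$derived_allele[n_tot == 0] <- NA_character_
  vt$polarized <- !is.na(vt$derived_allele)
  vt
}

#' Dosage of the derived allele
#'
#' Flips dosages at sites where the reference allele is derived;
#' unpolarized sites become `NA`.
#'
#' @inheritParams polarize_derived
#' @return matrix of derived-allele dosages.
#' @export
derived_dosage <- function(gm, vt) {
  stopifnot(!is.null(vt$derived_allele))
  d <- gm
  flip <- which(!is.na(vt$derived_allele) & vt$derived_allele == "ref")
  d[, flip] <- 2L - d[, flip, drop = FALSE]
  d[, is.na(vt$derived_allele)] <- NA_integer_
  d
}

#' Classify coding effects of SNPs against a reference and CDS annotation
#'
#' Codon-level classifier: each variant inside a CDS is evaluated against
#' the standard genetic code, strand-aware. Stop-gained changes are
#' loss-of-function; missense changes get a Grantham score and a
#' deleterious flag (GS >= `gs_threshold`). Variants outside any CDS are
#' class "other". A CDS whose length is not a multiple of three is a hard
#' error naming the feature.
#'
#' @param vt variant table (`chrom`, 0-based `pos`, `ref`, `alt`).
#' @param ref DNAStringSet reference genome.
#' @param gff GFF3 data frame with CDS rows (1-based inclusive).
#' @param gs_threshold Grantham cutoff for the deleterious flag.
#' @return data frame `chrom`, `pos`, `class` (synonymous / missense /
#'   stop_gained / stop_lost / other), `aa_ref`, `aa_alt`, `gs`,
#'   `deleterious` (missense with GS >= threshold), `lof` (stop_gained).
#' @export
classify_effects <- function(vt, ref, gff, gs_threshold = 150) {
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  bad <- which((cds$end - cds$start + 1) %% 3 != 0)
  if (length(bad))
    stop("CDS frame inconsistency (length not a multiple of 3): ",
         cds$attributes[bad[1]])
  out <- data.frame(chrom = vt$chrom, pos = vt$pos,
                    class = "other", aa_ref = NA_character_,
                    aa_alt = NA_character_, gs = NA_real_,
                    stringsAsFactors = FALSE)
  pos1 <- vt$pos + 1L
  for (i in seq_len(nrow(cds))) {
    hit <- which(vt$chrom == cds$seqid[i] & pos1 >= cds$start[i] &
                   pos1 <= cds$end[i])
    if (!length(hit)) next
    s <- toupper(as.character(ref[[cds$seqid[i]]]))
    gseq <- substring(s, cds$start[i], cds$end[i])
    coding <- if (cds$strand[i] == "+") gseq else .revcomp(gseq)
    for (h in hit) {
      cpos <- if (cds$strand[i] == "+") pos1[h] - cds$start[i] + 1L else
        cds$end[i] - pos1[h] + 1L
      alt_cb <- if (cds$strand[i] == "+") toupper(vt$alt[h]) else
        chartr("ACGT", "TGCA", toupper(vt$alt[h]))
      if (!alt_cb %in% c("A", "C", "G", "T")) next   # ambiguous -> other
      codon_i <- (cpos - 1L) %/% 3L + 1L
      within <- (cpos - 1L) %% 3L + 1L
      codon <- substring(coding, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
      if (grepl("[^ACGT]", codon)) next
      ref_cb <- substring(coding, cpos, cpos)
      if (alt_cb == ref_cb) next                     # matches reference
      ef <- .codon_effect(codon, within, alt_cb)
      out$class[h] <- ef$class
      out$aa_ref[h] <- ef$aa_ref
      out$aa_alt[h] <- ef$aa_alt
      if (ef$class == "missense")
        out$gs[h] <- grantham_score(ef$aa_ref, ef$aa_alt)
    }
  }
  out$deleterious <- out$class == "missense" & !is.na(out$gs) &
    out$gs >= gs_threshold
  out$lof <- out$class == "stop_gained"
  out
}

#' Per-individual genetic-load ratios
#'
#' Counts homozygous-derived (`hom`) and heterozygous (`het`) genotypes per
#' individual over the derived, polarized sites of a class (DEL = radical
#' missense; LOF = stop-gained), then summarizes the homozygous burden:
#' \describe{
#'   \item{allele_fraction (default)}{`2 hom / (2 hom + het)` - the
#'     fraction of derived deleterious alleles carried homozygously,
#'     bounded in [0, 1].}
#'   \item{literal}{`2 hom / (hom + het)`, the box-plot caption arithmetic
#'     sometimes quoted in the literature; it can exceed 1.}
#' }
#'
#' @param gm samples x sites dosage matrix.
#' @param vt polarized variant table (see [polarize_derived()]).
#' @param ann effect annotation from [classify_effects()] or a truth table
#'   with columns `chrom`, `pos`, and either `deleterious`/`lof` or
#'   `class`.
#' @param class "DEL" or "LOF".
#' @param formula "allele_fraction" or "literal".
#' @return data frame `sample`, `n_hom`, `n_het`, `ratio` (`NA` when an
#'   individual carries no qualifying allele).
#' @export
load_ratio <- function(gm, vt, ann, class = c("DEL", "LOF"),
                       formula = c("allele_fraction", "literal")) {
  class <- match.arg(class)
  formula <- match.arg(formula)
  key_vt <- paste(vt$chrom, vt$pos)
  qual <- if (class == "LOF") {
    if (!is.null(ann$lof)) ann$lof else ann$class %in% c("LOF", "stop_gained")
  } else {
    if (!is.null(ann$deleterious)) ann$deleterious & !(ann$class %in%
                                                         c("LOF", "stop_gained"))
    else ann$class == "missense"
  }
  key_ann <- paste(ann$chrom, ann$pos)[qual]
  use <- which(vt$polarized & key_vt %in% key_ann)
  dd <- derived_dosage(gm, vt)[, use, drop = FALSE]
  n_hom <- rowSums(dd == 2L, na.rm = TRUE)
  n_het <- rowSums(dd == 1L, na.rm = TRUE)
  den <- if (formula == "allele_fraction") 2 * n_hom + n_het else
    n_hom + n_het
  data.frame(sample = rownames(gm), n_hom = n_hom, n_het = n_het,
             ratio = ifelse(den > 0, 2 * n_hom / den, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Homozygous-LOF density inside vs outside ROH
#'
#' Per sample, counts homozygous-derived LOF genotypes inside and outside
#' that sample's ROH segments, converts both to per-Mb densities
#' (normalizing by ROH and non-ROH genome length), and compares the two
#' density vectors across samples with a two-sided Wilcoxon rank-sum test
#' (exact for small samples without ties, normal approximation with tie
#' correction otherwise).
#'
#' @inheritParams load_ratio
#' @param segments ROH segment table (`sample`, `chrom`, `start`, `end`).
#' @param genome_bp total genome length in bp.
#' @return list with `per_sample` (counts, Mb, densities; inside density is
#'   `NA` for samples without ROH) and `p_value` / `statistic` of the test.
#' @export
roh_lof_enrichment <- function(gm, vt, ann, segments, genome_bp) {
  key_vt <- paste(vt$chrom, vt$pos)
  qual <- if (!is.null(ann$lof)) ann$lof else
    ann$class %in% c("LOF", "stop_gained")
  key_ann <- paste(ann$chrom, ann$pos)[qual]
  use <- which(vt$polarized & key_vt %in% key_ann)
  dd <- derived_dosage(gm, vt)[, use, drop = FALSE]
  vchrom <- vt$chrom[use]; vpos <- vt$pos[use]
  ids <- rownames(gm)
  rows <- lapply(seq_along(ids), function(si) {
    seg <- segments[segments$sample == ids[si], , drop = FALSE]
    in_roh <- rep(FALSE, length(use))
    roh_bp <- 0
    if (nrow(seg)) {
      for (cn in unique(seg$chrom)) {
        s2 <- seg[seg$chrom == cn, ]
        ir <- IRanges::reduce(IRanges::IRanges(s2$start + 1L, s2$end))
        roh_bp <- roh_bp + sum(IRanges::width(ir))
        ov <- IRanges::overlapsAny(
          IRanges::IRanges(vpos + 1L, vpos + 1L), ir)
        in_roh <- in_roh | (vchrom == cn & ov)
      }
    }
    hom <- !is.na(dd[si, ]) & dd[si, ] == 2L
    n_in <- sum(hom & in_roh); n_out <- sum(hom & !in_roh)
    in_mb <- roh_bp / 1e6; out_mb <- (genome_bp - roh_bp) / 1e6
    data.frame(sample = ids[si], n_in = n_in, n_out = n_out,
               roh_mb = in_mb, non_roh_mb = out_mb,
               dens_in = if (in_mb > 0) n_in / in_mb else NA_real_,
               dens_out = if (out_mb > 0) n_out / out_mb else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  di <- per_sample$dens_in[!is.na(per_sample$dens_in)]
  do <- per_sample$dens_out[!is.na(per_sample$dens_out)]
  if (length(di) && length(do)) {
    wt <- suppressWarnings(stats::wilcox.test(di, do,
                                              alternative = "two.sided"))
    list(per_sample = per_sample, p_value = wt$p.value,
         statistic = unname(wt$statistic))
  } else {
    list(per_sample = per_sample, p_value = NA_real_,
         statistic = NA_real_)
  }
}

#' Classify CDS positions by codon degeneracy
#'
#' For every CDS position, counts how many of the three possible base
#' substitutions preserve the encoded amino acid: 0-fold positions (every
#' change is nonsynonymous) and 4-fold positions (no change is) are
#' labelled; everything else - including 2/3-fold positions, ambiguous
#' bases, and positions claimed by overlapping CDS with conflicting
#' classes - is "other".
#'
#' @param ref DNAStringSet reference genome.
#' @param gff GFF3 data frame with CDS rows.
#' @return data frame `chrom`, `pos` (0-based), `fold` in
#'   {"0-fold", "4-fold", "other"}.
#' @export
degeneracy_sites <- function(ref, gff) {
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  bad <- which((cds$end - cds$start + 1) %% 3 != 0)
  if (length(bad))
    stop("CDS frame inconsistency (length not a multiple of 3): ",
         cds$attributes[bad[1]])
  acc <- new.env(parent = emptyenv())
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(cds))) {
    s <- toupper(as.character(ref[[cds$seqid[i]]]))
    gseq <- substring(s, cds$start[i], cds$end[i])
    coding <- if (cds$strand[i] == "+") gseq else .revcomp(gseq)
    len <- nchar(coding)
    for (cpos in seq_len(len)) {
      codon_i <- (cpos - 1L) %/% 3L + 1L
      within <- (cpos - 1L) %% 3L + 1L
      codon <- substring(coding, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
      refb <- substring(coding, cpos, cpos)
      fold <- if (grepl("[^ACGT]", codon)) "other" else {
        aa <- .translate_codon(codon)
        n_syn <- sum(vapply(setdiff(bases, refb), function(ab) {
          alt <- codon; substr(alt, within, within) <- ab
          .translate_codon(alt) == aa
        }, logical(1)))
        if (n_syn == 0) "0-fold" else if (n_syn == 3) "4-fold" else "other"
      }
      gpos1 <- if (cds$strand[i] == "+") cds$start[i] + cpos - 1L else
        cds$end[i] - cpos + 1L
      key <- paste0(cds$seqid[i], ":", gpos1)
      old <- acc[[key]]
      acc[[key]] <- if (is.null(old) || identical(old, fold)) fold else
        "other"
    }
  }
  keys <- ls(acc)
  chrom <- sub(":.*", "", keys)
  pos1 <- as.integer(sub(".*:", "", keys))
  out <- data.frame(chrom = chrom, pos = pos1 - 1L,
                    fold = vapply(keys, function(k) acc[[k]], character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Ratio of nucleotide diversity at 0-fold vs 4-fold degenerate sites
#'
#' Diversity restricted to each degeneracy class, with class-specific
#' callable denominators (number of class positions scaled by the mean
#' non-missing fraction at the class's variant sites). A high ratio
#' indicates weak or relaxed purifying selection.
#'
#' @param gm samples x sites dosage matrix.
#' @param vt variant table aligned to `gm`.
#' @param deg degeneracy table from [degeneracy_sites()].
#' @param pop sample ids defining the population (default all).
#' @return list with `pi0`, `pi4`, `ratio` (`NA` when pi4 is 0 or a class
#'   is empty).
#' @export
pi0_pi4 <- function(gm, vt, deg, pop = NULL) {
  g <- .subset_pop(gm, pop)
  st <- .site_pi_terms(g)
  frac_ok <- colMeans(!is.na(g))
  key_vt <- paste(vt$chrom, vt$pos)
  class_pi <- function(fold) {
    sites <- deg[deg$fold == fold, , drop = FALSE]
    if (!nrow(sites)) return(NA_real_)
    idx <- which(key_vt %in% paste(sites$chrom, sites$pos) & !is.na(st$pi))
    callable <- nrow(sites) * (if (length(idx)) mean(frac_ok[idx]) else 1)
    if (callable <= 0) return(NA_real_)
    sum(st$pi[idx]) / callable
  }
  pi0 <- class_pi("0-fold")
  pi4 <- class_pi("4-fold")
  ratio <- if (is.na(pi0) || is.na(pi4) || pi4 == 0) NA_real_ else pi0 / pi4
  list(pi0 = pi0, pi4 = pi4, ratio = ratio)
}
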