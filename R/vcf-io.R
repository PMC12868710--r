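#' Read a VCF into a genotype matrix and variant table
#'
#' Wraps [vcfR::read.vcfR()]. Diploid genotypes are converted to ALT-allele
#' dosages (0/1/2); `./.` becomes `NA`. VCF 1-based positions are converted
#' to the package's internal 0-based convention. Multiallelic records are
#' kept but flagged `biallelic = FALSE` with missing dosages, never silently
#' split. GATK-style site annotations (QD, MQ, FS, SOR, MQRankSum,
#' ReadPosRankSum) are parsed from INFO when present.
#'
#' @param path path to a VCF (plain or gzipped).
#' @return list with `gm` (samples x sites integer dosage matrix) and `vt`
#'   (variant table with `chrom`, `pos` 0-based, `ref`, `alt`, `biallelic`,
#'   `is_snp`, plus any QC annotation columns found).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]; pos1 <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic <- !grepl(",", alt, fixed = TRUE)
  is_snp <- nchar(ref) == 1L & biallelic & nchar(alt) == 1L
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  ok <- is.na(gt) | grepl("^[0-9.]([/|][0-9.])?$", gt)
  if (any(!ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("malformed genotype at ", chrom[bad[1]], ":", pos1[bad[1]],
         " sample ", colnames(gt)[bad[2]], " ('", gt[!ok][1], "')")
  }
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  a1[is.na(gt)] <- "."; a2[is.na(gt)] <- "."
  hap <- !is.na(gt) & a2 == ""
  a2[hap] <- a1[hap]                               # haploid calls
  dos <- ifelse(a1 == "." | a2 == "." | is.na(gt), NA_integer_,
                (a1 == "1") + (a2 == "1"))
  gm <- t(matrix(as.integer(dos), nrow = nrow(gt),
                 dimnames = dimnames(gt)))
  gm[, !biallelic] <- NA_integer_
  vt <- data.frame(chrom = chrom, pos = pos1 - 1L, ref = ref, alt = alt,
                   biallelic = biallelic, is_snp = is_snp,
                   stringsAsFactors = FALSE)
  info <- fix[, "INFO"]
  for (tag in c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")) {
    m <- regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]+"), info))
    hit <- grepl(paste0(tag, "="), info)
    if (any(hit)) {
      val <- rep(NA_real_, length(info))
      val[hit] <- as.numeric(sub(paste0(".*", tag, "="), "",
                                 regmatches(info,
                                            regexpr(paste0("(^|;)", tag, "=[^;]+"),
                                                    info))))
      vt[[tag]] <- val
    }
  }
  colnames(gm) <- paste0(vt$chrom, ":", vt$pos + 1L)
  list(gm = gm, vt = vt)
}

#' Write a genotype matrix and variant table as VCF v4.2
#'
#' Genotypes are written unphased (`0/1`); missing as `./.`. Any QC
#' annotation columns present in `vt` are emitted as INFO tags so the file
#' round-trips through [read_vcf()].
#'
#' @param gm samples x sites dosage matrix.
#' @param vt variant table (0-based `pos`).
#' @param path output file path.
#' @param chrom_lengths optional named vector; emitted as contig headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, vt, path, chrom_lengths = NULL) {
  stopifnot(nrow(vt) == ncol(gm))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=relictpop")
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  qc_tags <- intersect(c("QD", "MQ", "FS", "SOR", "MQRankSum",
                         "ReadPosRankSum"), names(vt))
  for (tag in qc_tags)
    hdr <- c(hdr, sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", tag, tag))
  hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  samples <- rownames(gm)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(gm)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  info <- if (length(qc_tags)) {
    apply(vt[, qc_tags, drop = FALSE], 1, function(r) {
      ok <- !is.na(r)
      if (!any(ok)) "." else
        paste(paste0(qc_tags[ok], "=", format(r[ok], trim = TRUE,
                                              scientific = FALSE)),
              collapse = ";")
    })
  } else rep(".", nrow(vt))
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(gm), ncol = ncol(gm))
  ok <- !is.na(gm)
  gt[ok] <- code[as.character(gm[ok])]
  body <- paste(vt$chrom, vt$pos + 1L, ".", vt$ref, vt$alt, ".", ".",
                info, "GT",
                apply(gt, 2, paste, collapse = "\t")[seq_len(nrow(vt))],
                sep = "\t")
  # apply over columns gives one string per site
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings.
#' @param path file path.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs a DNAStringSet (or named character vector).
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read / write GFF3 feature tables
#'
#' Minimal GFF3 support sufficient for CDS annotation: the nine standard
#' columns are preserved verbatim, coordinates stay 1-based inclusive as in
#' the format, and `write_gff()` is the exact inverse of `read_gff()`.
#'
#' @param path file path.
#' @return data frame with columns `seqid`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase`, `attributes`.
#' @export
read_gff <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  if (!length(ln))
    return(data.frame(seqid = character(0), source = character(0),
                      type = character(0), start = integer(0),
                      end = integer(0), score = character(0),
                      strand = character(0), phase = character(0),
                      attributes = character(0), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  if (ncol(f) != 9) stop("malformed GFF3: expected 9 columns")
  data.frame(seqid = f[, 1], source = f[, 2], type = f[, 3],
             start = as.integer(f[, 4]), end = as.integer(f[, 5]),
             score = f[, 6], strand = f[, 7], phase = f[, 8],
             attributes = f[, 9], stringsAsFactors = FALSE)
}

#' @rdname read_gff
#' @param gff a GFF data frame as returned by `read_gff()`.
#' @export
write_gff <- function(gff, path) {
  writeLines(c("##gff-version 3",
               paste(gff$seqid, gff$source, gff$type, gff$start, gff$end,
                     gff$score, gff$strand, gff$phase, gff$attributes,
                     sep = "\t")), path)
  invisible(path)
}
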