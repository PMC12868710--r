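#' Detect runs of homozygosity (PLINK-style scanning windows)
#'
#' Two-phase algorithm: (1) every window of `min_snps` consecutive SNPs on
#' a chromosome is scored homozygous-eligible when it contains at most
#' `het_allow` heterozygous and at most `miss_allow` missing calls for the
#' individual; (2) a SNP is in a run when the fraction of eligible windows
#' among all windows covering it is at least `hit_frac`. Maximal stretches
#' of in-run SNPs become segments; segments on the same chromosome closer
#' than `gap_bp` are merged, and merged segments must still span at least
#' `min_snps` SNPs and `min_len` bp. Chromosomes shorter than `min_len`
#' simply yield no segments.
#'
#' @param gm samples x sites dosage matrix.
#' @param vt variant table aligned to `gm` (sorted positions).
#' @param min_snps minimum SNPs per scanning window and per segment
#'   (default 50).
#' @param min_len minimum segment length in bp (default 100 kb).
#' @param het_allow heterozygotes tolerated per window (default 1).
#' @param miss_allow missing calls tolerated per window (default 5).
#' @param hit_frac minimum eligible-window fraction per SNP (default 0.05).
#' @param gap_bp merge segments separated by less than this (default
#'   100 kb, scaled to desk-size genomes; set to 1 Mb for PLINK parity on
#'   full-size genomes).
#' @return data frame of segments: `sample`, `chrom`, `start`, `end`
#'   (0-based half-open), `n_snps`, `length`, `class`
#'   (`"long"` > 1 Mb, `"medium"` > 100 kb, else `"short"`).
#' @export
detect_roh <- function(gm, vt, min_snps = 50, min_len = 1e5,
                       het_allow = 1, miss_allow = 5, hit_frac = 0.05,
                       gap_bp = 1e5) {
  out <- list()
  ids <- rownames(gm)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(gm)))
  for (cn in unique(vt$chrom)) {
    cidx <- which(vt$chrom == cn)
    pos <- vt$pos[cidx]
    S <- length(cidx)
    if (S < min_snps) next
    nw <- S - min_snps + 1L
    for (si in seq_len(nrow(gm))) {
      g <- gm[si, cidx]
      het <- as.integer(!is.na(g) & g == 1L)
      mis <- as.integer(is.na(g))
      ch <- cumsum(c(0L, het)); cm <- cumsum(c(0L, mis))
      w <- seq_len(nw)
      elig <- (ch[w + min_snps] - ch[w]) <= het_allow &
        (cm[w + min_snps] - cm[w]) <= miss_allow
      ce <- cumsum(c(0L, as.integer(elig)))
      j <- seq_len(S)
      w_lo <- pmax(1L, j - min_snps + 1L)
      w_hi <- pmin(j, nw)
      covered <- w_hi - w_lo + 1L
      hits <- ce[w_hi + 1L] - ce[w_lo]
      inrun <- covered > 0 & hits / pmax(covered, 1L) >= hit_frac
      r <- rle(inrun)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      seg <- data.frame(lo = starts[r$values], hi = ends[r$values])
      seg$n_snps <- seg$hi - seg$lo + 1L
      seg$length <- pos[seg$hi] + 1L - pos[seg$lo]
      # candidate segments must qualify on their own ...
      seg <- seg[seg$n_snps >= min_snps & seg$length >= min_len, ,
                 drop = FALSE]
      if (!nrow(seg)) next
      # ... and qualifying neighbours closer than gap_bp are then merged
      keep <- list(); cur <- seg[1, ]
      for (k in seq_len(nrow(seg))[-1]) {
        if (pos[seg$lo[k]] - (pos[cur$hi] + 1L) < gap_bp) cur$hi <- seg$hi[k]
        else { keep[[length(keep) + 1]] <- cur; cur <- seg[k, ] }
      }
      keep[[length(keep) + 1]] <- cur
      seg <- do.call(rbind, keep)
      seg$n_snps <- seg$hi - seg$lo + 1L
      seg$start <- pos[seg$lo]
      seg$end <- pos[seg$hi] + 1L
      seg$length <- seg$end - seg$start
      out[[length(out) + 1]] <- data.frame(
        sample = ids[si], chrom = cn, start = seg$start, end = seg$end,
        n_snps = seg$n_snps, length = seg$length,
        class = ifelse(seg$length > 1e6, "long",
                       ifelse(seg$length > 1e5, "medium", "short")),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), length = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$sample, res$chrom, res$start), , drop = FALSE]
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Fraction of the genome covered by ROH segments longer than each class
#' threshold. Overlapping segments of one individual are merged before
#' summing; a segment long enough for several classes counts in each.
#'
#' @param segments segment table from [detect_roh()] (or planted truth).
#' @param genome_bp total genome length in bp.
#' @param classes named vector of minimum segment lengths per class.
#' @param samples sample ids to report (default: those present in
#'   `segments`); samples without segments get F_ROH = 0.
#' @return data frame `sample`, `class`, `total_roh_bp`, `genome_bp`,
#'   `froh`.
#' @export
froh <- function(segments, genome_bp,
                 classes = c(medium = 1e5, long = 1e6),
                 samples = NULL) {
  stopifnot(genome_bp > 0)
  if (is.null(segments$length))
    segments$length <- segments$end - segments$start
  if (is.null(samples)) samples <- unique(segments$sample)
  rows <- list()
  for (cl in names(classes)) {
    for (sid in samples) {
      seg <- segments[segments$sample == sid &
                        segments$length > classes[[cl]], , drop = FALSE]
      bp <- 0
      if (nrow(seg)) {
        for (cn in unique(seg$chrom)) {
          s2 <- seg[seg$chrom == cn, ]
          ir <- IRanges::reduce(IRanges::IRanges(s2$start + 1L, s2$end))
          bp <- bp + sum(IRanges::width(ir))
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample = sid, class = cl, total_roh_bp = bp,
        genome_bp = genome_bp, froh = bp / genome_bp,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Base-pair Jaccard between detected and true ROH sets
#'
#' Per-sample |intersection| / |union| over genomic intervals. Two empty
#' sets score 1 (nothing to find, nothing found).
#'
#' @param detected,truth segment tables with `sample`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return named numeric vector, one score per sample in either table.
#' @export
roh_recovery_score <- function(detected, truth) {
  samples <- union(unique(detected$sample), unique(truth$sample))
  out <- stats::setNames(numeric(length(samples)), samples)
  for (sid in samples) {
    d <- detected[detected$sample == sid, , drop = FALSE]
    t2 <- truth[truth$sample == sid, , drop = FALSE]
    if (!nrow(d) && !nrow(t2)) { out[sid] <- 1; next }
    inter <- 0; uni <- 0
    for (cn in union(d$chrom, t2$chrom)) {
      ir_d <- IRanges::IRanges(d$start[d$chrom == cn] + 1L,
                               d$end[d$chrom == cn])
      ir_t <- IRanges::IRanges(t2$start[t2$chrom == cn] + 1L,
                               t2$end[t2$chrom == cn])
      inter <- inter + sum(IRanges::width(IRanges::intersect(ir_d, ir_t)))
      uni <- uni + sum(IRanges::width(IRanges::union(ir_d, ir_t)))
    }
    out[sid] <- if (uni > 0) inter / uni else 1
  }
  out
}
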