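#' Pipeline configuration
#'
#' Flat per-stage configuration for the end-to-end synthetic analysis.
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults. All thresholds of every stage are exposed here; the defaults
#' give a desk-scale demonstration run (a 2-Mb two-chromosome genome and
#' a 68-diploid three-lineage panel) that completes
#' in a few minutes on one CPU.
#'
#' @param ... named overrides of the defaults, nested by stage, e.g.
#'   `sim = list(genome_length = 1e6)`.
#' @param yaml_file optional YAML file whose values are applied before
#'   `...`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(..., yaml_file = NULL) {
  defaults <- list(
    seed = 1L,
    stages = list(simulate = TRUE, filter = TRUE, stats = TRUE,
                  roh = TRUE, load = TRUE, gea = TRUE, offset = TRUE),
    sim = list(n_lineages = 3, samples_per_lineage = c(21, 5, 42),
               genome_length = 2e6, n_chrom = 2, block_bp = 5000,
               missing_rate = 0.02, n_genes = 40, zero_fold_keep = 0.45,
               inject = c(synonymous = 100, missense = 120, lof = 40),
               hom_freq = c(YN = 0.2, VN = 0.1, SC = 0.1),
               het_freq = 0.2,
               roh_tracts = 2, roh_len = c(2e5, 4e5),
               roh_sample_frac = 0.4,
               n_adaptive = 120, effect_size = 3, grid_dim = c(12, 12),
               shift_scale = 1),
    filter = list(max_missing = 0.2, min_maf = 0.05,
                  prune_window = 50, prune_step = 10, prune_r2 = 0.2),
    stats = list(window = 1e5, ld_max_dist = 5e4, ld_bins = 20,
                 mantel_perm = 999),
    roh = list(min_snps = 50, min_len = 1e5, het_allow = 1,
               miss_allow = 5, hit_frac = 0.05, gap_bp = 1e5),
    load = list(gs_threshold = 150),
    gea = list(K = 3, fdr = 0.05, min_vars = 3, n_axes = NULL,
               sd_mult = 3.5),
    offset = list(taus = c(0.15, 0.05)))
  user <- list(...)
  if (!is.null(yaml_file))
    user <- utils::modifyList(yaml::read_yaml(yaml_file), user)
  check_keys <- function(u, d, path = "") {
    bad <- setdiff(names(u), names(d))
    if (length(bad))
      stop("unknown config key(s): ",
           paste0(path, bad, collapse = ", "))
    for (k in names(u))
      if (is.list(d[[k]]) && !is.null(names(d[[k]])) && is.list(u[[k]]))
        check_keys(u[[k]], d[[k]], paste0(path, k, "."))
  }
  check_keys(user, defaults)
  cfg <- utils::modifyList(defaults, user)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order (simulate, filter,
#' stats / roh / load, gea, offset), writing each stage's artifacts as
#' plain-text files under `out_dir` plus a markdown summary report. A rerun
#' with the same configuration and seed reproduces every output
#' byte-for-byte. Disabling a stage skips it and any downstream stage that
#' needs its outputs refuses to run with an actionable error.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  log_file <- file.path(out_dir, "pipeline.log")
  logln <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_file, append = TRUE, sep = "")
    message(msg)
  }
  cat("", file = log_file)
  st <- config$stages
  res <- list(config = config)
  seed0 <- as.integer(config$seed)

  run_stage <- function(name, expr) {
    logln("[", name, "] starting")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  tsv <- function(x, name)
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  if (isTRUE(st$simulate)) {
    res$sim <- run_stage("simulate", {
      sc <- config$sim
      dcfg <- demography_config(
        n_lineages = sc$n_lineages,
        samples_per_lineage = sc$samples_per_lineage,
        genome_length = sc$genome_length, n_chrom = sc$n_chrom,
        block_bp = sc$block_bp, missing_rate = sc$missing_rate,
        seed = seed0 + 1L)
      sim <- simulate_genotypes(dcfg)
      refcds <- simulate_reference_and_cds(sim$chrom_lengths,
                                           n_genes = sc$n_genes,
                                           seed = seed0 + 2L)
      sim <- harmonize_ref_alleles(sim, refcds$ref)
      sim <- purify_zero_fold(sim, refcds$ref, refcds$gff,
                              keep = sc$zero_fold_keep,
                              seed = seed0 + 7L)
      sim <- inject_functional_variants(sim, refcds$ref, refcds$gff,
                                        counts = sc$inject,
                                        hom_freq = sc$hom_freq,
                                        het_freq = sc$het_freq,
                                        seed = seed0 + 3L)
      set.seed(seed0 + 4L)
      n_roh <- max(1, round(sc$roh_sample_frac * nrow(sim$gm)))
      roh_samples <- sort(sample(rownames(sim$gm), n_roh))
      sim <- plant_roh(sim, n_tracts = sc$roh_tracts,
                       length_range = sc$roh_len,
                       samples = roh_samples, seed = seed0 + 5L)
      sim <- simulate_environment(sim, n_adaptive = sc$n_adaptive,
                                  effect_size = sc$effect_size,
                                  grid_dim = sc$grid_dim,
                                  shift_scale = sc$shift_scale,
                                  seed = seed0 + 6L)
      write_vcf(sim$gm, sim$vt, file.path(out_dir, "genotypes.vcf"),
                sim$chrom_lengths)
      write_fasta(refcds$ref, file.path(out_dir, "reference.fa"))
      write_gff(refcds$gff, file.path(out_dir, "annotation.gff3"))
      tsv(sim$meta, "samples.tsv")
      tsv(data.frame(sample_id = rownames(sim$env$sites),
                     sim$env$sites, check.names = FALSE), "env_sites.tsv")
      tsv(sim$env$grid, "env_grid_current.tsv")
      tsv(sim$env$grid_future, "env_grid_future.tsv")
      tsv(sim$truth$planted_roh, "truth_roh.tsv")
      tsv(sim$truth$effects, "truth_effects.tsv")
      tsv(sim$truth$adaptive, "truth_adaptive.tsv")
      list(sim = sim, ref = refcds)
    })
  }
  if (isTRUE(st$filter)) {
    res$filter <- run_stage("filter", {
      vcf <- file.path(out_dir, "genotypes.vcf")
      if (!file.exists(vcf))
        stop("genotypes.vcf not found; enable the simulate stage or ",
             "place a VCF in the output directory")
      g <- read_vcf(vcf)
      fc <- config$filter
      hard <- apply_hard_filters(g$vt)
      gm1 <- g$gm[, attr(hard, "idx"), drop = FALSE]
      core <- select_core_variants(hard, gm1, fc$max_missing)
      gm_core <- gm1[, attr(core, "idx"), drop = FALSE]
      mafv <- maf_filter(gm_core, core, fc$min_maf)
      gm_maf <- gm_core[, attr(mafv, "idx"), drop = FALSE]
      pruned <- ld_prune(gm_maf, mafv, fc$prune_window, fc$prune_step,
                         fc$prune_r2)
      gm_pruned <- gm_maf[, attr(pruned, "idx"), drop = FALSE]
      tsv(core[, c("chrom", "pos")], "core_sites.bed3")
      tsv(pruned[, c("chrom", "pos")], "unlinked_sites.bed3")
      logln("[filter] core=", nrow(core), " maf=", nrow(mafv),
            " unlinked=", nrow(pruned))
      list(core = list(gm = gm_core, vt = core),
           maf = list(gm = gm_maf, vt = mafv),
           pruned = list(gm = gm_pruned, vt = pruned))
    })
  }
  meta <- if (!is.null(res$sim)) res$sim$sim$meta else {
    f <- file.path(out_dir, "samples.tsv")
    if (file.exists(f)) utils::read.delim(f) else NULL
  }
  chrlen <- if (!is.null(res$sim)) res$sim$sim$chrom_lengths else NULL

  if (isTRUE(st$stats)) {
    res$stats <- run_stage("stats", {
      if (is.null(res$filter)) stop("stats requires the filter stage")
      scfg <- config$stats
      core <- res$filter$core
      lineages <- split(meta$sample_id, meta$lineage)
      pi_tabs <- lapply(names(lineages), function(ln) {
        t2 <- window_pi(core$gm, core$vt, chrlen, lineages[[ln]],
                        scfg$window)
        t2$lineage <- ln
        t2
      })
      pi_tab <- do.call(rbind, pi_tabs)
      d_tabs <- lapply(names(lineages), function(ln) {
        t2 <- window_tajima_d(core$gm, core$vt, chrlen, lineages[[ln]],
                              scfg$window)
        t2$lineage <- ln
        t2
      })
      d_tab <- do.call(rbind, d_tabs)
      prs <- utils::combn(names(lineages), 2)
      fst_tabs <- lapply(seq_len(ncol(prs)), function(k) {
        t2 <- window_fst(core$gm, core$vt, chrlen,
                         lineages[[prs[1, k]]], lineages[[prs[2, k]]],
                         scfg$window)
        t2$pair <- paste(prs[, k], collapse = "-")
        t2
      })
      fst_tab <- do.call(rbind, fst_tabs)
      het <- individual_heterozygosity(core$gm)
      het_tab <- data.frame(sample = names(het), lineage = meta$lineage,
                            het = het, row.names = NULL)
      pc <- pca_genotypes(res$filter$pruned$gm)
      pops <- meta$pop
      gen_d <- linearized_fst_matrix(res$filter$pruned$gm, pops)
      pop_xy <- aggregate_by_pop(meta[, c("lat", "lon")], pops)
      geo_d <- geo_distance_matrix(pop_xy[, "lat"], pop_xy[, "lon"],
                                   rownames(pop_xy))
      tree <- nj_tree(gen_d)
      ape::write.tree(tree, file.path(out_dir, "nj_pops.nwk"))
      ld <- ld_decay(res$filter$maf$gm[, seq_len(min(400, ncol(res$filter$maf$gm))), drop = FALSE],
                     res$filter$maf$vt[seq_len(min(400, nrow(res$filter$maf$vt))), , drop = FALSE],
                     scfg$ld_max_dist, scfg$ld_bins)
      tsv(pi_tab, "window_pi.tsv")
      tsv(d_tab, "window_tajima_d.tsv")
      tsv(fst_tab, "window_fst.tsv")
      tsv(het_tab, "heterozygosity.tsv")
      tsv(ld, "ld_decay.tsv")
      tsv(data.frame(sample = rownames(pc$coords),
                     pc$coords[, 1:4, drop = FALSE],
                     check.names = FALSE), "pca.tsv")
      list(pi = pi_tab, tajima = d_tab, fst = fst_tab, het = het_tab,
           pca = pc, gen_d = gen_d, geo_d = geo_d, tree = tree, ld = ld)
    })
  }
  if (isTRUE(st$roh)) {
    res$roh <- run_stage("roh", {
      if (is.null(res$filter)) stop("roh requires the filter stage")
      rc <- config$roh
      seg <- detect_roh(res$filter$core$gm, res$filter$core$vt,
                        rc$min_snps, rc$min_len, rc$het_allow,
                        rc$miss_allow, rc$hit_frac, rc$gap_bp)
      genome_bp <- sum(chrlen)
      fr <- froh(seg, genome_bp, samples = rownames(res$filter$core$gm))
      tsv(seg, "roh_segments.tsv")
      tsv(fr, "froh.tsv")
      jac <- NULL
      if (!is.null(res$sim) && !is.null(res$sim$sim$truth$planted_roh)) {
        jac <- roh_recovery_score(seg, res$sim$sim$truth$planted_roh)
        tsv(data.frame(sample = names(jac), jaccard = jac),
            "roh_recovery.tsv")
      }
      list(segments = seg, froh = fr, recovery = jac)
    })
  }
  if (isTRUE(st$load)) {
    res$load <- run_stage("load", {
      if (is.null(res$filter)) stop("load requires the filter stage")
      if (is.null(res$sim)) stop("load requires the simulate stage ",
                                 "(reference and annotation)")
      core <- res$filter$core
      ref <- res$sim$ref
      ann <- classify_effects(core$vt, ref$ref, ref$gff,
                              config$load$gs_threshold)
      vt_pol <- polarize_derived(core$gm, core$vt)
      del <- load_ratio(core$gm, vt_pol, ann, "DEL")
      lof <- load_ratio(core$gm, vt_pol, ann, "LOF")
      segs <- if (!is.null(res$roh)) res$roh$segments else
        stop("load requires the roh stage for the ROH-enrichment panel")
      enr <- roh_lof_enrichment(core$gm, vt_pol, ann, segs, sum(chrlen))
      deg <- degeneracy_sites(ref$ref, ref$gff)
      lineages <- split(meta$sample_id, meta$lineage)
      p04 <- lapply(lineages, function(ss)
        pi0_pi4(core$gm, core$vt, deg, ss))
      p04_tab <- data.frame(lineage = names(p04),
                            pi0 = vapply(p04, `[[`, 0, "pi0"),
                            pi4 = vapply(p04, `[[`, 0, "pi4"),
                            ratio = vapply(p04, `[[`, 0, "ratio"),
                            row.names = NULL)
      load_tab <- rbind(cbind(class = "DEL", del, lineage = meta$lineage),
                        cbind(class = "LOF", lof, lineage = meta$lineage))
      tsv(ann[ann$class != "other", ], "effects.tsv")
      tsv(load_tab, "load_ratios.tsv")
      tsv(enr$per_sample, "roh_lof.tsv")
      tsv(p04_tab, "pi0_pi4.tsv")
      tsv(deg, "degeneracy.tsv")
      list(ann = ann, vt_pol = vt_pol, del = del, lof = lof, enr = enr,
           deg = deg, pi0_pi4 = p04_tab)
    })
  }
  if (isTRUE(st$gea)) {
    res$gea <- run_stage("gea", {
      if (is.null(res$filter)) stop("gea requires the filter stage")
      if (is.null(res$sim)) stop("gea requires the simulate stage ",
                                 "(environmental layers)")
      gc_ <- config$gea
      env <- prune_env(res$sim$sim$env$sites)
      mafd <- res$filter$maf
      lf <- lfmm_assoc(mafd$gm, env, gc_$K, gc_$fdr, gc_$min_vars)
      rd <- rda_outliers(mafd$gm, env, gc_$n_axes, gc_$sd_mult)
      core_idx <- suppressWarnings(core_adaptive_set(lf, rd))
      gea_tab <- data.frame(chrom = mafd$vt$chrom, pos = mafd$vt$pos,
                            n_significant = lf$n_significant,
                            lfmm_outlier = lf$outlier,
                            rda_outlier = rd$outlier,
                            core = seq_len(nrow(mafd$vt)) %in% core_idx)
      tsv(gea_tab, "gea.tsv")
      logln("[gea] lfmm=", sum(lf$outlier), " rda=", sum(rd$outlier),
            " core=", length(core_idx))
      # isolation by distance / environment on the adaptive set
      pops <- meta$pop
      adaptive_idx <- if (length(core_idx) >= 20) core_idx else
        which(lf$outlier | rd$outlier)
      mant <- NULL
      if (length(adaptive_idx) >= 3) {
        gen_d <- suppressWarnings(
          linearized_fst_matrix(mafd$gm[, adaptive_idx, drop = FALSE],
                                pops))
        pop_xy <- aggregate_by_pop(meta[, c("lat", "lon")], pops)
        geo_d <- geo_distance_matrix(pop_xy[, "lat"], pop_xy[, "lon"],
                                     rownames(pop_xy))
        env_d <- env_distance_matrix(
          aggregate_by_pop(res$sim$sim$env$sites, pops))
        np <- config$stats$mantel_perm
        ibd <- mantel_test(gen_d, geo_d, np, seed = seed0 + 8L)
        ibe <- mantel_test(gen_d, env_d, np, seed = seed0 + 9L)
        ibd_p <- partial_mantel_test(gen_d, geo_d, env_d, np,
                                     seed = seed0 + 10L)
        ibe_p <- partial_mantel_test(gen_d, env_d, geo_d, np,
                                     seed = seed0 + 11L)
        mant <- data.frame(
          test = c("IBD", "IBE", "IBD|env", "IBE|geo"),
          r = c(ibd$r, ibe$r, ibd_p$r, ibe_p$r),
          p = c(ibd$p, ibe$p, ibd_p$p, ibe_p$p))
        tsv(mant, "mantel.tsv")
      }
      list(env = env, lfmm = lf, rda = rd, core = core_idx,
           table = gea_tab, mantel = mant)
    })
  }
  if (isTRUE(st$offset)) {
    res$offset <- run_stage("offset", {
      if (is.null(res$gea)) stop("offset requires the gea stage")
      sim <- res$sim$sim
      mafd <- res$filter$maf
      core_idx <- res$gea$core
      if (length(core_idx) < 20) {
        logln("[offset] fewer than 20 core adaptive loci; using all ",
              "LFMM or RDA outliers")
        core_idx <- which(res$gea$lfmm$outlier | res$gea$rda$outlier)
      }
      if (length(core_idx) < 1)
        stop("no adaptive loci available for GDM fitting")
      pops <- meta$pop
      env_pop <- aggregate_by_pop(sim$env$sites, pops)
      xy_pop <- aggregate_by_pop(meta[, c("lat", "lon")], pops)
      pd <- pairwise_dissimilarity(mafd$gm[, core_idx, drop = FALSE],
                                   pops, env_pop, xy_pop)
      model <- gdm_fit(pd$d, pd$env_i, pd$env_j, pd$geo)
      vn <- sim$env$var_names
      grid_c <- sim$env$grid
      grid_f <- sim$env$grid_future
      keep_pn <- setdiff(model$predictors, "geo")
      o_loc <- local_offset(model, grid_c[, c("lat", "lon", keep_pn)],
                            grid_f[, c("lat", "lon", keep_pn)])
      fr <- forward_reverse_offset(model, grid_c, grid_f)
      rgb <- rgb_map(o_loc, fr$forward, fr$reverse)
      migs <- lapply(config$offset$taus, function(tau)
        migration_distance(model, grid_c, grid_f, tau))
      names(migs) <- paste0("tau", config$offset$taus)
      off_tab <- data.frame(grid_c[, c("lat", "lon")],
                            o_local = o_loc, o_forward = fr$forward,
                            o_reverse = fr$reverse, rgb)
      for (k in seq_along(migs)) {
        off_tab[[paste0("dist_", names(migs)[k])]] <-
          migs[[k]]$distance_km
        off_tab[[paste0("bearing_", names(migs)[k])]] <- migs[[k]]$bearing
      }
      tsv(off_tab, "offsets.tsv")
      pol <- polar_summary(migs[[length(migs)]])
      list(model = model, table = off_tab, mig = migs, polar = pol)
    })
  }
  report <- write_report(res, file.path(out_dir, "report.md"))
  res$report <- report
  invisible(res)
}

#' Write the markdown summary report
#'
#' Per-lineage diversity, heterozygosity, F_ROH, load ratios, pi0/pi4,
#' GEA outlier counts and offset summaries, each computed from the stage
#' results (the report restates the stage TSVs, nothing else). Stages that
#' did not run are marked "not run".
#'
#' @param res stage-result list from [run_pipeline()].
#' @param path output file.
#' @return the report lines, invisibly.
#' @export
write_report <- function(res, path) {
  num <- function(x, d = 4) formatC(x, digits = d, format = "g")
  L <- c("# relictpop pipeline report", "")
  meta <- if (!is.null(res$sim)) res$sim$sim$meta else NULL
  L <- c(L, "## Diversity and structure", "")
  if (!is.null(res$stats)) {
    agg <- stats::aggregate(pi ~ lineage, res$stats$pi, mean,
                            na.rm = TRUE)
    het <- stats::aggregate(het ~ lineage, res$stats$het, mean,
                            na.rm = TRUE)
    fst <- stats::aggregate(fst ~ pair, res$stats$fst,
                            function(x) mean(x, na.rm = TRUE))
    taj <- stats::aggregate(tajima_d ~ lineage, res$stats$tajima, mean,
                            na.rm = TRUE)
    L <- c(L, "| lineage | mean pi | mean het | mean Tajima's D |",
           "|---|---|---|---|",
           vapply(seq_len(nrow(agg)), function(i)
             paste0("| ", agg$lineage[i], " | ", num(agg$pi[i]), " | ",
                    num(het$het[het$lineage == agg$lineage[i]]), " | ",
                    num(taj$tajima_d[taj$lineage == agg$lineage[i]]),
                    " |"), character(1)),
           "", "| lineage pair | mean FST |", "|---|---|",
           vapply(seq_len(nrow(fst)), function(i)
             paste0("| ", fst$pair[i], " | ", num(fst$fst[i]), " |"),
             character(1)), "")
  } else L <- c(L, "not run", "")
  L <- c(L, "## Inbreeding (ROH)", "")
  if (!is.null(res$roh)) {
    fr <- res$roh$froh
    fr$lineage <- meta$lineage[match(fr$sample, meta$sample_id)]
    agg <- stats::aggregate(froh ~ lineage + class, fr, mean)
    L <- c(L, "| lineage | class | mean F_ROH |", "|---|---|---|",
           vapply(seq_len(nrow(agg)), function(i)
             paste0("| ", agg$lineage[i], " | ", agg$class[i], " | ",
                    num(agg$froh[i]), " |"), character(1)), "")
  } else L <- c(L, "not run", "")
  L <- c(L, "## Genetic load", "")
  if (!is.null(res$load)) {
    for (cls in c("DEL", "LOF")) {
      tab <- if (cls == "DEL") res$load$del else res$load$lof
      tab$lineage <- meta$lineage[match(tab$sample, meta$sample_id)]
      agg <- stats::aggregate(ratio ~ lineage, tab, mean, na.rm = TRUE)
      L <- c(L, paste0("mean homozygous-", cls, " ratio: ",
                       paste(agg$lineage, num(agg$ratio), sep = "=",
                             collapse = ", ")))
    }
    L <- c(L, "",
           paste0("LOF-in-ROH rank-sum p = ", num(res$load$enr$p_value)),
           "", "| lineage | pi0/pi4 |", "|---|---|",
           vapply(seq_len(nrow(res$load$pi0_pi4)), function(i)
             paste0("| ", res$load$pi0_pi4$lineage[i], " | ",
                    num(res$load$pi0_pi4$ratio[i]), " |"), character(1)),
           "")
  } else L <- c(L, "not run", "")
  L <- c(L, "## Genotype-environment association", "")
  if (!is.null(res$gea)) {
    L <- c(L, paste0("LFMM outliers: ", sum(res$gea$lfmm$outlier),
                     "; RDA outliers: ", sum(res$gea$rda$outlier),
                     "; core adaptive set: ", length(res$gea$core)), "")
  } else L <- c(L, "not run", "")
  L <- c(L, "## Genetic offset", "")
  if (!is.null(res$offset)) {
    tb <- res$offset$table
    L <- c(L, paste0("mean local offset: ", num(mean(tb$o_local)),
                     "; mean forward: ", num(mean(tb$o_forward)),
                     "; mean reverse: ", num(mean(tb$o_reverse))),
           paste0("GDM variance explained: ",
                  num(res$offset$model$explained)), "")
    for (k in names(res$offset$mig)) {
      d <- res$offset$table[[paste0("dist_", k)]]
      L <- c(L, paste0(k, ": median migration distance ",
                       num(stats::median(d, na.rm = TRUE)), " km (",
                       sum(is.na(d)), " cells with no refuge)"))
    }
    L <- c(L, "")
  } else L <- c(L, "not run", "")
  writeLines(L, path)
  invisible(L)
}
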