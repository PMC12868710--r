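#' Demographic model configuration for the coalescent simulator
#'
#' Describes a caterpillar-shaped multi-lineage demography: the first lineage
#' diverges at the oldest split, the remaining lineages peel off at
#' successively more recent splits. Defaults emulate a three-lineage relict
#' plant system (Yunnan-like, Vietnam-like, South-China-like) that diverged
#' roughly 100 kya and 40 kya under a 5-year generation time, with a shared
#' pre-divergence bottleneck and small stable recent population sizes.
#'
#' Time is measured in generations before present. `split_times` is ordered
#' oldest first and must be strictly decreasing. `Ne_anc` gives the sizes of
#' the merged ancestral populations in backward merge order (most recent
#' merge first, root last). `Ne_epochs` optionally overrides deme sizes in
#' older epochs: a data frame with columns `deme` (extant lineage index, or
#' the strings "root"/"ancN" for the N-th merged ancestor), `start`
#' (generations ago from which the size applies, going into the past) and
#' `Ne`. The default places a large pre-bottleneck size on the root deme,
#' mirroring glacial contraction after an interglacial expansion.
#'
#' @param n_lineages number of extant lineages.
#' @param split_times generations ago of each divergence, oldest first
#'   (default 20000 and 8000 generations = 100 kya and 40 kya at 5 y/gen).
#' @param Ne diploid effective size per extant lineage.
#' @param Ne_anc diploid effective sizes of merged ancestors (most recent
#'   merge first; last entry is the root, by default a post-glacial
#'   bottleneck size).
#' @param Ne_epochs optional epoch table, see Details.
#' @param migration_rates per-generation migration fraction between extant
#'   lineages: scalar (symmetric) or an `n_lineages` x `n_lineages` matrix.
#' @param mu per-site per-generation mutation rate (default 1.25e-8).
#' @param recomb_rate nominal per-site per-generation recombination rate;
#'   linkage is modelled as free between blocks of `block_bp` consecutive
#'   bases and complete within a block.
#' @param genome_length total genome length in bp.
#' @param block_bp length of a non-recombining block.
#' @param n_chrom number of chromosomes the genome is split into.
#' @param samples_per_lineage diploid sample counts per lineage.
#' @param missing_rate per-genotype missingness injected uniformly.
#' @param generation_years years per generation, recorded for time scaling.
#' @param seed integer seed; a fixed seed makes all outputs reproducible.
#' @return an object of class `demography_config` (a validated list).
#' @export
demography_config <- function(n_lineages = 3,
                              split_times = c(20000, 8000),
                              Ne = c(8000, 10000, 14000),
                              Ne_anc = c(20000, 15000),
                              Ne_epochs = data.frame(deme = "root",
                                                     start = 36000,
                                                     Ne = 40000),
                              migration_rates = 2.5e-5,
                              mu = 1.25e-8,
                              recomb_rate = 1e-8,
                              genome_length = 2e6,
                              block_bp = 5000,
                              n_chrom = 2,
                              samples_per_lineage = c(21, 5, 42),
                              missing_rate = 0.02,
                              generation_years = 5,
                              seed = 1L) {
  L <- as.integer(n_lineages)
  if (L < 1) stop("n_lineages must be >= 1")
  if (L == 1) split_times <- numeric(0)
  if (length(split_times) != L - 1)
    stop("need ", L - 1, " split times for ", L, " lineages")
  if (L > 1 && any(diff(split_times) >= 0))
    stop("split_times must be strictly decreasing toward the present")
  if (any(split_times <= 0)) stop("split_times must be positive")
  Ne <- rep_len(Ne, L)
  if (L > 1) Ne_anc <- rep_len(Ne_anc, L - 1) else Ne_anc <- numeric(0)
  if (any(c(Ne, Ne_anc) < 2)) stop("all Ne must be >= 2")
  if (is.matrix(migration_rates)) {
    if (!all(dim(migration_rates) == c(L, L)))
      stop("migration_rates matrix must be n_lineages x n_lineages")
    M <- migration_rates
  } else {
    M <- matrix(migration_rates[1], L, L)
  }
  diag(M) <- 0
  if (any(M < 0) || mu < 0 || recomb_rate < 0)
    stop("all rates must be >= 0")
  if (genome_length < 1e4) stop("genome_length must be >= 10 kb")
  samples_per_lineage <- rep_len(as.integer(samples_per_lineage), L)
  if (any(samples_per_lineage < 2))
    stop("samples_per_lineage must all be >= 2")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  cfg <- list(n_lineages = L, split_times = split_times, Ne = Ne,
              Ne_anc = Ne_anc, Ne_epochs = Ne_epochs, migration = M,
              mu = mu, recomb_rate = recomb_rate,
              genome_length = genome_length, block_bp = block_bp,
              n_chrom = as.integer(n_chrom),
              samples_per_lineage = samples_per_lineage,
              missing_rate = missing_rate,
              generation_years = generation_years,
              seed = as.integer(seed))
  class(cfg) <- "demography_config"
  cfg
}

#' @export
print.demography_config <- function(x, ...) {
  cat("Demographic model:", x$n_lineages, "lineage(s)\n")
  if (length(x$split_times))
    cat("  splits (gen ago):", paste(x$split_times, collapse = ", "), "\n")
  cat("  Ne:", paste(x$Ne, collapse = ", "),
      if (length(x$Ne_anc)) paste0("(anc: ", paste(x$Ne_anc, collapse = ", "), ")"),
      "\n")
  cat("  mu:", x$mu, " genome:", x$genome_length, "bp in", x$n_chrom,
      "chromosome(s)\n")
  cat("  samples/lineage:", paste(x$samples_per_lineage, collapse = ", "), "\n")
  invisible(x)
}

# Internal: expand the config into an event schedule for the structured
# coalescent. Demes 1..L are the extant lineages; merged ancestors get ids
# L+1 .. 2L-1 in backward merge order (2L-1 is the root for L > 1).
.demog_schedule <- function(cfg) {
  L <- cfg$n_lineages
  n_demes <- max(2L * L - 1L, 1L)
  t_asc <- rev(cfg$split_times)              # most recent merge first
  merges <- NULL
  if (L > 1) {
    merges <- data.frame(t = t_asc, a = NA_integer_, b = NA_integer_,
                         new = L + seq_len(L - 1))
    # caterpillar: most recent merge joins the last two lineages, then each
    # earlier lineage joins the running ancestor; lineage 1 joins last.
    prev <- L
    for (j in seq_len(L - 1)) {
      merges$a[j] <- L - j
      merges$b[j] <- prev
      prev <- merges$new[j]
    }
  }
  # per-deme size step functions: starts (gen ago, ascending) and sizes
  starts <- vector("list", n_demes)
  sizes <- vector("list", n_demes)
  for (d in seq_len(L)) { starts[[d]] <- 0; sizes[[d]] <- cfg$Ne[d] }
  if (L > 1) for (j in seq_len(L - 1)) {
    d <- L + j
    starts[[d]] <- merges$t[j]
    sizes[[d]] <- cfg$Ne_anc[j]
  }
  ep <- cfg$Ne_epochs
  if (!is.null(ep) && nrow(ep)) {
    for (i in seq_len(nrow(ep))) {
      dm <- ep$deme[i]
      if (identical(dm, "root")) d <- n_demes
      else if (is.character(dm) && grepl("^anc", dm)) d <- L + as.integer(sub("anc", "", dm))
      else d <- as.integer(dm)
      starts[[d]] <- c(starts[[d]], ep$start[i])
      sizes[[d]] <- c(sizes[[d]], ep$Ne[i])
    }
    for (d in seq_len(n_demes)) {
      o <- order(starts[[d]])
      starts[[d]] <- starts[[d]][o]; sizes[[d]] <- sizes[[d]][o]
    }
  }
  boundaries <- sort(unique(c(t_asc, unlist(starts))))
  boundaries <- c(boundaries[boundaries > 0], Inf)
  list(L = L, n_demes = n_demes, merges = merges, starts = starts,
       sizes = sizes, mig = cfg$migration, boundaries = boundaries)
}

.deme_size_at <- function(sched, d, t) {
  s <- sched$starts[[d]]
  sched$sizes[[d]][max(1L, findInterval(t, s))]
}

# Internal: simulate one non-recombining genealogy under the structured
# coalescent with migration and population merges. Returns parent pointers,
# node times and the leaf deme assignment. Leaves are haplotypes ordered by
# lineage.
.sim_block_tree <- function(sched, n_hap_per_lineage) {
  L <- sched$L
  n <- sum(n_hap_per_lineage)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  deme_of <- rep(seq_len(L), n_hap_per_lineage)   # deme of each active lineage
  node_of <- seq_len(n)
  alive <- c(rep(TRUE, L), rep(FALSE, sched$n_demes - L))
  can_migrate <- seq_len(sched$n_demes) <= L
  nxt <- n + 1L
  t <- 0
  bidx <- 1L
  bnd <- sched$boundaries
  cur_ne <- vapply(seq_len(sched$n_demes), function(d)
    .deme_size_at(sched, d, 0), numeric(1))
  merges <- sched$merges
  mdone <- logical(if (is.null(merges)) 0 else nrow(merges))

  apply_boundary <- function(tb) {
    if (!is.null(merges)) {
      for (j in which(!mdone & merges$t <= tb)) {
        a <- merges$a[j]; b <- merges$b[j]; nw <- merges$new[j]
        deme_of[deme_of == a | deme_of == b] <<- nw
        alive[a] <<- FALSE; alive[b] <<- FALSE; alive[nw] <<- TRUE
        mdone[j] <<- TRUE
      }
    }
    for (d in which(alive))
      cur_ne[d] <<- .deme_size_at(sched, d, tb)
  }

  while (length(node_of) > 1L) {
    counts <- tabulate(deme_of, nbins = sched$n_demes)
    coal <- counts * (counts - 1) / 2 / (2 * cur_ne)
    coal[!alive] <- 0
    mig_out <- numeric(sched$n_demes)
    act <- which(alive & can_migrate & counts > 0)
    for (d in act)
      mig_out[d] <- counts[d] * sum(sched$mig[d, ][alive[seq_len(L)] &
                                                     seq_len(L) != d])
    R <- sum(coal) + sum(mig_out)
    tb <- bnd[bidx]
    if (R <= 0) { t <- tb; apply_boundary(t); bidx <- bidx + 1L; next }
    dt <- stats::rexp(1, R)
    if (t + dt >= tb) { t <- tb; apply_boundary(t); bidx <- bidx + 1L; next }
    t <- t + dt
    u <- stats::runif(1) * R
    cum <- 0
    done <- FALSE
    for (d in which(coal > 0)) {
      cum <- cum + coal[d]
      if (u <= cum) {
        pick <- sample(which(deme_of == d), 2L)
        node_time[nxt] <- t
        parent[node_of[pick]] <- nxt
        node_of <- c(node_of[-pick], nxt)
        deme_of <- c(deme_of[-pick], d)
        nxt <- nxt + 1L
        done <- TRUE
        break
      }
    }
    if (!done) {
      for (d in which(mig_out > 0)) {
        cum <- cum + mig_out[d]
        if (u <= cum) {
          targets <- which(alive[seq_len(L)] & seq_len(L) != d)
          w <- sched$mig[d, targets]
          j <- if (length(targets) == 1) targets else
            sample(targets, 1L, prob = w)
          i <- which(deme_of == d)
          i <- if (length(i) == 1) i else sample(i, 1L)
          deme_of[i] <- j
          break
        }
      }
    }
  }
  list(parent = parent, node_time = node_time, n_leaves = n,
       root = node_of[1])
}

# Internal: drop infinite-sites mutations on a genealogy.
# Returns 0-based positions within the block and, per mutation, the integer
# vector of leaf (haplotype) indices carrying the derived allele.
.mutate_tree <- function(tree, mu, block_bp) {
  n <- tree$n_leaves
  root <- tree$root
  blen <- numeric(root)
  has_par <- seq_len(root) != root
  blen[has_par] <- tree$node_time[tree$parent[seq_len(root)][has_par]] -
    tree$node_time[has_par]
  tbl <- sum(blen)
  n_mut <- stats::rpois(1, mu * block_bp * tbl)
  if (n_mut == 0)
    return(list(pos = integer(0), carriers = list()))
  # leaves under each node: nodes are created in increasing time order
  under <- vector("list", root)
  for (v in seq_len(n)) under[[v]] <- v
  kids <- split(seq_len(root - 1), tree$parent[seq_len(root - 1)])
  for (v in (n + 1L):root) {
    ch <- kids[[as.character(v)]]
    under[[v]] <- c(under[[ch[1]]], under[[ch[2]]])
  }
  branch <- sample.int(root, n_mut, replace = TRUE, prob = blen)
  pos <- sample.int(block_bp, n_mut, replace = TRUE) - 1L
  keep <- !duplicated(pos)
  list(pos = pos[keep], carriers = under[branch[keep]])
}
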