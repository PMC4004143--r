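# Balding-Nichols pooled-sequencing simulator with known ground truth.
#
# The generator emulates the study design every downstream statistic is
# built for: ~26 pooled population samples, each a pool of 5 diploids
# (10 haploid chromosome sets), resequenced to ~20-30X, with unigene-
# structured loci. Sites are biallelic; per-population allele frequencies
# follow the Balding-Nichols model around an ancestral frequency; a pool of
# chromosomes is drawn binomially from the population; reads sample the pool
# with replacement (infinite-template approximation) under Poisson coverage;
# sequencing errors substitute a read base uniformly to one of the other
# three bases.

#' Simulation settings for the pooled-sequencing generator
#'
#' Defaults mirror the study design this package models: 26 populations,
#' pools of 10 haploid chromosome sets, mean coverage 25X (the reported
#' 20-30X range), SNP density ~2.5% of transcribed sites, and background
#' differentiation F = 0.05 (the magnitude of the genome-wide mean pairwise
#' F_ST observed in Corn Belt populations).
#'
#' @param n_pops Number of pooled populations.
#' @param n_unigenes Number of unigene loci.
#' @param sites_per_unigene Sites per unigene.
#' @param seg_fraction Fraction of sites polymorphic in the metapopulation.
#' @param anc_freq_range Range of the uniform law for the ancestral
#'   minor-allele frequency (default `c(0.05, 0.5)`).
#' @param F Balding-Nichols differentiation parameter in `[0, 1)`; at 0 all
#'   populations share the ancestral frequency.
#' @param pool_chromosomes Haploid chromosome sets per pool (default 10,
#'   i.e. 5 diploids).
#' @param mean_coverage Mean of the Poisson read-depth law per site and pool.
#' @param error_rate Per-base substitution probability (default 1e-3,
#'   i.e. the residual error after a PHRED >= 30 base-quality filter).
#' @param outlier_fraction Fraction of unigenes given elevated between-group
#'   differentiation (requires two `group_labels`).
#' @param outlier_F Differentiation parameter for outlier unigenes, applied
#'   between the two groups.
#' @param group_labels Optional per-population group label vector (at most
#'   two distinct labels); names, if present, become population names.
#' @param seed Integer RNG seed; all output is deterministic given the seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pops = 26L, n_unigenes = 500L,
                       sites_per_unigene = 200L, seg_fraction = 0.025,
                       anc_freq_range = c(0.05, 0.5), F = 0.05,
                       pool_chromosomes = 10L, mean_coverage = 25,
                       error_rate = 1e-3, outlier_fraction = 0,
                       outlier_F = 0, group_labels = NULL, seed = 1L) {
  stopifnot(n_pops >= 1, n_unigenes >= 1, sites_per_unigene >= 1,
            seg_fraction >= 0, seg_fraction <= 1,
            length(anc_freq_range) == 2, anc_freq_range[1] > 0,
            anc_freq_range[2] <= 0.5, anc_freq_range[1] <= anc_freq_range[2],
            F >= 0, F < 1, pool_chromosomes >= 2, mean_coverage > 0,
            error_rate >= 0, error_rate <= 1,
            outlier_fraction >= 0, outlier_fraction <= 1,
            outlier_F >= 0, outlier_F < 1)
  if (!is.null(group_labels)) {
    if (length(group_labels) != n_pops)
      stop("group_labels must have one label per population")
    if (length(unique(group_labels)) > 2)
      stop("at most two group labels are supported")
  }
  if (outlier_fraction > 0 &&
      (is.null(group_labels) || length(unique(group_labels)) != 2))
    stop("outlier injection needs exactly two group labels")
  structure(list(n_pops = as.integer(n_pops),
                 n_unigenes = as.integer(n_unigenes),
                 sites_per_unigene = as.integer(sites_per_unigene),
                 seg_fraction = seg_fraction,
                 anc_freq_range = anc_freq_range, F = F,
                 pool_chromosomes = as.integer(pool_chromosomes),
                 mean_coverage = mean_coverage, error_rate = error_rate,
                 outlier_fraction = outlier_fraction, outlier_F = outlier_F,
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols draw: Beta(p(1-F)/F, (1-p)(1-F)/F); degenerates to p at F=0.
bn_draw <- function(p, F) {
  if (F <= 0) return(p)
  rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# Uniform substitution of counted bases to one of the other three bases.
apply_seq_errors <- function(cnt, error_rate) {
  if (error_rate <= 0) return(cnt)
  n <- nrow(cnt)
  moved <- matrix(0L, n, 4L)
  for (b in 1:4) {
    m <- rbinom(n, cnt[, b], error_rate)
    cnt[, b] <- cnt[, b] - m
    d1 <- rbinom(n, m, 1 / 3)          # exact multinomial split over the
    d2 <- rbinom(n, m - d1, 1 / 2)     # three destination bases
    dest <- setdiff(1:4, b)
    moved[, dest[1]] <- moved[, dest[1]] + d1
    moved[, dest[2]] <- moved[, dest[2]] + d2
    moved[, dest[3]] <- moved[, dest[3]] + (m - d1 - d2)
  }
  cnt + moved
}

# Core generator: given site-level truth (p, seg, ref, alt, outlier flag),
# draw population frequencies, pool counts, coverages and read counts for
# all populations. Returns profiles (long) and the per-population truth.
generate_counts <- function(sites, cfg, pops, groups) {
  nS <- nrow(sites)
  P <- length(pops)
  Q <- matrix(0, nS, P)
  seg <- sites$segregating
  if (any(seg)) {
    p <- sites$anc_freq[seg]
    out <- sites$outlier[seg]
    if (any(out)) {
      glab <- unique(groups)
      pg <- matrix(p, sum(seg), 2)
      pg[out, 1] <- bn_draw(p[out], cfg$outlier_F)
      pg[out, 2] <- bn_draw(p[out], cfg$outlier_F)
      for (j in seq_len(P)) {
        base_p <- ifelse(out, pg[, match(groups[j], glab)], p)
        Q[seg, j] <- bn_draw(base_p, cfg$F)
      }
    } else {
      for (j in seq_len(P)) Q[seg, j] <- bn_draw(p, cfg$F)
    }
  }
  n <- cfg$pool_chromosomes
  idx <- seq_len(nS * P)
  Qv <- as.vector(Q)
  Cv <- rbinom(nS * P, n, Qv)
  Mv <- rpois(nS * P, cfg$mean_coverage)
  altreads <- rbinom(nS * P, Mv, Cv / n)
  cnt <- matrix(0L, nS * P, 4L)
  cnt[cbind(idx, rep(sites$ref_i, P))] <- as.integer(Mv - altreads)
  alt_i <- ifelse(is.na(sites$alt_i), sites$ref_i %% 4L + 1L, sites$alt_i)
  aidx <- cbind(idx, rep(alt_i, P))
  cnt[aidx] <- cnt[aidx] + as.integer(altreads)
  cnt <- apply_seq_errors(cnt, cfg$error_rate)
  profiles <- data.table(pop = rep(pops, each = nS),
                         unigene = rep(sites$unigene, P),
                         pos = rep(sites$pos, P),
                         A = cnt[, 1], C = cnt[, 2], G = cnt[, 3], T = cnt[, 4])
  profiles <- profiles[A + C + G + T > 0L]
  freqs <- data.table(pop = rep(pops, each = nS),
                      unigene = rep(sites$unigene, P),
                      pos = rep(sites$pos, P),
                      freq = Qv, pool_count = as.integer(Cv))[rep(seg, P)]
  list(profiles = profiles, freqs = freqs)
}

#' Simulate a pooled-sequenced metapopulation with known truth
#'
#' Draws, for each segregating site, an ancestral minor-allele frequency,
#' Balding-Nichols per-population frequencies, binomial pool allele counts,
#' Poisson read depths, and reads sampled from the pool with replacement,
#' optionally perturbed by uniform substitution errors. Non-segregating
#' sites are monomorphic for the ancestral base. If `cfg$outlier_fraction`
#' is positive, that fraction of unigenes is given elevated between-group
#' differentiation at level `cfg$outlier_F`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `profiles` (long base-count table: `pop`, `unigene`,
#'   `pos`, `A`,`C`,`G`,`T`; zero-coverage cells are absent) and `truth`,
#'   itself a list of `sites` (ancestral frequency, ref/alt bases,
#'   segregating flag), `freqs` (per population and segregating site: true
#'   allele frequency and pool allele count), `unigenes` (outlier status)
#'   and `config`.
#' @export
simulate_metapopulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  P <- cfg$n_pops
  pops <- if (!is.null(names(cfg$group_labels))) names(cfg$group_labels)
          else sprintf("pop%02d", seq_len(P))
  groups <- if (!is.null(cfg$group_labels)) as.character(cfg$group_labels)
            else rep("all", P)
  U <- cfg$n_unigenes
  S <- cfg$sites_per_unigene
  ug <- sprintf("ug%05d", seq_len(U))
  nS <- U * S
  seg <- runif(nS) < cfg$seg_fraction
  ref_i <- sample.int(4L, nS, replace = TRUE)
  alt_i <- (ref_i - 1L + sample.int(3L, nS, replace = TRUE)) %% 4L + 1L
  alt_i[!seg] <- NA_integer_
  p <- ifelse(seg, runif(nS, cfg$anc_freq_range[1], cfg$anc_freq_range[2]), 0)
  out_ug <- rep(FALSE, U)
  if (cfg$outlier_fraction > 0)
    out_ug[sample.int(U, round(cfg$outlier_fraction * U))] <- TRUE
  sites <- data.table(unigene = rep(ug, each = S), pos = rep(seq_len(S), U),
                      segregating = seg, ref_i = ref_i, alt_i = alt_i,
                      anc_freq = p, outlier = rep(out_ug, each = S))
  gen <- generate_counts(sites, cfg, pops, groups)
  truth <- list(sites = sites[, .(unigene, pos, segregating,
                                  ref = BASES[ref_i], alt = BASES[alt_i],
                                  anc_freq)],
                freqs = gen$freqs,
                unigenes = data.table(unigene = ug, outlier = out_ug),
                config = cfg)
  list(profiles = gen$profiles, truth = truth)
}

#' Inject between-group divergence into simulated unigenes
#'
#' Regenerates a random fraction of unigenes with elevated between-group
#' frequency divergence at level `outlier_F`, as a test bed for the
#' two-group outlier scans. Site positions, segregating status, alleles and
#' ancestral frequencies are preserved; group-level frequencies, pool
#' counts, depths and reads are redrawn for the selected unigenes.
#'
#' @param profiles,truth Output of [simulate_metapopulation()].
#' @param groups Named character vector mapping every population to exactly
#'   one of two labels.
#' @param outlier_fraction Fraction of unigenes to alter.
#' @param outlier_F Between-group differentiation level for altered
#'   unigenes.
#' @param seed Integer RNG seed.
#' @return A list `(profiles, truth)` with `truth$unigenes$outlier` marking
#'   the altered unigenes.
#' @export
inject_group_divergence <- function(profiles, truth, groups,
                                    outlier_fraction, outlier_F, seed = 1L) {
  cfg <- truth$config
  pops <- unique(profiles$pop)
  if (is.null(names(groups)) || !setequal(names(groups), pops))
    stop("groups must be named with every population exactly once")
  if (length(unique(groups)) != 2)
    stop("groups must partition populations into exactly two labels")
  if (outlier_fraction == 0) return(list(profiles = profiles, truth = truth))
  stopifnot(outlier_fraction > 0, outlier_fraction <= 1,
            outlier_F >= 0, outlier_F < 1)
  set.seed(as.integer(seed))
  ug <- truth$unigenes$unigene
  pick <- sample.int(length(ug), round(outlier_fraction * length(ug)))
  altered <- ug[pick]
  cfg2 <- cfg
  cfg2$outlier_F <- outlier_F
  sites <- as.data.table(truth$sites)[unigene %in% altered]
  sites[, ref_i := match(ref, BASES)]
  sites[, alt_i := match(alt, BASES)]
  sites[, outlier := TRUE]
  gen <- generate_counts(sites, cfg2, pops, as.character(groups[pops]))
  prof <- rbind(as_profiles_pop(profiles)[!unigene %in% altered],
                gen$profiles)
  setorder(prof, pop, unigene, pos)
  truth$freqs <- rbind(truth$freqs[!unigene %in% altered], gen$freqs)
  setorder(truth$freqs, pop, unigene, pos)
  truth$unigenes <- copy(truth$unigenes)[, outlier := unigene %in% altered]
  list(profiles = prof, truth = truth)
}

# profiles with a pop column, validated
as_profiles_pop <- function(x) {
  dt <- as_profiles(x)
  if (!"pop" %in% names(dt)) stop("a pop column is required")
  dt
}

#' Write simulation truth tables to CSV
#'
#' @param truth The `truth` element of [simulate_metapopulation()] output.
#' @param dir Output directory; files `truth_sites.csv`, `truth_freqs.csv`
#'   and `truth_unigenes.csv` are written there.
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("truth_sites.csv", "truth_freqs.csv",
                            "truth_unigenes.csv"))
  fwrite(truth$sites, paths[1])
  fwrite(truth$freqs, paths[2])
  fwrite(truth$unigenes, paths[3])
  invisible(paths)
}
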