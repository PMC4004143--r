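# Within-pool nucleotide diversity (pi) and derived summaries.
#
# Pool-seq reads are a two-stage sample: reads sample (with replacement) a
# pool of n chromosomes, which itself samples the population. The per-site
# estimator used here is the sample expected heterozygosity with both
# finite-sample corrections,
#
#   pi_hat = (1 - sum_a f_a^2) * M/(M-1) * n/(n-1),
#
# where f_a are post minimum-count base frequencies, M the post-zeroing
# read depth and n the pool chromosome count. Under the two-stage sampling
# model this is unbiased for the population expected heterozygosity
# (verified against a Monte-Carlo oracle in the test suite; the minimum
# count b > 1 induces a small, known downward truncation bias).

# Vectorised per-site pi on a post-filter count matrix.
pi_site_vec <- function(cnt, pool_chromosomes) {
  n <- pool_chromosomes
  M <- rowSums(cnt)
  raw <- 1 - rowSums((cnt / pmax(M, 1))^2)
  val <- raw * M / (M - 1) * n / (n - 1)
  val[M < 2] <- 0           # a lone read carries no heterozygosity signal
  val[raw == 0] <- 0        # monomorphic exactly 0 (avoids -0 artifacts)
  val
}

#' Per-site bias-corrected pooled nucleotide diversity
#'
#' @param profile A single-site profile: either a numeric count vector
#'   `(A, C, G, T)` or a one-row profile table. The site is assumed to have
#'   passed [filter_sites()] (minimum-count zeroing already applied).
#' @param pool_chromosomes Number of haploid chromosome sets in the pool.
#' @return The corrected per-site heterozygosity; 0 for monomorphic sites
#'   and for sites left with fewer than 2 reads.
#' @examples
#' pi_site(c(A = 6, C = 4, G = 0, T = 0), pool_chromosomes = 10) # 0.5926
#' @export
pi_site <- function(profile, pool_chromosomes) {
  cnt <- if (is.matrix(profile)) profile
         else if (is.numeric(profile)) matrix(profile, nrow = 1)
         else as.matrix(as_profiles(profile)[, BASES, with = FALSE])
  stopifnot(ncol(cnt) == 4, pool_chromosomes >= 2)
  pi_site_vec(cnt, pool_chromosomes)
}

#' Per-unigene nucleotide diversity within populations
#'
#' Applies [filter_sites()] and averages the per-site corrected
#' heterozygosity over all retained sites of each unigene; monomorphic
#' sites contribute 0, so pi is per-site over available sites, not over
#' SNPs only. Unigenes with no retained site get `NA` with `n_sites = 0`.
#'
#' @param profiles Profile table; if a `pop` column is present, statistics
#'   are computed per population.
#' @param pool_chromosomes Haploid chromosome sets per pool (single value,
#'   or named vector by population).
#' @param cfg A [filter_config()].
#' @return data.table with columns (`pop`,) `unigene`, `value`, `n_sites`.
#' @export
pi_unigene <- function(profiles, pool_chromosomes = 10L,
                       cfg = filter_config()) {
  dt <- filter_sites(profiles, cfg)
  has_pop <- "pop" %in% names(dt)
  if (!has_pop) dt[, pop := "pop1"]
  npool <- if (is.null(names(pool_chromosomes)))
    setNames(rep(pool_chromosomes[1], length(unique(dt$pop))), unique(dt$pop))
  else pool_chromosomes
  if (nrow(dt)) {
    dt[, value := pi_site_vec(as.matrix(.SD), npool[[.BY$pop]]),
       by = pop, .SDcols = BASES]
  } else {
    dt[, value := numeric(0)]
  }
  out <- dt[, .(value = mean(value), n_sites = .N), by = .(pop, unigene)]
  # unigenes present in input but with no retained site
  ap <- as_profiles(profiles)
  if (!"pop" %in% names(ap)) ap[, pop := "pop1"]
  all_ug <- unique(ap[, .(pop, unigene)])
  out <- out[all_ug, on = c("pop", "unigene")]
  out[is.na(n_sites), n_sites := 0L]
  if (!has_pop) out[, pop := NULL]
  setorderv(out, intersect(c("pop", "unigene"), names(out)))
  out[]
}

#' Remove high-pi outlier unigenes
#'
#' Unigenes with extreme within-pool diversity (default threshold
#' `pi > 0.15`, strict) are set aside before summary statistics; such
#' values arise from alignment collapse of paralogs rather than real
#' polymorphism.
#'
#' @param stats Output of [pi_unigene()].
#' @param threshold Strict upper bound on acceptable unigene pi.
#' @return A list with `kept` and `dropped` tables.
#' @export
drop_pi_outlier_unigenes <- function(stats, threshold = 0.15) {
  dt <- as.data.table(stats)
  bad <- !is.na(dt$value) & dt$value > threshold
  list(kept = dt[!bad], dropped = dt[bad])
}

#' Per-population mean nucleotide diversity
#'
#' Unweighted mean of per-unigene pi values (outliers should already have
#' been removed with [drop_pi_outlier_unigenes()]); unigenes with no
#' retained sites are excluded.
#'
#' @param stats A [pi_unigene()] table (the `kept` element after outlier
#'   removal).
#' @return data.table with columns `pop` (if present) and `mean_pi`.
#' @export
population_mean_pi <- function(stats) {
  dt <- as.data.table(stats)[!is.na(value)]
  if (nrow(dt) == 0) stop("no unigene pi values available")
  if ("pop" %in% names(dt)) dt[, .(mean_pi = mean(value)), by = pop]
  else dt[, .(mean_pi = mean(value))]
}

#' Effective population size from diversity
#'
#' Under neutral equilibrium, expected diversity is 4*Ne*mu, so
#' `Ne ~ pi / (4 mu)`.
#'
#' @param pi Per-site nucleotide diversity (> 0).
#' @param mu Mutation rate per bp per generation (> 0).
#' @return Effective population size estimate(s).
#' @examples
#' ne_estimate(0.006, 1e-9) # 1.5e6
#' @export
ne_estimate <- function(pi, mu) {
  stopifnot(all(pi > 0), all(mu > 0))
  pi / (4 * mu)
}
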