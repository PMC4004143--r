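# Between-population statistics: the absolute-divergence statistic pi_xy,
# per-unigene pairwise F_ST, group-combined frequency profiles, pairwise
# matrices, and bootstrap confidence intervals for genome-wide means.
#
# pi_xy is the average per-site expected heterozygosity among gametic
# unions between populations x and y,
#
#   pi_xy = (1/n) * sum_i (1 - sum_j x_ij * y_ij),
#
# over the n sites passing filters in both populations. It uses allele
# frequencies only, so unlike pi and F_ST it needs no pooled-sampling bias
# correction, and it estimates Nei's d_XY (absolute divergence, insensitive
# to within-population diversity).

# Inner join of two populations' filtered frequency tables on shared sites.
align_pair <- function(x, y, cfg) {
  fx <- profile_freqs(filter_sites(strip_pop(x), cfg))
  fy <- profile_freqs(filter_sites(strip_pop(y), cfg))
  setkey(fx, unigene, pos)
  setkey(fy, unigene, pos)
  j <- fx[fy, nomatch = NULL]
  fcols <- paste0("f", BASES)
  list(unigene = j$unigene,
       X = as.matrix(j[, fcols, with = FALSE]),
       Y = as.matrix(j[, paste0("i.", fcols), with = FALSE]),
       covX = j$coverage, covY = j$i.coverage)
}

strip_pop <- function(x) {
  dt <- as_profiles(x)
  if ("pop" %in% names(dt)) {
    if (length(unique(dt$pop)) > 1)
      stop("expected a single population; got several pop values")
    dt[, pop := NULL]
  }
  dt
}

#' Per-unigene absolute divergence (pi_xy) between two populations
#'
#' Only sites that pass [filter_sites()] in *both* populations enter the
#' calculation; `n_sites` counts those shared sites. Unigenes with no
#' shared site get `NA`.
#'
#' @param x,y Single-population profile tables.
#' @param cfg A [filter_config()].
#' @return data.table with `unigene`, `value`, `n_sites`.
#' @export
pixy_unigene <- function(x, y, cfg = filter_config()) {
  al <- align_pair(x, y, cfg)
  if (!length(al$unigene))
    return(data.table(unigene = character(), value = numeric(),
                      n_sites = integer()))
  site <- 1 - rowSums(al$X * al$Y)
  data.table(unigene = al$unigene, site = site)[
    , .(value = mean(site), n_sites = .N), by = unigene][]
}

#' Group-combined frequency profiles
#'
#' Combines member populations into one frequency profile per site by the
#' unweighted mean of the member frequency vectors (explicitly not
#' coverage-weighted, to avoid biases from uneven sequence coverage
#' between pools). A site is used only if it passes filters in every
#' member population.
#'
#' @param profiles Long profile table with a `pop` column.
#' @param members Population names to combine.
#' @param cfg A [filter_config()].
#' @return data.table with `unigene`, `pos`, `fA`,`fC`,`fG`,`fT`.
#' @export
group_profile <- function(profiles, members, cfg = filter_config()) {
  dt <- as_profiles_pop(profiles)[pop %in% members]
  if (!setequal(unique(dt$pop), members)) stop("missing member population")
  f <- profile_freqs(filter_sites(dt, cfg))
  fcols <- paste0("f", BASES)
  g <- f[, c(.(n = .N), lapply(.SD, mean)), by = .(unigene, pos),
         .SDcols = fcols]
  g <- g[n == length(members)][, n := NULL]
  setorder(g, unigene, pos)
  g[]
}

#' Per-unigene pairwise F_ST between two pooled populations
#'
#' Classical per-unigene F_ST = (pi_T - pi_S)/pi_T aggregated as a
#' ratio-of-sums over the shared filtered sites: pi_S is the mean of the
#' two within-population per-site diversities and pi_T the diversity of
#' the site-wise mean frequency profile. With `corrected = TRUE` (the
#' default) the within terms carry the pooled-sampling corrections
#' M/(M-1) * n/(n-1) and the total term uses the combined read depth and
#' combined chromosome count. Negative values are possible under the
#' corrections and are reported, not clamped. Unigenes with pi_T = 0 get
#' `NA`.
#'
#' @param x,y Single-population profile tables.
#' @param pool_x,pool_y Haploid chromosome sets per pool.
#' @param cfg A [filter_config()].
#' @param corrected Apply finite-sample corrections (default `TRUE`).
#' @return data.table with `unigene`, `value`, `n_sites`.
#' @export
fst_unigene <- function(x, y, pool_x = 10L, pool_y = 10L,
                        cfg = filter_config(), corrected = TRUE) {
  al <- align_pair(x, y, cfg)
  if (!length(al$unigene))
    return(data.table(unigene = character(), value = numeric(),
                      n_sites = integer()))
  hx <- 1 - rowSums(al$X^2)
  hy <- 1 - rowSums(al$Y^2)
  ht <- 1 - rowSums(((al$X + al$Y) / 2)^2)
  if (corrected) {
    hx <- hx * al$covX / (al$covX - 1) * pool_x / (pool_x - 1)
    hy <- hy * al$covY / (al$covY - 1) * pool_y / (pool_y - 1)
    hx[al$covX < 2] <- 0
    hy[al$covY < 2] <- 0
    mT <- al$covX + al$covY
    nT <- pool_x + pool_y
    ht <- ht * mT / (mT - 1) * nT / (nT - 1)
  }
  hs <- (hx + hy) / 2
  data.table(unigene = al$unigene, hs = hs, ht = ht)[
    , .(value = {
      st <- sum(ht)
      if (st == 0) NA_real_ else (st - sum(hs)) / st
    }, n_sites = .N), by = unigene][]
}

#' Pairwise population matrix of genome-wide pi_xy or F_ST
#'
#' For every pair of populations the per-unigene statistic is computed on
#' their shared filtered sites and summarised as the unweighted mean over
#' unigenes (unigenes with a missing value are skipped).
#'
#' @param profiles Long profile table with a `pop` column.
#' @param statistic `"pixy"` or `"fst"`.
#' @param cfg A [filter_config()].
#' @param pool_chromosomes Single value or named-by-population vector.
#' @param corrected Passed to [fst_unigene()].
#' @return A symmetric matrix with population dimnames and zero diagonal.
#' @export
pairwise_matrix <- function(profiles, statistic = c("pixy", "fst"),
                            cfg = filter_config(), pool_chromosomes = 10L,
                            corrected = TRUE) {
  statistic <- match.arg(statistic)
  dt <- as_profiles_pop(profiles)
  pops <- unique(dt$pop)
  if (length(pops) < 2) stop("need at least two populations")
  npool <- if (is.null(names(pool_chromosomes)))
    setNames(rep(pool_chromosomes[1], length(pops)), pops) else pool_chromosomes
  split_p <- split(dt, by = "pop")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1):length(pops)) {
      st <- if (statistic == "pixy")
        pixy_unigene(split_p[[pops[i]]], split_p[[pops[j]]], cfg)
      else fst_unigene(split_p[[pops[i]]], split_p[[pops[j]]],
                       npool[[pops[i]]], npool[[pops[j]]], cfg, corrected)
      m[i, j] <- m[j, i] <- mean(st$value, na.rm = TRUE)
    }
  }
  m
}

#' Percentile bootstrap CI for a genome-wide mean
#'
#' Resamples unigenes with replacement and reports the percentile interval
#' of the resampled means.
#'
#' @param values Per-unigene statistic values (`NA` dropped).
#' @param reps Bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional RNG seed.
#' @return Named numeric vector `(mean, lo, hi)`.
#' @export
bootstrap_mean_ci <- function(values, reps = 1000L, level = 0.95,
                              seed = NULL) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("no values to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  bm <- vapply(seq_len(reps),
               function(i) mean(v[sample.int(length(v), replace = TRUE)]),
               numeric(1))
  a <- (1 - level) / 2
  ci <- quantile(bm, c(a, 1 - a), names = FALSE)
  c(mean = mean(v), lo = ci[1], hi = ci[2])
}
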