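# Permutation outlier scan between two phenotype-defined groups of
# populations. Per unigene, the observed group-combined statistic (pi_xy or
# F_ST between the unweighted group mean frequency profiles) is compared to
# the nearest-rank 99th percentile of the same statistic over permuted
# population labels: exact enumeration of all label assignments when their
# number is small, uniform Monte-Carlo sampling without replacement
# otherwise. No multiple-testing correction is applied; with K enumerated
# assignments the best attainable significance is 1/K, so results are
# exploratory candidate lists by design.

#' Outlier-scan settings
#'
#' @param statistic `"pixy"` (absolute divergence) or `"fst"`.
#' @param percentile Permutation percentile used as the outlier threshold
#'   (default 99, nearest-rank).
#' @param enumeration_cap Enumerate all label assignments exactly when
#'   their count is at most this (default 10,000); otherwise sample.
#' @param n_monte_carlo Number of distinct assignments sampled when not
#'   enumerating (default 1,000).
#' @param min_sites Minimum shared filtered sites for a unigene to be
#'   scanned (default 50).
#' @param seed RNG seed (used only for Monte-Carlo sampling).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(statistic = c("pixy", "fst"), percentile = 99,
                        enumeration_cap = 10000L, n_monte_carlo = 1000L,
                        min_sites = 50L, seed = 1L) {
  statistic <- match.arg(statistic)
  stopifnot(percentile > 0, percentile < 100, enumeration_cap >= 1,
            n_monte_carlo >= 1, min_sites >= 1)
  structure(list(statistic = statistic, percentile = percentile,
                 enumeration_cap = as.integer(enumeration_cap),
                 n_monte_carlo = as.integer(n_monte_carlo),
                 min_sites = as.integer(min_sites), seed = as.integer(seed)),
            class = "scan_config")
}

#' Enumerate or sample two-group label assignments
#'
#' An assignment places `m` of the `k + m` populations in the second group.
#' All `choose(k + m, m)` distinct assignments are returned when that count
#' is at most `cap`; otherwise `n_monte_carlo` distinct assignments are
#' sampled uniformly without replacement.
#'
#' @param k,m Sizes of the two groups.
#' @param cap Enumeration cap.
#' @param n_monte_carlo Sample size when not enumerating.
#' @param seed RNG seed (Monte-Carlo only).
#' @return List with `assignments` (an `m` x K index matrix, columns =
#'   assignments, indices into the `k + m` populations) and `exact`.
#' @export
enumerate_assignments <- function(k, m, cap = 10000L,
                                  n_monte_carlo = 1000L, seed = 1L) {
  stopifnot(k >= 1, m >= 1)
  if (cap < 1) stop("cap must be >= 1")
  total <- choose(k + m, m)
  if (total <= cap) {
    a <- combn(k + m, m)
    return(list(assignments = a, exact = TRUE))
  }
  set.seed(as.integer(seed))
  n_mc <- min(n_monte_carlo, total)
  seen <- character(0)
  picks <- matrix(0L, m, 0L)
  while (ncol(picks) < n_mc) {
    draw <- replicate(n_mc - ncol(picks),
                      sort(sample.int(k + m, m)), simplify = "matrix")
    draw <- matrix(draw, nrow = m)
    key <- apply(draw, 2, paste, collapse = ",")
    new <- !duplicated(key) & !(key %in% seen)
    picks <- cbind(picks, draw[, new, drop = FALSE])
    seen <- c(seen, key[new])
  }
  list(assignments = picks, exact = FALSE)
}

# Shared filtered sites across all populations, as per-base frequency
# matrices (sites x pops) plus unigene index.
align_all <- function(profiles, pops, cfg) {
  dt <- as_profiles_pop(profiles)[pop %in% pops]
  if (!setequal(unique(dt$pop), pops)) stop("population missing from profiles")
  f <- profile_freqs(filter_sites(dt, cfg))
  f[, pop := factor(pop, levels = pops)]
  nshared <- f[, .N, by = .(unigene, pos)]
  f <- f[nshared[N == length(pops)], on = c("unigene", "pos")]
  setorder(f, unigene, pos, pop)
  S <- nrow(f) / length(pops)
  sites <- f[pop == pops[1], .(unigene, pos)]
  Fb <- lapply(paste0("f", BASES), function(cl)
    matrix(f[[cl]], nrow = S, ncol = length(pops), byrow = TRUE))
  names(Fb) <- BASES
  list(sites = sites, F = Fb)
}

# Per-unigene group statistic for a batch of assignments.
# Fb: list of 4 S x P matrices; WA, WB: P x K weight matrices.
scan_stat_batch <- function(Fb, WA, WB, ug, nsite, statistic) {
  S <- nrow(Fb[[1]])
  sxy <- sxx <- syy <- matrix(0, S, ncol(WA))
  for (b in BASES) {
    X <- Fb[[b]] %*% WA
    Y <- Fb[[b]] %*% WB
    sxy <- sxy + X * Y
    if (statistic == "fst") {
      sxx <- sxx + X * X
      syy <- syy + Y * Y
    }
  }
  if (statistic == "pixy") {
    rowsum(1 - sxy, ug) / as.vector(nsite)
  } else {
    # ht - hs = ((sxx + syy)/2 - sxy)/2 pointwise, since
    # ht = 1 - (sxx + 2 sxy + syy)/4 and hs = 1 - (sxx + syy)/2
    ht <- 1 - (sxx + 2 * sxy + syy) / 4
    hs <- 1 - (sxx + syy) / 2
    num <- rowsum(ht - hs, ug)
    den <- rowsum(ht, ug)
    val <- num / den
    val[den == 0] <- NA_real_
    val
  }
}

#' Permutation outlier scan between two population groups
#'
#' For every unigene with at least `min_sites` sites passing filters in all
#' populations of the comparison, computes the observed group-combined
#' statistic and its permutation null over relabelled populations, flags
#' unigenes whose observed value strictly exceeds the nearest-rank
#' percentile threshold. The site set of each unigene is fixed (shared
#' filtered sites across all populations) so that permuted statistics are
#' directly comparable to the observed one.
#'
#' @param profiles Long profile table with a `pop` column.
#' @param groups Named character vector mapping each population of the
#'   comparison to one of exactly two labels.
#' @param cfg A [scan_config()].
#' @param filter A [filter_config()].
#' @return data.table with `unigene`, `n_sites`, `observed`, `threshold`,
#'   `n_permutations_used`, `exact`, `outlier`.
#' @export
outlier_scan <- function(profiles, groups, cfg = scan_config(),
                 filter = filter_config()) {
  groups <- setNames(as.character(groups), names(groups))
  labs <- unique(groups)
  if (length(labs) != 2) stop("groups must use exactly two labels")
  pops <- names(groups)
  if (is.null(pops)) stop("groups must be named by population")
  gB <- pops[groups == labs[2]]
  k <- sum(groups == labs[1])
  m <- length(gB)
  al <- align_all(profiles, pops, filter)
  cnt <- al$sites[, .N, by = unigene]
  keep_ug <- cnt[N >= cfg$min_sites, unigene]
  keep <- al$sites$unigene %in% keep_ug
  if (!any(keep))
    return(data.table(unigene = character(), n_sites = integer(),
                      observed = numeric(), threshold = numeric(),
                      n_permutations_used = integer(), exact = logical(),
                      outlier = logical()))
  Fb <- lapply(al$F, function(mx) mx[keep, , drop = FALSE])
  ug <- factor(al$sites$unigene[keep], levels = keep_ug)
  ugi <- as.integer(ug)
  nsite <- tabulate(ugi, nbins = length(keep_ug))
  P <- length(pops)
  en <- enumerate_assignments(k, m, cfg$enumeration_cap, cfg$n_monte_carlo,
                              cfg$seed)
  asn <- en$assignments
  K <- ncol(asn)
  # observed assignment column
  obs_idx <- sort(match(gB, pops))
  make_w <- function(idx_mat) {
    WB <- matrix(0, P, ncol(idx_mat))
    WB[cbind(as.vector(idx_mat), rep(seq_len(ncol(idx_mat)), each = m))] <- 1 / m
    WA <- (matrix(1 / k, P, ncol(idx_mat))) * (WB == 0)
    list(WA = WA, WB = WB)
  }
  wobs <- make_w(matrix(obs_idx, ncol = 1))
  observed <- as.vector(scan_stat_batch(Fb, wobs$WA, wobs$WB, ugi, nsite,
                                        cfg$statistic))
  U <- length(keep_ug)
  perm <- matrix(NA_real_, U, K)
  chunk <- max(1L, floor(2e6 / length(ugi)))
  for (s in seq(1L, K, by = chunk)) {
    cols <- s:min(K, s + chunk - 1L)
    w <- make_w(asn[, cols, drop = FALSE])
    perm[, cols] <- scan_stat_batch(Fb, w$WA, w$WB, ugi, nsite, cfg$statistic)
  }
  rank_idx <- ceiling(cfg$percentile / 100 * K)
  threshold <- apply(perm, 1, function(r) sort(r)[rank_idx])
  res <- data.table(unigene = keep_ug, n_sites = nsite, observed = observed,
                    threshold = threshold, n_permutations_used = K,
                    exact = en$exact, outlier = observed > threshold)
  degenerate <- is.na(res$observed)
  if (any(degenerate))
    message(sum(degenerate), " degenerate unigene(s) excluded from scan")
  res[!degenerate][]
}
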