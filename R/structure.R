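# Population-structure analyses downstream of the pairwise matrices:
# principal coordinates analysis, SNP-discovery rarefaction, and
# isolation-by-distance regression with a Mantel test.

#' Principal coordinates analysis of a distance matrix
#'
#' Classical multidimensional scaling (Gower double-centering of the
#' squared distances followed by eigendecomposition, via
#' [stats::cmdscale()]). Axes are ordered by decreasing eigenvalue and the
#' sign of each axis is fixed so its largest-magnitude coordinate is
#' positive.
#'
#' @param dist Symmetric matrix with zero diagonal (e.g. a pairwise pi_xy
#'   matrix used as a genetic distance).
#' @param k Number of axes to return (default 2).
#' @return List with `points` (n x k' coordinate matrix, k' <= k positive-
#'   eigenvalue axes, zero-padded if the distances are degenerate) and
#'   `eig` (all eigenvalues, decreasing).
#' @export
pcoa <- function(dist, k = 2L) {
  m <- as.matrix(dist)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("pcoa needs a symmetric distance matrix")
  if (any(abs(diag(m)) > 1e-12)) stop("pcoa needs a zero diagonal")
  k <- min(k, nrow(m) - 1L)
  fit <- suppressWarnings(cmdscale(m, k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts)) || ncol(pts) < k) {
    pad <- matrix(0, nrow(m), k - NCOL(pts))
    pts <- cbind(pts, pad)
  }
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (length(i) && pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(m)
  list(points = pts, eig = fit$eig)
}

#' Segregating-site sets per population
#'
#' A site is in a population's SNP set when it passes [filter_sites()] and
#' still carries at least two alleles after minimum-count zeroing.
#'
#' @param profiles Long profile table with a `pop` column.
#' @param cfg A [filter_config()].
#' @return Named list of character vectors of `"unigene:pos"` keys.
#' @export
snp_sets <- function(profiles, cfg = filter_config()) {
  dt <- filter_sites(as_profiles_pop(profiles), cfg)
  cnt <- as.matrix(dt[, BASES, with = FALSE])
  seg <- rowSums(cnt > 0L) >= 2L
  dt <- dt[seg]
  split(paste(dt$unigene, dt$pos, sep = ":"), dt$pop)
}

#' SNP-discovery rarefaction curve
#'
#' Adds populations in random order and records how many new SNPs each one
#' contributes; the curve is the mean over `n_orders` random orders with a
#' 2.5/97.5 percentile envelope.
#'
#' @param sets Named list of per-population SNP key sets (see [snp_sets()]).
#' @param n_orders Number of random input orders (default 100).
#' @param seed Optional RNG seed.
#' @return data.table with `step`, `mean_new`, `lo`, `hi`; the per-order
#'   step counts are attached as attribute `per_order` (orders x steps).
#' @export
rarefaction <- function(sets, n_orders = 100L, seed = NULL) {
  P <- length(sets)
  if (P == 0) stop("no populations")
  if (!is.null(seed)) set.seed(seed)
  per <- matrix(0L, n_orders, P)
  for (o in seq_len(n_orders)) {
    ord <- sample.int(P)
    seen <- character(0)
    for (t in seq_len(P)) {
      new <- setdiff(sets[[ord[t]]], seen)
      per[o, t] <- length(new)
      seen <- c(seen, new)
    }
  }
  out <- data.table(step = seq_len(P),
                    mean_new = colMeans(per),
                    lo = apply(per, 2, quantile, 0.025, names = FALSE),
                    hi = apply(per, 2, quantile, 0.975, names = FALSE))
  setattr(out, "per_order", per)
  out[]
}

#' Linearize F_ST for isolation-by-distance regression
#'
#' @param fst F_ST value(s), each < 1.
#' @return `fst / (1 - fst)`, strictly increasing on `[0, 1)`.
#' @export
linearize_fst <- function(fst) {
  stopifnot(all(fst < 1, na.rm = TRUE))
  fst / (1 - fst)
}

# Great-circle distance matrix (km) on a spherical Earth, R = 6371 km.
haversine_km <- function(coords) {
  n <- nrow(coords)
  m <- matrix(0, n, n, dimnames = list(rownames(coords), rownames(coords)))
  for (i in seq_len(n - 1)) {
    d <- distHaversine(coords[i, c("lon", "lat")],
                       coords[(i + 1):n, c("lon", "lat"), drop = FALSE],
                       r = 6371)
    m[i, (i + 1):n] <- m[(i + 1):n, i] <- d
  }
  m
}

# All permutations of 1..n (n small; used for exact Mantel enumeration).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles, with a one-sided (upper)
#' permutation test that jointly permutes rows and columns of the second
#' matrix. When `factorial(n) <= n_perm` all label permutations are
#' enumerated and the p-value is exact (the identity permutation counts);
#' otherwise `n_perm` random permutations are drawn and
#' `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)`.
#'
#' @param a,b Symmetric matrices.
#' @param n_perm Permutation budget (default 9999).
#' @param seed Optional RNG seed.
#' @return List with `r`, `p`, `n_perm_used`, `exact`.
#' @export
mantel_test <- function(a, b, n_perm = 9999L, seed = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  stopifnot(all(dim(a) == n), all(dim(b) == n), n >= 3)
  lt <- lower.tri(a)
  r_obs <- cor(a[lt], b[lt])
  exact <- factorial(n) <= n_perm
  if (exact) {
    pm <- all_perms(n)
    rp <- apply(pm, 1, function(p) cor(a[lt], b[p, p][lt]))
    p <- mean(rp >= r_obs - 1e-12)
    k <- nrow(pm)
  } else {
    if (!is.null(seed)) set.seed(seed)
    rp <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(a[lt], b[p, p][lt])
    }, numeric(1))
    p <- (1 + sum(rp >= r_obs - 1e-12)) / (1 + n_perm)
    k <- n_perm
  }
  list(r = r_obs, p = p, n_perm_used = k, exact = exact)
}

#' Isolation by distance
#'
#' Regresses linearized F_ST, `F_ST/(1-F_ST)`, on the natural log of the
#' great-circle distance (haversine, spherical Earth R = 6371 km) between
#' populations, and tests the matrix correlation with a one-sided Mantel
#' test.
#'
#' @param fst_matrix Symmetric pairwise F_ST matrix.
#' @param coords data.frame with rownames (or a `name` column) matching the
#'   matrix labels and columns `lat`, `lon` in decimal degrees.
#' @param n_perm Mantel permutation budget (default 9999).
#' @param seed Optional RNG seed.
#' @return An `ibd_result` list: `pearson_r`, `mantel_p`, `slope`,
#'   `intercept`, `n_pairs`, `n_perm_used`, `exact`.
#' @export
ibd <- function(fst_matrix, coords, n_perm = 9999L, seed = NULL) {
  m <- as.matrix(fst_matrix)
  cd <- as.data.frame(coords)
  if ("name" %in% names(cd)) {
    rownames(cd) <- cd$name
  }
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- rownames(cd)
  if (!all(rownames(m) %in% rownames(cd))) stop("coordinates missing for some populations")
  cd <- cd[rownames(m), , drop = FALSE]
  if (nrow(m) < 4) stop("need at least 4 populations")
  dup <- duplicated(cd[, c("lat", "lon")]) |
    duplicated(cd[, c("lat", "lon")], fromLast = TRUE)
  if (any(dup))
    stop("duplicate coordinates: ", paste(rownames(cd)[dup], collapse = ", "))
  D <- haversine_km(as.matrix(cd[, c("lat", "lon")]))
  if (any(D[lower.tri(D)] <= 0)) stop("non-positive pairwise distance")
  lt <- lower.tri(m)
  y <- linearize_fst(m[lt])
  x <- log(D[lt])
  fit <- lm(y ~ x)
  mt <- mantel_test(log(D), linearize_fst(m), n_perm = n_perm, seed = seed)
  structure(list(pearson_r = cor(x, y), mantel_p = mt$p,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 n_pairs = sum(lt), n_perm_used = mt$n_perm_used,
                 exact = mt$exact),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf(
    "Isolation by distance over %d population pairs\n  Pearson r = %.3f,  Mantel p = %.4g (%s, %d permutations)\n  FST/(1-FST) = %.4g + %.4g * ln(km)\n",
    x$n_pairs, x$pearson_r, x$mantel_p,
    if (x$exact) "exact" else "sampled", x$n_perm_used,
    x$intercept, x$slope))
  invisible(x)
}
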