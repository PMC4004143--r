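# Shared fixture builders and independent oracles used across test files.

library(data.table)

# A single-population profile table from a list of count vectors (A,C,G,T).
make_profiles <- function(counts, unigene = "u1", pop = NULL) {
  dt <- data.table::as.data.table(do.call(rbind, counts))
  data.table::setnames(dt, c("A", "C", "G", "T"))
  dt[, unigene := unigene]
  dt[, pos := seq_len(.N), by = unigene]
  if (!is.null(pop)) dt[, pop := pop]
  dt[]
}

# SAM record line; defaults give a clean 10M read of A's at Q40.
sam_read <- function(qname = "r1", flag = 0L, rname = "ug1", pos = 1L,
                     mapq = 60L, cigar = "10M", seq = strrep("A", 10),
                     qual = strrep("I", nchar(seq))) {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq, qual,
        sep = "\t")
}

sam_header <- function(refs = c(ug1 = 100L)) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
}

# Brute-force per-unigene F_ST oracle (uncorrected): explicit per-site
# heterozygosities summed over sites, independent of the package path.
brute_fst <- function(cx, cy) {
  stopifnot(nrow(cx) == nrow(cy))
  ht_sum <- hs_sum <- 0
  for (i in seq_len(nrow(cx))) {
    fx <- cx[i, ] / sum(cx[i, ])
    fy <- cy[i, ] / sum(cy[i, ])
    hx <- 1 - sum(fx^2)
    hy <- 1 - sum(fy^2)
    fm <- (fx + fy) / 2
    ht <- 1 - sum(fm^2)
    hs_sum <- hs_sum + (hx + hy) / 2
    ht_sum <- ht_sum + ht
  }
  (ht_sum - hs_sum) / ht_sum
}

# Brute-force pi_xy oracle.
brute_pixy <- function(cx, cy) {
  v <- vapply(seq_len(nrow(cx)), function(i) {
    fx <- cx[i, ] / sum(cx[i, ])
    fy <- cy[i, ] / sum(cy[i, ])
    1 - sum(fx * fy)
  }, numeric(1))
  mean(v)
}

# All permutations of 1..n via filtered expand.grid (independent of the
# package's recursive generator).
enum_perms <- function(n) {
  g <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n)))
  g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}
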