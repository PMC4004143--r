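# Base-count profiles: reading, writing and the site-inclusion filters.
#
# A profile set is a data.frame/data.table with one row per (population,)
# unigene, position and integer columns A, C, G, T holding filtered read
# counts. The `pop` column is optional for single-population sets.

#' Site-inclusion filter settings
#'
#' Bundles the read- and site-level thresholds applied before any statistic
#' is computed: coverage bounds per site, the minimum count `b` a variant
#' needs to be believed, and the read-level mapping/base-quality cut-offs
#' used when piling up SAM records.
#'
#' @param min_coverage Minimum read depth for a site to be used (default 5).
#' @param max_coverage Maximum read depth; deeper sites are discarded as
#'   likely paralog/CNV collapse (default 40, strictly-greater-than rule:
#'   a site at exactly 40 is kept).
#' @param min_count Minimum count `b` for a base to be accepted as a real
#'   variant; lower non-zero counts are zeroed (default 2).
#' @param min_base_quality Minimum PHRED base quality for a read base to be
#'   counted (default 30).
#' @param min_mapq Minimum mapping quality for a read to be used (default 25).
#' @param drop_softclipped Drop reads whose CIGAR contains any soft-clip
#'   (`S`) operation; these typically mark exon/intron boundary mismatches
#'   when genomic reads are aligned to a transcriptome (default `TRUE`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_coverage = 5L, max_coverage = 40L,
                          min_count = 2L, min_base_quality = 30L,
                          min_mapq = 25L, drop_softclipped = TRUE) {
  stopifnot(min_coverage >= 1, max_coverage >= min_coverage, min_count >= 1,
            min_base_quality >= 0, min_mapq >= 0, is.logical(drop_softclipped))
  structure(list(min_coverage = as.integer(min_coverage),
                 max_coverage = as.integer(max_coverage),
                 min_count = as.integer(min_count),
                 min_base_quality = as.integer(min_base_quality),
                 min_mapq = as.integer(min_mapq),
                 drop_softclipped = isTRUE(drop_softclipped)),
            class = "filter_config")
}

# Coerce/validate a profile table. Always returns a fresh data.table.
as_profiles <- function(x) {
  need <- c("unigene", "pos", BASES)
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("profiles need columns unigene, pos, A, C, G, T")
  dt <- as.data.table(x)
  for (b in BASES) set(dt, j = b, value = as.integer(dt[[b]]))
  if (any(unlist(dt[, lapply(.SD, function(v) any(v < 0)), .SDcols = BASES])))
    stop("negative base counts")
  dt
}

#' Apply site-level filters to base-count profiles
#'
#' Drops sites whose raw coverage is below `min_coverage` or above
#' `max_coverage`, then zeroes any base whose count is below the minimum
#' count `b` (`min_count`) so that sub-threshold minor variants are treated
#' as absent, and recomputes coverage. Sites whose post-zeroing coverage
#' falls below `min_coverage` are also dropped, which makes the operation
#' idempotent: the coverage rule is read as applying to usable bases.
#'
#' @param profiles Profile table (columns `unigene`, `pos`, `A`,`C`,`G`,`T`,
#'   optionally `pop`).
#' @param cfg A [filter_config()].
#' @return Filtered profile table of the same shape.
#' @export
filter_sites <- function(profiles, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  dt <- as_profiles(profiles)
  cnt <- as.matrix(dt[, BASES, with = FALSE])
  cov <- rowSums(cnt)
  keep <- cov >= cfg$min_coverage & cov <= cfg$max_coverage
  dt <- dt[keep]
  cnt <- cnt[keep, , drop = FALSE]
  cnt[cnt > 0L & cnt < cfg$min_count] <- 0L
  keep2 <- rowSums(cnt) >= cfg$min_coverage
  for (j in seq_along(BASES)) set(dt, j = BASES[j], value = as.integer(cnt[, j]))
  dt[keep2]
}

#' Convert counts to base frequencies
#'
#' @param profiles A (filtered) profile table.
#' @return The table with `coverage` and frequency columns `fA`,`fC`,`fG`,`fT`
#'   appended; frequencies sum to 1 at every site.
#' @export
profile_freqs <- function(profiles) {
  dt <- as_profiles(profiles)
  cnt <- as.matrix(dt[, BASES, with = FALSE])
  cov <- rowSums(cnt)
  if (any(cov == 0)) stop("zero-coverage site; run filter_sites() first")
  dt[, coverage := as.integer(cov)]
  fr <- cnt / cov
  for (j in seq_along(BASES))
    set(dt, j = paste0("f", BASES[j]), value = fr[, j])
  dt
}

## ---- sync-style tab format ------------------------------------------------

#' Write profiles to a sync-style tab file
#'
#' One line per site: unigene, position, reference base (written as `N`,
#' unknown), then one `A:C:G:T:N:del` count string per population. A
#' `#`-prefixed header line records the population names so that
#' [read_sync()] restores them.
#'
#' @param profiles Profile table with a `pop` column.
#' @param path Output file path.
#' @export
write_sync <- function(profiles, path) {
  dt <- as_profiles(profiles)
  if (!"pop" %in% names(dt)) stop("write_sync needs a pop column")
  pops <- unique(dt$pop)
  wide <- dcast(dt, unigene + pos ~ pop, value.var = BASES, fill = 0L)
  setorder(wide, unigene, pos)
  cols <- lapply(pops, function(p) {
    sprintf("%d:%d:%d:%d:0:0",
            wide[[paste0("A_", p)]], wide[[paste0("C_", p)]],
            wide[[paste0("G_", p)]], wide[[paste0("T_", p)]])
  })
  lines <- do.call(paste, c(list(wide$unigene, wide$pos, "N"), cols,
                            list(sep = "\t")))
  writeLines(c(paste0("#unigene\tpos\tref\t", paste(pops, collapse = "\t")),
               lines), path)
  invisible(path)
}

#' Read a sync-style tab file into profiles
#'
#' Expects columns: reference name, 1-based position, reference base (`N`
#' allowed), then per-population `A:C:G:T:N:del` count strings. `N` and
#' deletion counts are parsed but ignored by all statistics. Cells with no
#' A/C/G/T reads yield no profile row.
#'
#' @param path Input file path.
#' @param pops Optional population names; defaults to a `#` header line if
#'   present, else `pop1..popN`.
#' @return Long profile table with a `pop` column.
#' @export
read_sync <- function(path, pops = NULL) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "#")) {
    hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
    if (is.null(pops) && length(hdr) > 3) pops <- hdr[-(1:3)]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(data.table(pop = character(), unigene = character(),
                                        pos = integer(), A = integer(),
                                        C = integer(), G = integer(), T = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]) || nf[1] < 4) {
    bad <- which(nf != nf[1] | nf < 4)[1]
    stop(sprintf("sync parse error at line %d: expected %d fields, got %d",
                 bad, max(nf[1], 4), nf[bad]))
  }
  npop <- nf[1] - 3L
  if (is.null(pops)) pops <- sprintf("pop%d", seq_len(npop))
  if (length(pops) != npop) stop("pop name count does not match sync columns")
  m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  out <- vector("list", npop)
  for (j in seq_len(npop)) {
    cs <- strsplit(m[, 3L + j], ":", fixed = TRUE)
    if (any(lengths(cs) != 6))
      stop(sprintf("sync parse error at line %d: count string needs 6 fields",
                   which(lengths(cs) != 6)[1]))
    cm <- matrix(as.integer(unlist(cs)), ncol = 6, byrow = TRUE)
    out[[j]] <- data.table(pop = pops[j], unigene = m[, 1],
                           pos = as.integer(m[, 2]),
                           A = cm[, 1], C = cm[, 2], G = cm[, 3], T = cm[, 4])
  }
  dt <- rbindlist(out)
  dt[A + C + G + T > 0L]
}

## ---- SNP-table dialect ----------------------------------------------------

#' Read a population SNP table (deposit dialect)
#'
#' Comma-separated: `unigene,position,sequence` followed by one column per
#' population. Missing genotypes are denoted by a dash; the unigene sequence
#' is listed on first usage only and is inherited by later rows of the same
#' unigene.
#'
#' @param path CSV file path.
#' @return A list with `records` (long table: unigene, pos, pop, state; dash
#'   becomes `NA`) and `sequences` (named character vector per unigene).
#' @export
read_snp_table <- function(path) {
  dt <- tryCatch(suppressWarnings(
    fread(path, colClasses = list(character = "sequence"))),
    error = function(e) NULL)
  if (is.null(dt) || nrow(dt) == 0) {
    warning("empty SNP table: ", path)
    return(list(records = data.table(unigene = character(), pos = integer(),
                                     pop = character(), state = character()),
                sequences = character()))
  }
  setnames(dt, 1:2, c("unigene", "pos"))
  if (names(dt)[3] != "sequence") stop("third column must be 'sequence'")
  if (anyDuplicated(dt[, .(unigene, pos)]))
    stop("duplicate (unigene, position) in SNP table")
  seqs <- dt[nzchar(sequence), .(s = sequence[1]), by = unigene]
  sequences <- setNames(seqs$s, seqs$unigene)
  popcols <- names(dt)[-(1:3)]
  rec <- melt(dt[, c("unigene", "pos", popcols), with = FALSE],
              id.vars = c("unigene", "pos"), variable.name = "pop",
              value.name = "state", variable.factor = FALSE)
  rec[, state := as.character(state)]
  rec[state == "-", state := NA_character_]
  list(records = rec[], sequences = sequences)
}

## ---- SAM records -> profiles ----------------------------------------------

#' Pile up filtered SAM records into base-count profiles
#'
#' Streams text SAM records; excludes unmapped reads, reads with mapping
#' quality below `min_mapq`, and (by default) any read whose CIGAR contains
#' a soft-clip operation. Of the remaining aligned bases, only those with
#' base quality at or above `min_base_quality` are counted. Coordinates are
#' 1-based along the reference (unigene).
#'
#' @param sam Path to a SAM file, or a character vector of SAM lines.
#' @param cfg A [filter_config()]; only the read-level fields are used here.
#' @return Profile table (`unigene`, `pos`, `A`,`C`,`G`,`T`), one row per
#'   site with at least one counted base. The number of excluded reads per
#'   reason is attached as attribute `excluded`.
#' @export
reads_to_profiles <- function(sam, cfg = filter_config()) {
  lines <- if (length(sam) == 1 && file.exists(sam)) readLines(sam) else sam
  hdr <- startsWith(lines, "@")
  refs <- NULL
  sq <- lines[hdr & startsWith(lines, "@SQ")]
  if (length(sq))
    refs <- sub("^SN:", "", vapply(strsplit(sq, "\t"), function(f)
      f[startsWith(f, "SN:")][1], character(1)))
  recs <- lines[!hdr & nzchar(lines)]
  excl <- c(unmapped = 0L, low_mapq = 0L, softclipped = 0L, low_basequal = 0L)
  acc_ref <- acc_pos <- acc_base <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    f <- strsplit(recs[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop("malformed SAM record: ", f[1])
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L || f[3] == "*") {
      excl["unmapped"] <- excl["unmapped"] + 1L
      next
    }
    if (!is.null(refs) && !(f[3] %in% refs))
      stop("unknown reference '", f[3], "' in record ", f[1])
    cigar <- f[6]
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    if (cigar == "*" || !length(ops) ||
        nchar(paste(ops, collapse = "")) != nchar(cigar))
      stop("malformed CIGAR '", cigar, "' in record ", f[1])
    if (as.integer(f[5]) < cfg$min_mapq) {
      excl["low_mapq"] <- excl["low_mapq"] + 1L
      next
    }
    op <- substr(ops, nchar(ops), nchar(ops))
    len <- as.integer(substr(ops, 1, nchar(ops) - 1))
    if (cfg$drop_softclipped && any(op == "S")) {
      excl["softclipped"] <- excl["softclipped"] + 1L
      next
    }
    seqc <- strsplit(f[10], "")[[1]]
    qual <- utf8ToInt(f[11]) - 33L
    refpos <- as.integer(f[4]); qpos <- 1L
    rp <- qp <- integer(0)
    for (k in seq_along(op)) {
      if (op[k] %in% c("M", "=", "X")) {
        rp <- c(rp, refpos:(refpos + len[k] - 1L))
        qp <- c(qp, qpos:(qpos + len[k] - 1L))
        refpos <- refpos + len[k]; qpos <- qpos + len[k]
      } else if (op[k] %in% c("I", "S")) {
        qpos <- qpos + len[k]
      } else if (op[k] %in% c("D", "N")) {
        refpos <- refpos + len[k]
      } # H, P: consume nothing
    }
    ok <- qual[qp] >= cfg$min_base_quality & seqc[qp] %in% BASES
    excl["low_basequal"] <- excl["low_basequal"] + sum(!ok)
    if (any(ok)) {
      acc_ref[[i]] <- rep(f[3], sum(ok))
      acc_pos[[i]] <- rp[ok]
      acc_base[[i]] <- seqc[qp][ok]
    }
  }
  long <- data.table(unigene = unlist(acc_ref), pos = unlist(acc_pos),
                     base = unlist(acc_base))
  if (nrow(long) == 0) {
    out <- data.table(unigene = character(), pos = integer(), A = integer(),
                      C = integer(), G = integer(), T = integer())
  } else {
    long[, base := factor(base, levels = BASES)]
    out <- dcast(long[, .N, by = .(unigene, pos, base)],
                 unigene + pos ~ base, value.var = "N", fill = 0L,
                 drop = c(TRUE, FALSE))
    for (b in BASES) if (!b %in% names(out)) out[, (b) := 0L]
    setcolorder(out, c("unigene", "pos", BASES))
    setorder(out, unigene, pos)
  }
  setattr(out, "excluded", excl)
  out[]
}

## ---- population metadata --------------------------------------------------

#' Load a population metadata table
#'
#' Reads a CSV with columns `name`, `state`, `year`, `source`, `diapause`,
#' `cry3bb1_response`, `pool_chromosomes` and optionally `pi`, `lat`, `lon`.
#' The packaged default transcribes the 26 western corn rootworm populations
#' of the study design this package models (20 field collections from
#' 2011/2012 plus 6 laboratory colonies, each a pool of 5 diploids, i.e. 10
#' haploid chromosome sets).
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A data.table, one row per pooled population sample.
#' @export
load_population_table <- function(path = system.file("extdata",
                                                     "wcr_populations.csv",
                                                     package = "poolscan")) {
  dt <- fread(path, na.strings = c("NA", ""))
  need <- c("name", "source", "diapause", "cry3bb1_response", "pool_chromosomes")
  if (!all(need %in% names(dt)))
    stop("population table needs columns: ", paste(need, collapse = ", "))
  ok <- dt$cry3bb1_response %in% c("high", "medium", "low") |
    is.na(dt$cry3bb1_response)
  if (!all(ok)) stop("cry3bb1_response must be high/medium/low or NA")
  if (any(dt$pool_chromosomes < 2)) stop("pool_chromosomes must be >= 2")
  dt[, diapause := as.logical(diapause)]
  dt[]
}
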