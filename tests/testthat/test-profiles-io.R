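test_that("pileup counts aligned bases and applies read-level filters", {
  lines <- c(sam_header(), sam_read())
  p <- reads_to_profiles(lines)
  expect_equal(nrow(p), 10L)
  expect_equal(p$A, rep(1L, 10))
  expect_equal(p$pos, 1:10)
  expect_equal(rowSums(p[, c("C", "G", "T")]), rep(0, 10))

  # soft-clipped reads contribute nothing under the default filter
  sc <- c(sam_header(), sam_read(cigar = "5S5M", seq = strrep("A", 10)))
  expect_equal(nrow(reads_to_profiles(sc)), 0L)
  keep <- reads_to_profiles(sc, filter_config(drop_softclipped = FALSE))
  expect_equal(nrow(keep), 5L)

  # MAPQ boundary: < 25 removed, 25 kept
  expect_equal(nrow(reads_to_profiles(c(sam_header(), sam_read(mapq = 24)))), 0L)
  expect_equal(nrow(reads_to_profiles(c(sam_header(), sam_read(mapq = 25)))), 10L)

  # base-quality filter: only Q >= 30 bases are counted ('?' is Q30, '>' Q29)
  bq <- c(sam_header(),
          sam_read(seq = "AAAAA", qual = "I?>I>", cigar = "5M"))
  p <- reads_to_profiles(bq)
  expect_equal(p$pos, c(1, 2, 4))
  expect_equal(sum(p$A), 3L)
})

test_that("pileup walks CIGAR operations correctly", {
  # 3M2D3M: query bases land at ref 1-3 and 6-8; 2I consumes query only
  r <- sam_read(cigar = "3M2D3M", seq = "AAACCC", qual = "IIIIII")
  p <- reads_to_profiles(c(sam_header(), r))
  expect_equal(p$pos, c(1:3, 6:8))
  expect_equal(p$A, c(1, 1, 1, 0, 0, 0))
  expect_equal(p$C, c(0, 0, 0, 1, 1, 1))
  r2 <- sam_read(cigar = "2M2I2M", seq = "AATTGG", qual = "IIIIII")
  p2 <- reads_to_profiles(c(sam_header(), r2))
  expect_equal(p2$pos, 1:4)
  expect_equal(p2$G, c(0, 0, 1, 1))
  # hard clips do not trigger the soft-clip rule
  r3 <- sam_read(cigar = "2H4M", seq = "AAAA", qual = "IIII")
  expect_equal(nrow(reads_to_profiles(c(sam_header(), r3))), 4L)
})

test_that("pileup rejects malformed records and unknown references", {
  expect_error(reads_to_profiles(c(sam_header(), sam_read(rname = "ugX"))),
               "unknown reference")
  expect_error(reads_to_profiles(c(sam_header(), sam_read(cigar = "10Q"))),
               "malformed CIGAR")
  expect_error(reads_to_profiles(c(sam_header(), sam_read(cigar = "*"))),
               "malformed CIGAR")
})

test_that("counted bases never exceed aligned bases", {
  set.seed(42)
  reads <- lapply(1:20, function(i) {
    len <- sample(5:15, 1)
    sam_read(qname = paste0("r", i), pos = sample(1:50, 1),
             mapq = sample(c(10, 30, 60), 1),
             cigar = sprintf("%dM", len),
             seq = paste(sample(c("A", "C", "G", "T"), len, TRUE),
                         collapse = ""),
             qual = paste(sample(strsplit("I?>5", "")[[1]], len, TRUE),
                          collapse = ""))
  })
  p <- reads_to_profiles(c(sam_header(), unlist(reads)))
  total_aligned <- sum(vapply(reads, function(r)
    nchar(strsplit(r, "\t")[[1]][10]), numeric(1)))
  expect_lte(sum(p[, c("A", "C", "G", "T")]), total_aligned)
})

test_that("pileup agrees with Rsamtools on a soft-clip-free fixture", {
  skip_if_not_installed("Rsamtools")
  set.seed(7)
  reads <- lapply(1:30, function(i) {
    len <- sample(6:12, 1)
    sam_read(qname = paste0("r", i), pos = sample(1:30, 1),
             mapq = sample(c(20, 40), 1),
             cigar = sprintf("%dM", len),
             seq = paste(sample(c("A", "C", "G", "T"), len, TRUE),
                         collapse = ""),
             qual = paste(sample(c("I", "5"), len, TRUE), collapse = ""))
  })
  lines <- c(sam_header(c(ug1 = 60L)), unlist(reads))
  samf <- tempfile(fileext = ".sam")
  writeLines(lines, samf)
  bam <- Rsamtools::asBam(samf, tempfile(), overwrite = TRUE)
  pp <- Rsamtools::PileupParam(max_depth = 1000, min_base_quality = 30,
                               min_mapq = 25, distinguish_strands = FALSE,
                               min_nucleotide_depth = 1)
  ref <- as.data.table(Rsamtools::pileup(bam, pileupParam = pp))
  ref[, nucleotide := as.character(nucleotide)]
  mine <- reads_to_profiles(lines)
  long <- melt(mine, id.vars = c("unigene", "pos"), variable.name = "nucleotide",
               value.name = "count", variable.factor = FALSE)[count > 0]
  merged <- merge(long, ref[, .(pos, nucleotide, ref_count = count)],
                  by.x = c("pos", "nucleotide"), by.y = c("pos", "nucleotide"),
                  all = TRUE)
  expect_true(all(!is.na(merged$count)) && all(!is.na(merged$ref_count)))
  expect_equal(merged$count, merged$ref_count)
})

test_that("site filters apply coverage bounds and minimum-count zeroing", {
  prof <- make_profiles(list(c(3, 1, 0, 0),    # coverage 4: dropped
                             c(41, 0, 0, 0),   # coverage 41: dropped
                             c(40, 0, 0, 0),   # exactly 40: kept
                             c(9, 1, 0, 0),    # minor zeroed -> monomorphic
                             c(6, 4, 0, 0)))   # untouched
  f <- filter_sites(prof)
  expect_equal(f$pos, c(3, 4, 5))
  expect_equal(f[pos == 4, c(A, C, G, T)], c(9L, 0L, 0L, 0L))
  expect_equal(f[pos == 5, c(A, C, G, T)], c(6L, 4L, 0L, 0L))
})

test_that("site filtering is idempotent", {
  set.seed(1)
  for (rep in 1:5) {
    cnt <- matrix(rpois(400, sample(c(1, 3, 8), 1)), ncol = 4)
    prof <- make_profiles(asplit(cnt, 1))
    once <- filter_sites(prof)
    twice <- filter_sites(once)
    expect_equal(as.data.frame(twice), as.data.frame(once))
  }
})

test_that("sync files round-trip simulated profiles", {
  sim <- simulate_metapopulation(sim_config(n_pops = 3, n_unigenes = 4,
                                            sites_per_unigene = 25,
                                            seg_fraction = 0.4, seed = 5))
  f <- tempfile(fileext = ".sync")
  write_sync(sim$profiles, f)
  back <- read_sync(f)
  expect_equal(as.data.frame(back), as.data.frame(sim$profiles))
})

test_that("sync parsing follows the column definition", {
  f <- tempfile()
  writeLines("u1\t5\tN\t3:0:7:0:0:0", f)
  p <- read_sync(f)
  expect_equal(p$unigene, "u1")
  expect_equal(p$pos, 5L)
  expect_equal(unlist(p[, c("A", "C", "G", "T")], use.names = FALSE),
               c(3L, 0L, 7L, 0L))
  # zero-count cells yield no profile row
  writeLines(c("u1\t5\tN\t3:0:7:0:0:0\t0:0:0:0:0:0"), f)
  expect_equal(nrow(read_sync(f)), 1L)
  # ragged lines are named by line number
  writeLines(c("u1\t5\tN"), f)
  expect_error(read_sync(f), "line 1")
})

test_that("SNP tables handle dashes, sequence inheritance and duplicates", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("unigene,position,sequence,p1,p2,p3",
               "u1,5,ACGTACGT,A,A,-",
               "u1,9,,C,-,C",
               "u2,2,TTTT,G,G,G"), f)
  tab <- read_snp_table(f)
  expect_equal(unname(tab$sequences["u1"]), "ACGTACGT")
  expect_equal(unname(tab$sequences["u2"]), "TTTT")
  rec <- tab$records
  expect_true(is.na(rec[unigene == "u1" & pos == 5 & pop == "p3", state]))
  expect_equal(rec[unigene == "u1" & pos == 9 & pop == "p1", state], "C")
  writeLines(c("unigene,position,sequence,p1",
               "u1,5,ACGT,A", "u1,5,,C"), f)
  expect_error(read_snp_table(f), "duplicate")
  writeLines(character(0), f)
  expect_warning(read_snp_table(f), "empty")
})
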