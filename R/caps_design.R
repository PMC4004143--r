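# In-silico CAPS (cleaved amplified polymorphic sequence) marker design:
# find SNPs whose two haplotypes differ in restriction-enzyme recognition
# site content, so the SNP is scorable as a digest-fragment polymorphism.

#' Built-in restriction enzyme table
#'
#' A small vetted set of commercially common enzymes; user tables with the
#' same columns (`name`, `recognition` IUPAC pattern, `cut_offset`) are
#' accepted everywhere an enzyme table is.
#'
#' @return data.table with columns `name`, `recognition`, `cut_offset`.
#' @export
caps_enzymes <- function() {
  data.table(name = c("RsaI", "EcoRI", "AluI", "HinfI", "TaqI"),
             recognition = c("GTAC", "GAATTC", "AGCT", "GANTC", "TCGA"),
             cut_offset = c(2L, 1L, 2L, 1L, 1L))
}

check_iupac <- function(pattern) {
  if (!nzchar(pattern)) stop("empty recognition pattern")
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CODE_MAP))
  if (length(bad))
    stop("non-IUPAC character(s) in pattern: ", paste(bad, collapse = ", "))
  toupper(pattern)
}

# Match positions of an IUPAC pattern on the forward strand of seq,
# excluding any match whose window contains N (N never matches).
match_positions <- function(pattern, seq) {
  L <- nchar(pattern)
  if (nchar(seq) < L) return(integer(0))
  hits <- matchPattern(DNAString(pattern), DNAString(seq), fixed = "subject")
  st <- BiocGenerics::start(hits)
  if (!length(st)) return(integer(0))
  npos <- which(strsplit(seq, "")[[1]] == "N")
  if (length(npos))
    st <- st[!vapply(st, function(s) any(npos >= s & npos <= s + L - 1L),
                     logical(1))]
  st
}

#' Count restriction recognition sites in a sequence
#'
#' Matches the enzyme's IUPAC pattern on both strands (reverse-strand match
#' positions are mapped to forward coordinates); palindromic patterns are
#' counted once per position. `N` in the sequence never matches.
#'
#' @param sequence Character string over A/C/G/T/N.
#' @param enzyme One row of an enzyme table (list or data.frame with
#'   `recognition`), or a pattern string.
#' @return Integer count of recognition positions.
#' @export
count_sites <- function(sequence, enzyme) {
  pattern <- check_iupac(if (is.character(enzyme)) enzyme
                         else as.character(enzyme$recognition))
  seq <- toupper(sequence)
  if (!nzchar(seq)) return(0L)
  if (!all(strsplit(seq, "")[[1]] %in% c(BASES, "N")))
    stop("sequence must be over A/C/G/T/N")
  fwd <- match_positions(pattern, seq)
  rcpat <- as.character(reverseComplement(DNAString(pattern)))
  if (rcpat == pattern) return(length(fwd))      # palindromic: once per site
  rev <- match_positions(rcpat, seq)
  length(fwd) + length(rev)
}

#' Screen SNP haplotype pairs for CAPS candidates
#'
#' Each pair is the reference and alternate flanking sequence of one SNP,
#' identical except at the SNP position. A candidate is emitted for every
#' (SNP, enzyme) whose two haplotypes differ in recognition-site count.
#'
#' @param pairs data.frame with columns `unigene`, `position`, `ref_hap`,
#'   `alt_hap`.
#' @param enzymes Enzyme table (default [caps_enzymes()]).
#' @return data.table of candidates: `unigene`, `position`, `enzyme`,
#'   `ref_sites`, `alt_sites`.
#' @export
screen_snps <- function(pairs, enzymes = caps_enzymes()) {
  pr <- as.data.table(pairs)
  stopifnot(all(c("unigene", "position", "ref_hap", "alt_hap") %in% names(pr)))
  for (i in seq_len(nrow(pr))) {
    a <- strsplit(toupper(pr$ref_hap[i]), "")[[1]]
    b <- strsplit(toupper(pr$alt_hap[i]), "")[[1]]
    if (length(a) != length(b) || sum(a != b) != 1L)
      stop("haplotypes must differ at exactly one position (SNP ",
           pr$unigene[i], ":", pr$position[i], ")")
  }
  en <- as.data.table(enzymes)
  out <- list()
  for (i in seq_len(nrow(pr))) {
    for (j in seq_len(nrow(en))) {
      rs <- count_sites(pr$ref_hap[i], en[j])
      as_ <- count_sites(pr$alt_hap[i], en[j])
      if (rs != as_)
        out[[length(out) + 1L]] <- data.table(
          unigene = pr$unigene[i], position = pr$position[i],
          enzyme = en$name[j], ref_sites = rs, alt_sites = as_)
    }
  }
  if (!length(out))
    return(data.table(unigene = character(), position = integer(),
                      enzyme = character(), ref_sites = integer(),
                      alt_sites = integer()))
  rbindlist(out)
}

#' Build SNP flanking-haplotype pairs from unigene sequences
#'
#' @param snps data.frame with `unigene`, `position` (1-based), `ref`,
#'   `alt` single bases.
#' @param sequences Named character vector of unigene sequences.
#' @param flank Flank window half-width around the SNP (default 100 bp,
#'   clipped at sequence ends).
#' @return data.table with `unigene`, `position`, `ref_hap`, `alt_hap`.
#' @export
snp_haplotypes <- function(snps, sequences, flank = 100L) {
  sn <- as.data.table(snps)
  stopifnot(all(c("unigene", "position", "ref", "alt") %in% names(sn)))
  out <- vector("list", nrow(sn))
  for (i in seq_len(nrow(sn))) {
    s <- sequences[[sn$unigene[i]]]
    if (is.null(s) || is.na(s)) stop("no sequence for ", sn$unigene[i])
    p <- sn$position[i]
    if (p < 1 || p > nchar(s)) stop("SNP position outside sequence")
    if (toupper(substr(s, p, p)) != toupper(sn$ref[i]))
      stop("reference base mismatch at ", sn$unigene[i], ":", p)
    a <- max(1L, p - flank)
    b <- min(nchar(s), p + flank)
    ref_hap <- toupper(substr(s, a, b))
    alt_hap <- ref_hap
    substr(alt_hap, p - a + 1L, p - a + 1L) <- toupper(sn$alt[i])
    out[[i]] <- data.table(unigene = sn$unigene[i], position = p,
                           ref_hap = ref_hap, alt_hap = alt_hap)
  }
  rbindlist(out)
}
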