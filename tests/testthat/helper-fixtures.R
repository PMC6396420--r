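# Shared fixture builders and independent oracles.

# Quick evidence-store builder with sensible defaults.
make_store <- function(site_id, allele, tlen = 150L, properly_paired = TRUE,
                       base_quality = 35L, map_quality = 60L,
                       fragment_id = NULL) {
  n <- max(length(site_id), length(allele))
  if (is.null(fragment_id)) fragment_id <- sprintf("fx%06d", seq_len(n))
  rl <- function(x) if (n == 0L) x[0L] else rep_len(x, n)
  evidence_store(tibble::tibble(
    site_id = rl(site_id),
    allele = rl(allele),
    tlen = rl(as.integer(tlen)),
    properly_paired = rl(properly_paired),
    base_quality = rl(as.integer(base_quality)),
    map_quality = rl(as.integer(map_quality)),
    fragment_id = fragment_id
  ))
}

# One-row site table helper.
make_site <- function(g_mother, g_father, ref = "A", alt = "G",
                      chrom = "chr1", pos = 100L) {
  variant_sites(chrom, pos, ref, alt, g_mother, g_father)
}

# Independent probability-space oracle for the site posterior: direct
# enumeration of prior x product-likelihood over the three genotypes, no
# logs, no shared code with the implementation.
brute_posteriors <- function(prior, g_mother, alleles, f, epsilon) {
  geno <- c("0/0", "0/1", "1/1")
  emit <- function(allele, g) {
    if (g == "0/1") return(0.5)
    match_alt <- g == "1/1"
    is_alt <- allele == "ALT"
    if (is_alt == match_alt) 1 - epsilon else epsilon
  }
  lik <- vapply(geno, function(g) {
    prod(vapply(seq_along(alleles), function(j) {
      emit(alleles[j], g) * f[j] + emit(alleles[j], g_mother) * (1 - f[j])
    }, numeric(1)))
  }, numeric(1))
  w <- prior * lik
  w / sum(w)
}

# Write a small SAM, convert to sorted+indexed BAM, return the BAM path.
make_bam <- function(reads, contig = "chr1", contig_len = 10000L) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len))
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    paste(r$qname, r$flag, contig, r$pos, r$mapq, r$cigar, "=",
          r$pnext, r$tlen, r$seq, r$qual, sep = "\t")
  }, character(1))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, lines), sam)
  Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                   indexDestination = TRUE)
}

# A proper read-pair row pair supporting one base at `pos` for SNPs. The
# forward mate carries the site; both mates agree unless seq2 differs.
pair_rows <- function(qname, pos, seq, qual = NULL, tlen = 172L,
                      mapq = 60L, flag = 99L) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  data.frame(qname = qname, flag = flag, pos = pos, mapq = mapq,
             cigar = paste0(nchar(seq), "M"), pnext = pos + tlen - nchar(seq),
             tlen = tlen, seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

# Small simulated family used by several tests.
small_family <- function(seed = 11L, true_ff = 0.15, depth = 80,
                         n = c(maternal_only_het = 300L,
                               paternal_only_het = 300L,
                               double_het = 300L,
                               fetal_informative = 600L)) {
  simulate_trio(sim_config(n_sites = n, true_ff = true_ff,
                           depth_mean = depth, seed = seed))
}
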