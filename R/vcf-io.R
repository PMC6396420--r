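#' Write a single-sample genotype VCF
#'
#' Minimal VCF 4.2 writer used for parental genotypes and simulated fetal
#' truth, so that synthetic families round-trip through the same loaders as
#' real ones.
#'
#' @param sites Site tibble.
#' @param genotypes Character vector of genotypes aligned with `sites`.
#' @param path Output path (`.vcf`; plain text).
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(sites, genotypes, path, sample_name = "SAMPLE") {
  stopifnot(nrow(sites) == length(genotypes))
  check_genotype(genotypes)
  contigs <- unique(sites$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nipgeno",
    paste0("##contig=<ID=", contigs, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT", genotypes, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write fetal genotype calls as VCF 4.2
#'
#' One record per posterior result, sample `FETUS`, with FORMAT fields:
#' `GT` (called genotype), `PP` (the three genotype posteriors, rounded to 6
#' decimals), `CT` (site inheritance category), `DP` (cfDNA observation
#' depth) and `FM` (fetal-fraction mode used). Sites with zero observations
#' are emitted with the prior's argmax and a `NOOBS` flag in INFO.
#'
#' @param results Posterior tibble from [genotype_all()].
#' @param sites Site tibble covering every result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fetal_vcf <- function(results, sites, path) {
  df <- inner_join(as_tibble(results),
                   select(sites, "site_id", "chrom", "pos", "ref", "alt"),
                   by = "site_id")
  if (nrow(df) != nrow(results)) {
    stop("every result must match exactly one site", call. = FALSE)
  }
  df <- arrange(df, .data$chrom, .data$pos)
  contigs <- unique(df$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nipgeno",
    paste0("##contig=<ID=", contigs, ">"),
    '##INFO=<ID=NOOBS,Number=0,Type=Flag,Description="No cfDNA observations; posterior equals the Mendelian prior">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Called fetal genotype (maximum posterior)">',
    '##FORMAT=<ID=PP,Number=3,Type=Float,Description="Posterior probabilities of genotypes 0/0, 0/1, 1/1">',
    '##FORMAT=<ID=CT,Number=1,Type=String,Description="Site inheritance category from the parental genotypes">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Number of cfDNA fragment observations used">',
    '##FORMAT=<ID=FM,Number=1,Type=String,Description="Fetal fraction mode: LENGTH_DEPENDENT or FIXED">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "FETUS", sep = "\t")
  )
  pp <- sprintf("%.6f,%.6f,%.6f", df$q00, df$q01, df$q11)
  info <- if_else(df$n_obs == 0L, "NOOBS", ".")
  sample_field <- paste(df$called, pp, df$category, df$n_obs, df$ff_mode,
                        sep = ":")
  body <- paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS", info,
                "GT:PP:CT:DP:FM", sample_field, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a fetal VCF written by [write_fetal_vcf()]
#'
#' @param path Path to the VCF.
#' @return A tibble with the site fields and the posterior columns recovered
#'   to their printed precision.
#' @export
read_fetal_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- normalize_gt(vcfR::extract.gt(v, element = "GT")[, 1L])
  pp <- vcfR::extract.gt(v, element = "PP")[, 1L]
  ppm <- do.call(rbind, lapply(strsplit(pp, ","), as.numeric))
  tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    site_id = paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
    called = unname(gt),
    q00 = unname(ppm[, 1L]), q01 = unname(ppm[, 2L]),
    q11 = unname(ppm[, 3L]),
    category = unname(vcfR::extract.gt(v, element = "CT")[, 1L]),
    n_obs = as.integer(vcfR::extract.gt(v, element = "DP")[, 1L]),
    ff_mode = unname(vcfR::extract.gt(v, element = "FM")[, 1L]),
    no_obs = grepl("NOOBS", fix$INFO)
  )
}
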