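#' Classify a biallelic site by the parental genotype pair
#'
#' The inheritance category of a site is a pure function of the two parental
#' genotypes. Sites where exactly one parent is heterozygous reduce the fetal
#' call to het vs. hom; double-heterozygous sites admit all three fetal
#' genotypes; sites where the parents are homozygous for different alleles are
#' fetal-informative (every fragment carrying the paternal-specific allele is
#' fetal-derived); sites where both parents share the same homozygous genotype
#' carry no information about transmission.
#'
#' @param g_mother,g_father Character vectors of genotypes, each element one of
#'   `"0/0"`, `"0/1"`, `"1/1"`. Recycled to a common length.
#' @return Character vector of categories: `"MATERNAL_ONLY_HET"`,
#'   `"PATERNAL_ONLY_HET"`, `"DOUBLE_HET"`, `"FETAL_INFORMATIVE"` or
#'   `"UNINFORMATIVE"`.
#' @examples
#' classify_site("0/1", "0/0")  # MATERNAL_ONLY_HET
#' classify_site("0/0", "1/1")  # FETAL_INFORMATIVE
#' @export
classify_site <- function(g_mother, g_father) {
  check_genotype(g_mother)
  check_genotype(g_father)
  n <- max(length(g_mother), length(g_father))
  g_mother <- rep_len(g_mother, n)
  g_father <- rep_len(g_father, n)
  m_het <- g_mother == "0/1"
  f_het <- g_father == "0/1"
  out <- character(n)
  out[m_het & !f_het] <- "MATERNAL_ONLY_HET"
  out[!m_het & f_het] <- "PATERNAL_ONLY_HET"
  out[m_het & f_het] <- "DOUBLE_HET"
  hom_diff <- !m_het & !f_het & g_mother != g_father
  out[hom_diff] <- "FETAL_INFORMATIVE"
  out[!m_het & !f_het & g_mother == g_father] <- "UNINFORMATIVE"
  out
}

check_genotype <- function(g) {
  bad <- !g %in% GENOTYPES
  if (any(bad)) {
    stop("invalid genotype(s): ", paste(unique(g[bad]), collapse = ", "),
         "; expected one of ", paste(GENOTYPES, collapse = ", "), call. = FALSE)
  }
  invisible(g)
}

#' Mendelian prior over the fetal genotype
#'
#' Transmission probabilities of one allele drawn from each parent. Genotypes
#' impossible under Mendelian transmission receive prior 0; de novo mutation is
#' not modelled, so data can never resurrect a zero-prior genotype downstream.
#'
#' @inheritParams classify_site
#' @return A tibble with one row per input pair and columns `p00`, `p01`,
#'   `p11` summing to 1.
#' @examples
#' mendelian_prior("0/1", "0/1")  # 0.25 / 0.50 / 0.25
#' @export
mendelian_prior <- function(g_mother, g_father) {
  check_genotype(g_mother)
  check_genotype(g_father)
  n <- max(length(g_mother), length(g_father))
  g_mother <- rep_len(g_mother, n)
  g_father <- rep_len(g_father, n)
  # probability each parent transmits the ALT allele
  p_alt <- c("0/0" = 0, "0/1" = 0.5, "1/1" = 1)
  pm <- unname(p_alt[g_mother])
  pf <- unname(p_alt[g_father])
  tibble(
    p00 = (1 - pm) * (1 - pf),
    p01 = pm * (1 - pf) + (1 - pm) * pf,
    p11 = pm * pf
  )
}

#' Build a site table from parental genotype vectors
#'
#' Constructs the canonical site tibble used across the package, validating
#' alleles and deriving `var_type`, `category` and `site_id`.
#'
#' @param chrom,pos,ref,alt Vectors describing each biallelic variant
#'   (1-based VCF position; alleles over `A`,`C`,`G`,`T`).
#' @param g_mother,g_father Parental genotypes (`"0/0"`, `"0/1"`, `"1/1"`).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `var_type`,
#'   `g_mother`, `g_father`, `category`, `site_id`, sorted by (chrom, pos).
#' @export
variant_sites <- function(chrom, pos, ref, alt, g_mother, g_father) {
  ok_allele <- function(a) grepl("^[ACGT]+$", a)
  if (!all(ok_allele(ref)) || !all(ok_allele(alt))) {
    stop("alleles must be non-empty strings over A,C,G,T", call. = FALSE)
  }
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  check_genotype(g_mother)
  check_genotype(g_father)
  tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    var_type = if_else(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL"),
    g_mother = g_mother, g_father = g_father,
    category = classify_site(g_mother, g_father),
    site_id = paste(chrom, pos, ref, alt, sep = ":")
  ) |>
    arrange(.data$chrom, .data$pos)
}

#' Load parental variant calls from two single-sample VCFs
#'
#' Takes the union of sites seen in either parent. A parent without a record at
#' a site is assigned `0/0` only when that parent's VCF explicitly carries the
#' site as homozygous-reference; otherwise the site is dropped. Multi-allelic
#' records, records with non-ACGT alleles, REF-mismatched duplicates and
#' records with missing genotypes are dropped and counted.
#'
#' @param maternal_vcf,paternal_vcf Paths to VCF files (plain or gzipped),
#'   each with a GT field for exactly one sample.
#' @return A site tibble as from [variant_sites()], with an attribute
#'   `"dropped"` giving named drop counters.
#' @export
load_parental_variants <- function(maternal_vcf, paternal_vcf) {
  m <- read_parent_vcf(maternal_vcf)
  f <- read_parent_vcf(paternal_vcf)
  dropped <- m$dropped + f$dropped

  key <- c("chrom", "pos", "ref", "alt")
  joined <- dplyr::full_join(
    rename(m$tab, g_mother = "gt"),
    rename(f$tab, g_father = "gt"),
    by = key
  )

  # REF inconsistency: same (chrom, pos) present with different REF alleles in
  # the two parents. Such positions are unusable and dropped entirely.
  ref_conflict <- joined |>
    distinct(.data$chrom, .data$pos, .data$ref) |>
    count(.data$chrom, .data$pos) |>
    filter(.data$n > 1L)
  n_conflict <- nrow(ref_conflict)
  if (n_conflict > 0L) {
    joined <- anti_join(joined, ref_conflict, by = c("chrom", "pos"))
  }

  # A parent absent at a site gets 0/0 only if its VCF covers the position as
  # hom-ref (possibly under another record); here absence means no record at
  # all, so the site is dropped unless an explicit 0/0 record exists.
  n_uncovered <- sum(is.na(joined$g_mother) | is.na(joined$g_father))
  joined <- filter(joined, !is.na(.data$g_mother), !is.na(.data$g_father))

  dropped <- c(dropped,
               ref_mismatch = n_conflict,
               uncovered_in_one_parent = n_uncovered)

  out <- variant_sites(joined$chrom, joined$pos, joined$ref, joined$alt,
                       joined$g_mother, joined$g_father)
  attr(out, "dropped") <- dropped
  out
}

# Read one single-sample VCF into (chrom, pos, ref, alt, gt), counting dropped
# records. Hom-ref records are kept so the other parent's union logic can see
# explicit 0/0 coverage.
read_parent_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(list(tab = tibble(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             gt = character()),
                dropped = c(multiallelic = 0L, bad_allele = 0L, missing_gt = 0L)))
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw) || ncol(gt_raw) < 1L) {
    stop("VCF has no GT field: ", path, call. = FALSE)
  }
  gt <- normalize_gt(gt_raw[, 1L])

  alt <- fix$ALT
  ref <- fix$REF
  multi <- grepl(",", alt)
  ok_allele <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt) & ref != alt
  bad_gt <- is.na(gt)
  keep <- !multi & ok_allele & !bad_gt
  list(
    tab = tibble(
      chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
      ref = ref[keep], alt = alt[keep], gt = gt[keep]
    ) |> distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                  .keep_all = TRUE),
    dropped = c(multiallelic = sum(multi),
                bad_allele = sum(!multi & !ok_allele),
                missing_gt = sum(!multi & ok_allele & bad_gt))
  )
}

normalize_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[gt == "1/0"] <- "0/1"
  gt[!gt %in% GENOTYPES] <- NA_character_
  gt
}
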