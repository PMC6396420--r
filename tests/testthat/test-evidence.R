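test_that("evidence store enforces its field invariants", {
  expect_error(make_store("s1", "BAD"), "REF or ALT")
  expect_error(
    evidence_store(tibble::tibble(site_id = "s", allele = "REF", tlen = 0L,
                                  properly_paired = TRUE, base_quality = 30L,
                                  map_quality = 60L, fragment_id = "f1")),
    "properly_paired"
  )
  st <- make_store(c("s1", "s1"), c("REF", "ALT"))
  expect_s3_class(st, "nipgeno_store")
  expect_identical(nrow(st), 2L)
})

test_that("store serialization round-trips losslessly and deterministically", {
  fam <- small_family(seed = 5L, n = c(maternal_only_het = 30L,
                                       fetal_informative = 70L))
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.tsv.gz")
  p2 <- file.path(dir, "b.tsv.gz")
  write_store(fam$store, p1)
  back <- read_store(p1)
  expect_equal(as.data.frame(back), as.data.frame(fam$store))
  expect_equal(attr(back, "metadata")$true_ff,
               attr(fam$store, "metadata")$true_ff)

  write_store(fam$store, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  # empty store: valid header-only file
  empty <- make_store(character(0), character(0))
  p3 <- file.path(dir, "empty.tsv.gz")
  write_store(empty, p3)
  expect_identical(nrow(read_store(p3)), 0L)
})

test_that("schema-version mismatch is an explicit error naming both versions", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "s.tsv.gz")
  write_store(make_store("s1", "REF"), p)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  meta$schema_version <- "99"
  jsonlite::write_json(meta, paste0(p, ".json"), auto_unbox = TRUE)
  expect_error(read_store(p), "'99'.*'1'|schema version")
})

test_that("SNP observations carry allele, absolute TLEN and pairing", {
  # site chr1:100 A>G; r1 supports REF, r2 supports ALT with negative TLEN
  site <- make_site("0/1", "0/0")
  reads <- rbind(
    pair_rows("r1", 96L, "AAAAAAAAAA", tlen = 172L),   # base A at 100
    pair_rows("r2", 98L, "GGGGGGGGGG", tlen = 150L, flag = 147L)
  )
  reads$tlen[2] <- -150L
  bam <- make_bam(reads)
  st <- extract_observations(bam, site)
  st <- st[order(st$fragment_id), ]
  expect_identical(st$allele, c("REF", "ALT"))
  expect_identical(st$tlen, c(172L, 150L))
  expect_true(all(st$properly_paired))
})

test_that("disagreeing mates, duplicates and low qualities are filtered", {
  site <- make_site("0/1", "0/0")
  reads <- rbind(
    pair_rows("dis", 96L, "AAAAAAAAAA"),                 # REF at 100
    pair_rows("dis", 95L, "GGGGGGGGGG", flag = 147L),    # mate says ALT
    pair_rows("dup", 96L, "AAAAAAAAAA", flag = 1123L),   # duplicate flag
    pair_rows("lowq", 96L, "AAAAAAAAAA",
              qual = paste0(strrep("I", 4), "#", strrep("I", 5))),  # baseq 2
    pair_rows("lowm", 96L, "AAAAAAAAAA", mapq = 5L),
    pair_rows("ok1", 96L, "AAAAAAAAAA"),
    pair_rows("ok2", 97L, "GGGGGGGGGG")
  )
  st <- extract_observations(make_bam(reads), site,
                             min_mapq = 20L, min_baseq = 13L)
  expect_setequal(st$fragment_id, c("ok1", "ok2"))

  # survivor count under the base-quality gate alone: 3 fragments, one low
  reads2 <- rbind(
    pair_rows("a", 96L, "AAAAAAAAAA"),
    pair_rows("b", 96L, "AAAAAAAAAA"),
    pair_rows("c", 96L, "AAAAAAAAAA",
              qual = paste0(strrep("I", 4), "#", strrep("I", 5)))
  )
  st2 <- extract_observations(make_bam(reads2), site)
  expect_identical(nrow(st2), 2L)
})

test_that("observation extraction is invariant under record order", {
  site <- make_site("0/1", "0/0")
  reads <- rbind(
    pair_rows("x1", 96L, "AAAAAAAAAA"),
    pair_rows("x2", 97L, "GGGGGGGGGG"),
    pair_rows("x3", 93L, "AAAAAAAAAA")
  )
  st_a <- extract_observations(make_bam(reads), site)
  st_b <- extract_observations(make_bam(reads[c(3, 1, 2), ]), site)
  ord <- function(x) {
    x <- tibble::as_tibble(x)
    attr(x, "metadata") <- NULL
    x[order(x$fragment_id), ]
  }
  expect_equal(ord(st_a), ord(st_b))
})

test_that("indel alleles require an exact local haplotype match", {
  # deletion site chr1:100 ATT>A
  del_site <- variant_sites("chr1", 100L, "ATT", "A", "0/1", "0/0")
  reads <- rbind(
    pair_rows("ref", 96L, "AAAAATTAAA"),                       # matches ATT
    data.frame(qname = "alt", flag = 99L, pos = 96L, mapq = 60L,
               cigar = "5M2D5M", pnext = 200L, tlen = 160L,
               seq = "AAAAAAAAAA", qual = "IIIIIIIIII",
               stringsAsFactors = FALSE),                       # A with 2D
    pair_rows("nei", 96L, "AAAAGTTAAA")                         # neither
  )
  st <- extract_observations(make_bam(reads), del_site)
  st <- st[order(st$fragment_id), ]
  expect_identical(st$fragment_id, c("alt", "ref"))
  expect_identical(st$allele, c("ALT", "REF"))

  # insertion site chr1:100 A>ATT
  ins_site <- variant_sites("chr1", 100L, "A", "ATT", "0/1", "0/0")
  reads2 <- rbind(
    pair_rows("ref", 96L, "AAAAACCCCC"),                       # plain A
    data.frame(qname = "alt", flag = 99L, pos = 96L, mapq = 60L,
               cigar = "5M2I5M", pnext = 200L, tlen = 160L,
               seq = "AAAAATTCCCCC", qual = "IIIIIIIIIIII",
               stringsAsFactors = FALSE)                        # A + TT ins
  )
  st2 <- extract_observations(make_bam(reads2), ins_site)
  st2 <- st2[order(st2$fragment_id), ]
  expect_identical(st2$allele, c("ALT", "REF"))
})

test_that("unindexed input and out-of-bounds sites are handled", {
  expect_error(extract_observations(tempfile(fileext = ".bam"),
                                    make_site("0/1", "0/0")),
               "not found")
  site_far <- variant_sites("chr1", 99999L, "A", "G", "0/1", "0/0")
  bam <- make_bam(pair_rows("r", 96L, "AAAAAAAAAA"))
  expect_warning(st <- extract_observations(bam, site_far), "contig bounds")
  expect_identical(nrow(st), 0L)
})
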