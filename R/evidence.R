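#' Construct an evidence store
#'
#' The evidence store is the caller's sole read-level input: one row per
#' (fragment, site) observation, carrying the supported allele, the absolute
#' template length, pairing status and qualities. A `tlen` of 0 marks an
#' unavailable template length and forces `properly_paired = FALSE`.
#'
#' @param observations A data frame with columns `site_id`, `allele`
#'   (`"REF"`/`"ALT"`), `tlen` (non-negative integer), `properly_paired`
#'   (logical), `base_quality`, `map_quality` (numeric phred scores),
#'   `fragment_id` (character, unique per physical fragment).
#' @param metadata Named list of provenance values stored alongside the table
#'   and serialized with it.
#' @return A tibble of class `nipgeno_store` with a `metadata` attribute.
#' @export
evidence_store <- function(observations, metadata = list()) {
  cols <- c("site_id", "allele", "tlen", "properly_paired",
            "base_quality", "map_quality", "fragment_id")
  missing <- setdiff(cols, names(observations))
  if (length(missing) > 0L) {
    stop("observations lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  obs <- as_tibble(observations)[cols]
  obs$site_id <- as.character(obs$site_id)
  obs$allele <- as.character(obs$allele)
  obs$tlen <- as.integer(obs$tlen)
  obs$properly_paired <- as.logical(obs$properly_paired)
  obs$base_quality <- as.integer(obs$base_quality)
  obs$map_quality <- as.integer(obs$map_quality)
  obs$fragment_id <- as.character(obs$fragment_id)
  if (any(!obs$allele %in% c("REF", "ALT"))) {
    stop("allele must be REF or ALT", call. = FALSE)
  }
  if (any(obs$tlen < 0L)) stop("tlen must be >= 0", call. = FALSE)
  bad_tlen0 <- obs$tlen == 0L & obs$properly_paired
  if (any(bad_tlen0)) {
    stop("tlen = 0 requires properly_paired = FALSE", call. = FALSE)
  }
  structure(obs, class = c("nipgeno_store", class(obs)),
            metadata = c(list(schema_version = STORE_SCHEMA_VERSION),
                         metadata[setdiff(names(metadata), "schema_version")]))
}

#' @export
print.nipgeno_store <- function(x, ...) {
  cat(sprintf("<nipgeno evidence store: %d observations at %d sites>\n",
              nrow(x), dplyr::n_distinct(x$site_id)))
  NextMethod()
}

store_metadata <- function(store) attr(store, "metadata") %||% list()

#' Write / read an evidence store
#'
#' The on-disk dialect is a gzip-compressed tab-delimited table with a fixed
#' column order plus a JSON sidecar (`<path>.json`) holding the schema version
#' and provenance metadata. The round trip is lossless and byte-deterministic
#' for identical inputs.
#'
#' @param store An evidence store from [evidence_store()].
#' @param path Output path, conventionally ending in `.tsv.gz`.
#' @return `write_store()` returns `path` invisibly; `read_store()` returns
#'   the reconstructed store.
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "nipgeno_store"))
  meta <- store_metadata(store)
  readr::write_tsv(as_tibble(store), path)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  meta_path <- sidecar_path(path)
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(schema_version = STORE_SCHEMA_VERSION)
  }
  ver <- as.character(meta$schema_version %||% "<missing>")
  if (!identical(ver, STORE_SCHEMA_VERSION)) {
    stop(sprintf("evidence store schema version mismatch: file has '%s', ",
                 ver),
         sprintf("this package reads '%s'", STORE_SCHEMA_VERSION),
         call. = FALSE)
  }
  obs <- readr::read_tsv(
    path,
    col_types = readr::cols(
      site_id = readr::col_character(),
      allele = readr::col_character(),
      tlen = readr::col_integer(),
      properly_paired = readr::col_logical(),
      base_quality = readr::col_integer(),
      map_quality = readr::col_integer(),
      fragment_id = readr::col_character()
    ),
    progress = FALSE
  )
  evidence_store(obs, metadata = meta[setdiff(names(meta), "schema_version")])
}

sidecar_path <- function(path) paste0(path, ".json")

#' Extract per-fragment allele observations from an indexed alignment file
#'
#' For every site, each fragment overlapping the position contributes at most
#' one observation, and only when its read(s) unambiguously support REF or
#' ALT. If both mates cover the site and disagree, the fragment is discarded.
#' SNP support is the base identity at the site; indel support requires the
#' CIGAR-expanded local read sequence over the REF-allele interval (inserted
#' bases included) to match exactly one of the two allele sequences.
#' Duplicate-flagged, secondary and supplementary alignments are skipped, as
#' are reads below the quality gates.
#'
#' @param bam Path to an indexed BAM file.
#' @param sites Site tibble from [variant_sites()] or
#'   [load_parental_variants()].
#' @param min_mapq,min_baseq Phred quality gates; lenient defaults consistent
#'   with filtering before, not instead of, the Bayesian model.
#' @return An evidence store; provenance metadata records the source file and
#'   quality gates.
#' @export
extract_observations <- function(bam, sites, min_mapq = 20L, min_baseq = 13L) {
  if (!file.exists(bam)) stop("alignment file not found: ", bam, call. = FALSE)
  bai <- paste0(bam, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("alignment file is not indexed: ", bam, call. = FALSE)
  }
  sites <- arrange(sites, .data$chrom, .data$pos)

  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  out <- vector("list", nrow(sites))
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  what <- c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual", "isize")

  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    if (!s$chrom %in% names(hdr) || s$pos > hdr[[s$chrom]]) {
      warning("site beyond contig bounds, skipped: ", s$site_id, call. = FALSE)
      next
    }
    w_end <- s$pos + nchar(s$ref)  # one past the REF interval, see indel rule
    gr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, w_end))
    param <- Rsamtools::ScanBamParam(flag = flags, what = what, which = gr)
    reads <- Rsamtools::scanBam(bam, param = param)[[1L]]
    if (length(reads$qname) == 0L) next
    out[[i]] <- site_observations(reads, s, min_mapq, min_baseq)
  }
  obs <- bind_rows(out)
  if (nrow(obs) == 0L) {
    obs <- tibble(site_id = character(), allele = character(),
                  tlen = integer(), properly_paired = logical(),
                  base_quality = integer(), map_quality = integer(),
                  fragment_id = character())
  }
  evidence_store(obs, metadata = list(
    source_alignments = basename(bam),
    min_mapq = min_mapq, min_baseq = min_baseq,
    n_sites_queried = nrow(sites)
  ))
}

# Resolve the supported allele for every read overlapping one site, then
# collapse mates: agreeing mates yield one observation, disagreeing mates none.
site_observations <- function(reads, site, min_mapq, min_baseq) {
  keep <- !is.na(reads$mapq) & reads$mapq >= min_mapq
  if (!any(keep)) return(NULL)
  seqs <- as.character(reads$seq)[keep]
  quals <- as(reads$qual, "IntegerList")[keep]
  calls <- purrr::pmap(
    list(reads$pos[keep], reads$cigar[keep], seqs, as.list(quals)),
    function(pos, cigar, seq, qual) {
      read_allele_call(pos, cigar, seq, qual, site)
    }
  )
  supported <- purrr::map_chr(calls, "allele")
  baseq <- purrr::map_int(calls, "base_quality")
  ok <- supported %in% c("REF", "ALT") & baseq >= min_baseq
  if (!any(ok)) return(NULL)

  tl <- abs(reads$isize[keep][ok])
  tl[is.na(tl)] <- 0L
  pp <- bitwAnd(reads$flag[keep][ok], 0x2L) != 0L & tl > 0L
  df <- tibble(
    site_id = site$site_id,
    allele = supported[ok],
    tlen = as.integer(tl),
    properly_paired = pp,
    base_quality = baseq[ok],
    map_quality = as.integer(reads$mapq[keep][ok]),
    fragment_id = reads$qname[keep][ok]
  )
  # one observation per physical fragment; disagreeing mates are discarded
  df |>
    group_by(.data$fragment_id) |>
    filter(dplyr::n_distinct(.data$allele) == 1L) |>
    slice(1L) |>
    ungroup()
}

# Walk a read's CIGAR and return the allele it supports at `site`, with the
# phred quality of the supporting base (minimum over bases for indels).
# Returns allele "NONE" when the read does not span the site, is ambiguous,
# or matches neither allele.
read_allele_call <- function(read_pos, cigar, seq, qual, site) {
  none <- list(allele = "NONE", base_quality = 0L)
  ops <- cigar_ops(cigar)
  if (is.null(ops)) return(none)

  ref_len <- nchar(site$ref)
  want_from <- site$pos
  want_to <- site$pos + ref_len - 1L
  # require the alignment to span one base past the REF interval so that an
  # insertion at its right edge cannot be truncated silently
  span_to <- if (nchar(site$alt) > ref_len) want_to + 1L else want_to

  rpos <- read_pos          # next reference coordinate consumed
  qpos <- 1L                # next query coordinate consumed
  local <- character(0)     # query bases attributed to the REF interval
  local_q <- integer(0)
  covered <- logical(ref_len)  # which REF-interval positions the read aligns

  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      idx <- seq_len(len)
      refc <- rpos + idx - 1L
      inwin <- refc >= want_from & refc <= want_to
      if (any(inwin)) {
        qidx <- qpos + idx[inwin] - 1L
        local <- c(local, substring(seq, qidx, qidx))
        local_q <- c(local_q, qual[qidx])
        covered[refc[inwin] - want_from + 1L] <- TRUE
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "I") {
      # insertion anchored after reference position rpos - 1
      anchor <- rpos - 1L
      if (anchor >= want_from && anchor <= want_to) {
        qidx <- qpos + seq_len(len) - 1L
        local <- c(local, substring(seq, qidx, qidx))
        local_q <- c(local_q, qual[qidx])
      }
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      refc <- rpos + seq_len(len) - 1L
      covered[refc[refc >= want_from & refc <= want_to] - want_from + 1L] <- TRUE
      rpos <- rpos + len
    } else if (op %in% c("S")) {
      qpos <- qpos + len
    } # H, P consume nothing relevant
  }
  aligned_end <- rpos - 1L
  if (read_pos > want_from || aligned_end < span_to || !all(covered)) {
    return(none)
  }
  hap <- paste(local, collapse = "")
  is_ref <- hap == site$ref
  is_alt <- hap == site$alt
  if (is_ref == is_alt) return(none)  # neither, or degenerate ambiguity
  bq <- if (length(local_q) > 0L) min(local_q) else 0L
  list(allele = if (is_ref) "REF" else "ALT", base_quality = as.integer(bq))
}

cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(NULL)
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  if (m[1L] == -1L) return(NULL)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  data.frame(
    len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
    op = sub("^\\d+", "", toks),
    stringsAsFactors = FALSE
  )
}
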