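#' Count fetal-labelled and shared-labelled fragments at informative sites
#'
#' At fetal-informative sites the parents are homozygous for different
#' alleles, so every fragment carrying the paternal-specific allele must be
#' fetal-derived. Those fragments accrue to the fetal-labelled length
#' histogram and the count `b`; fragments carrying the maternal allele (shared
#' with the plasma background) accrue to the shared-labelled histogram and the
#' count `a`. The shared histogram is knowingly contaminated by the minority
#' of fetal fragments that carry the maternal allele; no correction is
#' applied.
#'
#' @param store Evidence store.
#' @param sites Site tibble; must contain at least one `FETAL_INFORMATIVE`
#'   site.
#' @param max_tlen Histogram support upper bound; lengths above it (or
#'   unavailable) fall into an overflow bucket.
#' @return A list with `histogram` (tibble: `tlen` 1..`max_tlen`,
#'   `count_fetal`, `count_shared`), `a`, `b`, and overflow counts.
#' @export
collect_informative_counts <- function(store, sites, max_tlen = 500L) {
  info <- filter(sites, .data$category == "FETAL_INFORMATIVE")
  if (nrow(info) == 0L) {
    stop("no FETAL_INFORMATIVE sites: cannot estimate the fetal fraction; ",
         "use a fixed fetal-fraction profile instead", call. = FALSE)
  }
  # the paternal-specific allele is ALT when the father is 1/1, REF when 0/0
  info <- mutate(info,
                 paternal_allele = if_else(.data$g_father == "1/1", "ALT", "REF"))
  obs <- inner_join(as_tibble(store),
                    select(info, "site_id", "paternal_allele"),
                    by = "site_id")
  obs <- mutate(obs, fetal_labelled = .data$allele == .data$paternal_allele)

  in_range <- obs$properly_paired & obs$tlen >= 1L & obs$tlen <= max_tlen
  tl <- obs$tlen[in_range]
  fl <- obs$fetal_labelled[in_range]
  count_fetal <- tabulate(tl[fl], nbins = max_tlen)
  count_shared <- tabulate(tl[!fl], nbins = max_tlen)

  list(
    histogram = tibble(tlen = seq_len(max_tlen),
                       count_fetal = count_fetal,
                       count_shared = count_shared),
    a = sum(!obs$fetal_labelled),
    b = sum(obs$fetal_labelled),
    overflow_fetal = sum(obs$fetal_labelled) - sum(count_fetal),
    overflow_shared = sum(!obs$fetal_labelled) - sum(count_shared)
  )
}

#' Total fetal fraction from informative allele counts
#'
#' The fetus is heterozygous at fetal-informative sites, so only half of its
#' fragments show the paternal-specific allele; the fraction of cffDNA within
#' all cfDNA is therefore estimated as `2 b / (a + b)`, clamped to
#' `(1e-6, 1)`.
#'
#' @param a Count of shared-allele (maternal-allele) fragments.
#' @param b Count of paternal-specific-allele fragments.
#' @return A single fetal fraction in `[1e-6, 1]`.
#' @export
estimate_total_ff <- function(a, b) {
  if (a + b <= 0) stop("a + b must be positive", call. = FALSE)
  min(max(2 * b / (a + b), 1e-6), 1)
}

#' Estimate total and per-fragment-length fetal fractions
#'
#' Groups informative-site fragments by template length and applies the
#' allele-count estimator within each length bin: `f_L = 2 b_L / (a_L + b_L)`
#' (clamped to `[0, 1]`). Bins with fewer than `min_count` informative
#' fragments fall back to the pooled total fraction; shorter fragments are
#' expected to receive larger fractions (the fetal length mode, about 140 bp,
#' lies below the maternal mode of about 166 bp). An optional rescaled
#' approximation derives `f_L` from the two labelled length distributions and
#' the total fraction instead of per-bin counts.
#'
#' @inheritParams collect_informative_counts
#' @param min_count Minimum informative fragments a length bin needs before
#'   its own estimate is trusted.
#' @param method `"direct"` (per-bin allele counts, default) or `"rescaled"`
#'   (mixture inversion from the labelled length distributions).
#' @param smooth_window Odd moving-average window applied to the per-bin
#'   counts before estimation; `0` (default) disables smoothing.
#' @return An object of class `nipgeno_ff_profile`: total fraction,
#'   per-length table, counts and the fallback parameters.
#' @export
estimate_per_length_ff <- function(store, sites, min_count = 50L,
                                   max_tlen = 500L,
                                   method = c("direct", "rescaled"),
                                   smooth_window = 0L) {
  method <- match.arg(method)
  cc <- collect_informative_counts(store, sites, max_tlen = max_tlen)
  total_ff <- estimate_total_ff(cc$a, cc$b)

  h <- cc$histogram
  cf <- h$count_fetal
  cs <- h$count_shared
  if (smooth_window >= 3L) {
    if (smooth_window %% 2L == 0L) {
      stop("smooth_window must be odd", call. = FALSE)
    }
    k <- rep(1, smooth_window)
    cf_s <- stats::filter(cf, k, sides = 2)
    cs_s <- stats::filter(cs, k, sides = 2)
    cf_use <- ifelse(is.na(cf_s), cf, as.numeric(cf_s))
    cs_use <- ifelse(is.na(cs_s), cs, as.numeric(cs_s))
  } else {
    cf_use <- cf
    cs_use <- cs
  }

  n_bin <- cf_use + cs_use
  if (method == "direct") {
    ff <- ifelse(n_bin > 0, pmin(pmax(2 * cf_use / pmax(n_bin, 1), 0), 1),
                 total_ff)
  } else {
    # mixture inversion: with fetal length law p_F and (contaminated) shared
    # law p_S, f_L = f p_F(L) / (f p_F(L) + (1 - f) p_S(L))
    p_f <- cf_use / max(sum(cf_use), 1)
    p_s <- cs_use / max(sum(cs_use), 1)
    denom <- total_ff * p_f + (1 - total_ff) * p_s
    ff <- ifelse(denom > 0, total_ff * p_f / denom, total_ff)
  }
  low <- (cf + cs) < min_count
  ff[low] <- total_ff

  structure(
    list(
      total_ff = total_ff,
      table = tibble(tlen = h$tlen, count_fetal = cf, count_shared = cs,
                     ff = ff),
      a = cc$a, b = cc$b,
      min_count = as.integer(min_count), max_tlen = as.integer(max_tlen),
      method = method, smooth_window = as.integer(smooth_window),
      fixed = FALSE
    ),
    class = "nipgeno_ff_profile"
  )
}

#' Build a fixed (length-independent) fetal-fraction profile
#'
#' Every lookup returns `total_ff`; used for the fixed-fraction baseline mode
#' of the genotyper and when no informative sites are available.
#'
#' @param total_ff Fetal fraction in `(0, 1]`.
#' @param max_tlen Kept for interface parity with estimated profiles.
#' @return A `nipgeno_ff_profile` whose per-length values all equal
#'   `total_ff`.
#' @export
ff_profile_fixed <- function(total_ff, max_tlen = 500L) {
  stopifnot(is.numeric(total_ff), length(total_ff) == 1L,
            total_ff > 0, total_ff <= 1)
  structure(
    list(
      total_ff = total_ff,
      table = tibble(tlen = seq_len(max_tlen),
                     count_fetal = 0L, count_shared = 0L, ff = total_ff),
      a = NA_integer_, b = NA_integer_,
      min_count = 0L, max_tlen = as.integer(max_tlen),
      method = "fixed", smooth_window = 0L,
      fixed = TRUE
    ),
    class = "nipgeno_ff_profile"
  )
}

#' @export
print.nipgeno_ff_profile <- function(x, ...) {
  cat(sprintf(
    "<nipgeno fetal-fraction profile: total_ff = %.4f (%s), max_tlen = %d>\n",
    x$total_ff, x$method, x$max_tlen))
  invisible(x)
}

#' Look up the fetal fraction applied to each observation
#'
#' Properly paired fragments with a template length between 1 and `max_tlen`
#' receive their length bin's fraction; fragments that are not properly
#' paired, or longer than `max_tlen`, fall back to the total fraction. The
#' result is floored at `1e-6` so a likelihood never collapses to a purely
#' maternal mixture.
#'
#' @param profile A `nipgeno_ff_profile`.
#' @param tlen Integer vector of template lengths.
#' @param properly_paired Logical vector, recycled against `tlen`.
#' @return Numeric vector of fetal fractions in `[1e-6, 1]`.
#' @export
lookup_ff <- function(profile, tlen, properly_paired = TRUE) {
  stopifnot(inherits(profile, "nipgeno_ff_profile"))
  n <- max(length(tlen), length(properly_paired))
  tlen <- rep_len(as.integer(tlen), n)
  properly_paired <- rep_len(properly_paired, n)
  out <- rep(profile$total_ff, n)
  use_bin <- properly_paired & tlen >= 1L & tlen <= profile$max_tlen
  out[use_bin] <- profile$table$ff[tlen[use_bin]]
  pmin(pmax(out, 1e-6), 1)
}

#' Write / read a fetal-fraction profile
#'
#' Serialized as a TSV (`tlen`, `count_fetal`, `count_shared`, `ff`) with a
#' JSON sidecar holding the scalar fields; the round trip is exact.
#'
#' @param profile A `nipgeno_ff_profile`.
#' @param path Output TSV path.
#' @return `write_ff_profile()` returns `path` invisibly; `read_ff_profile()`
#'   the reconstructed profile.
#' @export
write_ff_profile <- function(profile, path) {
  stopifnot(inherits(profile, "nipgeno_ff_profile"))
  readr::write_tsv(profile$table, path)
  header <- profile[setdiff(names(profile), "table")]
  # hex representation keeps the total fraction bit-exact through JSON
  header$total_ff_hex <- sprintf("%a", profile$total_ff)
  jsonlite::write_json(header, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_ff_profile
#' @export
read_ff_profile <- function(path) {
  header <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(tlen = readr::col_integer(),
                            count_fetal = readr::col_integer(),
                            count_shared = readr::col_integer(),
                            ff = readr::col_double()),
    progress = FALSE
  )
  total_ff <- if (!is.null(header$total_ff_hex)) {
    as.numeric(header$total_ff_hex)
  } else {
    header$total_ff
  }
  structure(
    list(total_ff = total_ff, table = tab,
         a = header$a %||% NA_integer_, b = header$b %||% NA_integer_,
         min_count = as.integer(header$min_count),
         max_tlen = as.integer(header$max_tlen),
         method = header$method, smooth_window = as.integer(header$smooth_window),
         fixed = isTRUE(header$fixed)),
    class = "nipgeno_ff_profile"
  )
}
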