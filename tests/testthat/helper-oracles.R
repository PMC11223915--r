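# Independent oracles used to freeze expected values and back the
# property tests. These deliberately avoid the code paths they check:
# normalization is verified by brute-force enumeration of equivalent
# placements, quantiles by direct order-statistic interpolation, and
# cDNA coordinates by an exhaustive coordinate walker.

# all equivalent left-anchored placements of a trimmed pure indel (or
# SNV), by trying every (pos, ref-length) pair against the edited
# sequence; returns a data.frame of pos/ref/alt
enum_placements <- function(v, seq) {
  E <- apply_variant(v, seq)
  L <- nchar(seq); LE <- nchar(E)
  # every anchored equivalent placement of a d-base indel uses a REF of
  # at most d + 2 bases (anchor + edited bases, one base of slack), so
  # bounding the REF length keeps the enumeration exhaustive
  max_rl <- abs(LE - L) + 2L
  out <- list()
  for (p in seq_len(L)) {
    if (substr(seq, 1, p - 1) != substr(E, 1, p - 1)) next
    for (rl in seq.int(0L, min(max_rl, L - p + 1L))) {
      alt_len <- LE - L + rl
      if (alt_len < 1L || rl < 1L) next
      suffix_len <- L - (p + rl - 1L)
      if (suffix_len > 0L &&
          substr(seq, p + rl, L) != substr(E, LE - suffix_len + 1L, LE)) next
      if (suffix_len == 0L && p + rl - 1L != L) next
      ref <- substr(seq, p, p + rl - 1L)
      alt <- substr(E, p, p - 1L + alt_len)
      if (ref == alt) next
      tv <- tryCatch(trim_alleles(gvariant(v$chrom, p, ref, alt)),
                     error = function(e) NULL)
      if (is.null(tv)) next
      is_snv <- nchar(tv$ref) == nchar(tv$alt)
      is_anchored_indel <- nchar(tv$ref) != nchar(tv$alt) &&
        min(nchar(tv$ref), nchar(tv$alt)) == 1L &&
        substr(tv$ref, 1, 1) == substr(tv$alt, 1, 1)
      if (is_snv || is_anchored_indel)
        out[[length(out) + 1L]] <- data.frame(
          pos = tv$pos, ref = tv$ref, alt = tv$alt,
          stringsAsFactors = FALSE)
    }
  }
  unique(do.call(rbind, out))
}

# expected left/right normal forms by enumeration: min / max position
oracle_normalize <- function(v, seq) {
  pl <- enum_placements(v, seq)
  pl <- pl[order(pl$pos), , drop = FALSE]
  list(left = pl[1, ], right = pl[nrow(pl), ], placements = pl)
}

# type-7 quantile by direct interpolation between order statistics
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
}

tukey_oracle <- function(x, k_lower = 4, k_upper = 5) {
  q1 <- quantile_oracle(x, 0.25); q3 <- quantile_oracle(x, 0.75)
  c(lower = q1 - k_lower * (q3 - q1), upper = q3 + k_upper * (q3 - q1))
}

# exhaustive cDNA coordinate walker: builds the full genomic->coding
# lookup for a transcript, then resolves intronic offsets by scanning
# outward to the nearest exonic base
cdna_walker <- function(t, g) {
  exonic <- unlist(mapply(seq.int, t$exon_starts, t$exon_ends,
                          SIMPLIFY = FALSE))
  txpos <- if (t$strand == "-") rev(exonic) else exonic
  cds_first_g <- if (t$strand == "+") t$cds_start else t$cds_end
  cds_last_g <- if (t$strand == "+") t$cds_end else t$cds_start
  cpos_of <- function(gg) {
    idx <- match(gg, txpos)
    cf <- match(cds_first_g, txpos); cl <- match(cds_last_g, txpos)
    if (idx < cf) idx - cf            # 5' UTR counts negative
    else if (idx > cl) idx - cl       # past the stop
    else idx - cf + 1L
  }
  if (g %in% exonic) return(list(cpos = cpos_of(g), offset = 0L))
  lo <- g; hi <- g
  repeat {
    lo <- lo - 1L; hi <- hi + 1L
    lo_in <- lo %in% exonic; hi_in <- hi %in% exonic
    if (lo_in || hi_in) {
      # tie (equidistant) resolves to the donor side: the exon that is
      # 5' of the intron in transcript direction
      if (lo_in && hi_in) {
        anchor <- if (t$strand == "+") lo else hi
      } else anchor <- if (lo_in) lo else hi
      d <- abs(g - anchor)
      # sign: + when past the transcript-direction end of the anchor exon
      past_donor <- if (t$strand == "+") anchor < g else anchor > g
      return(list(cpos = cpos_of(anchor),
                  offset = if (past_donor) d else -d))
    }
  }
}

# random pure indel inside a repeat-rich reference, left-anchored
random_indel <- function(seq, rng_pos, max_unit = 3L, max_copies = 4L) {
  L <- nchar(seq)
  p <- rng_pos
  if (stats::runif(1) < 0.5) {     # deletion of d bases after anchor
    d <- sample.int(4L, 1L)
    if (p + d > L - 1L) d <- max(1L, L - 1L - p)
    gvariant("1", p, substr(seq, p, p + d), substr(seq, p, p))
  } else {                          # insertion after anchor
    ins <- paste(sample(c("A", "C", "G", "T"), sample.int(4L, 1L),
                        replace = TRUE), collapse = "")
    gvariant("1", p, substr(seq, p, p), paste0(substr(seq, p, p), ins))
  }
}

# repeat-rich test reference: random backbone with implanted
# homopolymer and dinucleotide tracts
repeat_rich_reference <- function(seed, length = 60L) {
  units <- c("A", "T", "AT", "CA", "GT", "AAT")
  u1 <- sample(units, 1L); u2 <- sample(units, 1L)
  make_reference(seed, length, repeat_tracts = list(
    list(pos = 11L, unit = u1, n = 4L),
    list(pos = 35L, unit = u2, n = 3L)))
}

# small cohort of profiles built directly (no files) for QC tests
toy_profile <- function(id, keys, copies = NULL, panel = NULL, order = 1L) {
  if (is.null(panel)) panel <- panel_regions("1", 1L, 10000L)
  pos <- as.integer(sub("^1:(\\d+):.*$", "\\1", keys))
  rec <- data.frame(chrom = "1", pos = pos,
                    ref = sub("^1:\\d+:([A-Z]+):.*$", "\\1", keys),
                    alt = sub("^.*:([A-Z]+)$", "\\1", keys),
                    alt_copies = if (is.null(copies)) rep(1L, length(keys))
                                 else copies)
  sample_profile(id, rec, panel, submission_order = order)
}

key_of <- function(pos, ref = "A", alt = "G") sprintf("1:%d:%s:%s", pos, ref, alt)
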