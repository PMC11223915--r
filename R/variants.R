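# Variant representation and reference-based normalization.
#
# A genomic variant is stored VCF-style: 1-based position of the first
# reference base, non-empty REF and ALT allele strings. Indels inside
# repeat tracts admit many equivalent placements; the left (most-5')
# placement is the canonical identity used throughout the database, while
# the right (most-3') placement backs coding-DNA style naming.

.DNA_CHARS <- c("A", "C", "G", "T", "N")

#' Construct a genomic variant
#'
#' @param chrom chromosome name.
#' @param pos 1-based position of the first reference base.
#' @param ref reference allele (non-empty, characters in ACGTN).
#' @param alt alternate allele (non-empty, characters in ACGTN).
#' @return an object of class `gvariant`.
#' @examples
#' gvariant("1", 100, "CAG", "CTG")
#' @export
gvariant <- function(chrom, pos, ref, alt) {
  chrom <- unname(chrom)
  ref <- unname(toupper(ref)); alt <- unname(toupper(alt))
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    .stopf("chrom must be a non-empty string")
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) .stopf("pos must be >= 1")
  for (a in c(ref, alt)) {
    if (!nzchar(a) || !all(strsplit(a, "")[[1]] %in% .DNA_CHARS))
      .stopf("alleles must be non-empty strings over ACGTN, got '%s'", a)
  }
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt),
            class = "gvariant")
}

#' @export
print.gvariant <- function(x, ...) {
  cat(sprintf("<variant %s:%d %s>%s\n", x$chrom, x$pos, x$ref, x$alt))
  invisible(x)
}

#' Canonical variant key
#'
#' Identity string `chrom:pos:ref:alt`. For a stable database identity the
#' variant should first be left-normalized (see [normalize_variant()]).
#'
#' @param v a `gvariant`.
#' @return character scalar.
#' @export
variant_key <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Trim shared allele context
#'
#' Removes the shared suffix, then the shared prefix (advancing the
#' position), always retaining one anchor base of shared context rather
#' than emptying an allele (VCF convention).
#'
#' @param v a `gvariant`.
#' @return a trimmed `gvariant`.
#' @export
trim_alleles <- function(v) {
  ref <- v$ref; alt <- v$alt; pos <- v$pos
  if (ref == alt) .stopf("non-variant: ref == alt ('%s') at %s:%d",
                         ref, v$chrom, v$pos)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         .last_char(ref) == .last_char(alt)) {
    ref <- .drop_last(ref); alt <- .drop_last(alt)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- .drop_first(ref); alt <- .drop_first(alt)
    pos <- pos + 1L
  }
  if (ref == alt) .stopf("non-variant after trimming at %s:%d", v$chrom, v$pos)
  gvariant(v$chrom, pos, ref, alt)
}

# check REF against the reference sequence
.check_ref <- function(v, seq) {
  end <- v$pos + nchar(v$ref) - 1L
  if (end > nchar(seq))
    .stopf("variant %s extends beyond reference (length %d)",
           variant_key(v), nchar(seq))
  obs <- substr(seq, v$pos, end)
  if (obs != v$ref)
    .stopf("reference mismatch at %s:%d: REF is '%s' but reference has '%s'",
           v$chrom, v$pos, v$ref, obs)
  invisible(TRUE)
}

#' Left-normalize (most-5' placement)
#'
#' Shifts a trimmed variant to its most-5' equivalent placement on the
#' reference, keeping the usual VCF left anchor for indels. SNVs are
#' returned unchanged; the operation is idempotent.
#'
#' @param v a `gvariant`.
#' @param reference named character vector of chromosome sequences (or a
#'   single unnamed sequence string).
#' @return the most-5' equivalent `gvariant`.
#' @export
shift_left <- function(v, reference) {
  seq <- .ref_seq(reference, v$chrom)
  v <- trim_alleles(v)
  .check_ref(v, seq)
  ref <- v$ref; alt <- v$alt; pos <- v$pos
  if (nchar(ref) == 1L && nchar(alt) == 1L) return(v)   # SNV/MNV-free fast path
  repeat {
    if (.last_char(ref) == .last_char(alt)) {
      ref <- .drop_last(ref); alt <- .drop_last(alt)
      if (!nzchar(ref) || !nzchar(alt)) {
        if (pos == 1L) {          # cannot extend; restore the dropped base
          b <- substr(seq, pos + nchar(ref), pos + nchar(ref))
          ref <- paste0(ref, b); alt <- paste0(alt, b)
          break
        }
        pos <- pos - 1L
        b <- substr(seq, pos, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- .drop_first(ref); alt <- .drop_first(alt); pos <- pos + 1L
  }
  gvariant(v$chrom, pos, ref, alt)
}

#' Right-normalize (most-3' placement)
#'
#' Mirror of [shift_left()]: shifts a trimmed variant to its most-3'
#' equivalent placement, re-anchored on the left in the usual VCF style
#' (so the key of the right form is still `chrom:pos:ref:alt` with a
#' leading shared base for indels). Idempotent; SNVs unchanged.
#'
#' @inheritParams shift_left
#' @return the most-3' equivalent `gvariant`.
#' @export
shift_right <- function(v, reference) {
  seq <- .ref_seq(reference, v$chrom)
  L <- nchar(seq)
  v <- trim_alleles(v)
  .check_ref(v, seq)
  ref <- v$ref; alt <- v$alt; pos <- v$pos
  if (nchar(ref) == 1L && nchar(alt) == 1L) return(v)
  repeat {
    if (substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- .drop_first(ref); alt <- .drop_first(alt); pos <- pos + 1L
      if (!nzchar(ref) || !nzchar(alt)) {
        nxt <- pos + nchar(ref)          # first reference base after REF
        if (nxt > L) {                   # cannot extend; restore on the left
          pos <- pos - 1L
          b <- substr(seq, pos, pos)
          ref <- paste0(b, ref); alt <- paste0(b, alt)
          break
        }
        b <- substr(seq, nxt, nxt)
        ref <- paste0(ref, b); alt <- paste0(alt, b)
      }
    } else break
  }
  # trim shared suffix; if that would empty an allele, swap the right
  # anchor for a left anchor taken from the reference
  while (.last_char(ref) == .last_char(alt)) {
    if (nchar(ref) > 1L && nchar(alt) > 1L) {
      ref <- .drop_last(ref); alt <- .drop_last(alt)
    } else if (pos > 1L) {
      ref <- .drop_last(ref); alt <- .drop_last(alt)
      pos <- pos - 1L
      b <- substr(seq, pos, pos)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      break
    } else break
  }
  gvariant(v$chrom, pos, ref, alt)
}

#' Normalize a variant to its left and right placements
#'
#' @inheritParams shift_left
#' @return an object of class `normalized_variant`: list with elements
#'   `left`, `right` (both `gvariant`) and `key`, the canonical identity
#'   string built from the left form.
#' @export
normalize_variant <- function(v, reference) {
  left <- shift_left(v, reference)
  right <- shift_right(v, reference)
  structure(list(left = left, right = right, key = variant_key(left)),
            class = "normalized_variant")
}

#' @export
print.normalized_variant <- function(x, ...) {
  cat(sprintf("<normalized %s | right %s:%d:%s:%s>\n", x$key,
              x$right$chrom, x$right$pos, x$right$ref, x$right$alt))
  invisible(x)
}

#' Apply a variant to a reference sequence
#'
#' Returns the edited sequence; used by the normalization equivalence
#' invariant (left and right placements must yield identical edits).
#'
#' @inheritParams shift_left
#' @return character scalar, the edited chromosome sequence.
#' @export
apply_variant <- function(v, reference) {
  seq <- .ref_seq(reference, v$chrom)
  .check_ref(v, seq)
  paste0(substr(seq, 1, v$pos - 1L), v$alt,
         substr(seq, v$pos + nchar(v$ref), nchar(seq)))
}
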