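# Variant representation: a wild-type/mutant pair differing by one contiguous
# in-frame indel, plus the coordinate bijection between the two sequences.

#' Standard amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes, in the fixed column order used
#' by all probability matrices in this package.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Nonstandard letters tolerated in input sequences; positions carrying them are
# excluded from probability sums (no defined marginal) with a warning.
NONSTANDARD_AA <- c("X", "U", "B", "Z")

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

validate_sequence <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L)
    stop("EmptySequence: ", what, " must be a non-empty string", call. = FALSE)
  ch <- seq_chars(toupper(s))
  bad <- setdiff(unique(ch), c(AA_ALPHABET, NONSTANDARD_AA))
  if (length(bad))
    stop("InvalidResidue: ", what, " contains non-amino-acid letters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(ch %in% NONSTANDARD_AA))
    warning("nonstandard residues (", paste(intersect(ch, NONSTANDARD_AA), collapse = ","),
            ") in ", what, "; these positions are excluded from probability sums",
            call. = FALSE)
  paste(ch, collapse = "")
}

#' Construct an in-frame indel variant
#'
#' Builds a validated `protein_variant`: a wild-type/mutant sequence pair that
#' differ by exactly one contiguous run of inserted or deleted residues.
#' Coordinates are 1-based; `indel_start` indexes the first indel residue in
#' the *longer* of the two sequences.
#'
#' @param variant_id opaque identifier.
#' @param wt_sequence,mut_sequence amino-acid strings (20 standard letters;
#'   `X`, `U`, `B`, `Z` tolerated with a warning).
#' @param indel_kind `"deletion"` or `"insertion"`. If `NULL`, the annotation
#'   is inferred from the sequences via [infer_indel()].
#' @param indel_start 1-based position of the first indel residue in the longer
#'   sequence.
#' @param indel_length number of inserted/deleted residues (>= 1).
#' @param label optional `"benign"` or `"pathogenic"`.
#' @return An object of class `protein_variant`.
#' @details When an explicit annotation (`indel_kind`/`indel_start`/
#'   `indel_length`) is supplied it takes precedence over inference, but is
#'   validated against the sequences: removing the annotated residues from the
#'   longer sequence must reproduce the shorter one exactly.
#' @examples
#' v <- protein_variant("v1", "ACDEF", "ACEF")
#' v$indel_kind    # "deletion"
#' v$indel_start   # 3
#' @export
protein_variant <- function(variant_id, wt_sequence, mut_sequence,
                            indel_kind = NULL, indel_start = NULL,
                            indel_length = NULL, label = NULL) {
  wt <- validate_sequence(wt_sequence, "wt_sequence")
  mut <- validate_sequence(mut_sequence, "mut_sequence")
  if (!is.null(label)) {
    label <- match.arg(label, c("benign", "pathogenic"))
  }
  have_annot <- !is.null(indel_kind) && !is.null(indel_start) && !is.null(indel_length)
  if (have_annot) {
    indel_kind <- match.arg(indel_kind, c("deletion", "insertion"))
    indel_start <- as.integer(indel_start)
    indel_length <- as.integer(indel_length)
    check_annotation(wt, mut, indel_kind, indel_start, indel_length)
  } else {
    inf <- infer_indel_core(wt, mut)
    indel_kind <- inf$kind
    indel_start <- inf$start
    indel_length <- inf$length
  }
  structure(
    list(variant_id = as.character(variant_id),
         wt_sequence = wt, mut_sequence = mut,
         indel_kind = indel_kind,
         indel_start = indel_start,
         indel_length = indel_length,
         label = label),
    class = "protein_variant")
}

#' @export
print.protein_variant <- function(x, ...) {
  cat(sprintf("<protein_variant %s> %s of %d aa at %d (wt %d aa, mut %d aa)%s\n",
              x$variant_id, x$indel_kind, x$indel_length, x$indel_start,
              nchar(x$wt_sequence), nchar(x$mut_sequence),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

check_annotation <- function(wt, mut, kind, start, len) {
  if (len < 1L) stop("indel_length must be >= 1", call. = FALSE)
  lw <- nchar(wt); lm <- nchar(mut)
  if (abs(lw - lm) != len)
    stop("AnnotationMismatch: |len(wt) - len(mut)| != indel_length", call. = FALSE)
  long <- if (kind == "deletion") wt else mut
  short <- if (kind == "deletion") mut else wt
  if (nchar(long) <= nchar(short))
    stop("AnnotationMismatch: indel_kind inconsistent with sequence lengths", call. = FALSE)
  ll <- nchar(long)
  if (start < 1L || start + len - 1L > ll)
    stop("AnnotationMismatch: indel interval outside the longer sequence", call. = FALSE)
  rebuilt <- paste0(substr(long, 1L, start - 1L), substr(long, start + len, ll))
  if (!identical(rebuilt, short))
    stop("AnnotationMismatch: removing the annotated indel from the longer ",
         "sequence does not reproduce the shorter sequence", call. = FALSE)
  invisible(TRUE)
}

# Longest-common-prefix / longest-common-suffix placement of a single
# contiguous indel. Repeat-region ambiguity (e.g. poly-A runs) resolves to the
# LEFTMOST placement.
infer_indel_core <- function(wt, mut) {
  lw <- nchar(wt); lm <- nchar(mut)
  if (lw == lm) {
    if (identical(wt, mut))
      stop("NoIndel: sequences are identical", call. = FALSE)
    stop("MultiSite: equal-length sequences cannot differ by a single indel",
         call. = FALSE)
  }
  kind <- if (lw > lm) "deletion" else "insertion"
  long <- if (lw > lm) wt else mut
  short <- if (lw > lm) mut else wt
  lc <- seq_chars(long); sc <- seq_chars(short)
  ll <- length(lc); ls <- length(sc)
  len <- ll - ls
  # longest common prefix
  p <- 0L
  while (p < ls && lc[p + 1L] == sc[p + 1L]) p <- p + 1L
  # longest common suffix
  s <- 0L
  while (s < ls && lc[ll - s] == sc[ls - s]) s <- s + 1L
  # removal interval [i, i+len-1] is valid iff i-1 <= p and ll-(i+len)+1 <= s
  i <- max(1L, ll - len - s + 1L)
  if (i - 1L > p)
    stop("MultiSite: difference is not a single contiguous indel", call. = FALSE)
  list(kind = kind, start = i, length = len)
}

#' Infer a single contiguous indel from a sequence pair
#'
#' Locates the indel by longest-common-prefix / longest-common-suffix scan.
#' When the placement is ambiguous (the indel sits in a repeat), the leftmost
#' placement is returned.
#'
#' @inheritParams protein_variant
#' @return A `protein_variant`.
#' @export
infer_indel <- function(wt_sequence, mut_sequence, variant_id = "variant") {
  protein_variant(variant_id, wt_sequence, mut_sequence)
}

#' Overlap map between wild-type and mutant coordinates
#'
#' Returns the order-preserving bijection between the positions present in both
#' sequences, i.e. every residue outside the indel. Row `i` pairs
#' `wt_pos[i]` with `mut_pos[i]`; there are exactly
#' `min(len(wt), len(mut))` rows.
#'
#' @param variant a `protein_variant`.
#' @return A data.frame with integer columns `wt_pos` and `mut_pos`.
#' @examples
#' build_overlap_map(protein_variant("v", "ACDEF", "ACEF"))
#' @export
build_overlap_map <- function(variant) {
  stopifnot(inherits(variant, "protein_variant"))
  a <- variant$indel_start
  len <- variant$indel_length
  lw <- nchar(variant$wt_sequence); lm <- nchar(variant$mut_sequence)
  ll <- max(lw, lm)
  long_pos <- setdiff(seq_len(ll), seq.int(a, a + len - 1L))
  short_pos <- ifelse(long_pos < a, long_pos, long_pos - len)
  if (variant$indel_kind == "deletion") {
    out <- data.frame(wt_pos = long_pos, mut_pos = as.integer(short_pos))
  } else {
    out <- data.frame(wt_pos = as.integer(short_pos), mut_pos = long_pos)
  }
  rownames(out) <- NULL
  out
}

#' Indel subsequence and interval
#'
#' Extracts the inserted or deleted residues and their 1-based closed interval
#' in the longer sequence (wild-type coordinates for deletions, mutant
#' coordinates for insertions).
#'
#' @param variant a `protein_variant`.
#' @return A list with `subsequence`, `interval` (`c(start, end)`), and
#'   `frame` (`"wt"` or `"mut"`).
#' @export
indel_region <- function(variant) {
  stopifnot(inherits(variant, "protein_variant"))
  a <- variant$indel_start
  b <- a + variant$indel_length - 1L
  long <- if (variant$indel_kind == "deletion") variant$wt_sequence else variant$mut_sequence
  list(subsequence = substr(long, a, b),
       interval = c(a, b),
       frame = if (variant$indel_kind == "deletion") "wt" else "mut")
}
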