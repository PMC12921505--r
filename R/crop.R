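# Truncation of long sequences around the indel so pairs fit a protein
# language model's input capacity, keeping both crops aligned on shared flanks.

#' Crop a long variant around its indel
#'
#' Sequences longer than `length_limit` are truncated around the indel,
#' retaining up to `buffer` residues on each side of it. The longer-sequence
#' crop therefore has at most `2 * buffer + indel_length` residues; when that
#' exceeds `model_cap` the flanks are reduced symmetrically so the crop is
#' exactly `model_cap` (the upstream flank takes the odd residue). Near a
#' terminus the missing flank is clipped, not transferred to the other side,
#' so wild-type and mutant crops always share identical flanking residues.
#'
#' @param variant a `protein_variant`.
#' @param length_limit sequences at or under this length are returned
#'   untouched (default 1000).
#' @param buffer residues retained on each side of the indel (default 500).
#' @param model_cap hard capacity of the downstream model (default 1022).
#' @return A list of class `crop_result`: `cropped_variant`
#'   (a `protein_variant`), `wt_offset` and `mut_offset` (0-based indices of
#'   the crop start within the full sequences, 0 for an identity crop).
#' @examples
#' v <- protein_variant("v", strrep("A", 50), paste0(strrep("A", 25), "G", strrep("A", 25)))
#' crop_variant(v)$wt_offset  # 0: under the limit
#' @export
crop_variant <- function(variant, length_limit = 1000L, buffer = 500L,
                         model_cap = 1022L) {
  stopifnot(inherits(variant, "protein_variant"))
  lw <- nchar(variant$wt_sequence); lm <- nchar(variant$mut_sequence)
  ll <- max(lw, lm)
  len <- variant$indel_length
  if (len >= model_cap)
    stop("IndelTooLong: indel of ", len, " residues cannot fit model capacity ",
         model_cap, call. = FALSE)
  if (ll <= length_limit) {
    return(structure(list(cropped_variant = variant, wt_offset = 0L,
                          mut_offset = 0L),
                     class = "crop_result"))
  }
  a <- variant$indel_start
  b <- a + len - 1L
  if (2L * buffer + len > model_cap) {
    flank <- model_cap - len
    up <- as.integer(ceiling(flank / 2))
    down <- as.integer(floor(flank / 2))
  } else {
    up <- down <- as.integer(buffer)
  }
  ws <- max(1L, a - up)         # crop bounds in the longer sequence
  we <- min(ll, b + down)
  # corresponding bounds in the shorter sequence (indel positions skipped)
  ss <- if (ws < a) ws else b + 1L - len
  se <- if (we > b) we - len else a - 1L
  long_is_wt <- variant$indel_kind == "deletion"
  long_seq <- if (long_is_wt) variant$wt_sequence else variant$mut_sequence
  short_seq <- if (long_is_wt) variant$mut_sequence else variant$wt_sequence
  long_crop <- substr(long_seq, ws, we)
  short_crop <- substr(short_seq, ss, se)
  cropped <- suppressWarnings(protein_variant(
    variant$variant_id,
    wt_sequence = if (long_is_wt) long_crop else short_crop,
    mut_sequence = if (long_is_wt) short_crop else long_crop,
    indel_kind = variant$indel_kind,
    indel_start = a - ws + 1L,
    indel_length = len,
    label = variant$label))
  structure(list(cropped_variant = cropped,
                 wt_offset = if (long_is_wt) ws - 1L else ss - 1L,
                 mut_offset = if (long_is_wt) ss - 1L else ws - 1L),
            class = "crop_result")
}

#' @export
print.crop_result <- function(x, ...) {
  cat(sprintf("<crop_result> wt_offset=%d mut_offset=%d\n", x$wt_offset, x$mut_offset))
  print(x$cropped_variant)
  invisible(x)
}
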