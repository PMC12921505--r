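# Per-residue interpretability: the overlap probability score decomposes
# exactly into per-position differences d_i = P(x_i = s_i | s_mut) -
# P(x_i = s_i | s_wt), each in [-1, 1]. The track explains WHERE in the
# sequence the model sees the indel's effect and can be painted onto a
# structure through the B-factor column for viewing in any molecular viewer.

#' Per-residue probability-difference track
#'
#' For every overlap pair, the mutant observed probability minus the
#' wild-type observed probability. The track sums exactly to the variant's
#' overlap probability score (`indellm` method), giving a per-residue
#' decomposition of the prediction.
#'
#' @param variant a `protein_variant` (cropped if necessary).
#' @param provider a `plm_provider`.
#' @param wt_offset 0-based offset of the crop start within the full
#'   wild-type sequence (from [crop_variant()]); used to report
#'   `full_wt_pos`.
#' @param masked use masked marginals instead of single-pass marginals.
#' @return A data.frame of class `difference_track` with columns `wt_pos`,
#'   `mut_pos`, `full_wt_pos`, `wt_residue`, `difference` (`NA` where either
#'   probability is undefined). The indel interval (longer-sequence
#'   coordinates) and kind are attached as attributes `indel_interval` /
#'   `indel_kind`.
#' @export
residue_difference_track <- function(variant, provider, wt_offset = 0L,
                                     masked = FALSE) {
  stopifnot(inherits(variant, "protein_variant"),
            inherits(provider, "plm_provider"))
  marg <- if (masked) provider$masked_marginals else provider$marginals
  p_wt <- observed_probabilities(marg(variant$wt_sequence), variant$wt_sequence)
  p_mut <- observed_probabilities(marg(variant$mut_sequence), variant$mut_sequence)
  omap <- build_overlap_map(variant)
  d <- p_mut[omap$mut_pos] - p_wt[omap$wt_pos]
  out <- data.frame(wt_pos = omap$wt_pos, mut_pos = omap$mut_pos,
                    full_wt_pos = omap$wt_pos + as.integer(wt_offset),
                    wt_residue = seq_chars(variant$wt_sequence)[omap$wt_pos],
                    difference = d, stringsAsFactors = FALSE)
  reg <- indel_region(variant)
  attr(out, "indel_interval") <- reg$interval
  attr(out, "indel_kind") <- variant$indel_kind
  attr(out, "variant_id") <- variant$variant_id
  class(out) <- c("difference_track", class(out))
  out
}

#' Write a difference track as TSV
#'
#' Columns `wt_pos`, `mut_pos`, `full_seq_pos`, `wt_residue`, `difference`;
#' the indel interval is recorded in a `#` comment line so track files remain
#' self-describing.
#'
#' @param track a `difference_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(track, path) {
  iv <- attr(track, "indel_interval")
  kind <- attr(track, "indel_kind")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(iv))
    writeLines(sprintf("# indel: %s of positions %d-%d (%s coordinates)",
                       kind, iv[1], iv[2],
                       if (identical(kind, "deletion")) "wt" else "mut"), con)
  df <- data.frame(wt_pos = track$wt_pos, mut_pos = track$mut_pos,
                   full_seq_pos = track$full_wt_pos,
                   wt_residue = track$wt_residue,
                   difference = track$difference)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a track TSV
#'
#' @param path file written by [write_track_table()].
#' @return data.frame with the track columns.
#' @export
read_track_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Paint a difference track onto a PDB structure
#'
#' Replaces the temperature-factor (B-factor) column of the chosen chain with
#' the per-residue differences, clamped to `[-1, 1]` and written at 2
#' decimals; residues not covered by the track get 0.00 and deleted residues
#' present in the structure get the sentinel 9.99. Matching is by PDB residue
#' number against `full_wt_pos + residue_offset`; residues with insertion
#' codes are not matched (a warning is emitted). All other record content is
#' preserved.
#'
#' @param pdb_path input PDB file.
#' @param chain_id chain to annotate.
#' @param track a `difference_track`.
#' @param out_path output PDB path.
#' @param residue_offset added to `full_wt_pos` before matching PDB residue
#'   numbers (use when the construct numbering differs from the full
#'   sequence).
#' @return `out_path`, invisibly.
#' @export
annotate_structure <- function(pdb_path, chain_id, track, out_path,
                               residue_offset = 0L) {
  pdb <- bio3d::read.pdb(pdb_path)
  atoms <- pdb$atom
  in_chain <- atoms$chain == chain_id
  if (!any(in_chain))
    stop("ChainNotFound: chain '", chain_id, "' absent from ", pdb_path,
         call. = FALSE)
  has_icode <- in_chain & !is.na(atoms$insert) & nzchar(atoms$insert)
  if (any(has_icode)) {
    warning("residues with insertion codes are not matched (",
            sum(has_icode), " atom(s))", call. = FALSE)
    in_chain <- in_chain & !has_icode
  }
  d <- pmin(1, pmax(-1, track$difference))
  target <- track$full_wt_pos + as.integer(residue_offset)
  hit <- match(atoms$resno, target)
  newb <- rep(0, nrow(atoms))
  ok <- in_chain & !is.na(hit) & !is.na(d[ifelse(is.na(hit), 1L, hit)])
  newb[ok] <- round(d[hit[ok]], 2)
  if (identical(attr(track, "indel_kind"), "deletion")) {
    iv <- attr(track, "indel_interval")
    # wt-frame interval; deleted residues may still exist in the wt structure
    del_full <- seq.int(iv[1], iv[2]) +
      (min(track$full_wt_pos) - min(track$wt_pos)) + as.integer(residue_offset)
    newb[in_chain & atoms$resno %in% del_full] <- 9.99
  }
  if (!any(in_chain & (!is.na(hit)) ))
    stop("NoResidueOverlap: no chain residue matches the track coordinates",
         call. = FALSE)
  pdb$atom$b <- newb
  bio3d::write.pdb(pdb, file = out_path)
  invisible(out_path)
}
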