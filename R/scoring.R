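# Zero-shot pathogenicity scores for in-frame indels.
#
# Two families of scores over a wild-type/mutant pair:
#  * pseudo-log-likelihood difference over the FULL sequences
#    ("brandes": PLL(mut) - PLL(wt)), which carries a length bias because the
#    two sums have different numbers of terms;
#  * sum of observed-residue PROBABILITIES restricted to the overlap region
#    ("indellm": sum_mut - sum_wt over positions present in both sequences),
#    which compares like with like and damps low-probability fluctuations in
#    poorly conserved regions.
# Both have |.| variants (magnitude of disruption regardless of direction) and
# the overlap score has a masked-marginals variant.

SCORE_METHODS <- c("brandes", "brandes_abs", "indellm", "indellm_abs",
                   "indellm_masked")

#' Pseudo-log likelihood of a sequence
#'
#' Sum over positions of the natural log of the probability the model assigns
#' to the observed residue. `restrict_to` limits the sum to a position set
#' given in the sequence's own coordinates (the overlap-restricted form).
#' Positions with `NA` probability (nonstandard residues) are dropped with a
#' warning; an exact zero probability inside the restriction is an error, not
#' silently floored, to surface backend pathologies.
#'
#' @param observed numeric vector of observed-residue probabilities
#'   (see [observed_probabilities()]).
#' @param restrict_to optional integer vector of positions to include.
#' @return The log-probability sum (a single number).
#' @examples
#' pll(c(0.5, 0.25))  # log(0.125)
#' @export
pll <- function(observed, restrict_to = NULL) {
  p <- if (is.null(restrict_to)) observed else observed[restrict_to]
  if (anyNA(p)) {
    warning("dropping ", sum(is.na(p)),
            " position(s) with undefined probability from the PLL sum",
            call. = FALSE)
    p <- p[!is.na(p)]
  }
  if (any(p == 0))
    stop("ZeroProbability: a position has probability exactly 0", call. = FALSE)
  sum(log(p))
}

#' Score a variant with a zero-shot method
#'
#' Computes one of the five zero-shot scores from per-position probability
#' matrices of the wild-type and mutant sequences. Positions bearing
#' nonstandard residues are excluded in a paired fashion: if either member of
#' an overlap pair is undefined, the pair is dropped from both sums.
#'
#' @param variant a `protein_variant` (crop long sequences first with
#'   [crop_variant()]).
#' @param provider a `plm_provider`.
#' @param method one of `"brandes"`, `"brandes_abs"`, `"indellm"`,
#'   `"indellm_abs"`, `"indellm_masked"`.
#' @return A list of class `score_result`: `variant_id`, `method`, `score`,
#'   `orientation` (`"lower_is_pathogenic"` for the signed scores,
#'   `"higher_is_pathogenic"` for the absolute variants), and `components`
#'   (the wild-type and mutant aggregates before subtraction).
#' @examples
#' prov <- synthetic_provider(synthetic_spec(seed = 3))
#' score_variant(protein_variant("v", "ACDEFGHIK", "ACDFGHIK"), prov, "indellm")
#' @export
score_variant <- function(variant, provider, method = "indellm") {
  stopifnot(inherits(variant, "protein_variant"),
            inherits(provider, "plm_provider"))
  method <- match.arg(method, SCORE_METHODS)
  marg <- if (method == "indellm_masked") provider$masked_marginals else
    provider$marginals
  p_wt <- observed_probabilities(marg(variant$wt_sequence), variant$wt_sequence)
  p_mut <- observed_probabilities(marg(variant$mut_sequence), variant$mut_sequence)

  if (method %in% c("brandes", "brandes_abs")) {
    wt_agg <- pll(p_wt)
    mut_agg <- pll(p_mut)
  } else {
    omap <- build_overlap_map(variant)
    keep <- !is.na(p_wt[omap$wt_pos]) & !is.na(p_mut[omap$mut_pos])
    if (!all(keep))
      warning("excluding ", sum(!keep),
              " overlap pair(s) with undefined probability from both sums",
              call. = FALSE)
    wt_agg <- sum(p_wt[omap$wt_pos[keep]])
    mut_agg <- sum(p_mut[omap$mut_pos[keep]])
  }
  score <- mut_agg - wt_agg
  is_abs <- endsWith(method, "_abs")
  structure(list(variant_id = variant$variant_id,
                 method = method,
                 score = if (is_abs) abs(score) else score,
                 orientation = if (is_abs) "higher_is_pathogenic" else
                   "lower_is_pathogenic",
                 components = c(wt = wt_agg, mut = mut_agg)),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result %s> %s = %.4f (%s; wt %.4f, mut %.4f)\n",
              x$variant_id, x$method, x$score, x$orientation,
              x$components[["wt"]], x$components[["mut"]]))
  invisible(x)
}

#' Classify a zero-shot score against a threshold
#'
#' For `lower_is_pathogenic` scores (signed PLL / probability differences) a
#' variant is called pathogenic when its score is strictly below the
#' threshold; for `higher_is_pathogenic` (absolute) scores, strictly above.
#' A score exactly equal to the threshold is called benign. The default
#' threshold -0.59 is the published ROC-optimal operating point of the
#' overlap probability score on the curated clinical indel set; it applies to
#' the `indellm` method and should be refit (see [optimal_threshold()]) for
#' other methods or backends.
#'
#' @param result a `score_result` (or a bare numeric score, in which case
#'   `orientation` must be supplied).
#' @param threshold decision threshold on the score scale.
#' @param orientation asserted orientation; must match the result's.
#' @return `"benign"` or `"pathogenic"`.
#' @export
classify <- function(result, threshold = -0.59, orientation = NULL) {
  if (inherits(result, "score_result")) {
    if (!is.null(orientation) && !identical(orientation, result$orientation))
      stop("OrientationMismatch: result is ", result$orientation,
           " but threshold was supplied as ", orientation, call. = FALSE)
    orientation <- result$orientation
    score <- result$score
  } else {
    if (is.null(orientation))
      stop("orientation required for bare numeric scores", call. = FALSE)
    orientation <- match.arg(orientation,
                             c("lower_is_pathogenic", "higher_is_pathogenic"))
    score <- as.numeric(result)
  }
  pathogenic <- if (orientation == "lower_is_pathogenic") score < threshold
                else score > threshold
  ifelse(pathogenic, "pathogenic", "benign")
}

#' Score a set of variants into a table
#'
#' Applies [crop_variant()] then [score_variant()] to each variant and
#' collects a tidy table, including crop offsets so per-residue tracks can be
#' mapped back to full-sequence coordinates.
#'
#' @param variants list of `protein_variant`.
#' @param provider a `plm_provider`.
#' @param method scoring method, see [score_variant()].
#' @param threshold classification threshold (default the published -0.59 for
#'   signed scores; pass your own for `_abs` methods).
#' @param length_limit,buffer,model_cap forwarded to [crop_variant()].
#' @return data.frame: `variant_id`, `method`, `score`, `wt_component`,
#'   `mut_component`, `call`, `wt_offset`, `mut_offset`.
#' @export
score_variants <- function(variants, provider, method = "indellm",
                           threshold = -0.59, length_limit = 1000L,
                           buffer = 500L, model_cap = 1022L) {
  rows <- lapply(variants, function(v) {
    cr <- crop_variant(v, length_limit, buffer, model_cap)
    res <- score_variant(cr$cropped_variant, provider, method)
    data.frame(variant_id = v$variant_id, method = method,
               score = res$score,
               wt_component = res$components[["wt"]],
               mut_component = res$components[["mut"]],
               call = classify(res, threshold),
               wt_offset = cr$wt_offset, mut_offset = cr$mut_offset,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
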