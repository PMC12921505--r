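# Shared fixtures: a hand-specified provider whose observed probabilities are
# given explicitly, random variant generators for property tests, and
# independent brute-force oracles kept deliberately separate from the package
# implementations they check.

# Provider returning, for each known sequence, a probability matrix in which
# the observed residue at position i carries obs[[seq]][i] and the remaining
# mass is uniform over the other 19 letters. Embeddings may be supplied as
# explicit matrices.
fixed_provider <- function(obs = list(), embeds = list(), embed_dim = 4L) {
  matrix_for <- function(sequence) {
    p <- obs[[sequence]]
    stopifnot(!is.null(p), length(p) == nchar(sequence))
    ch <- strsplit(sequence, "")[[1]]
    m <- matrix((1 - p) / 19, nrow = length(p), ncol = 20L)
    col <- match(ch, AA_ALPHABET)
    ok <- !is.na(col) & !is.na(p)
    m[cbind(which(ok), col[ok])] <- p[ok]
    colnames(m) <- AA_ALPHABET
    m
  }
  plm_provider(
    id = "fixed",
    marginals = matrix_for,
    masked_marginals = matrix_for,
    embed = function(sequence) {
      e <- embeds[[sequence]]
      if (is.null(e)) matrix(0, nchar(sequence), embed_dim) else e
    },
    embed_dim = embed_dim)
}

# The worked deletion fixture used across scoring and interpretability tests:
# wt ACDEF with observed probabilities .9 .8 .5 .7 .6, mut ACEF (D deleted)
# with .9 .7 .6 .5.
deletion_fixture <- function() {
  list(variant = protein_variant("fx1", "ACDEF", "ACEF"),
       provider = fixed_provider(obs = list(
         "ACDEF" = c(0.9, 0.8, 0.5, 0.7, 0.6),
         "ACEF" = c(0.9, 0.7, 0.6, 0.5))))
}

random_aa_string <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                                      collapse = "")

# A random single-indel variant drawn from the current RNG stream.
random_variant <- function(min_len = 10L, max_len = 60L, max_indel = 8L) {
  lw <- sample(min_len:max_len, 1L)
  wt <- random_aa_string(lw)
  kind <- sample(c("deletion", "insertion"), 1L)
  len <- sample.int(min(max_indel, lw - 2L), 1L)
  if (kind == "deletion") {
    start <- sample.int(lw - len + 1L, 1L)
    mut <- paste0(substr(wt, 1L, start - 1L), substr(wt, start + len, lw))
  } else {
    start <- sample.int(lw + 1L, 1L)
    mut <- paste0(substr(wt, 1L, start - 1L), random_aa_string(len),
                  substr(wt, start, lw))
  }
  suppressWarnings(protein_variant(paste0("rv", start, kind, len), wt, mut))
}

# Independent oracle: overlap probability score by an explicit simultaneous
# walk over both sequences, skipping the ANNOTATED indel interval. Never uses
# build_overlap_map.
oracle_indellm <- function(variant, provider) {
  p_wt <- observed_probabilities(provider$marginals(variant$wt_sequence),
                                 variant$wt_sequence)
  p_mut <- observed_probabilities(provider$marginals(variant$mut_sequence),
                                  variant$mut_sequence)
  a <- variant$indel_start
  b <- a + variant$indel_length - 1L
  i <- 1L; j <- 1L          # i walks wt, j walks mut
  acc <- 0
  lw <- nchar(variant$wt_sequence); lm <- nchar(variant$mut_sequence)
  while (i <= lw || j <= lm) {
    if (variant$indel_kind == "deletion" && i >= a && i <= b) {
      i <- i + 1L
      next
    }
    if (variant$indel_kind == "insertion" && j >= a && j <= b) {
      j <- j + 1L
      next
    }
    if (!is.na(p_wt[i]) && !is.na(p_mut[j]))
      acc <- acc + (p_mut[j] - p_wt[i])
    i <- i + 1L; j <- j + 1L
  }
  acc
}

# Brute-force AUC: pairwise concordance over all positive/negative pairs,
# half credit for ties, after orienting scores so larger = more pathogenic.
oracle_auc <- function(scores, labels, orientation) {
  s <- if (orientation == "lower_is_pathogenic") -scores else scores
  pos <- s[labels == 1L]; neg <- s[labels == 0L]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Brute-force Youden threshold: evaluate J over all midpoints between
# adjacent distinct scores plus the observed values, using the package's
# classification rule; returns the best achievable J.
oracle_best_j <- function(scores, labels, orientation) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1L) (head(u, -1) + tail(u, -1)) / 2 else numeric(0)
  cands <- sort(unique(c(u, mids, min(u) - 1, max(u) + 1)))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  j <- vapply(cands, function(t) {
    call <- classify(scores, threshold = t, orientation = orientation)
    sum(call == "pathogenic" & labels == 1L) / np -
      sum(call == "pathogenic" & labels == 0L) / nn
  }, numeric(1))
  max(j)
}
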