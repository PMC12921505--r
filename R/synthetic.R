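# Deterministic synthetic probability/embedding backend and labeled-dataset
# generator. Every stage of the pipeline (scoring, features, training,
# splitting) is testable fully offline against this backend: outputs are a
# pure function of (sequence, seed, injected overrides), bitwise reproducible.

# Evaluate expr under a private RNG stream, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

derive_seed <- function(...) {
  p <- 2147483629
  h <- 17
  for (v in c(...)) h <- (h * 131 + as.numeric(v)) %% p
  as.integer(h)
}

#' Specification for the synthetic backend and dataset generator
#'
#' Collects the knobs of the deterministic synthetic provider: the RNG seed,
#' embedding dimensionality, the Dirichlet-like concentration controlling how
#' peaked per-position distributions are, the weight boost given to the
#' observed residue (so observed probabilities sit in a realistic mid range
#' rather than near 1/20), the bounded jitter distinguishing masked from
#' unmasked marginals, and the two class-signal channels used by
#' [generate_labeled_dataset()]:
#'
#' * `effect_size` — fractional depression of mutant observed probabilities
#'   within `effect_window` residues of the indel for pathogenic variants
#'   (0 = no probability signal);
#' * `embedding_shift` — offset added to the indel-region embedding rows of
#'   pathogenic variants (scalar recycled over dimensions, or a length-`D`
#'   vector; 0 = no embedding signal).
#'
#' @param seed integer RNG seed; identical specs give bitwise identical output.
#' @param embed_dim embedding dimensionality `D`.
#' @param concentration gamma shape for per-row probability draws.
#' @param observed_boost multiplicative weight on the observed residue's cell.
#' @param jitter per-cell relative perturbation bound for masked marginals
#'   (kept at most 0.05).
#' @param constant if non-`NULL`, embeddings are this constant everywhere
#'   (degenerate mode for tests).
#' @param effect_size,embedding_shift class-signal channels, see above.
#' @param effect_window half-width (residues) of the probability-depression
#'   window around the indel.
#' @param class_balance fraction of pathogenic variants.
#' @param insertion_frac fraction of insertions among generated indels.
#' @param max_indel_length generated indel lengths are drawn from
#'   `1:max_indel_length` with geometrically decaying weights, so most indels
#'   are 1-2 residues long as in curated clinical sets.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, embed_dim = 16L, concentration = 0.5,
                           observed_boost = 8, jitter = 0.05, constant = NULL,
                           effect_size = 0, embedding_shift = 0,
                           effect_window = 10L, class_balance = 0.4,
                           insertion_frac = 0.32, max_indel_length = 10L) {
  stopifnot(jitter >= 0, jitter <= 0.05, concentration > 0, observed_boost > 0,
            effect_size >= 0, effect_size < 1,
            class_balance > 0, class_balance < 1)
  structure(list(seed = as.integer(seed), embed_dim = as.integer(embed_dim),
                 concentration = concentration, observed_boost = observed_boost,
                 jitter = jitter, constant = constant,
                 effect_size = effect_size, embedding_shift = embedding_shift,
                 effect_window = as.integer(effect_window),
                 class_balance = class_balance,
                 insertion_frac = insertion_frac,
                 max_indel_length = as.integer(max_indel_length)),
            class = "synthetic_spec")
}

#' Deterministic synthetic probability/embedding backend
#'
#' Builds a [plm_provider] whose marginals, masked marginals and embeddings
#' are pure functions of `(sequence, spec$seed)` plus any injected overrides.
#' Rows are strictly positive and sum to 1; masked marginals are the unmasked
#' matrix perturbed by a seeded bounded jitter (then renormalized), so the two
#' modes are distinct but strongly correlated, mimicking the mild differences
#' seen between single-pass and per-position-masked scoring of real models.
#'
#' Overrides pin the probability of a given residue at a given position of a
#' given sequence (remaining mass is renormalized over the other letters), and
#' embedding shifts add a fixed offset to chosen rows; both are the injection
#' points the dataset generator uses to plant class signal.
#'
#' @param spec a [synthetic_spec()] (or arguments passed to it via `...`).
#' @param ... used to build a spec when `spec` is missing.
#' @return A `plm_provider` (subclass `synthetic_provider`).
#' @examples
#' p <- synthetic_provider(synthetic_spec(seed = 7))
#' m <- p$marginals("ACDEFG")
#' all.equal(rowSums(m), rep(1, 6))
#' @export
synthetic_provider <- function(spec = synthetic_spec(...), ...) {
  stopifnot(inherits(spec, "synthetic_spec"))
  state <- new.env(parent = emptyenv())
  state$overrides <- list()   # key "<hash>:<pos>" -> list(residue=, prob=)
  state$shifts <- list()      # key "<hash>" -> list(positions=, shift=)

  base_matrix <- function(sequence) {
    ch <- seq_chars(sequence)
    L <- length(ch)
    col <- match(ch, AA_ALPHABET)
    with_seed(derive_seed(spec$seed, 11, sequence_hash(sequence)), {
      m <- matrix(stats::rgamma(L * 20L, shape = spec$concentration) + 1e-8,
                  nrow = L, ncol = 20L)
      ok <- !is.na(col)
      m[cbind(which(ok), col[ok])] <- m[cbind(which(ok), col[ok])] *
        spec$observed_boost + spec$concentration * spec$observed_boost
      m / rowSums(m)
    })
  }

  apply_overrides <- function(m, sequence) {
    h <- as.character(sequence_hash(sequence))
    keys <- names(state$overrides)
    if (is.null(keys)) return(m)
    mine <- keys[startsWith(keys, paste0(h, ":"))]
    for (k in mine) {
      ov <- state$overrides[[k]]
      i <- as.integer(sub("^[0-9]+:", "", k))
      j <- match(ov$residue, AA_ALPHABET)
      rest <- setdiff(seq_len(20L), j)
      m[i, rest] <- m[i, rest] * (1 - ov$prob) / sum(m[i, rest])
      m[i, j] <- ov$prob
    }
    m
  }

  colnames_aa <- function(m, sequence) {
    dimnames(m) <- list(NULL, AA_ALPHABET)
    check_prob_matrix(m, sequence)
  }

  provider <- plm_provider(
    id = "synthetic",
    marginals = function(sequence) {
      colnames_aa(apply_overrides(base_matrix(sequence), sequence), sequence)
    },
    masked_marginals = function(sequence) {
      m <- base_matrix(sequence)
      with_seed(derive_seed(spec$seed, 23, sequence_hash(sequence)), {
        f <- matrix(stats::runif(length(m), 1 - spec$jitter, 1 + spec$jitter),
                    nrow = nrow(m))
        m <- m * f
        m <- m / rowSums(m)
      })
      colnames_aa(apply_overrides(m, sequence), sequence)
    },
    embed = function(sequence) {
      L <- nchar(sequence)
      D <- spec$embed_dim
      if (!is.null(spec$constant)) {
        e <- matrix(spec$constant, nrow = L, ncol = D)
      } else {
        e <- with_seed(derive_seed(spec$seed, 37, sequence_hash(sequence)),
                       matrix(stats::rnorm(L * D), nrow = L, ncol = D))
      }
      sh <- state$shifts[[as.character(sequence_hash(sequence))]]
      if (!is.null(sh))
        e[sh$positions, ] <- sweep(e[sh$positions, , drop = FALSE], 2L,
                                   sh$shift, `+`)
      e
    },
    embed_dim = spec$embed_dim)
  provider$spec <- spec
  provider$.state <- state
  class(provider) <- c("synthetic_provider", class(provider))
  provider
}

#' Pin an observed-residue probability in the synthetic backend
#'
#' After the call, `marginals` and `masked_marginals` for `sequence` return
#' exactly `prob` at `(position, residue)`, with the remaining mass
#' renormalized over the other 19 letters.
#'
#' @param provider a `synthetic_provider`.
#' @param sequence the sequence the override applies to.
#' @param position 1-based position.
#' @param residue one-letter amino-acid code.
#' @param prob probability in (0, 1).
#' @export
set_probability_override <- function(provider, sequence, position, residue, prob) {
  stopifnot(inherits(provider, "synthetic_provider"))
  if (!is.finite(prob) || prob <= 0 || prob >= 1)
    stop("InvalidOverride: probability must lie strictly inside (0, 1)",
         call. = FALSE)
  if (!residue %in% AA_ALPHABET)
    stop("InvalidOverride: unknown residue '", residue, "'", call. = FALSE)
  key <- paste0(sequence_hash(sequence), ":", as.integer(position))
  provider$.state$overrides[[key]] <- list(residue = residue, prob = prob)
  invisible(provider)
}

#' Add an embedding offset to chosen rows of a sequence's embedding
#'
#' @param provider a `synthetic_provider`.
#' @param sequence target sequence.
#' @param positions 1-based row indices to shift.
#' @param shift numeric offset, scalar or length-`D`.
#' @export
set_embedding_shift <- function(provider, sequence, positions, shift) {
  stopifnot(inherits(provider, "synthetic_provider"))
  D <- provider$embed_dim
  shift <- rep_len(as.numeric(shift), D)
  provider$.state$shifts[[as.character(sequence_hash(sequence))]] <-
    list(positions = as.integer(positions), shift = shift)
  invisible(provider)
}

random_sequence <- function(length) {
  paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
}

mutate_sequence <- function(sequence, rate) {
  ch <- seq_chars(sequence)
  k <- max(1L, round(rate * length(ch)))
  idx <- sample(length(ch), k)
  ch[idx] <- sample(AA_ALPHABET, k, replace = TRUE)
  paste(ch, collapse = "")
}

#' Generate a labeled synthetic indel dataset with cluster structure
#'
#' Emulates the statistical structure the downstream classifiers must learn:
#' sequence families (ancestors mutated at 10-40% of positions, giving the
#' identity clusters a splitter must keep atomic), mixed insertion/deletion
#' kinds and lengths, and two independent, injectable pathogenicity signals —
#' a depression of mutant observed probabilities around the indel
#' (`effect_size`, visible to zero-shot probability scores) and an offset on
#' indel-region embeddings (`embedding_shift`, visible only to embedding-based
#' classifiers). With both channels at zero, labels are independent of every
#' generated quantity.
#'
#' @param spec a [synthetic_spec()].
#' @param n number of variants (>= 10).
#' @param mean_length mean wild-type sequence length (lengths vary around it).
#' @return A list: `records` (data.frame with `variant_id`, `wt_seq`,
#'   `mut_seq`, `indel_kind`, `indel_start`, `indel_length`, `label`,
#'   `cluster_id`), `variants` (list of `protein_variant`), `clusters`
#'   (named vector `variant_id -> cluster_id`), and `provider` (a
#'   `synthetic_provider` carrying the injected signals).
#' @export
generate_labeled_dataset <- function(spec, n, mean_length = 60L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n < 10L) stop("InvalidSpec: n must be at least 10", call. = FALSE)
  provider <- synthetic_provider(spec)
  len_weights <- 0.5 ^ (seq_len(spec$max_indel_length) - 1L)

  gen <- with_seed(derive_seed(spec$seed, 53), {
    n_fam <- max(3L, as.integer(round(n / 5)))
    ancestors <- vapply(seq_len(n_fam), function(i)
      random_sequence(sample(seq.int(mean_length - 20L, mean_length + 20L), 1L)),
      character(1))
    fam <- sample(rep_len(seq_len(n_fam), n))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      wt <- mutate_sequence(ancestors[fam[i]], stats::runif(1, 0.10, 0.40))
      lw <- nchar(wt)
      kind <- if (stats::runif(1) < spec$insertion_frac) "insertion" else "deletion"
      len <- sample.int(spec$max_indel_length, 1L, prob = len_weights)
      len <- min(len, lw - 2L)
      if (kind == "deletion") {
        start <- sample.int(lw - len + 1L, 1L)
        mut <- paste0(substr(wt, 1L, start - 1L), substr(wt, start + len, lw))
      } else {
        start <- sample.int(lw + 1L, 1L)
        ins <- random_sequence(len)
        mut <- paste0(substr(wt, 1L, start - 1L), ins, substr(wt, start, lw))
      }
      label <- if (stats::runif(1) < spec$class_balance) "pathogenic" else "benign"
      rows[[i]] <- data.frame(
        variant_id = sprintf("synth%04d", i), wt_seq = wt, mut_seq = mut,
        indel_kind = kind, indel_start = start, indel_length = len,
        label = label, cluster_id = sprintf("fam%03d", fam[i]),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  # normalize annotation to the package convention (leftmost placement)
  variants <- lapply(seq_len(nrow(gen)), function(i)
    protein_variant(gen$variant_id[i], gen$wt_seq[i], gen$mut_seq[i],
                    label = gen$label[i]))
  gen$indel_kind <- vapply(variants, `[[`, character(1), "indel_kind")
  gen$indel_start <- vapply(variants, `[[`, integer(1), "indel_start")
  gen$indel_length <- vapply(variants, `[[`, integer(1), "indel_length")

  # plant class signal on pathogenic variants
  shift_on <- any(rep_len(as.numeric(spec$embedding_shift),
                          spec$embed_dim) != 0)
  for (i in which(gen$label == "pathogenic")) {
    v <- variants[[i]]
    if (spec$effect_size > 0) {
      omap <- build_overlap_map(v)
      a_mut <- if (v$indel_kind == "insertion") v$indel_start else
        min(v$indel_start, nchar(v$mut_sequence))
      b_mut <- if (v$indel_kind == "insertion")
        v$indel_start + v$indel_length - 1L else a_mut
      near <- omap$mut_pos[omap$mut_pos >= a_mut - spec$effect_window &
                           omap$mut_pos <= b_mut + spec$effect_window]
      base <- observed_probabilities(provider$marginals(v$mut_sequence),
                                     v$mut_sequence)
      ch <- seq_chars(v$mut_sequence)
      for (p in near) {
        newp <- min(0.999, max(1e-4, base[p] * (1 - spec$effect_size)))
        set_probability_override(provider, v$mut_sequence, p, ch[p], newp)
      }
    }
    if (shift_on) {
      reg <- indel_region(v)
      long_seq <- if (reg$frame == "wt") v$wt_sequence else v$mut_sequence
      set_embedding_shift(provider, long_seq,
                          seq.int(reg$interval[1], reg$interval[2]),
                          spec$embedding_shift)
    }
  }

  clusters <- stats::setNames(gen$cluster_id, gen$variant_id)
  list(records = gen, variants = variants, clusters = clusters,
       provider = provider)
}
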