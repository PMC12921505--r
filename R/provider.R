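# Backend contract for per-position probabilities and per-residue embeddings.
#
# A provider is an S3 object (class "plm_provider") with fields:
#   id                 character backend identifier
#   embed_dim          integer embedding dimensionality D
#   marginals          function(sequence) -> L x 20 row-stochastic matrix
#                      (single unmasked forward pass)
#   masked_marginals   function(sequence) -> L x 20 row-stochastic matrix,
#                      row i from a pass with position i masked
#   embed              function(sequence) -> L x D matrix, one row per
#                      residue (special tokens excluded)
# Probability matrices are restricted to the 20 canonical amino-acid columns
# (AA_ALPHABET order); backends with a larger vocabulary must renormalize the
# canonical mass. Backends are selected by name via `get_backend()`; the
# package ships the deterministic "synthetic" backend, and external adapters
# (e.g. an ESM2-650M wrapper) can be registered at runtime.

#' Create a provider object from backend functions
#'
#' Low-level constructor for probability/embedding backends. Most users want
#' [synthetic_provider()]; this is the extension point for wrapping a real
#' protein language model.
#'
#' @param id backend identifier string.
#' @param marginals,masked_marginals functions `sequence -> L x 20` row-
#'   stochastic matrix with columns in [AA_ALPHABET] order.
#' @param embed function `sequence -> L x D` numeric matrix.
#' @param embed_dim integer D.
#' @return An object of class `plm_provider`.
#' @export
plm_provider <- function(id, marginals, masked_marginals, embed, embed_dim) {
  structure(list(id = id, marginals = marginals,
                 masked_marginals = masked_marginals,
                 embed = embed, embed_dim = as.integer(embed_dim)),
            class = "plm_provider")
}

#' @export
print.plm_provider <- function(x, ...) {
  cat(sprintf("<plm_provider '%s'> embed_dim=%d\n", x$id, x$embed_dim))
  invisible(x)
}

backend_registry <- new.env(parent = emptyenv())

#' Register / fetch a probability backend by name
#'
#' @param name backend name (`"synthetic"` is built in).
#' @param factory function(...) returning a `plm_provider`.
#' @return `get_backend` returns the constructed provider.
#' @rdname backends
#' @export
register_backend <- function(name, factory) {
  stopifnot(is.function(factory))
  assign(name, factory, envir = backend_registry)
  invisible(name)
}

#' @param ... passed to the backend factory.
#' @rdname backends
#' @export
get_backend <- function(name, ...) {
  if (!exists(name, envir = backend_registry, inherits = FALSE))
    stop("BackendUnavailable: no backend registered under '", name, "'",
         call. = FALSE)
  provider <- get(name, envir = backend_registry)(...)
  stopifnot(inherits(provider, "plm_provider"))
  provider
}

check_prob_matrix <- function(m, sequence) {
  L <- nchar(sequence)
  stopifnot(is.matrix(m), nrow(m) == L, ncol(m) == 20L)
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-6))
    stop("probability matrix rows must sum to 1 (max dev ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  invisible(m)
}

#' Observed-residue probabilities
#'
#' Extracts `P(x_i = s_i | s)` — the probability the model assigns to the
#' residue actually present at each position. Positions carrying nonstandard
#' letters (X, U, B, Z) have no defined marginal and are returned as `NA`.
#'
#' @param matrix an `L x 20` probability matrix with columns in [AA_ALPHABET]
#'   order (rows may be named or not).
#' @param sequence the amino-acid string of length `L`.
#' @return Numeric vector of length `L`; `NA` at nonstandard positions.
#' @export
observed_probabilities <- function(matrix, sequence) {
  ch <- seq_chars(sequence)
  if (nrow(matrix) != length(ch))
    stop("LengthMismatch: matrix has ", nrow(matrix), " rows but sequence has ",
         length(ch), " residues", call. = FALSE)
  col <- match(ch, AA_ALPHABET)
  out <- rep(NA_real_, length(ch))
  ok <- !is.na(col)
  out[ok] <- matrix[cbind(which(ok), col[ok])]
  out
}

#' Memoise a provider
#'
#' Wraps a provider so repeated calls on the same sequence reuse the stored
#' result instead of recomputing a forward pass. With `cache_dir` set, results
#' also persist on disk (one RDS per matrix plus a JSON sidecar recording the
#' backend id, sequence hash and mode), so scoring and feature building across
#' sessions never recompute.
#'
#' @param provider a `plm_provider`.
#' @param cache_dir optional directory for the on-disk cache.
#' @return A `plm_provider` with identical contract.
#' @export
cached_provider <- function(provider, cache_dir = NULL) {
  stopifnot(inherits(provider, "plm_provider"))
  mem <- new.env(parent = emptyenv())
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  fetch <- function(mode, sequence) {
    key <- paste0(mode, ":", sequence)
    if (exists(key, envir = mem, inherits = FALSE))
      return(get(key, envir = mem))
    val <- NULL
    h <- sequence_hash(sequence)
    if (!is.null(cache_dir)) {
      f <- file.path(cache_dir, paste0(provider$id, "_", mode, "_", h, ".rds"))
      if (file.exists(f)) val <- readRDS(f)
    }
    if (is.null(val)) {
      val <- provider[[mode]](sequence)
      if (!is.null(cache_dir)) {
        f <- file.path(cache_dir, paste0(provider$id, "_", mode, "_", h, ".rds"))
        saveRDS(val, f)
        jsonlite::write_json(
          list(backend = provider$id, sequence_hash = h, mode = mode,
               length = nchar(sequence)),
          sub("\\.rds$", ".json", f), auto_unbox = TRUE)
      }
    }
    assign(key, val, envir = mem)
    val
  }
  plm_provider(
    id = provider$id,
    marginals = function(sequence) fetch("marginals", sequence),
    masked_marginals = function(sequence) fetch("masked_marginals", sequence),
    embed = function(sequence) fetch("embed", sequence),
    embed_dim = provider$embed_dim)
}

# Deterministic 31-bit polynomial hash of a sequence string; used for cache
# file names and for deriving per-sequence RNG streams in the synthetic
# backend. Stays below 2^31 - 1.
sequence_hash <- function(sequence) {
  p <- 2147483629
  h <- 0
  for (v in utf8ToInt(sequence)) h <- (h * 131 + v) %% p
  as.integer(h)
}
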