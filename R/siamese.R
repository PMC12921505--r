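# Transfer-learning classifier over frozen per-residue embeddings: a Siamese
# network with ONE shared hidden layer (linear D -> 8, LeakyReLU, dropout 0.5
# at train time) applied with tied weights to each sequence representation,
# branch outputs concatenated with any scalar inputs into a 2-node softmax
# head. Trained with cross-entropy / Adam, early-stopped on validation AUC.
#
# Four feature configurations:
#   model 1: mean embedding of the full wt and mut sequences
#   model 2: model 1 + the overlap probability score as a scalar
#   model 3: model 2 + indel type (0 deletion / 1 insertion) and indel length
#   model 4: mean embeddings of the OVERLAP region of wt and mut, the mean
#            embedding of the indel residues of the longer sequence, plus
#            indel type and length (no probability score)

#' Build the feature bundle for one variant
#'
#' @param variant a `protein_variant`.
#' @param provider a `plm_provider`.
#' @param model_id 1-4, see the configurations above.
#' @param indellm_score precomputed overlap probability score; if `NULL` and
#'   the configuration needs it, it is computed from `provider`.
#' @return A list of class `feature_bundle`: `model_id`, `wt_repr`,
#'   `mut_repr`, `indel_repr` (model 4 only, else `NULL`), `scalars` (named
#'   numeric vector, possibly empty), `label`.
#' @export
build_features <- function(variant, provider, model_id,
                           indellm_score = NULL) {
  stopifnot(inherits(variant, "protein_variant"),
            inherits(provider, "plm_provider"),
            model_id %in% 1:4)
  e_wt <- provider$embed(variant$wt_sequence)
  e_mut <- provider$embed(variant$mut_sequence)
  if (nrow(e_wt) != nchar(variant$wt_sequence) ||
      nrow(e_mut) != nchar(variant$mut_sequence))
    stop("ShapeMismatch: embedding rows must align 1:1 with residues",
         call. = FALSE)
  scalars <- numeric(0)
  indel_repr <- NULL
  if (model_id == 4L) {
    omap <- build_overlap_map(variant)
    wt_repr <- colMeans(e_wt[omap$wt_pos, , drop = FALSE])
    mut_repr <- colMeans(e_mut[omap$mut_pos, , drop = FALSE])
    reg <- indel_region(variant)
    e_long <- if (reg$frame == "wt") e_wt else e_mut
    indel_repr <- colMeans(
      e_long[seq.int(reg$interval[1], reg$interval[2]), , drop = FALSE])
  } else {
    wt_repr <- colMeans(e_wt)
    mut_repr <- colMeans(e_mut)
  }
  if (model_id %in% c(2L, 3L)) {
    if (is.null(indellm_score))
      indellm_score <- score_variant(variant, provider, "indellm")$score
    scalars <- c(scalars, indellm_score = indellm_score)
  }
  if (model_id %in% c(3L, 4L)) {
    scalars <- c(scalars,
                 indel_type = as.numeric(variant$indel_kind == "insertion"),
                 indel_length = as.numeric(variant$indel_length))
  }
  structure(list(model_id = as.integer(model_id), wt_repr = wt_repr,
                 mut_repr = mut_repr, indel_repr = indel_repr,
                 scalars = scalars, label = variant$label),
            class = "feature_bundle")
}

#' Build feature bundles for a variant list
#'
#' @inheritParams build_features
#' @param variants list of `protein_variant`.
#' @param scores optional named numeric vector `variant_id -> indellm score`.
#' @return list of `feature_bundle`.
#' @export
build_feature_set <- function(variants, provider, model_id, scores = NULL) {
  lapply(variants, function(v)
    build_features(v, provider, model_id,
                   indellm_score = if (!is.null(scores)) scores[[v$variant_id]]))
}

# Stack bundles into design matrices: one B x D matrix per branch plus a
# B x ns scalar matrix.
stack_rows <- function(bundles, field) {
  tmpl <- bundles[[1]][[field]]
  m <- vapply(bundles, `[[`, tmpl, field)
  if (is.matrix(m)) t(m)
  else matrix(m, ncol = length(tmpl),
              dimnames = list(NULL, names(tmpl)))
}

stack_bundles <- function(bundles) {
  mid <- unique(vapply(bundles, `[[`, integer(1), "model_id"))
  stopifnot(length(mid) == 1L)
  branches <- list(wt = stack_rows(bundles, "wt_repr"),
                   mut = stack_rows(bundles, "mut_repr"))
  if (!is.null(bundles[[1]]$indel_repr))
    branches$indel <- stack_rows(bundles, "indel_repr")
  scalars <- if (length(bundles[[1]]$scalars) > 0)
    stack_rows(bundles, "scalars") else
    matrix(0, nrow = length(bundles), ncol = 0L)
  labels <- vapply(bundles, function(b)
    if (is.null(b$label)) NA_character_ else b$label, character(1))
  list(model_id = mid, branches = branches, scalars = scalars, labels = labels)
}

# Scalar standardization fit on the training split: indel_length is log1p-
# transformed then z-scored; other scalars z-scored. Constant columns are
# centered only.
fit_scaler <- function(scalars) {
  nm <- colnames(scalars)
  log_cols <- which(nm == "indel_length")
  transform <- function(m) {
    if (length(log_cols)) m[, log_cols] <- log1p(m[, log_cols])
    m
  }
  tr <- transform(scalars)
  mu <- if (ncol(tr)) colMeans(tr) else numeric(0)
  sd <- if (ncol(tr)) apply(tr, 2L, stats::sd) else numeric(0)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd, log_cols = log_cols, transform = transform)
}

apply_scaler <- function(scaler, scalars) {
  if (!ncol(scalars)) return(scalars)
  m <- scaler$transform(scalars)
  sweep(sweep(m, 2L, scaler$mu, `-`), 2L, scaler$sd, `/`)
}

lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. branches: list of B x D matrices; weights w: W1 (H x D),
# b1 (H), W2 (2 x (H*nb + ns)), b2 (2). Dropout masks applied when training.
siamese_forward <- function(w, branches, scalars, slope, dropout = NULL) {
  acts <- lapply(branches, function(X) X %*% t(w$W1) + rep(w$b1, each = nrow(X)))
  hidden <- lapply(acts, lrelu, slope = slope)
  if (!is.null(dropout))
    hidden <- Map(function(H, M) H * M / 0.5, hidden, dropout)
  Z <- do.call(cbind, c(hidden, list(scalars)))
  logits <- Z %*% t(w$W2) + rep(w$b2, each = nrow(Z))
  list(acts = acts, hidden = hidden, Z = Z, P = softmax_rows(logits))
}

siamese_backward <- function(w, fw, branches, scalars, y, slope, dropout) {
  B <- nrow(fw$P)
  H <- length(w$b1)
  nb <- length(branches)
  Y <- cbind(1 - y, y)                     # column 2 = pathogenic
  dlog <- (fw$P - Y) / B
  dW2 <- t(dlog) %*% fw$Z
  db2 <- colSums(dlog)
  dZ <- dlog %*% w$W2
  dW1 <- matrix(0, H, ncol(branches[[1]]))
  db1 <- numeric(H)
  for (k in seq_len(nb)) {
    dH <- dZ[, ((k - 1) * H + 1):(k * H), drop = FALSE]
    if (!is.null(dropout)) dH <- dH * dropout[[k]] / 0.5
    dA <- dH * lrelu_grad(fw$acts[[k]], slope)
    dW1 <- dW1 + t(dA) %*% branches[[k]]
    db1 <- db1 + colSums(dA)
  }
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_step <- function(state, w, g, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(w)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, w = w)
}

#' Default training hyperparameters
#'
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param negative_slope LeakyReLU slope for negative inputs.
#' @param hidden hidden-layer width (8 throughout this work).
#' @param dropout hidden-unit dropout rate at train time.
#' @param patience early-stopping patience in epochs (validation AUC).
#' @param max_epochs epoch cap.
#' @return named list.
#' @export
siamese_hyperparams <- function(batch_size = 64L, learning_rate = 1e-3,
                                negative_slope = 0.01, hidden = 8L,
                                dropout = 0.5, patience = 10L,
                                max_epochs = 200L) {
  list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
       negative_slope = negative_slope, hidden = as.integer(hidden),
       dropout = dropout, patience = as.integer(patience),
       max_epochs = as.integer(max_epochs))
}

#' Train the Siamese pathogenicity classifier
#'
#' Embedding inputs are frozen (the upstream language model is never
#' updated); only the shared hidden layer and the softmax head are fit.
#' Training minimizes cross-entropy with Adam; after every epoch the
#' validation AUC of the pathogenic-node probability is recorded, and the
#' weights from the best epoch are restored when no improvement has been seen
#' for `patience` epochs (or at the epoch cap). A fixed `seed` makes the run
#' bit-reproducible (initialization, shuffling and dropout all draw from it).
#'
#' @param train_bundles,val_bundles lists of `feature_bundle` (labels
#'   required) from disjoint record sets.
#' @param hyperparams see [siamese_hyperparams()].
#' @param seed integer seed.
#' @return A list of class `siamese_model`: `weights`, `scaler`, `model_id`,
#'   `hyperparams`, `seed`, `history` (per-epoch validation AUC),
#'   `best_epoch`, `val_auc`.
#' @export
train_classifier <- function(train_bundles, val_bundles,
                             hyperparams = siamese_hyperparams(),
                             seed = 1L) {
  tr <- stack_bundles(train_bundles)
  va <- stack_bundles(val_bundles)
  stopifnot(tr$model_id == va$model_id)
  if (anyNA(tr$labels) || anyNA(va$labels))
    stop("all training and validation bundles need labels", call. = FALSE)
  y_tr <- as.integer(tr$labels == "pathogenic")
  y_va <- as.integer(va$labels == "pathogenic")
  if (length(unique(y_tr)) < 2L)
    stop("DegenerateLabels: training set has a single class", call. = FALSE)
  scaler <- fit_scaler(tr$scalars)
  s_tr <- apply_scaler(scaler, tr$scalars)
  s_va <- apply_scaler(scaler, va$scalars)
  hp <- hyperparams
  D <- ncol(tr$branches[[1]])
  H <- hp$hidden
  nb <- length(tr$branches)
  ns <- ncol(s_tr)

  with_seed(as.integer(seed), {
    w <- list(W1 = matrix(stats::rnorm(H * D, sd = sqrt(2 / D)), H, D),
              b1 = numeric(H),
              W2 = matrix(stats::rnorm(2 * (H * nb + ns),
                                       sd = sqrt(2 / (H * nb + ns))),
                          2, H * nb + ns),
              b2 = numeric(2))
    adam <- list(m = lapply(w, function(x) x * 0),
                 v = lapply(w, function(x) x * 0))
    n <- length(y_tr)
    best <- list(auc = -Inf, w = w, epoch = 0L)
    history <- numeric(0)
    stall <- 0L
    step <- 0L
    for (epoch in seq_len(hp$max_epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = hp$batch_size)) {
        b <- idx[start:min(start + hp$batch_size - 1L, n)]
        Xb <- lapply(tr$branches, function(X) X[b, , drop = FALSE])
        drop_masks <- if (hp$dropout > 0)
          lapply(seq_len(nb), function(k)
            matrix(stats::rbinom(length(b) * H, 1L, 1 - hp$dropout),
                   length(b), H)) else NULL
        fw <- siamese_forward(w, Xb, s_tr[b, , drop = FALSE],
                              hp$negative_slope, drop_masks)
        g <- siamese_backward(w, fw, Xb, s_tr[b, , drop = FALSE], y_tr[b],
                              hp$negative_slope, drop_masks)
        step <- step + 1L
        upd <- adam_step(adam, w, g, hp$learning_rate, step)
        adam <- upd$state; w <- upd$w
      }
      p_va <- siamese_forward(w, va$branches, s_va, hp$negative_slope)$P[, 2L]
      auc <- if (length(unique(y_va)) > 1L)
        roc_and_auc(p_va, y_va, "higher_is_pathogenic")$auc else NA_real_
      history <- c(history, auc)
      if (is.na(auc) || auc > best$auc) {
        best <- list(auc = if (is.na(auc)) best$auc else auc, w = w,
                     epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall > hp$patience) break
      }
    }
    structure(list(weights = best$w, scaler = scaler,
                   model_id = tr$model_id, hyperparams = hp,
                   seed = as.integer(seed), history = history,
                   best_epoch = best$epoch, val_auc = best$auc),
              class = "siamese_model")
  })
}

#' @export
print.siamese_model <- function(x, ...) {
  cat(sprintf("<siamese_model %d> D=%d, best epoch %d/%d, val AUC %.4f\n",
              x$model_id, ncol(x$weights$W1), x$best_epoch, length(x$history),
              x$val_auc))
  invisible(x)
}

#' Predict pathogenicity probability and call
#'
#' Inference is deterministic (dropout off). The probability is the softmax
#' output of the pathogenic node; the default decision threshold 0.46 is the
#' published operating point fitted on the curated clinical set.
#'
#' @param model a `siamese_model`.
#' @param bundles a `feature_bundle` or list of them (same `model_id`).
#' @param threshold call pathogenic when probability is strictly above this.
#' @return data.frame: `pathogenic_probability`, `call`.
#' @export
predict_pathogenicity <- function(model, bundles, threshold = 0.46) {
  if (inherits(bundles, "feature_bundle")) bundles <- list(bundles)
  st <- stack_bundles(bundles)
  if (st$model_id != model$model_id)
    stop("ShapeMismatch: bundles are model ", st$model_id,
         " but classifier is model ", model$model_id, call. = FALSE)
  if (ncol(st$branches[[1]]) != ncol(model$weights$W1))
    stop("ShapeMismatch: embedding dimension differs from training",
         call. = FALSE)
  s <- apply_scaler(model$scaler, st$scalars)
  p <- siamese_forward(model$weights, st$branches, s,
                       model$hyperparams$negative_slope)$P[, 2L]
  data.frame(pathogenic_probability = p,
             call = ifelse(p > threshold, "pathogenic", "benign"),
             stringsAsFactors = FALSE)
}

#' Train replicate models with different initializations
#'
#' @param train_bundles,val_bundles,hyperparams as [train_classifier()].
#' @param test_bundles optional labeled bundles for test metrics.
#' @param n_replicates number of replicate fits (seeds `base_seed + 0:(n-1)`).
#' @param base_seed first seed.
#' @param threshold decision threshold for MCC/F1.
#' @return list: `models`, and `metrics` (data.frame of per-replicate MCC,
#'   F1, AUC on the test set when given, else on validation) plus
#'   `summary` (mean and sd per metric).
#' @export
replicate_runs <- function(train_bundles, val_bundles, test_bundles = NULL,
                           hyperparams = siamese_hyperparams(),
                           n_replicates = 5L, base_seed = 1L,
                           threshold = 0.46) {
  stopifnot(n_replicates >= 1L)
  eval_set <- if (is.null(test_bundles)) val_bundles else test_bundles
  st <- stack_bundles(eval_set)
  y <- as.integer(st$labels == "pathogenic")
  models <- vector("list", n_replicates)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    m <- train_classifier(train_bundles, val_bundles, hyperparams,
                          seed = base_seed + r - 1L)
    pred <- predict_pathogenicity(m, eval_set, threshold)
    cc <- confusion(y, as.integer(pred$call == "pathogenic"))
    auc <- roc_and_auc(pred$pathogenic_probability, y,
                       "higher_is_pathogenic")$auc
    models[[r]] <- m
    rows[[r]] <- data.frame(replicate = r, seed = base_seed + r - 1L,
                            mcc = mcc(cc), f1 = f1(cc), auc = auc)
  }
  metrics <- do.call(rbind, rows)
  summary <- data.frame(
    metric = c("mcc", "f1", "auc"),
    mean = c(mean(metrics$mcc), mean(metrics$f1), mean(metrics$auc)),
    sd = c(stats::sd(metrics$mcc), stats::sd(metrics$f1),
           stats::sd(metrics$auc)))
  summary$sd[is.na(summary$sd)] <- 0
  list(models = models, metrics = metrics, summary = summary)
}

#' Grid search over training hyperparameters
#'
#' Exhaustively trains one model per grid point and returns the configuration
#' with the best validation AUC; ties break toward the smaller learning rate,
#' then the smaller batch size.
#'
#' @param grid data.frame whose columns are hyperparameter names (any of
#'   `batch_size`, `learning_rate`, `negative_slope`, `hidden`, `dropout`,
#'   `patience`, `max_epochs`); one row per configuration.
#' @param train_bundles,val_bundles as [train_classifier()].
#' @param seed training seed (shared across grid points).
#' @return list: `best` (hyperparameter list), `log` (grid with a `val_auc`
#'   column).
#' @export
grid_search <- function(grid, train_bundles, val_bundles, seed = 1L) {
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    stop("EmptyGrid: supply at least one configuration", call. = FALSE)
  aucs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hp <- utils::modifyList(siamese_hyperparams(), as.list(grid[i, , drop = FALSE]))
    aucs[i] <- train_classifier(train_bundles, val_bundles, hp, seed)$val_auc
  }
  log <- cbind(grid, val_auc = aucs)
  ord <- order(-aucs,
               if ("learning_rate" %in% names(grid)) grid$learning_rate else
                 rep(0, nrow(grid)),
               if ("batch_size" %in% names(grid)) grid$batch_size else
                 rep(0, nrow(grid)))
  best <- utils::modifyList(siamese_hyperparams(),
                            as.list(grid[ord[1L], , drop = FALSE]))
  list(best = best, log = log)
}
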