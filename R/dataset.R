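# Labeled-dataset handling: table loading with row-level validation, 4-level
# label binarization, indel size classes, CD-HIT .clstr parsing, and
# cluster-atomic stratified train/validation/test splitting.

normalize_label <- function(x) {
  key <- gsub("[ _]+", "_", tolower(trimws(x)))
  map <- c(benign = "benign", likely_benign = "benign",
           pathogenic = "pathogenic", likely_pathogenic = "pathogenic")
  out <- unname(map[key])
  out
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop("MissingColumn: file is empty", call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE)
}

#' Load a labeled variant table
#'
#' Reads a TSV/CSV with columns `variant_id`, `wt_seq`, `mut_seq` and optional
#' `indel_kind`, `indel_start`, `indel_length`, `label`, `source`,
#' `cluster_id`. Each row is validated into a `protein_variant`; explicit
#' indel annotations take precedence over inference but must be consistent
#' with the sequences. Four-level clinical labels are binarized
#' (likely pathogenic/pathogenic -> pathogenic; likely benign/benign ->
#' benign). Rows that fail validation, and rows with unparseable labels, are
#' reported with reasons — never silently dropped.
#'
#' @param path table path.
#' @return list: `variants` (list of `protein_variant`), `records`
#'   (data.frame of the valid rows with binarized `label`), `failures`
#'   (data.frame `row`, `variant_id`, `reason`).
#' @export
load_records <- function(path) {
  df <- read_table_auto(path)
  required <- c("variant_id", "wt_seq", "mut_seq")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("MissingColumn: ", paste(missing, collapse = ", "), call. = FALSE)
  variants <- list()
  keep <- logical(nrow(df))
  fail <- list()
  labels <- rep(NA_character_, nrow(df))
  for (i in seq_len(nrow(df))) {
    lab <- NULL
    if ("label" %in% names(df) && !is.na(df$label[i]) && nzchar(df$label[i])) {
      lab <- normalize_label(df$label[i])
      if (is.na(lab)) {
        fail[[length(fail) + 1L]] <- data.frame(
          row = i, variant_id = df$variant_id[i],
          reason = paste0("unparseable label '", df$label[i], "'"))
        next
      }
    }
    v <- tryCatch({
      has_annot <- all(c("indel_kind", "indel_start", "indel_length") %in%
                         names(df)) &&
        !is.na(df$indel_kind[i]) && !is.na(df$indel_start[i]) &&
        !is.na(df$indel_length[i])
      suppressWarnings(protein_variant(
        df$variant_id[i], df$wt_seq[i], df$mut_seq[i],
        indel_kind = if (has_annot) df$indel_kind[i],
        indel_start = if (has_annot) df$indel_start[i],
        indel_length = if (has_annot) df$indel_length[i],
        label = lab))
    }, error = function(e) e)
    if (inherits(v, "error")) {
      fail[[length(fail) + 1L]] <- data.frame(
        row = i, variant_id = df$variant_id[i], reason = conditionMessage(v))
    } else {
      keep[i] <- TRUE
      labels[i] <- if (is.null(lab)) NA_character_ else lab
      variants[[length(variants) + 1L]] <- v
    }
  }
  records <- df[keep, , drop = FALSE]
  records$label <- labels[keep]
  records$indel_kind <- vapply(variants, `[[`, character(1), "indel_kind")
  records$indel_start <- vapply(variants, `[[`, integer(1), "indel_start")
  records$indel_length <- vapply(variants, `[[`, integer(1), "indel_length")
  rownames(records) <- NULL
  failures <- if (length(fail)) do.call(rbind, fail) else
    data.frame(row = integer(0), variant_id = character(0),
               reason = character(0))
  if (nrow(failures))
    message(nrow(failures), " row(s) failed validation; see $failures")
  list(variants = variants, records = records, failures = failures)
}

#' Indel size class
#'
#' Indels of 1-2 residues are `"short"`, longer ones `"long"`.
#'
#' @param indel_length integer vector of lengths (>= 1).
#' @return character vector `"short"`/`"long"`.
#' @export
size_class <- function(indel_length) {
  if (any(indel_length < 1L))
    stop("NonPositiveLength: indel lengths must be >= 1", call. = FALSE)
  ifelse(indel_length <= 2L, "short", "long")
}

#' Parse a CD-HIT `.clstr` file
#'
#' Reads the cluster dialect written by CD-HIT (`>Cluster k` headers followed
#' by one member line per sequence, ids wrapped as `>id...`).
#'
#' @param path cluster file path.
#' @return named character vector: `sequence_id -> cluster_id` (cluster ids
#'   are `"cluster_<k>"`).
#' @export
parse_clusters <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1]], ">Cluster"))
    stop("UnknownFormat: expected a '>Cluster' header", call. = FALSE)
  current <- NA_character_
  ids <- character(0); cl <- character(0)
  for (ln in lines) {
    if (startsWith(ln, ">Cluster")) {
      current <- paste0("cluster_", trimws(sub("^>Cluster", "", ln)))
    } else {
      m <- regmatches(ln, regexpr(">[^.]+\\.\\.\\.", ln))
      if (!length(m))
        stop("UnknownFormat: cannot parse member line: ", ln, call. = FALSE)
      id <- sub("^>", "", sub("\\.\\.\\.$", "", m))
      if (id %in% ids)
        stop("DuplicateMember: sequence '", id,
             "' appears in more than one cluster entry", call. = FALSE)
      ids <- c(ids, id); cl <- c(cl, current)
    }
  }
  stats::setNames(cl, ids)
}

record_strata <- function(records) {
  paste(records$indel_kind, size_class(records$indel_length),
        ifelse(is.na(records$label), "unlabeled", records$label), sep = ":")
}

#' Cluster-atomic stratified split assignment
#'
#' Randomly distributes identity clusters over train/validation/test while
#' keeping every cluster whole (no leakage of near-identical sequences across
#' splits) and balancing the eight strata formed by indel type x size class x
#' label. The algorithm is a seeded greedy allocation: clusters are shuffled,
#' then each is assigned to the split with the largest remaining
#' target-normalized deficit over the strata the cluster touches.
#'
#' @param records data.frame with `variant_id`, `indel_kind`, `indel_length`,
#'   `label` (as from [load_records()] or [generate_labeled_dataset()]).
#' @param clusters named vector `variant_id -> cluster_id`; records absent
#'   from it become singleton clusters.
#' @param fractions target split fractions (train, validation, test).
#' @param seed RNG seed; identical seeds give identical assignments.
#' @return A list of class `split_assignment`: `assignment` (named vector
#'   `variant_id -> split`), `fractions`, `seed`.
#' @export
assign_splits <- function(records, clusters = NULL,
                          fractions = c(train = 0.8, validation = 0.1,
                                        test = 0.1),
                          seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  splits <- c("train", "validation", "test")
  fractions <- stats::setNames(as.numeric(fractions), splits)
  ids <- as.character(records$variant_id)
  cl <- if (is.null(clusters)) stats::setNames(rep(NA_character_, length(ids)), ids)
        else clusters[ids]
  miss <- is.na(cl)
  cl[miss] <- paste0("singleton_", ids[miss])
  names(cl) <- ids
  strata <- record_strata(records)
  stratum_levels <- unique(strata)
  n_str <- stats::setNames(as.numeric(table(factor(strata, stratum_levels))),
                           stratum_levels)
  # per-cluster stratum composition
  comp <- table(cl, factor(strata, stratum_levels))
  cluster_ids <- rownames(comp)
  assignment <- stats::setNames(rep(NA_character_, length(ids)), ids)
  cur <- matrix(0, nrow = 3L, ncol = length(stratum_levels),
                dimnames = list(splits, stratum_levels))
  with_seed(as.integer(seed), {
    ord <- sample(length(cluster_ids))
    for (k in ord) {
      cvec <- comp[k, ]
      touched <- cvec > 0
      # deficit of split s over touched strata, normalized by the target
      # fraction so 10% splits compete with the 80% split
      deficit <- vapply(splits, function(s)
        sum((fractions[[s]] * n_str[touched] - cur[s, touched]) /
              fractions[[s]]), numeric(1))
      pick <- splits[which.max(deficit)]
      cur[pick, ] <- cur[pick, ] + cvec
      assignment[cl == cluster_ids[k]] <- pick
    }
  })
  structure(list(assignment = assignment, fractions = fractions,
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  print(table(x$assignment))
  invisible(x)
}

#' Dataset composition summary
#'
#' Counts records by split (or overall) in the layout used for dataset
#' composition tables: total, short/long deletions, short/long insertions,
#' benign, pathogenic.
#'
#' @param records data.frame with `indel_kind`, `indel_length`, `label`.
#' @param assignment optional `split_assignment`.
#' @return data.frame, one row per dataset (Full plus splits when given).
#' @export
summarize_records <- function(records, assignment = NULL) {
  one <- function(df, name) {
    sz <- if (nrow(df)) size_class(df$indel_length) else character(0)
    data.frame(
      dataset = name,
      total = nrow(df),
      short_deletions = sum(df$indel_kind == "deletion" & sz == "short"),
      long_deletions = sum(df$indel_kind == "deletion" & sz == "long"),
      short_insertions = sum(df$indel_kind == "insertion" & sz == "short"),
      long_insertions = sum(df$indel_kind == "insertion" & sz == "long"),
      benign = sum(df$label == "benign", na.rm = TRUE),
      pathogenic = sum(df$label == "pathogenic", na.rm = TRUE))
  }
  out <- one(records, "Full")
  if (!is.null(assignment)) {
    sp <- assignment$assignment[as.character(records$variant_id)]
    for (s in c("train", "validation", "test"))
      out <- rbind(out, one(records[which(sp == s), , drop = FALSE], s))
  }
  rownames(out) <- NULL
  out
}

#' Fallback identity clustering for synthetic data
#'
#' A naive greedy clusterer over shared k-mer content, used only when no
#' CD-HIT output is available (tests and synthetic pipelines): each sequence
#' joins the first existing cluster whose representative shares at least
#' `threshold` of its k-mers, else founds a new cluster.
#'
#' @param sequences named character vector (`id -> sequence`).
#' @param k k-mer size.
#' @param threshold containment fraction for joining a cluster.
#' @return named vector `id -> cluster_id`.
#' @export
kmer_clusters <- function(sequences, k = 4L, threshold = 0.5) {
  kmers <- function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(s)
    unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
  }
  reps <- list()
  out <- character(length(sequences))
  for (i in seq_along(sequences)) {
    km <- kmers(sequences[[i]])
    placed <- FALSE
    for (j in seq_along(reps)) {
      if (mean(km %in% reps[[j]]) >= threshold) {
        out[i] <- names(reps)[j]; placed <- TRUE; break
      }
    }
    if (!placed) {
      cid <- paste0("kmer_cluster_", length(reps) + 1L)
      reps[[cid]] <- km
      out[i] <- cid
    }
  }
  stats::setNames(out, names(sequences))
}
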