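write_toy_table <- function(path, sep = "\t") {
  df <- data.frame(
    variant_id = c("a", "b", "c", "d"),
    wt_seq = c("ACDEF", "ACDEF", "ACDEF", "ACDEF"),
    mut_seq = c("ACEF", "ACDEF", "ACWDEF", "ACF"),
    label = c("Likely pathogenic", "benign", "Benign", "uncertain"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

test_that("table loading validates rows and binarizes labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_toy_table(path)
  suppressMessages(out <- load_records(path))
  # b has identical sequences, d has an unparseable label
  expect_equal(nrow(out$records), 2L)
  expect_equal(out$records$variant_id, c("a", "c"))
  expect_equal(out$records$label, c("pathogenic", "benign"))
  expect_equal(nrow(out$failures), 2L)
  expect_match(out$failures$reason[out$failures$variant_id == "b"], "NoIndel")
  expect_match(out$failures$reason[out$failures$variant_id == "d"],
               "unparseable label")
  # CSV dialect
  csv <- withr::local_tempfile(fileext = ".csv")
  write_toy_table(csv, sep = ",")
  suppressMessages(out2 <- load_records(csv))
  expect_equal(out2$records$variant_id, out$records$variant_id)
})

test_that("missing required columns and empty files are explicit errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(variant_id = "a", wt_seq = "ACD"), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_records(path), "MissingColumn")
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(load_records(empty), "MissingColumn")
})

test_that("size classes split at two residues", {
  expect_equal(size_class(c(1L, 2L, 3L, 10L)),
               c("short", "short", "long", "long"))
  expect_error(size_class(0L), "NonPositiveLength")
})

test_that("CD-HIT cluster files parse into a sequence-to-cluster map", {
  path <- withr::local_tempfile(fileext = ".clstr")
  writeLines(c(">Cluster 0",
               "0\t120aa, >seqA... *",
               "1\t118aa, >seqB... at 82.3%",
               ">Cluster 1",
               "0\t75aa, >seqC... *"), path)
  cl <- parse_clusters(path)
  expect_equal(cl, c(seqA = "cluster_0", seqB = "cluster_0",
                     seqC = "cluster_1"))
  # singleton-only file: as many clusters as sequences
  single <- withr::local_tempfile(fileext = ".clstr")
  writeLines(c(">Cluster 0", "0\t10aa, >s1... *",
               ">Cluster 1", "0\t10aa, >s2... *"), single)
  expect_equal(length(unique(parse_clusters(single))), 2L)
  dup <- withr::local_tempfile(fileext = ".clstr")
  writeLines(c(">Cluster 0", "0\t10aa, >s1... *",
               ">Cluster 1", "0\t10aa, >s1... *"), dup)
  expect_error(parse_clusters(dup), "DuplicateMember")
  bad <- withr::local_tempfile(fileext = ".clstr")
  writeLines("not a cluster file", bad)
  expect_error(parse_clusters(bad), "UnknownFormat")
})

test_that("split assignment is cluster-atomic, seeded, and a partition", {
  spec <- synthetic_spec(seed = 77)
  ds <- generate_labeled_dataset(spec, 300)
  sa <- assign_splits(ds$records, ds$clusters, seed = 5)
  expect_setequal(names(sa$assignment), ds$records$variant_id)
  expect_true(all(sa$assignment %in% c("train", "validation", "test")))
  # atomicity: one split per cluster
  per_cluster <- tapply(sa$assignment[ds$records$variant_id],
                        ds$clusters[ds$records$variant_id],
                        function(x) length(unique(x)))
  expect_true(all(per_cluster == 1L))
  expect_identical(assign_splits(ds$records, ds$clusters, seed = 5)$assignment,
                   sa$assignment)
  expect_false(identical(
    assign_splits(ds$records, ds$clusters, seed = 6)$assignment,
    sa$assignment))
})

test_that("singleton clusters with uniform strata split 8/1/1", {
  records <- data.frame(variant_id = paste0("r", 1:10),
                        indel_kind = "deletion", indel_length = 1L,
                        label = "benign", stringsAsFactors = FALSE)
  sa <- assign_splits(records, clusters = NULL, seed = 1)
  expect_equal(sort(as.integer(table(sa$assignment)), decreasing = TRUE),
               c(8L, 1L, 1L))
})

test_that("one giant cluster forces everything into a single split", {
  records <- data.frame(variant_id = paste0("r", 1:20),
                        indel_kind = "insertion", indel_length = 3L,
                        label = "pathogenic", stringsAsFactors = FALSE)
  clusters <- stats::setNames(rep("big", 20), records$variant_id)
  sa <- assign_splits(records, clusters, seed = 2)
  expect_equal(length(unique(sa$assignment)), 1L)
})

test_that("summaries count the type-size-label composition consistently", {
  records <- data.frame(
    variant_id = paste0("r", 1:4),
    indel_kind = c("deletion", "deletion", "insertion", "insertion"),
    indel_length = c(1L, 5L, 2L, 7L),
    label = c("benign", "pathogenic", "benign", "pathogenic"),
    stringsAsFactors = FALSE)
  s <- summarize_records(records)
  expect_equal(s$total, 4L)
  expect_equal(unlist(s[1, c("short_deletions", "long_deletions",
                             "short_insertions", "long_insertions")],
                      use.names = FALSE), rep(1L, 4))
  expect_equal(s$benign + s$pathogenic, s$total)
  empty <- summarize_records(records[0, ])
  expect_equal(empty$total, 0L)
  expect_equal(empty$benign, 0L)
  # permutation invariance
  s2 <- summarize_records(records[sample(4), ])
  expect_equal(s2, s)
})

test_that("stratum fractions track targets over many seeds", {
  spec <- synthetic_spec(seed = 31)
  ds <- generate_labeled_dataset(spec, 1000)
  strata <- paste(ds$records$indel_kind, size_class(ds$records$indel_length),
                  ds$records$label)
  targets <- c(train = 0.8, validation = 0.1, test = 0.1)
  devs <- numeric(0)
  for (seed in 1:100) {
    sa <- assign_splits(ds$records, ds$clusters, seed = seed)
    sp <- sa$assignment[ds$records$variant_id]
    for (st in unique(strata)) {
      idx <- strata == st
      frac <- table(factor(sp[idx], names(targets))) / sum(idx)
      devs <- c(devs, abs(as.numeric(frac) - targets))
    }
  }
  expect_lt(mean(devs) * 100, 2)   # mean deviation below 2 percentage points
})

test_that("the k-mer fallback clusterer groups sequence families", {
  set.seed(12)
  anc <- random_aa_string(60)
  fam1 <- vapply(1:3, function(i) {
    ch <- strsplit(anc, "")[[1]]
    idx <- sample(60, 5)
    ch[idx] <- sample(AA_ALPHABET, 5, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  other <- random_aa_string(60)
  cl <- kmer_clusters(stats::setNames(c(fam1, other),
                                      c("f1", "f2", "f3", "solo")))
  expect_equal(length(unique(cl[c("f1", "f2", "f3")])), 1L)
  expect_false(cl[["solo"]] == cl[["f1"]])
})
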