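test_that("pairwise identity follows the both-non-gap convention", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 100)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 75)
  expect_equal(pairwise_identity("AC-GT", "ACAGT"), 100)
  # under the all-columns alternative the gap column counts as mismatch
  expect_equal(pairwise_identity("AC-GT", "ACAGT",
                                 denominator = "all_columns"), 80)
  # N matches nothing, including itself
  expect_equal(pairwise_identity("ANGT", "ANGT"), 75)
  expect_error(pairwise_identity("ACGT", "ACG"), "not aligned")
  expect_error(pairwise_identity("--", "AA"), "no comparable")
})

test_that("identity is symmetric, 100 on the diagonal, and matches a
           per-column hand count", {
  set.seed(5)
  aln <- gen_alignment(n_seqs = 4, length = 300, target_identity = 88,
                       seed = 5)
  m <- identity_matrix(aln)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 4))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(m[i, j], oracle_identity(aln[[i]], aln[[j]]))
})

test_that("identity is invariant to a shared fully-gapped column block", {
  a <- "ACGTACGT"; b <- "ACGAACGT"
  expect_equal(pairwise_identity(paste0(a, "----"), paste0(b, "----")),
               pairwise_identity(a, b))
})

test_that("identity matrix requires at least two sequences", {
  expect_error(identity_matrix(c(s1 = "ACGT")), "at least 2")
  two <- as_alignment(c(s1 = "ACGT", s2 = "ACGT"))
  expect_equal(unname(identity_matrix(two)),
               matrix(100, 2, 2))
})

test_that("alignment loading normalizes U to T and checks column counts", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">rna", "ACGU-", ">dna", "ACGT-"), fa)
  aln <- read_alignment(fa)
  expect_equal(unclass(aln)[["rna"]], "ACGT-")
  expect_equal(pairwise_identity(aln[["rna"]], aln[["dna"]]), 100)
  writeLines(c(">a", "ACGT", ">b", "ACG"), fa)
  expect_error(read_alignment(fa), "same column count")
  expect_error(as_alignment(c(a = "ACGT", b = "ACXT")), "characters")
})

test_that("helix-38 deletion detection thresholds on gap fraction", {
  region <- region_annotation("helix38_v6", 2, 10)
  gapped <- paste0("AC", strrep("-", 8), "GT")
  intact <- "ACGTACGTACGT"
  expect_true(detect_helix38_deletion(gapped, region))
  expect_false(detect_helix38_deletion(intact, region))
  # exactly at threshold counts as deleted
  half <- paste0("AC", strrep("-", 4), "ACGT", "GT")
  expect_true(detect_helix38_deletion(half, region))
  expect_error(detect_helix38_deletion("ACGT", region), "exceeds")
  expect_error(region_annotation("r", 5, 5), "start_col < end_col")
})

test_that("cluster labels encode the deletion state", {
  expect_identical(assign_cluster(TRUE), "A")
  expect_identical(assign_cluster(FALSE), "B")
  expect_identical(assign_cluster(c(TRUE, FALSE)), c("A", "B"))
})

test_that("cluster calls recover implanted deletions on synthetic alignments", {
  region <- region_annotation("helix38_v6", 480, 518)
  aln <- gen_alignment(n_seqs = 3, length = 1200, target_identity = 92,
                       deletion_spec = list(seq_ids = "seq_03",
                                            start_col = 480, end_col = 518,
                                            coverage = 0.8),
                       seed = 21)
  calls <- cluster_calls(aln, region)
  expect_equal(calls$cluster, c("B", "B", "A"))
  truth <- attr(aln, "truth")
  expect_equal(truth$facts$deletion$seq_ids, "seq_03")
})

test_that("region annotations round-trip through CSV", {
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(name = "helix38_v6", start_col = 480,
                              end_col = 518), csv, row.names = FALSE)
  regions <- read_region_annotations(csv)
  expect_equal(regions$helix38_v6$end_col, 518L)
})

test_that("alignments and identity matrices write to disk", {
  aln <- gen_alignment(n_seqs = 2, length = 100, target_identity = 95,
                       seed = 2)
  fa <- tempfile(fileext = ".fasta")
  write_alignment(aln, fa)
  expect_equal(unclass(read_alignment(fa)), unclass(aln),
               ignore_attr = TRUE)
  csv <- tempfile(fileext = ".csv")
  write_identity_matrix(identity_matrix(aln), csv)
  m <- as.matrix(utils::read.csv(csv, row.names = 1))
  expect_equal(unname(m), unname(identity_matrix(aln)))
})
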