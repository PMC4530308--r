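test_that("the reference water scenario reproduces the basin columns", {
  w <- gen_water_samples(scenario = "paper-basin")
  jun <- w[w$label == "basin-jun2012", ]
  expect_equal(jun$ph, 7.03)
  expect_equal(jun$temperature_c, 29.6)
  expect_equal(jun$conductivity_ms_cm, 28.9)
  expect_equal(jun$sulfide_uM, 33.1)
  expect_equal(jun$bicarbonate_mM, 2)
  truth <- attr(w, "truth")
  expect_equal(truth$schema, "achrotools-truth/1")
  expect_true(nzchar(truth$citations$calcium_mM))
})

test_that("water generator is seed-deterministic and honours n_samples", {
  a <- gen_water_samples(10, "jitter", seed = 33)
  b <- gen_water_samples(10, "jitter", seed = 33)
  expect_identical(a, b)
  c <- gen_water_samples(10, "jitter", seed = 34)
  expect_false(identical(a$ph, c$ph))
  empty <- gen_water_samples(0, "jitter", seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("label", "ph", "bicarbonate_mM") %in% names(empty)))
})

test_that("sediment generator covers the reference endpoints and bounds", {
  s <- gen_sediment_samples(scenario = "paper")
  expect_equal(s$porosity, c(0.9, 0.9))
  expect_equal(sort(s$avs_umol_per_g), c(0.3, 0.6))
  expect_identical(gen_sediment_samples(5, "jitter", 2),
                   gen_sediment_samples(5, "jitter", 2))
  big <- gen_sediment_samples(10000, "jitter", seed = 9)
  expect_true(all(big$porosity >= 0 & big$porosity <= 1))
})

test_that("marker surveys hit their completeness targets", {
  expect_true(all(gen_marker_survey(1, 50, 1)$present))
  expect_false(any(gen_marker_survey(0, 50, 1)$present))
  sv <- gen_marker_survey(0.8, 1000, 4)
  obs <- completeness(sv)
  se3 <- 3 * sqrt(0.8 * 0.2 / 1000)
  expect_lt(abs(obs - 0.8), se3)
  expect_identical(gen_marker_survey(0.5, 100, 8)$present,
                   gen_marker_survey(0.5, 100, 8)$present)
})

test_that("contig generator produces known length and GC structure", {
  one <- gen_contig_set(500, gc_modes = list(c(0.39, 0.03, 1)), seed = 12)
  expect_true(gc_unimodality(one$gc_fraction)$unimodal)
  two <- gen_contig_set(500, gc_modes = list(c(0.35, 0.02, 1),
                                             c(0.60, 0.02, 1)), seed = 12)
  expect_false(gc_unimodality(two$gc_fraction)$unimodal)
  flat <- gen_contig_set(50, meanlog = log(2000), sdlog = 0, seed = 1)
  expect_equal(n50(flat), 2000)  # all lengths equal
  expect_identical(gen_contig_set(100, seed = 5), gen_contig_set(100, seed = 5))
  # truth sidecar carries the drawn lengths for oracle checks
  truth <- attr(one, "truth")
  expect_equal(oracle_n50(truth$facts$lengths), n50(one))
})

test_that("alignment generator places substitutions by exact count", {
  ident <- gen_alignment(3, 400, 100, seed = 3)
  expect_equal(length(unique(unclass(ident))), 1)  # target 100%: identical

  aln <- gen_alignment(3, 1500, 91, seed = 6)
  truth <- attr(aln, "truth")
  d <- truth$facts$substitutions_per_pair
  expect_equal(d["seq_01", "seq_02"], 135)  # 0.09 x 1500, exact
  expect_equal(d["seq_01", "seq_03"], 135)
  expect_true(abs(d["seq_02", "seq_03"] - 135) <= 1)
  m <- identity_matrix(aln)
  expect_true(all(abs(m[upper.tri(m)] - 91) <= 1 / 15))
  expect_identical(unclass(gen_alignment(3, 1500, 91, seed = 6)),
                   unclass(aln))
})

test_that("deletion implants are exact and detectable", {
  aln <- gen_alignment(2, 600, 95,
                       deletion_spec = list(seq_ids = "seq_02",
                                            start_col = 100, end_col = 138,
                                            coverage = 1), seed = 10)
  region <- region_annotation("helix38_v6", 100, 138)
  expect_true(detect_helix38_deletion(aln[["seq_02"]], region))
  expect_false(detect_helix38_deletion(aln[["seq_01"]], region))
  expect_equal(attr(aln, "truth")$facts$deletion$gapped_columns, 38)
})

test_that("truth sidecars serialize as schema-tagged JSON", {
  sv <- gen_marker_survey(0.8, 20, 2)
  path <- tempfile(fileext = ".json")
  write_truth(sv, path)
  side <- jsonlite::read_json(path)
  expect_equal(side$schema, "achrotools-truth/1")
  expect_equal(side$facts$true_completeness, 0.8)
  expect_error(write_truth(list(), tempfile()), "no truth")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(gen_contig_set(10, seed = 1))
  after <- runif(1)
  expect_identical(before, after)
})
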