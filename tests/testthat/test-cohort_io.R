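test_that("mutation tables round-trip through TSV with validation", {
  co <- small_cohort(seed = 23, n_patients = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(co$mutations, path)
  back <- read_mutation_table(path)
  expect_equal(back, co$mutations)

  # empty file with header reads as an empty table
  write_mutation_table(co$mutations[0, ], path)
  expect_equal(nrow(read_mutation_table(path)), 0)

  # missing required column named in the error
  broken <- co$mutations[, setdiff(names(co$mutations), "t_depth")]
  utils::write.table(broken, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutation_table(path), "t_depth")

  # 0-based input flagged with its line number
  zero <- co$mutations; zero$pos[3] <- 0
  utils::write.table(zero, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutation_table(path), "1-based.*line\\(s\\) 4")
})

test_that("a full cohort round-trips through a directory", {
  co <- small_cohort(seed = 29, n_patients = 2)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$mutations, co$mutations)
  expect_equal(back$metadata, co$metadata)
  expect_equal(back$neoantigens, co$neoantigens, tolerance = 1e-12)
  expect_equal(back$truth$mutations, co$truth$mutations)
})

test_that("gene and pathway frequencies report auditable fractions", {
  tally <- example_cohort_tally()
  syne1 <- mutational_frequency(tally$mutations, "SYNE1", "sample", tally$metadata)
  expect_equal(syne1$numerator, 11)
  expect_equal(syne1$denominator, 30)
  expect_equal(percent_display(syne1$percent), 37)

  wnt <- pathway_patient_frequency(tally$mutations,
                                   c("APC", "AXIN1", "AMER1", "TCF7L2", "KMT2D"),
                                   tally$metadata)
  expect_equal(wnt$percent, 80)
  hgf <- pathway_patient_frequency(tally$mutations, c("KRAS", "COL5A1", "HGF"),
                                   tally$metadata)
  expect_equal(hgf$percent, 60)

  expect_warning(absent <- mutational_frequency(tally$mutations, "NOPE",
                                                "sample", tally$metadata),
                 "not present")
  expect_equal(absent$percent, 0)
  all_units <- mutational_frequency(
    data.frame(sample = c("a", "b"), gene = "X"), "X", "sample")
  expect_equal(all_units$percent, 100)
  expect_error(pathway_patient_frequency(tally$mutations, character(0)), "empty")
  expect_true(syne1$percent >= 0 && syne1$percent <= 100)
})

test_that("group tests agree with exact enumeration oracles", {
  # Fisher on [[2,13],[4,11]]: hypergeometric point-probability sum
  tab <- matrix(c(2, 13, 4, 11), nrow = 2, byrow = TRUE)
  got <- group_compare(tab, test = "fisher")$p_value
  # two-sided Fisher: sum of tables (by first cell a) no more probable
  pa <- function(a) choose(15, a) * choose(15, 6 - a) / choose(30, 6)
  probs <- vapply(max(0, 6 - 15):min(6, 15), pa, numeric(1))
  oracle <- sum(probs[probs <= pa(2) * (1 + 1e-7)])
  expect_equal(got, oracle, tolerance = 1e-10)

  # Wilcoxon on disjoint ranges: exact rank-sum enumeration for small n
  x <- c(1, 2, 3); y <- c(10, 11, 12, 13)
  got_w <- group_compare(c(x, y), rep(c("a", "b"), c(3, 4)), "wilcoxon")
  ranks <- rank(c(x, y))
  stat_obs <- sum(ranks[1:3]) - 3 * 4 / 2
  all_w <- apply(combn(7, 3), 2, function(ix) sum(rank(c(x, y))[ix]) - 6)
  p_exact <- mean(abs(all_w - 6) >= abs(stat_obs - 6)) # center = n1*n2/2
  expect_equal(got_w$p_value, p_exact, tolerance = 1e-10)

  # identical large samples are nowhere near significant
  set.seed(44)
  z <- rnorm(100)
  same <- group_compare(c(z, z), rep(c("a", "b"), each = 100), "wilcoxon")
  expect_gt(same$p_value, 0.9)

  chis <- group_compare(matrix(c(20, 10, 10, 20), 2), test = "chisq")
  expect_lt(chis$p_value, 0.05)
  expect_error(group_compare(matrix(c(0, 0, 5, 5), 2, byrow = TRUE),
                             test = "fisher"), "degenerate")
  expect_error(group_compare(1:5, rep("a", 5), "wilcoxon"), "2 non-empty")
})

test_that("pipeline is deterministic, filters purity, and writes a manifest", {
  co <- small_cohort(seed = 37, n_patients = 2)
  r1 <- run_pipeline(co)
  r2 <- run_pipeline(co)
  expect_identical(r1$mutations, r2$mutations)
  expect_identical(r1$patterns, r2$patterns)
  expect_identical(r1$tmb, r2$tmb)

  # a low-purity sample is excluded and reported
  co2 <- co
  low <- co2$metadata$sample[1]
  co2$metadata$purity[1] <- 0.1
  r3 <- run_pipeline(co2)
  expect_identical(r3$excluded_samples, low)
  expect_false(low %in% r3$mutations$sample)

  empty <- structure(list(mutations = co$mutations[0, ]), class = "paired_cohort")
  expect_error(run_pipeline(empty), "empty cohort")

  dir <- withr::local_tempdir()
  run_pipeline(co, out_dir = dir)
  expect_true(file.exists(file.path(dir, "run_manifest.json")))
  expect_true(file.exists(file.path(dir, "mutations_ccf.tsv")))
  expect_true(any(grepl("^tree_.*\\.nwk$", list.files(dir))))
  manifest <- jsonlite::read_json(file.path(dir, "run_manifest.json"))
  expect_identical(manifest$package, "clonemet")
  expect_true(!is.null(manifest$config$min_purity))
})
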