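test_that("match_mutations partitions variants into shared and private", {
  a <- rbind(mut_row("p", 1, 100, clonality = "clonal", ccf_hat = 1),
             mut_row("p", 2, 200, clonality = "subclonal", ccf_hat = 0.3))
  b <- a; b$sample <- "m"; b$lesion <- "metastasis"

  same <- match_mutations(a, b)
  expect_true(all(same$shared))
  expect_equal(nrow(same), 2)

  disjoint <- match_mutations(a, mut_row("m", 3, 300, lesion = "metastasis"))
  expect_false(any(disjoint$shared))
  expect_equal(nrow(disjoint), 3)

  one_empty <- match_mutations(a[0, ], b)
  expect_true(all(one_empty$status_primary == "absent"))

  dup <- rbind(a, a[1, ])
  expect_error(match_mutations(dup, b), "duplicate variant keys")

  # partition invariant: shared + private = total distinct variants
  pr <- pattern_proportions(disjoint)
  expect_equal(sum(pr), 1)
})

test_that("pattern labels concatenate the C/S/0 lesion codes", {
  expect_identical(classify_pattern("subclonal", "clonal"), "S-C")
  expect_identical(classify_pattern("absent", "clonal"), "0-C")
  expect_identical(classify_pattern("clonal", "clonal"), "C-C")
  expect_identical(classify_pattern(c("clonal", "subclonal"),
                                    c("absent", "subclonal")),
                   c("C-0", "S-S"))
  expect_error(classify_pattern("absent", "absent"), "absent in both")
  expect_error(classify_pattern("clonal", "weird"), "statuses")
})

test_that("shared/private proportions are exact fractions", {
  mk <- function(sp, sm) data.frame(
    variant_key = sprintf("k%d", seq_along(sp)), gene = "g",
    status_primary = sp, status_metastasis = sm,
    ccf_primary = NA_real_, ccf_metastasis = NA_real_,
    shared = sp != "absent" & sm != "absent", stringsAsFactors = FALSE)
  p <- pattern_proportions(mk(c("clonal", "clonal", "absent", "absent"),
                              c("clonal", "absent", "clonal", "clonal")))
  expect_equal(unname(p), c(0.25, 0.25, 0.50))
  all_shared <- pattern_proportions(mk(rep("clonal", 10), rep("clonal", 10)))
  expect_equal(unname(all_shared), c(1, 0, 0))
  empty <- mk("clonal", "clonal")[0, ]
  expect_error(pattern_proportions(empty), "empty")
})

test_that("median CCF ranks early events first with stable ties", {
  m <- rbind(mut_row("p", 1, 1, gene = "A", ccf_hat = 1.0),
             mut_row("p", 1, 2, gene = "A", ccf_hat = 1.0),
             mut_row("p", 1, 3, gene = "B", ccf_hat = 0.4),
             mut_row("p", 1, 4, gene = "C", ccf_hat = 0.4))
  r <- median_ccf_ranking(m, "primary")
  expect_identical(r$gene, c("A", "B", "C"))   # tie B/C broken lexicographically
  expect_equal(r$median_ccf, c(1.0, 0.4, 0.4))
  expect_identical(r$rank, 1:3)
  one <- median_ccf_ranking(mut_row("p", 1, 9, gene = "Z", ccf_hat = 1), "primary")
  expect_identical(one$rank, 1L)
})

test_that("recurrent pattern genes respect the min-sample floor", {
  cp <- data.frame(
    patient = c("P1", "P2", "P3", "P1"),
    gene = c("KRAS", "KRAS", "SYNE1", "APC"),
    pattern = c("S-C", "S-C", "S-C", "C-C"), stringsAsFactors = FALSE)
  expect_identical(recurrent_pattern_genes(cp, "S-C", 2)$gene, "KRAS")
  expect_setequal(recurrent_pattern_genes(cp, "S-C", 1)$gene, c("KRAS", "SYNE1"))
  expect_equal(nrow(recurrent_pattern_genes(cp, "C-S", 1)), 0)
})

test_that("arm calls use length-weighted means and fixed thresholds", {
  arms <- data.frame(chrom = "1", arm = c("1p", "1q"),
                     start = c(1, 1001), end = c(1000, 2000))
  seg <- function(start, end, lr) data.frame(
    sample = "s", chrom = "1", start = start, end = end, log2_ratio = lr)

  flat <- arm_level_call(seg(1, 2000, 0), arms)
  expect_true(all(flat$direction == "neutral"))

  gain <- arm_level_call(seg(1, 1000, log2(3 / 2)), arms)
  expect_identical(gain$direction[gain$arm == "1p"], "amp")

  cancel <- arm_level_call(rbind(seg(1, 500, 0.6), seg(501, 1000, -0.6)), arms)
  expect_identical(cancel$direction[cancel$arm == "1p"], "neutral")
  expect_equal(cancel$mean_log2[cancel$arm == "1p"], 0)

  # invariance to segment splitting
  whole <- arm_level_call(seg(1, 1000, 0.35), arms)
  split2 <- arm_level_call(rbind(seg(1, 500, 0.35), seg(501, 1000, 0.35)), arms)
  expect_equal(whole, split2)

  # uncovered arm omitted
  expect_false("1q" %in% gain$arm[gain$arm == "1q" & FALSE])
  only_p <- arm_level_call(seg(1, 1000, 0.3), arms)
  expect_identical(only_p$arm, "1p")
})

test_that("scna_ccf inverts the copy-ratio model exactly at zero noise", {
  expect_equal(scna_ccf(log2(3 / 2), 1, 1), 1.0)
  expect_equal(scna_ccf(0, 1, 1), 0)
  expect_equal(scna_ccf(log2(2.5 / 2), 1, 1), 0.5)
  set.seed(2)
  for (i in 1:25) {
    f <- runif(1); purity <- runif(1, 0.2, 1); delta <- sample(c(-1, 1), 1)
    lr <- log2((purity * (2 + f * delta) + (1 - purity) * 2) / 2)
    expect_equal(scna_ccf(lr, purity, delta), f, tolerance = 1e-10)
  }
  expect_error(scna_ccf(0.1, 1, 0), "delta_cn")
})

test_that("arm pattern table labels paired arm events like SNVs", {
  arms <- hg19_arms()
  mk_seg <- function(sample, arm_events) {
    do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
      a <- arms[i, ]
      lr <- if (a$arm %in% names(arm_events)) arm_events[[a$arm]] else 0
      data.frame(sample = sample, chrom = a$chrom, start = a$start,
                 end = a$end, log2_ratio = lr)
    }))
  }
  # 8q gain clonal in both; 17p loss absent in primary, clonal in metastasis
  p <- mk_seg("p", c("8q" = log2(3 / 2)))
  m <- mk_seg("m", c("8q" = log2(3 / 2), "17p" = log2(1 / 2)))
  ap <- arm_pattern_table(p, m, 1, 1)
  expect_identical(ap$pattern[ap$arm == "8q"], "C-C")
  expect_identical(ap$direction[ap$arm == "8q"], "amp")
  expect_identical(ap$pattern[ap$arm == "17p"], "0-C")
  expect_identical(ap$direction[ap$arm == "17p"], "del")
  expect_false("1p" %in% ap$arm)
})

test_that("hypergeometric enrichment matches closed forms and brute force", {
  uni <- sprintf("g%d", 1:100)
  full <- gene_set_enrichment(uni[1:5], list(s = uni[1:5], all = uni), uni)
  expect_equal(full$p_value[full$set == "s"], 1 / choose(100, 5))
  expect_equal(full$p_value[full$set == "all"], 1)

  # empty overlap: the tail probability is the trivial bound
  res <- gene_set_enrichment(uni[1:10], list(s = uni[90:99]), uni)
  expect_equal(res$overlap, 0)
  expect_equal(res$p_value, 1)

  # partial overlap: brute-force hypergeometric tail sum oracle
  res2 <- gene_set_enrichment(uni[1:10], list(s = uni[9:13]), uni)
  brute <- sum(vapply(2:5, function(k)
    choose(5, k) * choose(95, 10 - k) / choose(100, 10), numeric(1)))
  expect_equal(res2$overlap, 2)
  expect_equal(res2$p_value, brute, tolerance = 1e-12)

  expect_error(gene_set_enrichment(c("zzz"), list(s = uni[1:3]), uni), "subset")
  expect_warning(gene_set_enrichment(uni[1:3], list(s = c(uni[1:3], "zzz")), uni),
                 "intersecting")
})
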