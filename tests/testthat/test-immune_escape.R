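md1 <- data.frame(sample = "S1", patient = "P1", lesion = "primary",
                  purity = 0.8, stringsAsFactors = FALSE)

test_that("HLA-LOH needs both the copy-number and the significance condition", {
  set.seed(31)
  # clear one-allele loss: minor CN ~ 0, difference highly significant
  lost <- call_hla_loh(hla_bins(1, 0, 0.8), md1)
  expect_true(lost$is_loh)
  expect_lt(lost$minor_cn, 0.5)
  expect_lt(lost$p_value, 0.01)
  expect_identical(lost$lost_allele, "HLA-A*02")

  # balanced alleles: CN guard fails regardless of p
  bal <- call_hla_loh(hla_bins(1, 1, 0.8), md1)
  expect_false(bal$is_loh)
  expect_gte(bal$minor_cn, 0.5)
  expect_true(is.na(bal$lost_allele))

  # significant imbalance but minor CN above 0.5 (2 vs 1 copies): no LOH
  imb <- call_hla_loh(hla_bins(2, 1, 0.8, n_bins = 40, depth = 400), md1)
  expect_lt(imb$p_value, 0.01)
  expect_gte(imb$minor_cn, 0.5)
  expect_false(imb$is_loh)

  few <- hla_bins(1, 0, 0.8)[1:4, ]
  expect_error(call_hla_loh(few, md1), ">= 5")
})

test_that("LOH caller has the specified operating characteristics", {
  set.seed(202)
  hits <- vapply(1:80, function(i)
    call_hla_loh(hla_bins(1, 0, 0.5),
                 data.frame(sample = "S1", purity = 0.5))$is_loh, logical(1))
  expect_gte(mean(hits), 0.95)
  fps <- vapply(1:80, function(i)
    call_hla_loh(hla_bins(1, 1, 0.5),
                 data.frame(sample = "S1", purity = 0.5))$is_loh, logical(1))
  expect_lte(mean(fps), 0.05)
})

test_that("LOH incidence counts patients once", {
  md <- do.call(rbind, lapply(sprintf("P%d", 1:15), function(p) data.frame(
    patient = p, sample = paste0(p, c("_primary", "_metastasis")),
    lesion = c("primary", "metastasis"), purity = 0.6)))
  calls <- data.frame(sample = md$sample, is_loh = FALSE)
  calls$is_loh[calls$sample %in% c("P1_primary", "P1_metastasis",
                                   "P2_metastasis", "P3_metastasis",
                                   "P4_metastasis")] <- TRUE
  inc <- loh_incidence(calls, md)
  expect_equal(inc$positive, 4)
  expect_equal(inc$percent, 100 * 4 / 15)
  expect_equal(loh_incidence(calls, md, "primary")$positive, 1)
  expect_equal(loh_incidence(calls, md, "metastasis")$positive, 4)
  none <- calls; none$is_loh <- FALSE
  expect_equal(loh_incidence(none, md)$percent, 0)
  all_pos <- calls; all_pos$is_loh <- TRUE
  expect_equal(loh_incidence(all_pos, md)$percent, 100)
  expect_error(loh_incidence(calls, md[0, ]), "no patients")
})

test_that("depth filter reproduces the boundary behaviour exhaustively", {
  grid <- expand.grid(nd = c(4, 5, 6), nv = c(0.01, 0.02, 0.03),
                      td = c(8, 9, 10, 11), tv = c(0.39, 0.40, 0.41))
  recs <- data.frame(dna_normal_depth = grid$nd, dna_normal_vaf = grid$nv,
                     dna_tumor_depth = grid$td, dna_tumor_vaf = grid$tv)
  kept <- depth_filter_variants(recs)
  expected <- !(grid$nd <= 5 & grid$nv >= 0.02) & grid$td >= 10 & grid$tv >= 0.40
  expect_identical(nrow(kept), sum(expected))
  expect_identical(rownames(kept), rownames(recs)[expected])
  # idempotent
  expect_identical(depth_filter_variants(kept), kept)
  expect_error(depth_filter_variants(recs, normal_cov_cutoff = 25), "20")
})

test_that("expression calls honour the 5-read / 3-alt-read rule", {
  grid <- expand.grid(depth = 3:6, alt = 2:4)
  got <- call_expressed(grid$depth, pmin(grid$alt, grid$depth))
  expect_identical(got, grid$depth >= 5 & pmin(grid$alt, grid$depth) >= 3)
  expect_identical(call_expressed(5, 3), TRUE)
  expect_identical(call_expressed(4, 3), FALSE)
  expect_identical(call_expressed(20, 2), FALSE)
  expect_true(is.na(call_expressed(NA, 3)))
})

test_that("neoantigen summary counts and correlation behave", {
  mk <- function(sample, n_total, n_nonexpr) data.frame(
    sample = sample,
    clonality = rep(c("clonal", "subclonal"), length.out = n_total),
    expressed = c(rep(FALSE, n_nonexpr), rep(TRUE, n_total - n_nonexpr)))
  # non-expressed == total: perfect linearity
  recs <- rbind(mk("a", 10, 10), mk("b", 20, 20), mk("c", 5, 5))
  s <- neoantigen_summary(recs)
  expect_equal(s$correlation$r, 1)
  # constant totals: undefined, reported missing
  const <- rbind(mk("a", 10, 3), mk("b", 10, 6), mk("c", 10, 9))
  expect_true(is.na(neoantigen_summary(const)$correlation$r))
  # generic table matches the closed-form Pearson formula
  set.seed(6)
  sizes <- c(8, 15, 23, 31, 12)
  nonex <- c(5, 9, 16, 20, 7)
  recs3 <- do.call(rbind, Map(mk, sprintf("s%d", 1:5), sizes, nonex))
  r_hat <- neoantigen_summary(recs3)$correlation$r
  num <- sum((sizes - mean(sizes)) * (nonex - mean(nonex)))
  den <- sqrt(sum((sizes - mean(sizes))^2) * sum((nonex - mean(nonex))^2))
  expect_equal(r_hat, num / den)
  # fewer than 3 samples: missing
  expect_true(is.na(neoantigen_summary(mk("a", 5, 2))$correlation$r))
  # unknown expression excluded from expression counts
  u <- mk("a", 4, 2); u$expressed[1] <- NA
  cnt <- neoantigen_summary(u)$counts
  expect_equal(cnt$expressed + cnt$non_expressed, 3)
})

test_that("HLA-corrected TMB subtracts mutations presentable only by lost alleles", {
  muts <- do.call(rbind, lapply(1:10, function(i)
    mut_row("S1", 1, i * 10, clonality = if (i <= 6) "clonal" else "subclonal")))
  key <- paste(muts$chrom, muts$pos, muts$ref, muts$alt, sep = ":")
  # 3 mutations bind only the lost allele; 1 binds lost + kept; rest unbound
  neo <- data.frame(
    sample = "S1",
    variant_key = c(key[1], key[2], key[3], key[4], key[4]),
    hla_allele = c("HLA-A*02", "HLA-A*02", "HLA-A*02", "HLA-A*02", "HLA-B*01"),
    binding_rank = 0.5)
  loh <- data.frame(sample = "S1", hla_gene = "A", minor_cn = 0.1,
                    p_value = 1e-5, is_loh = TRUE, lost_allele = "HLA-A*02")
  rep <- hla_corrected_tmb(muts, neo, loh)
  expect_equal(rep$tmb_total, 10)
  expect_equal(rep$tmb_hla_corrected, 7)
  expect_equal(rep$tmb_clonal + rep$tmb_subclonal, rep$tmb_total)

  # no LOH anywhere: corrected equals total
  rep0 <- hla_corrected_tmb(muts, neo, loh[0, ])
  expect_equal(rep0$tmb_hla_corrected, rep0$tmb_total)

  # every mutation binds only the lost allele
  neo_all <- data.frame(sample = "S1", variant_key = key,
                        hla_allele = "HLA-A*02", binding_rank = 0.5)
  rep_all <- hla_corrected_tmb(muts, neo_all, loh)
  expect_equal(rep_all$tmb_hla_corrected, 0)

  # weak binders (rank > 2) never trigger the correction
  neo_weak <- neo; neo_weak$binding_rank <- 10
  expect_equal(hla_corrected_tmb(muts, neo_weak, loh)$tmb_hla_corrected, 10)

  # per-Mb normalisation
  rep_mb <- hla_corrected_tmb(muts, neo, loh, capture_mb = 53)
  expect_equal(rep_mb$tmb_total_per_mb, 10 / 53)
})

test_that("TMB invariants hold on a synthetic cohort", {
  co <- small_cohort(seed = 19)
  res <- run_pipeline(co)
  expect_true(all(res$tmb$tmb_clonal + res$tmb$tmb_subclonal == res$tmb$tmb_total))
  expect_true(all(res$tmb$tmb_hla_corrected <= res$tmb$tmb_total))
})
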