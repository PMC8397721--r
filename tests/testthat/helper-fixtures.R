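# shared fixtures, built in code at test time

# small cohort reused across tests (2 patients, default template)
small_cohort <- function(seed = 42, n_patients = 2, ...) {
  simulate_cohort(sim_config(n_patients = n_patients, seed = seed, ...))
}

# minimal mutation table rows for hand-built cases
mut_row <- function(sample, chrom, pos, ref = "A", alt = "T", gene = "G1",
                    lesion = "primary", patient = "P1", t_alt = 30,
                    t_depth = 100, purity = 1, cn_major = 1, cn_minor = 1,
                    clonality = NULL, ccf_hat = NULL) {
  out <- data.frame(patient = patient, sample = sample, lesion = lesion,
                    gene = gene, chrom = as.character(chrom), pos = pos,
                    ref = ref, alt = alt, t_alt = t_alt, t_depth = t_depth,
                    n_alt = 0L, n_depth = 100L, cn_major = cn_major,
                    cn_minor = cn_minor, purity = purity,
                    stringsAsFactors = FALSE)
  if (!is.null(clonality)) out$clonality <- clonality
  if (!is.null(ccf_hat)) out$ccf_hat <- ccf_hat
  out
}

# independent grid-posterior oracle for estimate_ccf, written from the
# definition: binomial pmf evaluated in log space via lchoose, flat prior
oracle_ccf_posterior <- function(t_alt, t_depth, purity, cn_tumor,
                                 multiplicity, grid_step = 0.01) {
  grid <- seq(0, 1, by = grid_step)
  vaf <- grid * purity * multiplicity /
    (purity * cn_tumor + (1 - purity) * 2)
  vaf <- pmin(vaf, 1)
  ll <- lchoose(t_depth, t_alt) + ifelse(
    vaf == 0, ifelse(t_alt == 0, 0, -Inf),
    t_alt * log(vaf) + (t_depth - t_alt) * log1p(-vaf))
  ll[vaf == 1 & t_alt == t_depth] <- 0
  w <- exp(ll - max(ll))
  post <- w / sum(w)
  # HPD: admit grid points by descending density until 0.95 mass
  ord <- order(post, decreasing = TRUE)
  k <- which(cumsum(post[ord]) >= 0.95)[1]
  list(grid = grid, post = post,
       mode = grid[which.max(post)],
       lo = grid[min(ord[1:k])],
       hi = grid[max(ord[1:k])])
}

# independent minimum parsimony score via phangorn: enumerate every
# unrooted topology and take the minimum Fitch score
oracle_min_parsimony <- function(mat) {
  pd <- phangorn::phyDat(t(mat), type = "USER", levels = c(0, 1))
  trees <- phangorn::allTrees(ncol(mat), rooted = FALSE,
                              tip.label = colnames(mat))
  min(vapply(trees, function(tr) phangorn::fitch(tr, pd), numeric(1)))
}

# random binary character matrix with a normal outgroup column
random_matrix <- function(n_leaves, n_variants) {
  repeat {
    m <- matrix(rbinom((n_leaves - 1) * n_variants, 1, 0.5),
                nrow = n_variants)
    m <- cbind(m, 0L)
    colnames(m) <- c(sprintf("S%d", seq_len(n_leaves - 1)), "normal")
    rownames(m) <- sprintf("v%d", seq_len(n_variants))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) >= 2) return(m)
  }
}

# deterministic-ish HLA bin table for one sample/gene from true copy numbers
hla_bins <- function(cn1, cn2, purity, n_bins = 20, depth = 150,
                     sample = "S1", gene = "A") {
  bins <- simulate_hla_coverage(cn1, cn2, purity, n_bins, depth)
  cbind(data.frame(sample = sample, hla_gene = gene,
                   allele1 = sprintf("HLA-%s*01", gene),
                   allele2 = sprintf("HLA-%s*02", gene),
                   stringsAsFactors = FALSE),
        bins)
}
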