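test_that("compute_maf counts minor alleles and flags relabels", {
  expect_equal(as.numeric(compute_maf(c(0, 0, 0, 0))), 0)
  expect_equal(as.numeric(compute_maf(c(1, 1, 1, 1))), 0.5)
  m <- compute_maf(c(2, 2, 1, 0))
  expect_equal(as.numeric(m), 0.375)   # 5/8 coded allele -> flipped to 3/8
  expect_true(attr(m, "swapped"))
  expect_false(attr(compute_maf(c(0, 1, 0)), "swapped"))
  expect_equal(as.numeric(compute_maf(c(1, NA, 0, 1))), 1 / 3)
  expect_error(compute_maf(c(NA, NA)), "missing")
})

test_that("exact HWE test reproduces the Levene enumeration", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  expect_equal(hwe_exact_test(100, 0, 0), 1)  # monomorphic convention
  expect_error(hwe_exact_test(-1, 2, 0), ">= 0")
  # symmetric in which homozygote is the minor one
  expect_equal(hwe_exact_test(5, 10, 85), hwe_exact_test(85, 10, 5))
})

test_that("exact HWE test approaches the chi-square test for large balanced counts", {
  chisq_hwe <- function(n_AA, n_Aa, n_aa) {
    n <- n_AA + n_Aa + n_aa
    p <- (2 * n_AA + n_Aa) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    pchisq(sum((c(n_AA, n_Aa, n_aa) - e)^2 / e), df = 1, lower.tail = FALSE)
  }
  for (counts in list(c(250, 500, 250), c(360, 480, 160), c(500, 380, 120))) {
    expect_lt(abs(hwe_exact_test(counts[1], counts[2], counts[3]) -
                    chisq_hwe(counts[1], counts[2], counts[3])), 0.01)
  }
})

test_that("QC filters remove SNPs for the documented reasons", {
  # col 1: MAF 0.04; col 2: HWE violation; col 3: one missing call; col 4: clean
  n <- 100
  d <- cbind(c(rep(1, 8), rep(0, 92)),
             c(rep(0, 50), rep(2, 50)),
             c(NA, rep(c(0, 1, 1, 0), 24), 0, 1, 0),
             rep(c(0, 1, 2, 1), 25))
  g <- mdr_geno(d, snp_info = tibble::tibble(snp_id = paste0("s", 1:4)))
  res <- apply_qc_filters(g)
  expect_identical(res$report$removal_reason,
                   c("maf", "hwe", "missing", "none"))
  expect_identical(res$geno$snp_info$snp_id, "s4")
  # reasons are mutually exclusive and cover every input SNP
  expect_identical(nrow(res$report), 4L)
  expect_identical(sum(res$report$pass) +
                     sum(res$report$removal_reason != "none"), 4L)
  # idempotence on the already-filtered matrix
  res2 <- apply_qc_filters(res$geno)
  expect_identical(res2$geno$dosage, res$geno$dosage)
  expect_true(all(res2$report$pass))
})

test_that("QC relabels major-allele-coded columns to minor dosage", {
  d <- cbind(rep(c(2, 2, 1, 2), 25), rep(c(0, 1, 2, 1), 25))
  g <- mdr_geno(d, snp_info = tibble::tibble(
    snp_id = c("a", "b"), major_allele = c("G", "C"),
    minor_allele = c("A", "T")))
  res <- apply_qc_filters(g)
  expect_true(res$geno$snp_info$swapped[1])
  expect_identical(res$geno$snp_info$major_allele[1], "A")
  expect_identical(unname(res$geno$dosage[, 1]), as.integer(2 - d[, 1]))
  expect_false(res$geno$snp_info$swapped[2])
})

test_that("pairwise r2 is symmetric and coding-flip invariant", {
  g <- simulate_genotypes(sim_config(n_subjects = 5000, n_snps = 2, seed = 42))
  expect_equal(pairwise_r2(g, 1, 1), 1)
  expect_equal(pairwise_r2(g, 1, 2), pairwise_r2(g, 2, 1))
  flipped <- g
  flipped$dosage[, 2] <- 2L - flipped$dosage[, 2]
  expect_equal(pairwise_r2(flipped, 1, 2), pairwise_r2(g, 1, 2))
  d2 <- g$dosage
  d2[, 2] <- 2L - d2[, 1]
  expect_equal(pairwise_r2(d2, 1, 2), 1)
  expect_lt(pairwise_r2(g, 1, 2), 0.01)
  mono <- mdr_geno(cbind(rep(0L, 10), rep(c(0L, 1L), 5)))
  expect_error(pairwise_r2(mono, 1, 2), "monomorphic")
})

test_that("duplicate pruning keeps the earliest input position", {
  base <- rep(c(0L, 1L, 2L, 1L), 10)
  other <- rep(c(2L, 0L, 1L, 1L), 10)
  d <- cbind(base, base, other, base)
  g <- mdr_geno(d, snp_info = tibble::tibble(snp_id = c("z9", "a1", "m5", "b2")))
  res <- prune_duplicate_snps(g)
  # three identical columns: the first by input order survives, despite
  # 'a1' and 'b2' preceding 'z9' alphabetically
  expect_identical(res$geno$snp_info$snp_id, c("z9", "m5"))
  expect_identical(res$report$removal_reason,
                   c("none", "duplicate_r2", "none", "duplicate_r2"))
  # flipped coding still counts as r2 = 1
  d2 <- cbind(base, 2L - base)
  res2 <- prune_duplicate_snps(mdr_geno(d2))
  expect_identical(ncol(res2$geno$dosage), 1L)
  # no duplicates: identity, and idempotence
  res3 <- prune_duplicate_snps(res$geno)
  expect_identical(res3$geno$dosage, res$geno$dosage)
})

test_that("ld_partners finds high-LD proxies, inclusively", {
  cfg <- sim_config(n_subjects = 2000, n_snps = 6, ld_block_sizes = c(2, 2),
                    ld_block_r2 = c(1, 0.9), maf_range = c(0.3, 0.3),
                    seed = 77)
  g <- simulate_genotypes(cfg)
  ids <- g$snp_info$snp_id
  expect_identical(ld_partners(g, ids[1])$snp_id, ids[2])  # exact copy
  p34 <- ld_partners(g, ids[3], r2_threshold = 0.8)
  expect_identical(p34$snp_id, ids[4])
  expect_true(p34$r2 >= 0.8)
  expect_identical(nrow(ld_partners(g, ids[5], 0.8)), 0L)
  expect_identical(nrow(ld_partners(g, ids[1], 1.01)), 0L)  # r2 <= 1 always
  expect_error(ld_partners(g, "nope"), "unknown snp id")
})
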