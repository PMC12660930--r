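test_that("basic QC applies the inclusive depth thresholds", {
  # genome of 100 1-kb bins on one chromosome
  sizes <- c(Chr1 = 1e5)
  genes <- sprintf("g%03d", 1:600)
  mk_counts <- function(reads, n_genes) {
    v <- integer(600)
    v[seq_len(n_genes)] <- c(rep(reads %/% n_genes, n_genes - 1L),
                             reads - (reads %/% n_genes) * (n_genes - 1L))
    v
  }
  cm <- count_matrix(cbind(n999 = mk_counts(999L, 500L),
                           n199 = mk_counts(5000L, 199L),
                           ok = mk_counts(1000L, 200L)) |>
                       `rownames<-`(genes))
  # WGBS reads covering sites in exactly 10 of the 100 bins
  calls <- rbind(mk_calls("n999", (0:9) * 1000 + 5, 0, 1),
                 mk_calls("n199", (0:9) * 1000 + 5, 0, 1),
                 mk_calls("ok", (0:9) * 1000 + 5, 0, 1))
  qc <- basic_qc(calls, cm, sizes)
  setkey(qc, nucleus_id)
  expect_true(qc["n999", fail_rna])    # 999 reads < 1000
  expect_true(qc["n199", fail_rna])    # 199 genes < 200
  expect_false(qc["ok", fail_rna])     # both boundaries inclusive
  expect_equal(qc$wgbs_bin_fraction, rep(0.10, 3))
  expect_false(any(qc$fail_wgbs))      # exactly 10% passes ("at least 10%")
  # nucleus missing from the count matrix fails RNA, no error
  qc2 <- basic_qc(mk_calls("ghost", 5, 0, 1), cm, sizes)
  expect_true(qc2[nucleus_id == "ghost", fail_rna])
})

test_that("organelle filter is strict at 10%", {
  m <- cbind(n11 = c(89L, 11L), n10 = c(90L, 10L), n0 = c(100L, 0L),
             empty = c(0L, 0L))
  rownames(m) <- c("nuc", "org")
  cm <- count_matrix(m, organelle_genes = "org")
  of <- organelle_filter(cm)
  setkey(of, nucleus_id)
  expect_true(of["n11", fail_organelle])    # 0.11 > 0.10
  expect_false(of["n10", fail_organelle])   # 0.10 not > 0.10
  expect_false(of["n0", fail_organelle])
  expect_false(of["empty", fail_organelle]) # undefined fraction, not flagged
  expect_true(is.na(of["empty", organelle_fraction]))
})

test_that("coverage doublet statistic counts sites by coverage class", {
  s <- coverage_doublet_stats(mk_calls("a", 1:3, 0, c(1, 1, 1)))
  expect_equal(unlist(s[, .(n_cov1, n_covmulti, multi_fraction)]),
               c(n_cov1 = 3, n_covmulti = 0, multi_fraction = 0))
  s2 <- coverage_doublet_stats(mk_calls("b", 1:4, 0, c(1, 2, 3, 1)))
  expect_equal(unlist(s2[, .(n_cov1, n_covmulti, multi_fraction)]),
               c(n_cov1 = 2, n_covmulti = 2, multi_fraction = 0.5))
  # union of two nuclei each covering ~50% of 1000 sites: expected
  # multi fraction p^2/(2p - p^2) = 1/3
  set.seed(21)
  capA <- runif(1000) < 0.5
  capB <- runif(1000) < 0.5
  cov <- capA + capB
  u <- meth_calls(data.table(chrom = "Chr1", pos = which(cov > 0) - 1L,
                             strand = "+", context = "CG", mc = 0L,
                             cov = as.integer(cov[cov > 0])), "u")
  mf <- coverage_doublet_stats(u)$multi_fraction
  expect_lt(abs(mf - 1 / 3), 0.05)
})

test_that("coverage censor flags planted doublets and ignores clean cohorts", {
  # all-zero multi fractions: nobody flagged
  clean <- data.table(nucleus_id = sprintf("n%03d", 1:50),
                      n_cov1 = 1000L + (1:50), n_covmulti = 0L,
                      multi_fraction = 0)
  expect_false(any(censor_coverage_doublets(clean)$doublet_coverage))
  # 100 singletons (~0.001) + 5 planted doublets (~0.3) at equal coverage
  set.seed(13)
  singles <- data.table(nucleus_id = sprintf("s%03d", 1:100),
                        n_cov1 = sample(900:1100, 100, TRUE))
  singles[, n_covmulti := rbinom(.N, n_cov1, 0.001)]
  doubs <- data.table(nucleus_id = sprintf("d%02d", 1:5),
                      n_cov1 = sample(900:1100, 5, TRUE))
  doubs[, n_covmulti := rbinom(.N, n_cov1, 0.3)]
  all <- rbind(singles, doubs)
  all[, multi_fraction := n_covmulti / (n_cov1 + n_covmulti)]
  res <- censor_coverage_doublets(all)
  expect_setequal(res[doublet_coverage == TRUE, nucleus_id], doubs$nucleus_id)
  # flagged set is invariant under permutation of input order
  res2 <- censor_coverage_doublets(all[sample(.N)])
  expect_setequal(res2[doublet_coverage == TRUE, nucleus_id],
                  res[doublet_coverage == TRUE, nucleus_id])
  # tiny cohorts warn and do not censor
  expect_warning(censor_coverage_doublets(all[1:5]), "fewer than")
})

test_that("conversion QC estimates and flags from chloroplast methylation", {
  a <- mk_calls("a", 1:500, 0, 1, chrom = "ChrC")
  qa <- conversion_qc(a)
  expect_equal(qa$conversion_estimate, 1)
  expect_false(qa$fail_conversion)
  b <- mk_calls("b", 1:500, c(rep(1, 25), rep(0, 475)), 1, chrom = "ChrC")
  qb <- conversion_qc(b)
  expect_equal(qb$chloro_mc_fraction, 0.05)
  expect_true(qb$fail_conversion)     # 0.05 > 0.03 with enough coverage
  # below the evidence floor the fraction is reported but not flagged
  c_ <- mk_calls("c", 1:50, c(rep(1, 10), rep(0, 40)), 1, chrom = "ChrC")
  expect_message(qc_ <- conversion_qc(c_), "withheld")
  expect_equal(qc_$chloro_mc_fraction, 0.2)
  expect_false(qc_$fail_conversion)
})

test_that("full QC recovers every planted failure category exactly", {
  sim <- make_fixture("qc_stress", seed = 1)
  qc <- nucleus_qc(sim$meth, sim$counts, sim$chrom_sizes)
  j <- qc[sim$truth$nuclei, on = "nucleus_id"]
  expect_true(all(j[planted %in% c("low_rna", "low_genes"), fail_rna]))
  expect_true(all(j[planted == "low_wgbs", fail_wgbs]))
  expect_true(all(j[planted == "high_organelle", fail_organelle]))
  expect_true(all(j[planted == "conversion_fail", fail_conversion]))
  expect_true(all(j[planted == "doublet", doublet_coverage]))
  # no false positives among clean nuclei
  expect_true(all(j[planted == "none", passed]))
  # passed <-> empty flag set
  expect_identical(qc$passed, qc$flags == "")
})
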