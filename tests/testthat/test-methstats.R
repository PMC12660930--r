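test_that("region means implement the weighted-mean formula", {
  rs <- region_set(data.table(chrom = "Chr1", start = 0L, end = 1000L), "r")
  calls <- mk_calls("a", c(10, 20), c(2, 1), c(4, 1))
  out <- region_mean_per_nucleus(calls, rs)
  expect_equal(out$mean, 0.6)                     # (2+1)/(4+1)
  # site outside the region is ignored
  calls2 <- rbind(calls, mk_calls("a", 5000, 1, 1))
  expect_equal(region_mean_per_nucleus(calls2, rs)$mean, 0.6)
  # no covered in-region site -> missing
  far <- mk_calls("b", 5000, 1, 1)
  expect_true(is.na(region_mean_per_nucleus(far, rs)$mean))
  # fully methylated -> 1; min_cov excludes shallow sites
  full <- mk_calls("c", c(1, 2), c(1, 3), c(1, 3))
  expect_equal(region_mean_per_nucleus(full, rs)$mean, 1)
  expect_equal(region_mean_per_nucleus(full, rs, min_cov = 2)$mean, 1)
  expect_equal(region_mean_per_nucleus(full, rs, min_cov = 2)$n_sites, 1L)
})

test_that("pseudobulk pooling is exact addition and coverage-weighted", {
  a <- mk_calls("a", 100, 1, 1); b <- mk_calls("b", 100, 0, 1)
  asg <- data.table(nucleus_id = c("a", "b"), cluster = "X")
  sheet <- sample_sheet(data.table(nucleus_id = c("a", "b"), genotype = "WT",
                                   experiment = "e", plate = "P",
                                   well = c("A1", "A2")))
  pooled <- pool_cluster(rbind(a, b), asg, sheet)
  expect_equal(pooled$mc, 1L)
  expect_equal(pooled$cov, 2L)
  # empty cluster warns
  asg2 <- rbind(asg, data.table(nucleus_id = "ghost", cluster = "Y"))
  expect_warning(pool_cluster(rbind(a, b), asg2,
                              sample_sheet(data.table(
                                nucleus_id = c("a", "b", "ghost"),
                                genotype = "WT", experiment = "e",
                                plate = "P", well = c("A1", "A2", "A3")))),
                 "empty")
  # removing one nucleus changes only its sites
  c_ <- mk_calls("c", 900, 1, 1)
  sheet3 <- sample_sheet(data.table(nucleus_id = c("a", "b", "c"),
                                    genotype = "WT", experiment = "e",
                                    plate = "P", well = c("A1", "A2", "A3")))
  asg3 <- data.table(nucleus_id = c("a", "b", "c"), cluster = "X")
  with_c <- pool_cluster(rbind(a, b, c_), asg3, sheet3)
  without_c <- pool_cluster(rbind(a, b), asg, sheet)
  expect_equal(with_c[pos == 100], without_c[pos == 100])
})

test_that("TSS windows are strand-aware and clipped", {
  sizes <- c(Chr1 = 1000L, Chr2 = 10000L)
  tss <- region_set(data.table(chrom = c("Chr2", "Chr1", "Chr2"),
                               start = c(1000L, 100L, 2000L),
                               end = c(1800L, 500L, 2600L),
                               id = c("plus", "clip", "minus"),
                               strand = c("+", "+", "-")), "genes")
  win <- tss_window_regions(tss, 400L, sizes)
  w <- as.data.table(win); setkey(w, id)
  expect_equal(w["plus", .(start, end)], data.table(start = 600L, end = 1400L),
               ignore_attr = TRUE)
  expect_equal(w["clip", .(start, end)], data.table(start = 0L, end = 500L),
               ignore_attr = TRUE)   # clipped at chromosome start
  expect_equal(w["minus", .(start, end)],
               data.table(start = 2200L, end = 3000L), ignore_attr = TRUE)
  expect_error(tss_window_regions(tss, 0L, sizes), "flank")
})

test_that("metaplot profiles are flat for uniform tracks and strand-symmetric", {
  # uniform 50% methylation at every 10 bp (each site exactly half)
  pos <- seq(0L, 9990L, 10L)
  track <- data.table(chrom = "Chr1", pos = pos, context = "CG",
                      mc = 1L, cov = 2L)
  rs <- region_set(data.table(chrom = "Chr1", start = c(2000L, 6000L),
                              end = c(3000L, 7000L), strand = c("+", "-")),
                   "r")
  prof <- profile_matrix(track, rs, mode = "reference_point", flank = 500L,
                         n_bins = 10L)
  expect_true(all(abs(prof$level - 0.5) < 1e-12))
  # step pattern: 0% upstream of the region, 100% inside the body
  mkstep <- function(rstart, rend, strand) {
    p <- seq(rstart - 500L, rend - 1L, 5L)
    data.table(chrom = "Chr1", pos = p, context = "CG",
               mc = as.integer(p >= rstart & p < rend), cov = 1L)
  }
  plus <- profile_matrix(mkstep(2000L, 3000L, "+"),
                         region_set(data.table(chrom = "Chr1", start = 2000L,
                                               end = 3000L, strand = "+"), "p"),
                         mode = "reference_point", flank = 500L, n_bins = 20L)
  minus_track <- {
    p <- seq(6000L + 1L, 7000L + 500L, 5L)
    data.table(chrom = "Chr1", pos = p, context = "CG",
               mc = as.integer(p < 7000L), cov = 1L)
  }
  minus <- profile_matrix(minus_track,
                          region_set(data.table(chrom = "Chr1", start = 6000L,
                                                end = 7000L, strand = "-"), "m"),
                          mode = "reference_point", flank = 500L, n_bins = 20L)
  expect_equal(plus$level, minus$level, tolerance = 0.05)
  # scale_regions maps the body onto n_bins
  sc <- profile_matrix(mkstep(2000L, 3000L, "+"),
                       region_set(data.table(chrom = "Chr1", start = 2000L,
                                             end = 3000L, strand = "+"), "p"),
                       mode = "scale_regions", n_bins = 10L)
  expect_true(all(sc$level == 1))
})

test_that("profile of a pooled track equals weighted mean of per-nucleus profiles", {
  sim <- make_fixture("tiny", seed = 12)
  rs <- sim$regions$VN_CG_hypo_DMR
  nuclei <- unique(sim$meth$nucleus_id)[1:6]
  per <- lapply(nuclei, function(n)
    profile_matrix(sim$meth[nucleus_id == n], rs, flank = 500L, n_bins = 10L))
  pooled_calls <- sim$meth[nucleus_id %in% nuclei,
                           .(mc = sum(mc), cov = sum(cov)),
                           by = .(chrom, pos, context)]
  pooled <- profile_matrix(pooled_calls, rs, flank = 500L, n_bins = 10L)
  mc <- Reduce(`+`, lapply(per, `[[`, "mc"))
  cov <- Reduce(`+`, lapply(per, `[[`, "cov"))
  expect_equal(pooled$mc, mc)
  expect_equal(pooled$cov, cov)
  expect_equal(pooled$level, ifelse(cov > 0, mc / cov, NA_real_))
})

test_that("mC density sums per-cytosine percentages over bins", {
  track <- data.table(chrom = "Chr1", pos = c(10L, 100L, 300L, 500L),
                      context = "CG", mc = c(5L, 10L, 0L, 3L),
                      cov = c(10L, 10L, 10L, 3L))
  # sites at 50%, 100%, 0% in bin [0,400) -> density 150; (3,3) has cov<5
  d <- mc_density_bins(track, bin_size = 400L, chrom_sizes = c(Chr1 = 800L))
  expect_equal(d[chrom == "Chr1" & start == 0 & context == "CG", density], 150)
  expect_equal(d[start == 400 & context == "CG", density], 0)  # empty bin
  expect_equal(nrow(d), 2L * 3L)
  # peak-centred window of width 400 at midpoint m covers [m-200, m+200)
  centers <- region_set(data.table(chrom = "Chr1", start = 100L, end = 500L,
                                   id = "pk"), "peaks")  # midpoint 300
  pc <- mc_density_bins(track, bin_size = 400L, mode = "peak_centered",
                        centers = centers, min_cov = 1L)
  expect_equal(pc[context == "CG", density], 100 + 0)  # pos 100 and 300; 500 is end-exclusive
})

test_that("Cohen's d matches closed forms and is scale invariant", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(0, 1), c(2, 3)), -2 / sqrt(0.5))
  expect_equal(cohens_d(c(0, 1) * 10, c(2, 3) * 10), -2 / sqrt(0.5))
  expect_equal(cohens_d(c(1, 1), c(0, 0)), Inf)
  expect_equal(cohens_d(c(1, 1), c(1, 1)), 0)
  expect_true(is.na(cohens_d(1, c(1, 2))))
  expect_equal(cohens_d(c(0, 1, NA), c(2, 3)), -2 / sqrt(0.5))
})

test_that("star categories follow the legend thresholds, left-closed", {
  expect_equal(star_category(c(0, 0.19, 0.2, 0.49, 0.5, 0.6, 0.9, -1.0,
                               1.49, 1.5, 3, Inf, -Inf)),
               c("n.e.", "n.e.", "*", "*", "**", "**", "***", "***",
                 "***", "****", "****", "****", "****"))
  expect_true(is.na(star_category(NA_real_)))
})

test_that("effect grid is antisymmetric in the pair and marks thin cells", {
  sim <- make_fixture("rescue", seed = 2)
  asg <- sim$truth$nuclei[cluster == "VN2", .(nucleus_id, cluster)]
  g1 <- effect_grid(sim$meth, sim$regions["VN_CG_hypo_DMR"], asg, sim$sheet,
                    pairs = list(c("WT", "mutA")))
  g2 <- effect_grid(sim$meth, sim$regions["VN_CG_hypo_DMR"], asg, sim$sheet,
                    pairs = list(c("mutA", "WT")))
  expect_equal(g1$cohens_d, -g2$cohens_d)
  expect_equal(g1$t_pvalue, g2$t_pvalue)
  # thin group -> insufficient, NA effect
  thin <- asg[1:3]
  gth <- effect_grid(sim$meth, sim$regions["VN_CG_hypo_DMR"], thin, sim$sheet,
                     pairs = list(c("WT", "mutA")))
  expect_true(any(gth$insufficient))
  expect_true(all(is.na(gth[insufficient == TRUE, cohens_d])))
})

test_that("permuted genotype labels yield null-centred effect sizes", {
  sim <- make_fixture("rescue", seed = 3)
  nuclei <- sim$truth$nuclei[cluster == "VN2" & genotype %in% c("WT", "mutA")]
  means <- region_mean_per_nucleus(sim$meth[nucleus_id %in% nuclei$nucleus_id],
                                   sim$regions$VN_CG_hypo_DMR)
  means <- nuclei[, .(nucleus_id, genotype)][means, on = "nucleus_id"]
  obs <- abs(cohens_d(means[genotype == "WT", mean],
                      means[genotype == "mutA", mean]))
  set.seed(99)
  perm <- replicate(50, {
    g <- sample(means$genotype)
    abs(cohens_d(means[g == "WT", mean], means[g == "mutA", mean]))
  })
  expect_lt(median(perm), 0.2)   # null effects are near zero
  expect_gt(obs, 0.9)            # the real contrast is large
})
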