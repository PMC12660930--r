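test_that("normalization is CP10K log1p with organelle exclusion", {
  m <- cbind(n1 = c(100L, 0L, 50L), n2 = c(200L, 0L, 100L))
  rownames(m) <- c("g1", "g2", "org1")
  cm <- count_matrix(m, organelle_genes = "org1")
  norm <- normalize_expression(cm)
  # single expressed nuclear gene with the whole 100-read library
  expect_equal(norm["g1", "n1"], log1p(10000))
  expect_equal(norm["g2", "n1"], 0)
  # doubling all counts leaves normalized values unchanged
  expect_equal(norm[, "n1"], norm[, "n2"])
  expect_false("org1" %in% rownames(norm))
  bad <- count_matrix(cbind(n1 = c(0L, 5L)) |>
                        `rownames<-`(c("g1", "org1")),
                      organelle_genes = "org1")
  expect_error(normalize_expression(bad), "all-zero")
})

test_that("marker scores assign the obvious cluster and ignore gene order", {
  set.seed(31)
  genes <- c(paste0("a", 1:3), paste0("b", 1:3), paste0("x", 1:14))
  panel <- list(A = paste0("a", 1:3), B = paste0("b", 1:3))
  m <- matrix(rpois(20 * 30, 5), 20, 30,
              dimnames = list(genes, paste0("n", 1:30)))
  m[panel$A, 1:15] <- m[panel$A, 1:15] + 40L
  m[panel$B, 16:30] <- m[panel$B, 16:30] + 40L
  cm <- count_matrix(m)
  norm <- normalize_expression(cm)
  asg <- assign_clusters(norm, panel)$assignment
  expect_equal(asg$cluster, rep(c("A", "B"), each = 15))
  # permuting gene order does not change labels
  norm2 <- norm[sample(nrow(norm)), ]
  expect_equal(assign_clusters(norm2, panel)$assignment$cluster, asg$cluster)
  # missing markers: dropped with warning; all-missing cluster errors
  expect_warning(assign_clusters(norm, list(A = c("a1", "a2", "gone"),
                                            B = panel$B)), "dropped")
  expect_error(suppressWarnings(
    assign_clusters(norm, list(A = c("nope1", "nope2"), B = panel$B))),
    "no markers")
})

test_that("VN/SN reassignment uses the inclusive log2-ratio window", {
  # hand-built normalized matrix: rows = markers, columns = nuclei
  norm <- rbind(sn1 = c(eq = 2, four = 4, edge = 2^0.2 * 3, mn = 2),
                vn1 = c(eq = 2, four = 1, edge = 3, mn = 2))
  panel <- list(VN4 = "vn1", VN5 = character(), SN = "sn1")
  asg <- data.table(nucleus_id = colnames(norm),
                    cluster = c("VN4", "SN", "SN", "MN"),
                    reassigned_vn_sn = FALSE)
  res <- vn_sn_doublet_reassign(norm, asg, panel, mature_vn = "VN4")
  setkey(res, nucleus_id)
  expect_equal(res["eq", cluster], "VN_and_SN")      # r = 0
  expect_equal(res["four", cluster], "SN")           # r = 2, kept
  expect_equal(res["edge", cluster], "VN_and_SN")    # r ~ 0.2, inclusive
  expect_equal(res["mn", cluster], "MN")             # non-candidates fixed
  expect_true(res["edge", log2_sn_vn_ratio] <= 0.2)
  # only {VN4, VN5, SN} can move, and only to VN_and_SN
  expect_setequal(res[reassigned_vn_sn == TRUE, cluster], "VN_and_SN")
})

test_that("trajectory fixture is assigned accurately with adjacent confusion", {
  sim <- make_fixture("trajectory", seed = 1)
  norm <- normalize_expression(sim$counts)
  asg <- assign_clusters(norm, sim$markers,
                         cluster_order = sim$config$clusters)$assignment
  j <- asg[sim$truth$nuclei, on = "nucleus_id"][is_doublet == FALSE]
  expect_gte(mean(j$cluster == j$i.cluster), 0.95)
  # misassignments land on developmentally adjacent clusters
  mis <- j[cluster != i.cluster]
  if (nrow(mis) > 0) {
    ord <- sim$config$clusters
    adjacent <- abs(match(mis$cluster, ord) - match(mis$i.cluster, ord)) <= 1 |
      (mis$cluster == "GN" & mis$i.cluster == "MN") |
      (mis$cluster == "SN" & mis$i.cluster == "GN") |
      (mis$cluster == "MN" & mis$i.cluster == "GN") |
      (mis$cluster == "GN" & mis$i.cluster == "SN")
    expect_gte(mean(adjacent), 0.9)
  }
})

test_that("frozen z-score parameters project a new cohort consistently", {
  sim <- make_fixture("tiny", seed = 6)
  norm <- normalize_expression(sim$counts)
  ref <- assign_clusters(norm, sim$markers, cluster_order = sim$config$clusters)
  # scoring the same nuclei against the frozen reference reproduces labels
  again <- assign_clusters(norm, sim$markers,
                           cluster_order = sim$config$clusters,
                           reference = ref$zparams)
  expect_equal(again$assignment$cluster, ref$assignment$cluster)
})

test_that("25-kb feature matrix computes bin fractions and conserves pooling", {
  calls <- rbind(mk_calls("a", c(100, 30000), c(1, 1), c(1, 1)),
                 mk_calls("b", 200, 0, 1))
  m <- methylome_feature_matrix(calls, c(Chr1 = 50000), bin_size = 25000)
  expect_equal(m["a", "Chr1:0:CG"], 1)       # (1,1) in first bin
  expect_equal(m["b", "Chr1:0:CG"], 0)
  expect_equal(m["a", "Chr1:25000:CG"], 1)
  expect_true(is.na(m["b", "Chr1:25000:CG"])) # empty bin is missing, not 0
  expect_true(all(is.na(m[, "Chr1:0:CHH"])))
  # hand case: calls (1,1) and (0,1) in one bin -> 0.5
  both <- mk_calls("c", c(10, 20), c(1, 0), c(1, 1))
  m2 <- methylome_feature_matrix(both, c(Chr1 = 25000), bin_size = 25000)
  expect_equal(m2["c", "Chr1:0:CG"], 0.5)
  # pooling nuclei reproduces pseudobulk bin values
  sim <- make_fixture("tiny", seed = 8)
  fm <- methylome_feature_matrix(sim$meth, sim$chrom_sizes)
  asg <- data.table(nucleus_id = rownames(fm), cluster = "all")
  pooled <- pool_cluster(sim$meth, asg, sim$sheet)
  pooled_fm <- methylome_feature_matrix(
    meth_calls(pooled[, .(nucleus_id = cluster, chrom, pos, strand, context,
                          mc, cov)]), sim$chrom_sizes)
  # feature-level: pooled fraction equals coverage-weighted mean over nuclei
  per <- sim$meth[, .(mc = sum(mc), cov = sum(cov)),
                  by = .(f = paste0(chrom, ":", (pos %/% 25000) * 25000,
                                    ":", context))]
  expect_equal(pooled_fm["all", per$f], setNames(per$mc / per$cov, per$f))
})
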