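# Expression-side statistics: TPM, a simple differential-expression
# stand-in (Welch t on log2 CPM, BH-adjusted — deliberately named so its
# calls are never conflated with a full count-model fit), the rescue
# classifier across genotypes, and the immature/mature activation-timing
# classifier.

#' Transcripts per million
#'
#' rate_g = count_g / length_g; TPM_g = 1e6 * rate_g / sum(rate). Columns
#' each sum to 1e6.
#'
#' @param counts matrix (transcripts x samples) or vector of counts.
#' @param lengths transcript lengths (> 0), recycled across samples.
#' @return TPM matrix/vector of the same shape.
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("tpm: lengths must be > 0")
  if (is.matrix(counts)) {
    rate <- counts / lengths
    tot <- colSums(rate)
    if (any(tot == 0)) stop("tpm: zero library")
    sweep(rate, 2L, tot / 1e6, "/")
  } else {
    rate <- counts / lengths
    if (sum(rate) == 0) stop("tpm: zero library")
    1e6 * rate / sum(rate)
  }
}

#' Simple differential-expression stand-in
#'
#' Per-transcript Welch t-test on log2(CPM + 1) with Benjamini-Hochberg
#' adjustment; log2 fold change from mean CPM with pseudocount 1. A
#' transcript is significant iff padj < `alpha` and |log2FC| > `lfc`.
#' This is a deliberately simple test, not a count-model fit; output
#' carries a `method` attribute naming it.
#'
#' @param counts_a,counts_b matrices (transcripts x replicates), >= 2
#'   replicates each.
#' @param alpha adjusted p-value cutoff.
#' @param lfc absolute log2 fold-change cutoff.
#' @return data.table: transcript_id, log2fc (A over B), p, padj,
#'   significant.
#' @export
de_standin <- function(counts_a, counts_b, alpha = 0.05, lfc = 1) {
  stopifnot(nrow(counts_a) == nrow(counts_b),
            ncol(counts_a) >= 2L, ncol(counts_b) >= 2L)
  cpm <- function(m) sweep(m, 2L, colSums(m) / 1e6, "/")
  la <- log2(cpm(counts_a) + 1); lb <- log2(cpm(counts_b) + 1)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1L, var); vb <- apply(lb, 1L, var)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tt), df)
  p[se2 == 0] <- 1  # identical constant groups: no evidence
  out <- data.table(
    transcript_id = rownames(counts_a) %||% as.character(seq_len(nrow(counts_a))),
    log2fc = log2(rowMeans(cpm(counts_a)) + 1) - log2(rowMeans(cpm(counts_b)) + 1),
    p = p)
  out[, padj := p.adjust(p, method = "BH")]
  out[, significant := padj < alpha & abs(log2fc) > lfc]
  setattr(out, "method", "welch_t_log2cpm_bh")
  out[]
}

#' Classify upregulated transcripts by extent of rescue across genotypes
#'
#' Replicates are first averaged within each genotype; rows (upregulated
#' transcripts) of the genotype-mean TPM matrix are z-scored and
#' clustered (average-linkage hierarchical clustering, Euclidean
#' distance, cut at `k`). Each cluster is labelled from its centroid mean
#' TPM per genotype, so several clusters may share a label; `k` larger
#' than the number of label categories makes the partition robust to how
#' the dendrogram splits. Labels come from the ratio
#' r = (log2(mutAB+1) - log2(WT+1)) / (log2(mutA+1) - log2(WT+1)):
#' r <= `r_rescued` -> rescued; <= `r_partial` -> partially_rescued;
#' otherwise not_rescued. Clusters whose centroids are low-signal
#' (denominator < `min_effect`) or non-monotone (r < `r_min`, a strong
#' inversion below wild type, or r > `r_max`, overshoot beyond the
#' derepressed mutant) are labelled "other"; mild undershoot below WT is
#' monotone over-rescue and stays "rescued".
#'
#' @param tpm_mat TPM matrix, transcripts x samples.
#' @param genotype_of_sample character vector (one per column) naming each
#'   sample's genotype; must include `wt`, `mut` and `rescue_mut`.
#' @param upregulated transcript ids to classify (rows of `tpm_mat`).
#' @param k number of clusters to cut.
#' @param wt,mut,rescue_mut genotype labels for wild type, the
#'   derepressed mutant, and the candidate rescuing genotype.
#' @param r_rescued,r_partial,r_min,r_max,min_effect centroid-ratio
#'   thresholds.
#' @return list: `labels` (data.table transcript_id, cluster, label),
#'   `centroids` (per-cluster mean TPM per genotype with r), `hclust`.
#' @export
rescue_classify <- function(tpm_mat, genotype_of_sample, upregulated,
                            k = 12L, wt = "WT", mut = "mutA",
                            rescue_mut = "mutAB",
                            r_rescued = 0.25, r_partial = 0.75,
                            r_min = -1, r_max = 1.5, min_effect = 0.5) {
  stopifnot(length(genotype_of_sample) == ncol(tpm_mat),
            all(c(wt, mut, rescue_mut) %in% genotype_of_sample))
  if (min(table(genotype_of_sample)) < 3L)
    warning("rescue_classify: fewer than 3 replicates for some genotype")
  m <- tpm_mat[intersect(upregulated, rownames(tpm_mat)), , drop = FALSE]
  genos <- unique(genotype_of_sample)
  gm <- vapply(genos, function(g)
    rowMeans(m[, genotype_of_sample == g, drop = FALSE]), numeric(nrow(m)))
  rsd <- apply(gm, 1L, sd)
  if (any(rsd == 0)) {
    warning("rescue_classify: dropping ", sum(rsd == 0),
            " constant transcript row(s)")
    m <- m[rsd > 0, , drop = FALSE]
    gm <- gm[rsd > 0, , drop = FALSE]
  }
  z <- t(scale(t(gm)))
  hc <- hclust(dist(z), method = "average")
  cl <- cutree(hc, k = min(k, nrow(m)))
  gmean <- function(rows, g)
    mean(m[rows, genotype_of_sample == g, drop = FALSE])
  cents <- rbindlist(lapply(sort(unique(cl)), function(ci) {
    rows <- names(cl)[cl == ci]
    mw <- gmean(rows, wt); mm <- gmean(rows, mut); mr <- gmean(rows, rescue_mut)
    num <- log2(mr + 1) - log2(mw + 1)
    den <- log2(mm + 1) - log2(mw + 1)
    r <- if (den != 0) num / den else NA_real_
    label <- if (is.na(r) || den < min_effect || r < r_min || r > r_max) "other"
    else if (r <= r_rescued) "rescued"
    else if (r <= r_partial) "partially_rescued"
    else "not_rescued"
    data.table(cluster = ci, n = length(rows), mean_wt = mw, mean_mut = mm,
               mean_rescue = mr, r = r, label = label)
  }))
  labels <- data.table(transcript_id = names(cl), cluster = unname(cl))
  labels <- cents[, .(cluster, label)][labels, on = "cluster"]
  setcolorder(labels, c("transcript_id", "cluster", "label"))
  list(labels = labels[], centroids = cents[], hclust = hc)
}

#' Classify transcripts by activation timing along the VN trajectory
#'
#' A transcript's activation cluster is the earliest cluster in
#' `vn_order` where log2((mut+1)/(wt+1)) exceeds `lfc_threshold` and the
#' mutant mean exceeds `min_expr`. Activation in an immature VN cluster
#' labels the transcript immature_VN; in a mature cluster, mature_VN;
#' never activated, none.
#'
#' @param wt_means,mut_means matrices (transcripts x clusters) of mean
#'   expression per cluster.
#' @param vn_order VN clusters in developmental order.
#' @param immature,mature partition of `vn_order`.
#' @param lfc_threshold log2 ratio threshold.
#' @param min_expr minimum mutant mean expression.
#' @return data.table: transcript_id, activation_cluster, label.
#' @export
timing_classify <- function(wt_means, mut_means,
                            vn_order = c("VN1", "VN1to2", "VN2", "VN3",
                                         "VN4", "VN5"),
                            immature = c("VN1", "VN1to2", "VN2", "VN3"),
                            mature = c("VN4", "VN5"),
                            lfc_threshold = 1, min_expr = 1) {
  stopifnot(identical(rownames(wt_means), rownames(mut_means)),
            all(vn_order %in% colnames(wt_means)))
  lfc <- log2(mut_means[, vn_order, drop = FALSE] + 1) -
    log2(wt_means[, vn_order, drop = FALSE] + 1)
  up <- lfc > lfc_threshold & mut_means[, vn_order, drop = FALSE] > min_expr
  first <- apply(up, 1L, function(v) if (any(v)) vn_order[which(v)[1L]]
                 else NA_character_)
  label <- fifelse(is.na(first), "none",
                   fifelse(first %in% immature, "immature_VN", "mature_VN"))
  data.table(transcript_id = rownames(wt_means),
             activation_cluster = first, label = label)
}
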