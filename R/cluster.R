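# Marker-score cluster assignment for pollen nuclei, mature-VN/SN doublet
# reassignment from the SN/VN marker log-ratio, and 25-kb methylome
# feature matrices for external embedding tools.

#' Normalize RNA counts to log counts-per-10k
#'
#' Organelle genes are excluded before library-size scaling; each nucleus
#' is scaled to 10,000 nuclear counts and log1p-transformed. Scale
#' invariant: doubling all counts of a nucleus leaves values unchanged.
#'
#' @param counts a [count_matrix].
#' @return numeric matrix (nuclear genes x nuclei) of log1p(CP10K) values.
#' @export
normalize_expression <- function(counts) {
  og <- organelle_genes(counts)
  m <- unclass(counts)
  m <- m[setdiff(rownames(m), og), , drop = FALSE]
  lib <- colSums(m)
  if (any(lib == 0L))
    stop("normalize_expression: all-zero nucleus (should have failed QC): ",
         paste(head(colnames(m)[lib == 0L], 3L), collapse = ", "))
  log1p(sweep(m, 2L, lib / 1e4, "/"))
}

# gene-wise z-score across nuclei; zero-variance genes map to 0
.zscore_rows <- function(m, center = NULL, scale = NULL) {
  if (is.null(center)) center <- rowMeans(m)
  if (is.null(scale)) scale <- apply(m, 1L, sd)
  z <- (m - center) / ifelse(scale > 0, scale, 1)
  z[scale == 0, ] <- 0
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  z
}

#' Assign nuclei to clusters by marker score
#'
#' Each cluster's score is the mean, over its marker genes, of the
#' gene-wise z-scored normalized expression; a nucleus gets the argmax
#' cluster, with ties broken by `cluster_order` priority. Markers missing
#' from the matrix are dropped with a warning; a cluster losing all of its
#' markers is an error. Passing `reference` (a previous assignment's
#' `zparams`) freezes the per-gene mean/SD so a new experiment is scored
#' against an existing cohort.
#'
#' @param norm normalized matrix from [normalize_expression].
#' @param panel named list: cluster -> marker gene ids; mature-VN and SN
#'   panels must be disjoint.
#' @param cluster_order tie-break priority; defaults to panel order.
#' @param reference optional list(center=, scale=) of frozen z-score
#'   parameters from a reference cohort.
#' @return list: `assignment` (data.table nucleus_id, cluster, reassigned,
#'   plus one score_<cluster> column each), `zparams` (center/scale used).
#' @export
assign_clusters <- function(norm, panel, cluster_order = names(panel),
                            reference = NULL) {
  stopifnot(length(panel) >= 1L, !is.null(names(panel)))
  n_before <- lengths(panel)
  panel <- lapply(panel, intersect, y = rownames(norm))
  if (any(lengths(panel) < n_before))
    warning("assign_clusters: ", sum(n_before - lengths(panel)),
            " marker genes missing from the matrix were dropped")
  for (cl in names(panel)) {
    if (length(panel[[cl]]) == 0L)
      stop("assign_clusters: cluster '", cl, "' has no markers in the matrix")
  }
  z <- .zscore_rows(norm, center = reference$center[rownames(norm)],
                    scale = reference$scale[rownames(norm)])
  scores <- vapply(panel, function(g)
    colMeans(z[g, , drop = FALSE]), numeric(ncol(norm)))
  if (ncol(norm) == 1L) scores <- matrix(scores, nrow = 1L,
                                         dimnames = list(colnames(norm), names(panel)))
  prio <- match(colnames(scores), cluster_order)
  label <- apply(scores, 1L, function(s) {
    best <- which(s == max(s))
    colnames(scores)[best[order(prio[best])][1L]]
  })
  out <- data.table(nucleus_id = colnames(norm), cluster = label,
                    reassigned_vn_sn = FALSE)
  out <- cbind(out, as.data.table(scores)[, setNames(.SD, paste0("score_", colnames(scores)))])
  list(assignment = out[],
       zparams = list(center = attr(z, "center"), scale = attr(z, "scale")))
}

#' Reassign mature-VN/SN marker doublets
#'
#' For nuclei currently labelled mature VN (VN4/VN5) or SN, computes
#' r = log2((mean SN-marker expression + eps) / (mean mature-VN-marker
#' expression + eps)) on the normalized matrix. Nuclei with r inside the
#' inclusive window [-window, window] express both panels at similar
#' levels and are relabelled "VN_and_SN" (doublet of a vegetative and a
#' sperm nucleus). All other labels are fixed points.
#'
#' @param norm normalized matrix from [normalize_expression].
#' @param assignment assignment data.table from [assign_clusters].
#' @param panel marker panel list.
#' @param mature_vn,sn_cluster cluster labels making up the mature-VN and
#'   SN panels.
#' @param window half-width of the inclusive log2-ratio window.
#' @param eps pseudocount guarding zero marker means.
#' @return updated assignment with `log2_sn_vn_ratio` and relabelled rows.
#' @export
vn_sn_doublet_reassign <- function(norm, assignment, panel,
                                   mature_vn = c("VN4", "VN5"),
                                   sn_cluster = "SN", window = 0.2,
                                   eps = 1e-9) {
  out <- copy(as.data.table(assignment))
  sn_markers <- intersect(panel[[sn_cluster]], rownames(norm))
  vn_markers <- intersect(unique(unlist(panel[mature_vn])), rownames(norm))
  if (!length(sn_markers) || !length(vn_markers))
    stop("vn_sn_doublet_reassign: SN or mature-VN markers missing from matrix")
  if (length(intersect(sn_markers, vn_markers)))
    stop("vn_sn_doublet_reassign: SN and mature-VN panels must be disjoint")
  out[, log2_sn_vn_ratio := NA_real_]
  cand <- out$cluster %in% c(mature_vn, sn_cluster)
  if (any(cand)) {
    ids <- out$nucleus_id[cand]
    sn_mean <- colMeans(norm[sn_markers, ids, drop = FALSE])
    vn_mean <- colMeans(norm[vn_markers, ids, drop = FALSE])
    r <- log2((sn_mean + eps) / (vn_mean + eps))
    out[cand, log2_sn_vn_ratio := r]
    hit <- cand & !is.na(out$log2_sn_vn_ratio) &
      out$log2_sn_vn_ratio >= -window & out$log2_sn_vn_ratio <= window
    out[hit, `:=`(cluster = "VN_and_SN", reassigned_vn_sn = TRUE)]
  }
  out[]
}

#' Per-nucleus methylome feature matrix over fixed genome bins
#'
#' The fraction of methylated cytosines per context is computed over
#' `bin_size` bins tiled genome-wide, by dividing methylated counts in the
#' context by total counts in the context detected in the bin. Bins with
#' no coverage are missing (NA), not 0.
#'
#' @param meth a [meth_calls] cohort table.
#' @param chrom_sizes named chromosome lengths (defines the bin grid).
#' @param bin_size bin width in bp (default 25 kb).
#' @return numeric matrix, nuclei x (chrom:bin:context) features; NA for
#'   uncovered bins.
#' @export
methylome_feature_matrix <- function(meth, chrom_sizes, bin_size = 25000L) {
  check_chrom_sizes(chrom_sizes)
  dt <- as.data.table(meth)[chrom %in% names(chrom_sizes)]
  dt <- dt[, .(mc = sum(mc), cov = sum(cov)),
           by = .(nucleus_id, chrom, bin = pos %/% as.integer(bin_size), context)]
  dt[, feature := paste0(chrom, ":", bin * as.integer(bin_size), ":", context)]
  dt[, level := mc / cov]
  features <- CJ(chrom = names(chrom_sizes), context = VALID_CONTEXTS,
                 sorted = FALSE)[, {
    nb <- ceiling(chrom_sizes[chrom] / bin_size)
    .(feature = paste0(chrom, ":", (seq_len(nb) - 1L) * as.integer(bin_size),
                       ":", context))
  }, by = .(chrom, context)]$feature
  wide <- dcast(dt, nucleus_id ~ feature, value.var = "level")
  m <- as.matrix(wide, rownames = "nucleus_id")
  missing <- setdiff(features, colnames(m))
  if (length(missing)) {
    m <- cbind(m, matrix(NA_real_, nrow(m), length(missing),
                         dimnames = list(rownames(m), missing)))
  }
  m[, features, drop = FALSE]
}
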