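# Nucleus-level quality control: basic RNA/WGBS depth filters, the
# organelle read-fraction filter, the haploid multi-coverage doublet
# statistic with cohort-level censoring, and chloroplast-based bisulfite
# conversion QC.

#' Basic per-nucleus RNA and WGBS depth QC
#'
#' A nucleus fails (`fail_rna`) with fewer than `min_rna_reads` total RNA
#' reads or fewer than `min_genes` detected genes; it fails (`fail_wgbs`)
#' when less than `min_bin_fraction` of fixed-width genome bins carry at
#' least one WGBS read. Both thresholds are inclusive ("at least").
#' The bin grid tiles each chromosome from 0 in fixed `bin_size` steps,
#' last partial bin included.
#'
#' @param meth a [meth_calls] cohort table.
#' @param counts a [count_matrix]; a nucleus absent from it (or all-zero)
#'   fails the RNA filter rather than erroring.
#' @param chrom_sizes named vector of chromosome lengths defining the bin
#'   grid.
#' @param min_rna_reads,min_genes,min_bin_fraction,bin_size thresholds;
#'   defaults 1000 reads, 200 genes, 10% of 1-kb bins.
#' @return data.table: nucleus_id, rna_reads, genes_detected,
#'   wgbs_bin_fraction, fail_rna, fail_wgbs.
#' @export
basic_qc <- function(meth, counts, chrom_sizes,
                     min_rna_reads = 1000L, min_genes = 200L,
                     min_bin_fraction = 0.10, bin_size = 1000L) {
  check_chrom_sizes(chrom_sizes)
  nuclei <- sort(union(unique(meth$nucleus_id), colnames(counts)))
  rna_reads <- setNames(integer(length(nuclei)), nuclei)
  genes <- setNames(integer(length(nuclei)), nuclei)
  present <- intersect(nuclei, colnames(counts))
  m <- unclass(counts)[, present, drop = FALSE]
  rna_reads[present] <- colSums(m)
  genes[present] <- colSums(m > 0L)
  total_bins <- sum(ceiling(chrom_sizes / bin_size))
  covbins <- as.data.table(meth)[chrom %in% names(chrom_sizes),
    .(n_bins = uniqueN(paste0(chrom, ":", pos %/% as.integer(bin_size)))),
    by = nucleus_id]
  out <- data.table(nucleus_id = nuclei, rna_reads = as.integer(rna_reads),
                    genes_detected = as.integer(genes))
  out <- covbins[out, on = "nucleus_id"]
  out[is.na(n_bins), n_bins := 0L]
  out[, wgbs_bin_fraction := n_bins / total_bins]
  out[, fail_rna := rna_reads < min_rna_reads | genes_detected < min_genes]
  out[, fail_wgbs := wgbs_bin_fraction < min_bin_fraction]
  out[, n_bins := NULL]
  out[]
}

#' Organelle RNA read-fraction filter
#'
#' Flags nuclei whose fraction of RNA reads on chloroplast/mitochondrial
#' genes strictly exceeds `max_fraction` (> 10% by default). A nucleus
#' with zero total reads gets an NA fraction and is not flagged here
#' (the RNA depth filter governs it).
#'
#' @param counts a [count_matrix] with flagged organelle genes.
#' @param max_fraction strict upper bound on the organelle fraction.
#' @return data.table: nucleus_id, organelle_fraction, fail_organelle.
#' @export
organelle_filter <- function(counts, max_fraction = 0.10) {
  og <- organelle_genes(counts)
  if (!length(og)) stop("organelle_filter: no organelle genes flagged")
  m <- unclass(counts)
  tot <- colSums(m)
  orgn <- colSums(m[og, , drop = FALSE])
  frac <- ifelse(tot > 0L, orgn / tot, NA_real_)
  data.table(nucleus_id = colnames(m), organelle_fraction = frac,
             fail_organelle = !is.na(frac) & frac > max_fraction)
}

#' Per-nucleus coverage doublet statistic
#'
#' Counts the sites covered exactly once and more than once. After PCR
#' deduplication a haploid nucleus should never show coverage above 1, so
#' an elevated multi-coverage fraction marks a likely doublet.
#'
#' @param meth a [meth_calls] table (one nucleus or a cohort).
#' @return data.table: nucleus_id, n_cov1, n_covmulti, multi_fraction
#'   (0 when no site is covered).
#' @export
coverage_doublet_stats <- function(meth) {
  out <- as.data.table(meth)[, .(n_cov1 = sum(cov == 1L),
                                 n_covmulti = sum(cov > 1L)), by = nucleus_id]
  out[, multi_fraction := fifelse(n_cov1 + n_covmulti > 0L,
                                  n_covmulti / (n_cov1 + n_covmulti), 0)]
  out[]
}

#' Censor likely doublets from multi-coverage outliers
#'
#' The multi-coverage fraction grows with total genome coverage even for
#' singletons, so nuclei are first binned into quantile bins of total
#' covered sites; within each bin a nucleus is flagged when its
#' multi-coverage fraction exceeds median + `k_mad` x MAD (MAD scaled by
#' 1.4826). When a bin's MAD is zero the rule falls back to flagging
#' values strictly above median + 1e-6, which never mass-flags identical
#' values. Deterministic and invariant to input order.
#'
#' The effective number of bins is capped at one per 20 nuclei: a median
#' and MAD over fewer points are not robust, and a too-fine grid lets a
#' handful of high-coverage doublets become their own bin median.
#'
#' @param stats output of [coverage_doublet_stats].
#' @param k_mad MAD multiplier.
#' @param n_coverage_bins maximum number of quantile bins of total
#'   covered sites.
#' @param min_nuclei below this cohort size no censoring is attempted
#'   (with a warning).
#' @return input with added columns coverage_bin and doublet_coverage.
#' @export
censor_coverage_doublets <- function(stats, k_mad = 5.0,
                                     n_coverage_bins = 10L,
                                     min_nuclei = 20L) {
  out <- copy(as.data.table(stats))
  setorder(out, nucleus_id)
  if (nrow(out) < min_nuclei) {
    warning("censor_coverage_doublets: fewer than ", min_nuclei,
            " nuclei; no censoring applied")
    out[, `:=`(coverage_bin = NA_integer_, doublet_coverage = FALSE)]
    return(out[])
  }
  total <- out$n_cov1 + out$n_covmulti
  n_bins <- max(1L, min(as.integer(n_coverage_bins), nrow(out) %/% 20L))
  qs <- unique(quantile(total, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE, type = 7))
  out[, coverage_bin := findInterval(total, qs, rightmost.closed = TRUE,
                                     all.inside = TRUE)]
  out[, doublet_coverage := {
    med <- median(multi_fraction)
    s <- mad(multi_fraction)            # 1.4826 scaling is mad()'s default
    if (s > 0) multi_fraction > med + k_mad * s
    else multi_fraction > med + 1e-6
  }, by = coverage_bin]
  out[]
}

#' Chloroplast-based bisulfite conversion QC
#'
#' The chloroplast genome is unmethylated, so its apparent methylation
#' fraction estimates the non-conversion rate. A nucleus is flagged when
#' the fraction exceeds `max_chloro_mc` and chloroplast coverage provides
#' at least `min_chloro_cov` reads of evidence; below that the fraction is
#' still reported but the flag is withheld.
#'
#' @param meth a [meth_calls] table.
#' @param chloro_chroms chloroplast chromosome names (default ChrC).
#' @param max_chloro_mc flag threshold on the apparent chloroplast
#'   methylation fraction.
#' @param min_chloro_cov minimum summed chloroplast coverage to trust the
#'   flag.
#' @return data.table: nucleus_id, chloro_cov, chloro_mc_fraction,
#'   conversion_estimate (= 1 - fraction), fail_conversion.
#' @export
conversion_qc <- function(meth, chloro_chroms = "ChrC",
                          max_chloro_mc = 0.03, min_chloro_cov = 100L) {
  dt <- as.data.table(meth)
  out <- dt[, .(chloro_cov = sum(cov[chrom %in% chloro_chroms]),
                chloro_mc = sum(mc[chrom %in% chloro_chroms])),
            by = nucleus_id]
  out[, chloro_mc_fraction := fifelse(chloro_cov > 0L,
                                      chloro_mc / chloro_cov, NA_real_)]
  out[, conversion_estimate := 1 - chloro_mc_fraction]
  out[, fail_conversion := !is.na(chloro_mc_fraction) &
        chloro_mc_fraction > max_chloro_mc & chloro_cov >= min_chloro_cov]
  if (any(out$chloro_cov < min_chloro_cov))
    message("conversion_qc: ", sum(out$chloro_cov < min_chloro_cov),
            " nuclei below min chloroplast coverage; conversion flag withheld")
  out[, chloro_mc := NULL]
  out[]
}

#' Full nucleus QC table
#'
#' Combines the basic RNA/WGBS filters, the organelle filter, the
#' coverage doublet censor and the conversion QC into one record per
#' nucleus. `passed` is TRUE iff no flag is set.
#'
#' @param meth a [meth_calls] cohort table.
#' @param counts a [count_matrix].
#' @param chrom_sizes named chromosome lengths (nuclear + organelle).
#' @param chloro_chroms chloroplast chromosome name(s); these are excluded
#'   from the WGBS bin grid.
#' @param thresholds named list overriding any of: min_rna_reads,
#'   min_genes, min_bin_fraction, bin_size, max_organelle_fraction,
#'   k_mad, n_coverage_bins, max_chloro_mc, min_chloro_cov.
#' @return data.table with one NucleusQCRecord row per nucleus: metrics,
#'   individual flags, a comma-separated `flags` summary, and `passed`.
#' @export
nucleus_qc <- function(meth, counts, chrom_sizes, chloro_chroms = "ChrC",
                       thresholds = list()) {
  th <- modifyList(list(min_rna_reads = 1000L, min_genes = 200L,
                        min_bin_fraction = 0.10, bin_size = 1000L,
                        max_organelle_fraction = 0.10, k_mad = 5.0,
                        n_coverage_bins = 10L, max_chloro_mc = 0.03,
                        min_chloro_cov = 100L), thresholds)
  nuclear <- chrom_sizes[setdiff(names(chrom_sizes), chloro_chroms)]
  qc <- basic_qc(meth, counts, nuclear, th$min_rna_reads, th$min_genes,
                 th$min_bin_fraction, th$bin_size)
  qc <- organelle_filter(counts, th$max_organelle_fraction)[qc, on = "nucleus_id"]
  cov <- censor_coverage_doublets(coverage_doublet_stats(meth),
                                  k_mad = th$k_mad,
                                  n_coverage_bins = th$n_coverage_bins)
  qc <- cov[qc, on = "nucleus_id"]
  conv <- conversion_qc(meth, chloro_chroms, th$max_chloro_mc,
                        th$min_chloro_cov)
  qc <- conv[qc, on = "nucleus_id"]
  for (col in c("fail_rna", "fail_wgbs", "fail_organelle",
                "doublet_coverage", "fail_conversion"))
    qc[is.na(get(col)), (col) := FALSE]
  flag_cols <- c("fail_rna", "fail_wgbs", "fail_organelle",
                 "doublet_coverage", "fail_conversion")
  qc[, flags := apply(.SD, 1L, function(v)
    paste(flag_cols[as.logical(v)], collapse = ",")), .SDcols = flag_cols]
  qc[, passed := flags == ""]
  setcolorder(qc, c("nucleus_id", "rna_reads", "genes_detected",
                    "wgbs_bin_fraction", "organelle_fraction"))
  qc[]
}
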