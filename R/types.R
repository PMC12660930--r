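#' @import data.table
#' @importFrom stats median mad quantile rbinom rnbinom runif rlnorm setNames
#'   sd var t.test p.adjust hclust cutree dist pt
#' @importFrom utils packageVersion head tail modifyList
NULL

VALID_CONTEXTS <- c("CG", "CHG", "CHH")
VALID_STRANDS  <- c("+", "-")

#' Construct a validated per-site methylation call table
#'
#' The atomic methylome record: one row per covered cytosine per nucleus,
#' with methylated (`mc`) and total (`cov`) read counts. A single table may
#' hold one nucleus or a whole cohort (distinguished by `nucleus_id`).
#' Coordinates are 0-based internally.
#'
#' @param x data.frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `mc`, `cov`, and optionally `nucleus_id`.
#' @param nucleus_id nucleus identifier applied to all rows when `x` has no
#'   `nucleus_id` column.
#' @return A `meth_calls` data.table sorted by (nucleus_id, chrom, pos).
#' @export
meth_calls <- function(x, nucleus_id = NULL) {
  dt <- as.data.table(x)
  if (!is.null(nucleus_id)) dt[, nucleus_id := as.character(nucleus_id)]
  if (!"nucleus_id" %in% names(dt)) dt[, nucleus_id := NA_character_]
  need <- c("nucleus_id", "chrom", "pos", "strand", "context", "mc", "cov")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("meth_calls: missing columns: ", paste(miss, collapse = ", "))
  dt <- dt[, ..need]
  dt[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
            strand = as.character(strand), context = as.character(context),
            mc = as.integer(mc), cov = as.integer(cov))]
  if (nrow(dt)) {
    if (anyNA(dt[, !"nucleus_id"])) stop("meth_calls: NA values not allowed")
    if (any(dt$pos < 0L)) stop("meth_calls: pos must be >= 0")
    if (!all(dt$strand %in% VALID_STRANDS)) stop("meth_calls: strand must be + or -")
    if (!all(dt$context %in% VALID_CONTEXTS))
      stop("meth_calls: context must be one of ", paste(VALID_CONTEXTS, collapse = "/"))
    if (any(dt$cov < 1L)) stop("meth_calls: cov must be >= 1")
    if (any(dt$mc < 0L)) stop("meth_calls: mc must be >= 0")
    bad <- which(dt$mc > dt$cov)
    if (length(bad))
      stop("meth_calls: mc > cov at row ", bad[1L], " (mc=", dt$mc[bad[1L]],
           ", cov=", dt$cov[bad[1L]], ")")
    if (anyDuplicated(dt, by = c("nucleus_id", "chrom", "pos", "strand")))
      stop("meth_calls: duplicated (chrom,pos,strand) within a nucleus")
  }
  setkey(dt, nucleus_id, chrom, pos)
  setattr(dt, "class", c("meth_calls", class(dt)))
  dt[]
}

#' Construct a validated region set
#'
#' A named, ordered set of genomic intervals in 0-based half-open (BED)
#' convention, used for DMRs, peaks, and TSS windows.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`, optionally
#'   `id` and `strand` (`*` or NA when unstranded).
#' @param name set name (e.g. "VN_CG_hypo_DMR").
#' @return A `region_set` data.table sorted by (chrom, start) with unique ids.
#' @export
region_set <- function(x, name = "regions") {
  dt <- as.data.table(x)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("region_set: missing columns: ", paste(miss, collapse = ", "))
  if (!"id" %in% names(dt)) dt[, id := sprintf("%s_%06d", name, seq_len(.N))]
  if (!"strand" %in% names(dt)) dt[, strand := NA_character_]
  dt <- dt[, .(chrom = as.character(chrom), start = as.integer(start),
               end = as.integer(end), id = as.character(id),
               strand = as.character(strand))]
  dt[strand %in% c(".", "*"), strand := NA_character_]
  if (nrow(dt)) {
    if (any(dt$start < 0L)) stop("region_set: start must be >= 0")
    bad <- which(dt$start >= dt$end)
    if (length(bad))
      stop("region_set: empty or inverted interval at row ", bad[1L],
           " (start=", dt$start[bad[1L]], ", end=", dt$end[bad[1L]], ")")
    if (!all(is.na(dt$strand) | dt$strand %in% VALID_STRANDS))
      stop("region_set: strand must be +, -, or NA")
    if (anyDuplicated(dt$id)) stop("region_set: interval ids must be unique")
  }
  setorder(dt, chrom, start, end)
  setattr(dt, "name", name)
  setattr(dt, "class", c("region_set", class(dt)))
  dt[]
}

#' Construct a validated RNA count matrix
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   nuclei in columns (colnames = nucleus ids).
#' @param organelle_genes character vector of gene ids flagged as
#'   chloroplast/mitochondrial.
#' @return A `count_matrix`: the integer matrix with an `organelle_genes`
#'   attribute.
#' @export
count_matrix <- function(counts, organelle_genes = character()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_matrix: counts must have gene rownames and nucleus colnames")
  if (anyDuplicated(rownames(counts))) stop("count_matrix: duplicated gene ids")
  if (anyDuplicated(colnames(counts))) stop("count_matrix: duplicated nucleus ids")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("count_matrix: counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  unknown <- setdiff(organelle_genes, rownames(counts))
  if (length(unknown))
    stop("count_matrix: organelle genes not in matrix: ",
         paste(head(unknown, 3L), collapse = ", "))
  attr(counts, "organelle_genes") <- as.character(organelle_genes)
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' Organelle gene ids of a count matrix
#' @param counts a `count_matrix`.
#' @return character vector of flagged gene ids.
#' @export
organelle_genes <- function(counts) {
  og <- attr(counts, "organelle_genes")
  if (is.null(og)) character() else og
}

#' Construct a validated sample sheet
#'
#' Maps every nucleus to genotype, experiment, plate and well.
#'
#' @param x data.frame with columns `nucleus_id`, `genotype`, `experiment`,
#'   `plate`, `well`.
#' @return A `sample_sheet` data.table keyed by nucleus_id.
#' @export
sample_sheet <- function(x) {
  dt <- as.data.table(x)
  need <- c("nucleus_id", "genotype", "experiment", "plate", "well")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("sample_sheet: missing columns: ", paste(miss, collapse = ", "))
  dt <- dt[, lapply(.SD, as.character), .SDcols = need]
  if (anyDuplicated(dt$nucleus_id)) stop("sample_sheet: nucleus ids must be unique")
  setkey(dt, nucleus_id)
  setattr(dt, "class", c("sample_sheet", class(dt)))
  dt[]
}

#' Construct a validated BLAST tabular (outfmt 6) hit table
#'
#' @param x data.frame with the 12 outfmt-6 columns plus `subject_class`
#'   (one of gene/TE/TEgene).
#' @return A `blast_hits` data.table.
#' @export
blast_hits <- function(x) {
  dt <- as.data.table(x)
  need <- c("query_id", "subject_id", "pct_identity", "aln_len", "mismatches",
            "gaps", "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "subject_class")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("blast_hits: missing columns: ", paste(miss, collapse = ", "))
  dt <- dt[, ..need]
  if (nrow(dt)) {
    if (!is.numeric(dt$bitscore) || anyNA(dt$bitscore))
      stop("blast_hits: non-numeric bitscore")
    if (any(dt$bitscore < 0)) stop("blast_hits: bitscore must be >= 0")
    if (!all(dt$subject_class %in% c("gene", "TE", "TEgene")))
      stop("blast_hits: subject_class must be gene, TE, or TEgene")
  }
  setattr(dt, "class", c("blast_hits", class(dt)))
  dt[]
}

# internal: named integer vector of chromosome lengths, validated
check_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector of chromosome lengths")
  if (any(chrom_sizes <= 0)) stop("chrom_sizes must be positive")
  chrom_sizes
}
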