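# Readers/writers for the external formats the pipeline touches. All are
# line-oriented TSV dialects; fread/fwrite do the heavy lifting and the
# type constructors do the validation.

#' Read a per-site methylation call table
#'
#' Expects six tab-separated columns (allc-style, no header):
#' chromosome, position, strand, context class (CG/CHG/CHH), methylated
#' read count, total read count. Positions are converted to the internal
#' 0-based convention according to `position_base`.
#'
#' @param path file path.
#' @param nucleus_id nucleus identifier to attach; defaults to the file
#'   basename without extension.
#' @param position_base 1 (default) if the file stores 1-based positions,
#'   0 if already 0-based.
#' @return A [meth_calls] table.
#' @export
read_meth_calls <- function(path, nucleus_id = NULL, position_base = 1L) {
  if (!position_base %in% c(0L, 1L)) stop("position_base must be 0 or 1")
  if (is.null(nucleus_id))
    nucleus_id <- sub("\\.[^.]*$", "", basename(path))
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t",
          col.names = c("chrom", "pos", "strand", "context", "mc", "cov"),
          colClasses = list(character = 1:6)),
    error = function(e) stop("read_meth_calls: parse error in ", path, ": ",
                             conditionMessage(e)))
  for (col in c("pos", "mc", "cov"))
    set(dt, j = col, value = suppressWarnings(as.integer(dt[[col]])))
  if (anyNA(dt$pos) || anyNA(dt$mc) || anyNA(dt$cov))
    stop("read_meth_calls: malformed line (non-integer field) in ", path,
         " at line ", which(is.na(dt$pos) | is.na(dt$mc) | is.na(dt$cov))[1L])
  dt[, pos := pos - as.integer(position_base)]
  meth_calls(dt, nucleus_id = nucleus_id)
}

#' Write a per-site methylation call table
#'
#' Inverse of [read_meth_calls]; a read/write pair is a lossless round
#' trip on canonical files.
#'
#' @param calls a [meth_calls] table holding a single nucleus.
#' @param path output path.
#' @param position_base base of positions written (default 1).
#' @export
write_meth_calls <- function(calls, path, position_base = 1L) {
  out <- as.data.table(calls)[, .(chrom, pos = pos + as.integer(position_base),
                                  strand, context, mc, cov)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file as a region set
#'
#' @param path BED file (chrom, start, end and optionally name, score,
#'   strand). Coordinates are kept exactly as read (BED is already 0-based
#'   half-open).
#' @param name region-set name; defaults to the file basename.
#' @return A [region_set].
#' @export
read_bed <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 3L) stop("read_bed: need at least 3 columns in ", path)
  out <- data.table(chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]),
                    end = as.integer(dt[[3L]]))
  if (ncol(dt) >= 4L) out[, id := as.character(dt[[4L]])]
  if (ncol(dt) >= 6L) out[, strand := as.character(dt[[6L]])]
  region_set(out, name = name)
}

#' Write a region set as BED6 (or BED3/BED4 when no strand/id is present)
#'
#' @param rs a [region_set].
#' @param path output path.
#' @export
write_bed <- function(rs, path) {
  dt <- as.data.table(rs)
  if (all(is.na(dt$strand))) {
    fwrite(dt[, .(chrom, start, end, id)], path, sep = "\t", col.names = FALSE)
  } else {
    out <- dt[, .(chrom, start, end, id, score = ".",
                  strand = fifelse(is.na(strand), ".", strand))]
    fwrite(out, path, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}

#' Read an RNA count matrix from TSV
#'
#' First column is the gene id, remaining columns are nuclei.
#'
#' @param path TSV file with header.
#' @param organelle_genes gene ids to flag as organellar (chloroplast or
#'   mitochondrial); alternatively a regular expression via
#'   `organelle_pattern` matched against gene ids.
#' @param organelle_pattern optional regex (e.g. `"^ATCG|^ATMG"`).
#' @return A [count_matrix].
#' @export
read_counts <- function(path, organelle_genes = NULL, organelle_pattern = NULL) {
  dt <- fread(path, header = TRUE, sep = "\t")
  genes <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- genes
  if (is.null(organelle_genes)) organelle_genes <- character()
  if (!is.null(organelle_pattern))
    organelle_genes <- union(organelle_genes, grep(organelle_pattern, genes, value = TRUE))
  count_matrix(m, organelle_genes = organelle_genes)
}

#' Write an RNA count matrix as TSV
#' @param counts a [count_matrix].
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  dt <- data.table(gene_id = rownames(counts))
  dt <- cbind(dt, as.data.table(unclass(counts)))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' @param path outfmt-6 file: 12 tab-separated columns, no header.
#' @param subject_class class of every subject in this file (gene, TE, or
#'   TEgene), or NULL if the file carries a 13th class column.
#' @return A [blast_hits] table.
#' @export
read_blast6 <- function(path, subject_class = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (is.null(subject_class)) {
    if (ncol(dt) != 13L)
      stop("read_blast6: expected 13 columns (12 outfmt-6 + subject_class), got ",
           ncol(dt))
  } else if (ncol(dt) != 12L) {
    stop("read_blast6: expected 12 outfmt-6 columns, got ", ncol(dt))
  }
  setnames(dt, seq_len(12L),
           c("query_id", "subject_id", "pct_identity", "aln_len", "mismatches",
             "gaps", "qstart", "qend", "sstart", "send", "evalue", "bitscore"))
  if (!is.numeric(dt$bitscore))
    stop("read_blast6: non-numeric bitscore in ", path)
  if (is.null(subject_class)) setnames(dt, 13L, "subject_class")
  else dt[, subject_class := subject_class]
  blast_hits(dt)
}

#' Read / write a sample sheet (TSV with header)
#' @param path TSV with columns nucleus_id, genotype, experiment, plate, well.
#' @return A [sample_sheet].
#' @export
read_sample_sheet <- function(path) sample_sheet(fread(path, sep = "\t"))

#' @rdname read_sample_sheet
#' @param sheet a [sample_sheet].
#' @export
write_sample_sheet <- function(sheet, path) {
  fwrite(as.data.table(sheet), path, sep = "\t")
  invisible(path)
}

#' Write a pooled methylation track as bedGraph
#'
#' Emits the fraction methylated per covered position (or per fixed-width
#' bin when `bin_size` is given), for one context of a pooled track.
#'
#' @param track data.table with columns chrom, pos, context, mc, cov
#'   (e.g. one cluster/genotype slice of [pool_cluster] output).
#' @param path output path.
#' @param context context to export (CG, CHG or CHH).
#' @param bin_size optional bin width in bp; NULL writes per-position rows.
#' @export
write_bedgraph <- function(track, path, context = "CG", bin_size = NULL) {
  ctx <- context
  dt <- as.data.table(track)[context == ctx]
  if (is.null(bin_size)) {
    out <- dt[, .(chrom, start = pos, end = pos + 1L, value = mc / cov)]
  } else {
    out <- dt[, .(mc = sum(mc), cov = sum(cov)),
              by = .(chrom, bin = pos %/% as.integer(bin_size))]
    out <- out[, .(chrom, start = bin * as.integer(bin_size),
                   end = (bin + 1L) * as.integer(bin_size), value = mc / cov)]
  }
  setorder(out, chrom, start)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
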