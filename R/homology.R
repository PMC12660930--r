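# Gene/TE homology classification from BLAST tabular bitscores.

#' Classify loci by best gene vs TE bitscore
#'
#' Per locus, the best gene bitscore and the best TE bitscore (TE and
#' TEgene subjects together) are compared; a score at or below
#' `min_bitscore` counts as no significant homology. Significance is
#' evaluated before the ratio rule:
#' only TE significant -> "TE"; only gene significant -> "gene"; both
#' significant -> the larger category when one score is at least `ratio`
#' times the other, else "ambiguous"; neither significant -> "neither".
#'
#' @param hits a [blast_hits] table (query_id is the locus id).
#' @param loci optional locus ids to report (loci without hits classify
#'   as "neither"); defaults to the query ids present.
#' @param min_bitscore significance cutoff (strict >).
#' @param ratio fold difference deciding between two significant scores.
#' @return data.table: locus_id, best_gene_bitscore, best_TE_bitscore,
#'   label.
#' @export
classify_homology <- function(hits, loci = NULL, min_bitscore = 100,
                              ratio = 3.0) {
  dt <- as.data.table(hits)
  if (nrow(dt) && any(dt$bitscore < 0))
    stop("classify_homology: negative bitscore")
  best <- dt[, .(
    best_gene_bitscore = max(c(0, bitscore[subject_class == "gene"])),
    best_TE_bitscore = max(c(0, bitscore[subject_class %in% c("TE", "TEgene")]))),
    by = .(locus_id = query_id)]
  if (is.null(loci)) loci <- best$locus_id
  out <- best[data.table(locus_id = as.character(loci)), on = "locus_id"]
  out[is.na(best_gene_bitscore), best_gene_bitscore := 0]
  out[is.na(best_TE_bitscore), best_TE_bitscore := 0]
  out[, label := {
    g_sig <- best_gene_bitscore > min_bitscore
    t_sig <- best_TE_bitscore > min_bitscore
    fcase(
      t_sig & !g_sig, "TE",
      g_sig & !t_sig, "gene",
      g_sig & t_sig &
        pmax(best_gene_bitscore, best_TE_bitscore) >=
        ratio * pmin(best_gene_bitscore, best_TE_bitscore),
      fifelse(best_gene_bitscore >= best_TE_bitscore, "gene", "TE"),
      g_sig & t_sig, "ambiguous",
      default = "neither")
  }]
  out[]
}
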