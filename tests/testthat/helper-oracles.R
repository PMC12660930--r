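# Independent oracles and small fixture builders shared across tests.
library(data.table)

# Brute-force reciprocal-overlap oracle: per-base logical coverage vectors
# and O(n*m) pairwise intersections. Deliberately naive; only feasible on
# small coordinate ranges.
oracle_reciprocal_overlap <- function(a, b, frac = 0.5) {
  a <- as.data.table(a)[, .(chrom, start, end)]
  b <- as.data.table(b)[, .(chrom, start, end)]
  cov_vec <- function(d, ch, L) {
    v <- logical(L)
    for (i in which(d$chrom == ch)) v[(d$start[i] + 1L):d$end[i]] <- TRUE
    v
  }
  chroms <- union(a$chrom, b$chrom)
  L <- max(c(a$end, b$end)) + 1L
  bcov <- lapply(chroms, function(ch) cov_vec(b, ch, L))
  names(bcov) <- chroms
  acov <- lapply(chroms, function(ch) cov_vec(a, ch, L))
  names(acov) <- chroms
  pair_shared <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))
  over_one <- function(x, other, othercov) {
    sapply(seq_len(nrow(x)), function(i) {
      ch <- x$chrom[i]; s <- x$start[i]; e <- x$end[i]
      shared <- sum(othercov[[ch]][(s + 1L):e])
      if (shared > frac * (e - s)) return(TRUE)
      oi <- which(other$chrom == ch)
      any(vapply(oi, function(j)
        pair_shared(s, e, other$start[j], other$end[j]) >
          frac * (other$end[j] - other$start[j]), logical(1)))
    })
  }
  list(a = over_one(a, b, bcov), b = over_one(b, a, acov))
}

# Enumeration oracle for the gene/TE bitscore rule: a literal transcription
# of the classification table, independent of the vectorised implementation.
oracle_homology <- function(best_gene, best_te, min_bs = 100, ratio = 3) {
  g_sig <- best_gene > min_bs
  t_sig <- best_te > min_bs
  if (!g_sig && !t_sig) return("neither")
  if (g_sig && !t_sig) return("gene")
  if (t_sig && !g_sig) return("TE")
  hi <- max(best_gene, best_te); lo <- min(best_gene, best_te)
  if (hi >= ratio * lo) {
    if (best_gene >= best_te) "gene" else "TE"
  } else "ambiguous"
}

# random non-self-overlapping interval set on small coordinates
random_region_set <- function(n, chroms = c("Chr1", "Chr2"), L = 10000L,
                              max_len = 200L, name = "rand") {
  rows <- list()
  occupied <- lapply(chroms, function(x) logical(L))
  names(occupied) <- chroms
  tries <- 0L
  while (length(rows) < n && tries < n * 200L) {
    tries <- tries + 1L
    ch <- sample(chroms, 1L)
    len <- sample.int(max_len, 1L)
    s <- sample.int(L - len, 1L) - 1L
    if (!any(occupied[[ch]][(s + 1L):(s + len)])) {
      occupied[[ch]][(s + 1L):(s + len)] <- TRUE
      rows[[length(rows) + 1L]] <- data.table(chrom = ch, start = s,
                                              end = s + len)
    }
  }
  region_set(rbindlist(rows), name = name)
}

# minimal hand-built meth_calls table
mk_calls <- function(nucleus_id, pos, mc, cov, chrom = "Chr1",
                     context = "CG", strand = "+") {
  meth_calls(data.table(chrom = chrom, pos = as.integer(pos),
                        strand = strand, context = context,
                        mc = as.integer(mc), cov = as.integer(cov)),
             nucleus_id = nucleus_id)
}
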