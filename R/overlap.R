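# Reciprocal >50% interval overlap between region sets, and a
# length-preserving shuffle null for enrichment testing.

# merge overlapping (not merely book-ended) intervals within a set;
# warn if anything merged
.merge_regions <- function(rs, warn = TRUE) {
  dt <- as.data.table(rs)[, .(chrom, start, end)]
  setorder(dt, chrom, start, end)
  dt[, grp := cumsum(c(TRUE, start[-1L] >= cummax(end)[-.N])), by = chrom]
  merged <- dt[, .(start = min(start), end = max(end)),
               by = .(chrom, grp)][, grp := NULL]
  if (warn && nrow(merged) < nrow(dt))
    warning("reciprocal_overlap: ", nrow(dt) - nrow(merged),
            " overlapping intervals merged within '", attr(rs, "name"), "'")
  region_set(merged, name = attr(rs, "name") %||% "regions")
}

#' Reciprocal coverage overlap between two region sets
#'
#' An A interval counts as overlapping when the bases it shares with the
#' union of B strictly exceed `frac` of its own length, OR when some
#' single B interval has more than `frac` of its length covered by that A
#' interval ("either ... >50% covered by the other"); symmetrically for
#' B. Overlapping intervals within a set are merged first (with a
#' warning).
#'
#' @param a,b [region_set]s.
#' @param frac coverage fraction threshold (strict inequality).
#' @return list: `a` and `b` per-interval data.tables (frac_covered,
#'   overlapping), and `summary` (n and n_overlapping per set).
#' @export
reciprocal_overlap <- function(a, b, frac = 0.5) {
  am <- .merge_regions(a); bm <- .merge_regions(b)
  am[, id := sprintf("A%05d", .I)]; bm[, id := sprintf("B%05d", .I)]
  setkey(am, chrom, start, end); setkey(bm, chrom, start, end)
  pairs <- foverlaps(am, bm, type = "any", nomatch = NULL)
  # per-pair shared bases; columns: b(start,end) = start/end, a = i.start/i.end
  pairs[, shared := pmin(end, i.end) - pmax(start, i.start)]
  a_sh <- pairs[, .(shared = sum(shared)), by = .(id = i.id)]
  b_sh <- pairs[, .(shared = sum(shared)), by = .(id = id)]
  # single-partner clause: any one partner covered > frac of its length
  a_from_b <- pairs[shared > frac * (end - start), unique(i.id)]
  b_from_a <- pairs[shared > frac * (i.end - i.start), unique(id)]
  res_a <- a_sh[am, on = "id"]
  res_a[is.na(shared), shared := 0L]
  res_a[, frac_covered := shared / (end - start)]
  res_a[, overlapping := shared > frac * (end - start) | id %in% a_from_b]
  res_b <- b_sh[bm, on = "id"]
  res_b[is.na(shared), shared := 0L]
  res_b[, frac_covered := shared / (end - start)]
  res_b[, overlapping := shared > frac * (end - start) | id %in% b_from_a]
  setcolorder(res_a, c("chrom", "start", "end", "id"))
  setcolorder(res_b, c("chrom", "start", "end", "id"))
  list(a = res_a[], b = res_b[],
       summary = data.table(set = c("a", "b"),
                            n = c(nrow(res_a), nrow(res_b)),
                            n_overlapping = c(sum(res_a$overlapping),
                                              sum(res_b$overlapping))))
}

#' Length-preserving random shuffle of a region set
#'
#' Interval lengths (and, by default, per-chromosome counts) are
#' preserved; placements are uniform over valid start positions, with
#' rejection sampling to keep shuffled intervals non-overlapping within
#' the set.
#'
#' @param rs a [region_set].
#' @param chrom_sizes named chromosome lengths.
#' @param n number of independent shuffles.
#' @param seed optional seed for reproducible shuffles.
#' @param within_chrom keep each interval on its source chromosome.
#' @param no_self_overlap reject placements that overlap an already
#'   placed interval of the same shuffle.
#' @param max_tries rejection-sampling retries per interval.
#' @return a [region_set] when n = 1, else a list of them.
#' @export
shuffle_regions <- function(rs, chrom_sizes, n = 1L, seed = NULL,
                            within_chrom = TRUE, no_self_overlap = TRUE,
                            max_tries = 1000L) {
  check_chrom_sizes(chrom_sizes)
  if (!is.null(seed)) set.seed(seed)
  src <- as.data.table(rs)
  one <- function(iter) {
    d <- copy(src)
    if (!within_chrom)
      d[, chrom := sample(names(chrom_sizes), .N, replace = TRUE,
                          prob = chrom_sizes / sum(chrom_sizes))]
    placed <- lapply(names(chrom_sizes), function(x) NULL)
    names(placed) <- names(chrom_sizes)
    out <- vector("list", nrow(d))
    ord <- order(-(d$end - d$start))  # place long intervals first
    for (i in ord) {
      len <- d$end[i] - d$start[i]
      ch <- d$chrom[i]
      L <- chrom_sizes[[ch]]
      if (L < len) stop("shuffle_regions: interval longer than chromosome ", ch)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- sample.int(L - len + 1L, 1L) - 1L
        e <- s + len
        p <- placed[[ch]]
        if (!no_self_overlap || is.null(p) ||
            !any(p$start < e & p$end > s)) { ok <- TRUE; break }
      }
      if (!ok) stop("shuffle_regions: could not place interval after ",
                    max_tries, " tries (chromosome too crowded)")
      placed[[ch]] <- rbind(p, data.table(start = s, end = e))
      out[[i]] <- data.table(chrom = ch, start = s, end = e, id = d$id[i])
    }
    region_set(rbindlist(out),
               name = paste0(attr(rs, "name") %||% "regions", "_shuffle", iter))
  }
  res <- lapply(seq_len(n), one)
  if (n == 1L) res[[1L]] else res
}

#' Shuffle-null enrichment test for reciprocal overlap
#'
#' Recomputes the observed count of A intervals overlapping B, then the
#' same count with A replaced by `n_iter` independent shuffles, and
#' reports the empirical z-score and one-sided enrichment p-value.
#'
#' @inheritParams reciprocal_overlap
#' @param chrom_sizes named chromosome lengths for shuffling.
#' @param n_iter number of shuffles.
#' @param seed seed for the shuffles.
#' @return list: observed, null (vector), z, p_empirical.
#' @export
overlap_shuffle_test <- function(a, b, chrom_sizes, frac = 0.5,
                                 n_iter = 100L, seed = NULL) {
  obs <- reciprocal_overlap(a, b, frac)$summary[set == "a", n_overlapping]
  shufs <- shuffle_regions(a, chrom_sizes, n = n_iter, seed = seed)
  null <- vapply(shufs, function(s)
    suppressWarnings(reciprocal_overlap(s, b, frac))$summary[
      set == "a", n_overlapping], numeric(1))
  z <- if (sd(null) > 0) (obs - mean(null)) / sd(null) else
    sign(obs - mean(null)) * Inf
  list(observed = obs, null = null, z = z,
       p_empirical = (1 + sum(null >= obs)) / (1 + n_iter))
}
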