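# Region methylation statistics: per-nucleus weighted region means,
# cluster/genotype pseudobulk pooling, TSS windows, metaplot profiles,
# mC density bins, Cohen's d and the stratified effect-size grid.

# join sites onto regions; returns meth rows annotated with region id.
# foverlaps treats intervals as closed, so the half-open [start, end) is
# joined as the closed [start, end - 1] against point sites.
.sites_in_regions <- function(meth, regions) {
  dt <- as.data.table(meth)
  rs <- as.data.table(regions)[, .(chrom, start, end = end - 1L,
                                   region_id = id, region_strand = strand)]
  setkey(rs, chrom, start, end)
  dt2 <- cbind(dt, dt[, .(start = pos, end = pos)])
  setkey(dt2, chrom, start, end)
  foverlaps(dt2, rs, type = "any", nomatch = NULL)
}

#' Per-nucleus weighted mean methylation over a region set
#'
#' The weighted mean is sum(methylated) / sum(total) across all covered
#' cytosines of the requested context inside the regions. Nuclei with no
#' qualifying coverage (or fewer than `min_sites` covered sites) get NA.
#'
#' @param meth a [meth_calls] cohort table.
#' @param regions a [region_set].
#' @param context CG, CHG or CHH.
#' @param min_cov minimum per-site coverage (1 for single nuclei; bulk
#'   analyses use 5).
#' @param min_sites minimum number of qualifying sites per nucleus.
#' @return data.table: nucleus_id, n_sites, mc, cov, mean.
#' @export
region_mean_per_nucleus <- function(meth, regions, context = "CG",
                                    min_cov = 1L, min_sites = 1L) {
  stopifnot(context %in% VALID_CONTEXTS)
  ctx <- context
  hits <- .sites_in_regions(meth, regions)
  hits <- hits[context == ctx & cov >= min_cov]
  agg <- hits[, .(n_sites = .N, mc = sum(mc), cov = sum(cov)), by = nucleus_id]
  out <- data.table(nucleus_id = unique(as.data.table(meth)$nucleus_id))
  out <- agg[out, on = "nucleus_id"]
  out[is.na(n_sites), `:=`(n_sites = 0L, mc = 0L, cov = 0L)]
  out[, mean := fifelse(cov > 0L & n_sites >= min_sites, mc / cov, NA_real_)]
  setorder(out, nucleus_id)
  out[]
}

#' Pool per-site methylation into cluster/genotype pseudobulk tracks
#'
#' Per-site methylated and total counts are summed across all member
#' nuclei of each (cluster, genotype); the pooled fraction is therefore
#' exactly the coverage-weighted mean of per-nucleus fractions. Censored
#' nuclei are excluded simply by not appearing in `assignment`.
#'
#' @param meth a [meth_calls] cohort table.
#' @param assignment data.table with nucleus_id and cluster (e.g. from
#'   [assign_clusters]); only listed nuclei are pooled.
#' @param sheet a [sample_sheet] supplying genotypes.
#' @return data.table: cluster, genotype, chrom, pos, strand, context,
#'   mc, cov.
#' @export
pool_cluster <- function(meth, assignment, sheet) {
  lab <- as.data.table(assignment)[, .(nucleus_id, cluster)]
  lab <- as.data.table(sheet)[, .(nucleus_id, genotype)][lab, on = "nucleus_id"]
  dt <- lab[as.data.table(meth), on = "nucleus_id", nomatch = NULL]
  empty <- setdiff(lab$cluster, dt$cluster)
  if (length(empty))
    warning("pool_cluster: empty cluster(s): ", paste(empty, collapse = ", "))
  out <- dt[, .(mc = sum(mc), cov = sum(cov)),
            by = .(cluster, genotype, chrom, pos, strand, context)]
  setorder(out, cluster, genotype, chrom, pos)
  out[]
}

#' Build TSS windows from stranded anchor regions
#'
#' The anchor is the 5' end of each region (start on +, end on -); the
#' window is [anchor - flank, anchor + flank), clipped to chromosome
#' bounds.
#'
#' @param tss a stranded [region_set] (e.g. transcript bodies).
#' @param flank window half-width in bp (> 0).
#' @param chrom_sizes named chromosome lengths for clipping.
#' @return a [region_set] of TSS windows (ids preserved).
#' @export
tss_window_regions <- function(tss, flank = 400L, chrom_sizes) {
  if (flank <= 0L) stop("tss_window_regions: flank must be > 0")
  check_chrom_sizes(chrom_sizes)
  dt <- as.data.table(tss)
  if (any(is.na(dt$strand)))
    stop("tss_window_regions: all regions must be stranded")
  dt[, anchor := fifelse(strand == "+", start, end)]
  if (any(dt$anchor < 0L | dt$anchor > chrom_sizes[dt$chrom]))
    stop("tss_window_regions: anchor outside chromosome")
  out <- dt[, .(chrom, start = pmax(0L, anchor - as.integer(flank)),
                end = pmin(as.integer(chrom_sizes[chrom]),
                           anchor + as.integer(flank)),
                id, strand)]
  region_set(out, name = paste0(attr(tss, "name"), "_tss", flank))
}

#' Metaplot profile of a pooled methylation track over regions
#'
#' In `reference_point` mode sites are binned by their strand-aware offset
#' from each region's 5' anchor within [-flank, flank); in `scale_regions`
#' mode each region body is linearly mapped onto `n_bins` bins. Each bin's
#' value is the coverage-weighted mean sum(mc)/sum(cov) over all
#' region-aligned sites in the bin; reverse-strand regions are flipped so
#' profiles are orientation-consistent.
#'
#' @param track pooled track from [pool_cluster] (any subset of its rows),
#'   or a [meth_calls] table with an added grouping — only chrom, pos,
#'   context, mc, cov are used.
#' @param regions a [region_set]; strand NA is treated as "+".
#' @param mode "reference_point" or "scale_regions".
#' @param context context to profile.
#' @param flank flank in bp (reference_point mode).
#' @param n_bins number of profile bins.
#' @return data.table: bin (1..n_bins), offset/fraction at bin midpoint,
#'   mc, cov, level.
#' @export
profile_matrix <- function(track, regions,
                           mode = c("reference_point", "scale_regions"),
                           context = "CG", flank = 1000L, n_bins = 50L) {
  mode <- match.arg(mode)
  ctx <- context
  dt <- as.data.table(track)[context == ctx]
  rs <- as.data.table(regions)
  rs[is.na(strand), strand := "+"]
  if (mode == "scale_regions" && any(rs$end - rs$start < 1L))
    stop("profile_matrix: region shorter than 1 bp")
  rs2 <- if (mode == "reference_point") {
    rs[, .(chrom, start = fifelse(strand == "+", start, end) - as.integer(flank),
           end = fifelse(strand == "+", start, end) + as.integer(flank),
           anchor = fifelse(strand == "+", start, end),
           rstart = start, rend = end, strand)]
  } else {
    rs[, .(chrom, start, end, anchor = start, rstart = start, rend = end, strand)]
  }
  rs2[, start := pmax(0L, start)]
  rs2[, end := end - 1L]   # closed-interval join against point sites
  setkey(rs2, chrom, start, end)
  iv <- dt[, .(chrom, start = pos, end = pos, pos, mc, cov)]
  setkey(iv, chrom, start, end)
  ov <- foverlaps(iv, rs2, type = "any", nomatch = NULL)
  if (mode == "reference_point") {
    ov[, off := fifelse(strand == "+", pos - anchor, anchor - pos)]
    ov <- ov[off >= -flank & off < flank]
    width <- 2 * flank / n_bins
    ov[, bin := pmin(n_bins, floor((off + flank) / width) + 1L)]
    mids <- -flank + (seq_len(n_bins) - 0.5) * width
  } else {
    ov[, frac := fifelse(strand == "+", (pos - rstart) / (rend - rstart),
                         (rend - 1L - pos) / (rend - rstart))]
    ov <- ov[frac >= 0 & frac < 1]
    ov[, bin := pmin(n_bins, floor(frac * n_bins) + 1L)]
    mids <- (seq_len(n_bins) - 0.5) / n_bins
  }
  agg <- ov[, .(mc = sum(mc), cov = sum(cov)), by = bin]
  out <- data.table(bin = seq_len(n_bins), mid = mids)
  out <- agg[out, on = "bin"]
  out[is.na(cov), `:=`(mc = 0L, cov = 0L)]
  out[, level := fifelse(cov > 0L, mc / cov, NA_real_)]
  setorder(out, bin)
  out[]
}

#' mC density over fixed-width bins
#'
#' Density is the sum over qualifying sites (coverage >= `min_cov`) of
#' 100 * mc/cov — i.e. summed per-cytosine methylation percentages — per
#' bin per context. In `tiled` mode the genome is split into
#' non-overlapping `bin_size` bins (empty bins report 0); in
#' `peak_centered` mode one window of width `bin_size` is centred on the
#' midpoint of each interval in `centers`.
#'
#' @param track per-site table with chrom, pos, context, mc, cov (bulk
#'   table or pooled track).
#' @param bin_size bin width in bp (default 400).
#' @param mode "tiled" or "peak_centered".
#' @param centers a [region_set] whose interval midpoints anchor the
#'   windows (peak_centered mode).
#' @param min_cov minimum per-site coverage (default 5, the bulk rule).
#' @param chrom_sizes named chromosome lengths (tiled mode; defines the
#'   full bin grid so empty bins appear with density 0).
#' @return data.table: chrom, start, end (and id in peak_centered mode),
#'   context, density.
#' @export
mc_density_bins <- function(track, bin_size = 400L,
                            mode = c("tiled", "peak_centered"),
                            centers = NULL, min_cov = 5L,
                            chrom_sizes = NULL) {
  mode <- match.arg(mode)
  dt <- as.data.table(track)[cov >= min_cov]
  dt[, pct := 100 * mc / cov]
  if (mode == "tiled") {
    if (is.null(chrom_sizes)) stop("mc_density_bins: tiled mode needs chrom_sizes")
    check_chrom_sizes(chrom_sizes)
    grid <- rbindlist(lapply(names(chrom_sizes), function(ch) {
      nb <- ceiling(chrom_sizes[[ch]] / bin_size)
      CJ(chrom = ch, bin = seq_len(nb) - 1L, context = VALID_CONTEXTS,
         sorted = FALSE)
    }))
    agg <- dt[chrom %in% names(chrom_sizes),
              .(density = sum(pct)),
              by = .(chrom, bin = pos %/% as.integer(bin_size), context)]
    out <- agg[grid, on = c("chrom", "bin", "context")]
    out[is.na(density), density := 0]
    out[, `:=`(start = bin * as.integer(bin_size),
               end = (bin + 1L) * as.integer(bin_size), bin = NULL)]
    setcolorder(out, c("chrom", "start", "end", "context", "density"))
    setorder(out, chrom, start, context)
  } else {
    if (is.null(centers)) stop("mc_density_bins: peak_centered mode needs centers")
    half <- as.integer(bin_size) %/% 2L
    win <- as.data.table(centers)[, .(chrom,
                                      mid = (start + end) %/% 2L, id)]
    win[, `:=`(start = mid - half, end = mid + half, mid = NULL)]
    wjoin <- copy(win)[, end := end - 1L]   # half-open window, closed join
    setkey(wjoin, chrom, start, end)
    iv <- dt[, .(chrom, start = pos, end = pos, context, pct)]
    setkey(iv, chrom, start, end)
    ov <- foverlaps(iv, wjoin, type = "any", nomatch = NULL)
    ov[, end := end + 1L]
    agg <- ov[, .(density = sum(pct)), by = .(chrom, start, end, id, context)]
    grid <- CJ(id = win$id, context = VALID_CONTEXTS, sorted = FALSE)
    out <- agg[win[grid, on = "id"], on = c("chrom", "start", "end", "id", "context")]
    out[is.na(density), density := 0]
    setorder(out, chrom, start, context)
  }
  out[]
}

#' Cohen's d with pooled standard deviation
#'
#' d = (mean(A) - mean(B)) / s_p with
#' s_p = sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA+nB-2)), sample SDs with
#' n-1 denominators. Missing values are dropped. When both groups are
#' constant: d = 0 if the means agree, signed infinity otherwise.
#'
#' @param a,b numeric vectors (>= 2 non-missing values each).
#' @return scalar d (NA when a group has fewer than 2 values).
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) return(NA_real_)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  dm <- mean(a) - mean(b)
  if (sp == 0) {
    if (dm == 0) 0 else sign(dm) * Inf
  } else dm / sp
}

#' Star category for an effect size
#'
#' |d| < 0.2 -> "n.e."; [0.2, 0.5) -> "*"; [0.5, 0.9) -> "**";
#' [0.9, 1.5) -> "***"; >= 1.5 (including infinite) -> "****".
#' Intervals are closed on the left so the mapping is total.
#'
#' @param d numeric vector of effect sizes.
#' @return character vector of labels (NA maps to NA).
#' @export
star_category <- function(d) {
  cut_pts <- c(0, 0.2, 0.5, 0.9, 1.5, Inf)
  labs <- c("n.e.", "*", "**", "***", "****")
  out <- labs[findInterval(abs(d), cut_pts, rightmost.closed = TRUE)]
  out[is.infinite(d)] <- "****"
  out[is.na(d)] <- NA_character_
  out
}

#' Stratified effect-size grid over clusters and genotype pairs
#'
#' For each (region set x context x cluster x genotype pair) computes
#' group means/SDs of per-nucleus region methylation, Cohen's d
#' (genotype A minus genotype B), its star category, and a two-sided
#' Welch t-test p-value. Cells with fewer than `min_n` nuclei in either
#' group are marked insufficient.
#'
#' @param meth a [meth_calls] cohort table.
#' @param region_sets named list of [region_set]s.
#' @param assignment data.table with nucleus_id and cluster (censored
#'   nuclei excluded by omission).
#' @param sheet a [sample_sheet].
#' @param pairs list of length-2 character vectors c(genotype_A,
#'   genotype_B).
#' @param contexts contexts to analyse.
#' @param min_cov,min_sites per-nucleus rules passed to
#'   [region_mean_per_nucleus].
#' @param min_n minimum group size for a valid cell.
#' @return EffectSizeGrid data.table: region_set, context, cluster,
#'   genotype_A, genotype_B, n_A, n_B, mean_A, mean_B, sd_A, sd_B,
#'   cohens_d, star, t_pvalue, insufficient.
#' @export
effect_grid <- function(meth, region_sets, assignment, sheet, pairs,
                        contexts = "CG", min_cov = 1L, min_sites = 1L,
                        min_n = 2L) {
  if (!is.list(pairs[[1]]) && !is.character(pairs[[1]])) pairs <- list(pairs)
  lab <- as.data.table(assignment)[, .(nucleus_id, cluster)]
  lab <- as.data.table(sheet)[, .(nucleus_id, genotype)][lab, on = "nucleus_id"]
  rows <- list()
  for (rs_name in names(region_sets)) {
    for (ctx in contexts) {
      means <- region_mean_per_nucleus(meth, region_sets[[rs_name]],
                                       context = ctx, min_cov = min_cov,
                                       min_sites = min_sites)
      means <- lab[means, on = "nucleus_id", nomatch = NULL]
      for (cl in sort(unique(lab$cluster))) {
        for (pr in pairs) {
          a <- means[cluster == cl & genotype == pr[1L] & !is.na(mean), mean]
          b <- means[cluster == cl & genotype == pr[2L] & !is.na(mean), mean]
          insuff <- length(a) < min_n || length(b) < min_n
          d <- if (insuff) NA_real_ else cohens_d(a, b)
          p <- if (insuff || sd(a) == 0 && sd(b) == 0) NA_real_ else
            tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
          rows[[length(rows) + 1L]] <- data.table(
            region_set = rs_name, context = ctx, cluster = cl,
            genotype_A = pr[1L], genotype_B = pr[2L],
            n_A = length(a), n_B = length(b),
            mean_A = if (length(a)) mean(a) else NA_real_,
            mean_B = if (length(b)) mean(b) else NA_real_,
            sd_A = if (length(a) > 1L) sd(a) else NA_real_,
            sd_B = if (length(b) > 1L) sd(b) else NA_real_,
            cohens_d = d, star = star_category(d), t_pvalue = p,
            insufficient = insuff)
        }
      }
    }
  }
  rbindlist(rows)
}

#' Rolling-mean smoothed chromosome-scale methylation profile
#'
#' Pools a per-site track into fixed windows and smooths with a centred
#' rolling mean over `window` bp sliding by `step` bp.
#'
#' @param track per-site table with chrom, pos, context, mc, cov.
#' @param context context to profile.
#' @param window smoothing window in bp.
#' @param step step between reported positions in bp.
#' @return data.table: chrom, pos (window centre), level.
#' @export
chromosome_profile <- function(track, context = "CG", window = 100000L,
                               step = 10000L) {
  ctx <- context
  dt <- as.data.table(track)[context == ctx,
    .(mc = sum(mc), cov = sum(cov)), by = .(chrom, bin = pos %/% as.integer(step))]
  half <- as.integer(round(window / step / 2))
  out <- dt[, {
    full <- seq(min(bin), max(bin))
    mcv <- covv <- numeric(length(full))
    mcv[match(bin, full)] <- mc; covv[match(bin, full)] <- cov
    lev <- vapply(seq_along(full), function(i) {
      j <- max(1L, i - half):min(length(full), i + half)
      if (sum(covv[j]) > 0) sum(mcv[j]) / sum(covv[j]) else NA_real_
    }, numeric(1))
    .(pos = (full + 0.5) * step, level = lev)
  }, by = chrom]
  out[]
}
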