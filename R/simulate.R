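# Synthetic pollen snmCT-seq generator. Emulates haploid single-nucleus
# methylomes along the MN -> VN maturation trajectory (with GN/SN branch),
# genotype-specific demethylation with rescue, physical doublets (read-set
# unions), bisulfite conversion failures, and marker-driven RNA counts.
# All randomness flows from one master seed through per-nucleus substreams
# keyed by nucleus id, so generation is order-independent and reproducible.

# deterministic 31-bit substream seed from (master seed, string key)
.str_seed <- function(master, key) {
  M <- 2147483647
  h <- as.double(master %% M)
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% M
  as.integer(h)
}

.clip01 <- function(x) pmin(1, pmax(0, x))

#' Define a region model for the synthetic generator
#'
#' A region model is a named set of intervals with a baseline methylation
#' per context, per-cluster deltas (the developmental trajectory), and
#' per-genotype deltas with optional rescue (a fraction of regions where a
#' rescuing genotype reverts to the wild-type delta).
#'
#' @param name region-set name.
#' @param n number of regions.
#' @param min_len,max_len region length range (bp).
#' @param baseline named numeric, baseline methylation per context.
#' @param context the context the deltas act on (CG, CHG or CHH).
#' @param cluster_deltas named numeric, per-cluster additive delta.
#' @param genotype_deltas named numeric, per-genotype additive delta
#'   (applied only in `genotype_clusters`).
#' @param genotype_clusters clusters where genotype deltas apply; NULL
#'   means the config's VN clusters.
#' @param rescue NULL, or `list(genotype=, match=, fraction=)`: in
#'   `fraction` of regions (flagged rescued), `genotype`'s delta is
#'   replaced by `match`'s (default WT, delta 0).
#' @param pericentromeric place regions in the middle third of each
#'   chromosome (emulating pericentromeric CHH-gain regions).
#' @return A `region_model` list.
#' @export
region_model <- function(name, n = 40L, min_len = 800L, max_len = 2000L,
                         baseline = c(CG = 0.85, CHG = 0.35, CHH = 0.08),
                         context = "CG",
                         cluster_deltas = numeric(),
                         genotype_deltas = numeric(),
                         genotype_clusters = NULL,
                         rescue = NULL,
                         pericentromeric = FALSE) {
  stopifnot(context %in% VALID_CONTEXTS, n >= 1, min_len >= 1,
            max_len >= min_len)
  if (!all(VALID_CONTEXTS %in% names(baseline)))
    stop("region_model: baseline must name all of CG/CHG/CHH")
  if (!is.null(rescue)) {
    rescue <- modifyList(list(genotype = NULL, match = "WT", fraction = 0.5),
                         rescue)
    if (is.null(rescue$genotype)) stop("region_model: rescue$genotype required")
    if (rescue$fraction < 0 || rescue$fraction > 1)
      stop("region_model: rescue fraction must be in [0,1]")
  }
  structure(list(name = name, n = as.integer(n), min_len = as.integer(min_len),
                 max_len = as.integer(max_len), baseline = baseline,
                 context = context, cluster_deltas = cluster_deltas,
                 genotype_deltas = genotype_deltas,
                 genotype_clusters = genotype_clusters, rescue = rescue,
                 pericentromeric = pericentromeric),
            class = "region_model")
}

# default region models emulating the pollen trajectory: progressive CG
# demethylation at CG hypo DMRs during VN maturation, and CHH gain at
# pericentromeric CHH hyper DMRs.
.default_region_models <- function(genotypes, clusters) {
  cg_deltas <- c(MN = 0, MNtoVN = -0.05, VN1 = -0.15, VN1to2 = -0.25,
                 VN2 = -0.35, VN3 = -0.45, VN4 = -0.55, VN5 = -0.60,
                 GN = 0, SN = 0)
  chh_deltas <- c(MN = 0, MNtoVN = 0.03, VN1 = 0.08, VN1to2 = 0.12,
                  VN2 = 0.16, VN3 = 0.20, VN4 = 0.24, VN5 = 0.26,
                  GN = 0, SN = 0)
  cg_deltas <- cg_deltas[intersect(names(cg_deltas), clusters)]
  chh_deltas <- chh_deltas[intersect(names(chh_deltas), clusters)]
  gdel <- if (length(genotypes) > 1)
    setNames(c(0, rep(-0.25, length(genotypes) - 1L)), genotypes)
  else numeric()
  rescue <- if ("mutAB" %in% genotypes)
    list(genotype = "mutAB", match = genotypes[1L], fraction = 0.5) else NULL
  list(
    region_model("VN_CG_hypo_DMR", n = 40L,
                 baseline = c(CG = 0.85, CHG = 0.35, CHH = 0.08),
                 context = "CG", cluster_deltas = cg_deltas,
                 genotype_deltas = gdel, rescue = rescue),
    region_model("VN_CHH_hyper_DMR", n = 30L,
                 baseline = c(CG = 0.80, CHG = 0.40, CHH = 0.05),
                 context = "CHH", cluster_deltas = chh_deltas,
                 pericentromeric = TRUE)
  )
}

#' Build a synthetic-dataset configuration
#'
#' Defaults encode the study conditions the generator emulates: a 10-stage
#' pollen nucleus trajectory, haploid nuclei with at most one read per
#' site, an unmethylated chloroplast, and marker-gene-driven RNA counts.
#'
#' @param seed master seed; every substream is derived from it.
#' @param n_chrom,chrom_len nuclear chromosomes and their length (bp).
#' @param chloro_chrom,chloro_len chloroplast chromosome name and length.
#' @param clusters ordered cluster labels (the developmental trajectory;
#'   assignment priority follows this order).
#' @param vn_clusters,mature_vn VN subsets used for genotype effects and
#'   the mature-VN/SN doublet rule.
#' @param genotypes genotype labels; first is wild type.
#' @param n_per_group nuclei per cluster per genotype.
#' @param site_density cytosine sites per kb per context (named CG/CHG/CHH).
#' @param chloro_site_density chloroplast sites per kb (context CG).
#' @param background_meth genome background methylation per context.
#' @param capture_prob per-site Bernoulli read-capture probability
#'   (haploid: a captured site has coverage exactly 1).
#' @param capture_lognorm_sd log-SD of the per-nucleus capture factor;
#'   nuclei differ in total genome coverage, which is what the
#'   coverage-binned doublet censor conditions on.
#' @param chloro_capture_prob capture probability on the chloroplast
#'   (defaults to `capture_prob`).
#' @param doublet_rate fraction of emitted nuclei that are doublets.
#' @param doublet_pairing "vn_sn" (mature-VN + SN partners, the dominant
#'   physical association in mature pollen) or "random".
#' @param conversion_failure `list(rate=, conversion=)`: fraction of nuclei
#'   with failed bisulfite conversion and their conversion rate; unaffected
#'   nuclei convert perfectly.
#' @param region_models list of [region_model]s; NULL uses the default
#'   CG-hypo/CHH-hyper pair.
#' @param rna RNA model: n_genes, markers_per_cluster, marker_fold,
#'   adjacent_fold_fraction (markers of adjacent trajectory clusters are
#'   elevated by marker_fold to this power), baseline_mean, dispersion,
#'   n_organelle_genes, organelle_fraction, libsize_factor_sd.
#' @param plant planted QC failures for stress fixtures:
#'   list(low_rna=, low_genes=, low_wgbs=, high_organelle=,
#'   conversion_fail=, doublets=) counts.
#' @param make_meth,make_rna switch either modality off to speed up
#'   fixtures that only exercise one of them.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 3L, chrom_len = 3e5,
                       chloro_chrom = "ChrC", chloro_len = 2e4,
                       clusters = c("MN", "MNtoVN", "VN1", "VN1to2", "VN2",
                                    "VN3", "VN4", "VN5", "GN", "SN"),
                       vn_clusters = c("VN1", "VN1to2", "VN2", "VN3",
                                       "VN4", "VN5"),
                       mature_vn = c("VN4", "VN5"),
                       genotypes = "WT",
                       n_per_group = 20L,
                       site_density = c(CG = 4, CHG = 2, CHH = 6),
                       chloro_site_density = 10,
                       background_meth = c(CG = 0.24, CHG = 0.08, CHH = 0.03),
                       capture_prob = 0.05,
                       capture_lognorm_sd = 0.25,
                       chloro_capture_prob = NULL,
                       doublet_rate = 0,
                       doublet_pairing = c("vn_sn", "random"),
                       conversion_failure = list(rate = 0, conversion = 0.90),
                       region_models = NULL,
                       rna = list(),
                       plant = list(),
                       make_meth = TRUE, make_rna = TRUE) {
  doublet_pairing <- match.arg(doublet_pairing)
  rna <- modifyList(list(n_genes = 300L, markers_per_cluster = 8L,
                         marker_fold = 8, adjacent_fold_fraction = 0.75,
                         mature_fold_fraction = 0.85,
                         baseline_mean = 5, dispersion = 0.1,
                         n_organelle_genes = 10L, organelle_fraction = 0.03,
                         libsize_factor_sd = 0.15), rna)
  plant <- modifyList(list(low_rna = 0L, low_genes = 0L, low_wgbs = 0L,
                           high_organelle = 0L, conversion_fail = 0L,
                           doublets = NULL), plant)
  conversion_failure <- modifyList(list(rate = 0, conversion = 0.90),
                                   conversion_failure)
  if (is.null(region_models))
    region_models <- .default_region_models(genotypes, clusters)
  probs <- c(capture_prob, doublet_rate, conversion_failure$rate,
             conversion_failure$conversion, rna$organelle_fraction,
             background_meth)
  if (any(probs < 0 | probs > 1))
    stop("sim_config: probabilities and methylation levels must be in [0,1]")
  if (!all(VALID_CONTEXTS %in% names(site_density)))
    stop("sim_config: site_density must name CG/CHG/CHH")
  if (!all(vn_clusters %in% clusters) || !all(mature_vn %in% clusters))
    stop("sim_config: vn_clusters/mature_vn must be a subset of clusters")
  if (doublet_pairing == "vn_sn" &&
      (doublet_rate > 0 || !is.null(plant$doublets)) &&
      !("SN" %in% clusters && any(mature_vn %in% clusters)))
    stop("sim_config: vn_sn doublets need SN and a mature VN cluster")
  for (rm in region_models) {
    unknown <- setdiff(names(rm$cluster_deltas), clusters)
    if (length(unknown))
      stop("sim_config: cluster_deltas for unknown clusters: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_len = as.integer(chrom_len),
                 chloro_chrom = chloro_chrom,
                 chloro_len = as.integer(chloro_len),
                 clusters = clusters, vn_clusters = vn_clusters,
                 mature_vn = mature_vn, genotypes = genotypes,
                 n_per_group = as.integer(n_per_group),
                 site_density = site_density,
                 chloro_site_density = chloro_site_density,
                 background_meth = background_meth,
                 capture_prob = capture_prob,
                 capture_lognorm_sd = capture_lognorm_sd,
                 chloro_capture_prob = chloro_capture_prob %||% capture_prob,
                 doublet_rate = doublet_rate,
                 doublet_pairing = doublet_pairing,
                 conversion_failure = conversion_failure,
                 region_models = region_models, rna = rna, plant = plant,
                 make_meth = make_meth, make_rna = make_rna),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# developmental adjacency: the VN maturation trajectory is the main path;
# GN/SN branch off the microspore (MN -> GN -> SN). Mature VN stages share
# most markers, so their mutual edge is stronger.
.cluster_edges <- function(cfg) {
  w_adj <- cfg$rna$adjacent_fold_fraction
  w_mat <- cfg$rna$mature_fold_fraction
  branch <- intersect(c("GN", "SN"), cfg$clusters)
  main <- setdiff(cfg$clusters, branch)
  edges <- list()
  if (length(main) > 1L)
    for (i in seq_len(length(main) - 1L)) {
      w <- if (all(main[i + 0:1] %in% cfg$mature_vn)) w_mat else w_adj
      edges[[length(edges) + 1L]] <- list(a = main[i], b = main[i + 1L], w = w)
    }
  prev <- if (length(main)) main[1L] else NULL  # branch roots at the microspore
  for (b in branch) {
    if (!is.null(prev))
      edges[[length(edges) + 1L]] <- list(a = prev, b = b, w = w_adj)
    prev <- b
  }
  adj <- setNames(vector("list", length(cfg$clusters)), cfg$clusters)
  for (e in edges) {
    adj[[e$a]] <- rbind(adj[[e$a]], data.frame(nb = e$b, w = e$w))
    adj[[e$b]] <- rbind(adj[[e$b]], data.frame(nb = e$a, w = e$w))
  }
  adj
}

# --- genome layout ---------------------------------------------------------

.sim_sites <- function(cfg) {
  set.seed(.str_seed(cfg$seed, "sites"))
  out <- vector("list", cfg$n_chrom + 1L)
  for (i in seq_len(cfg$n_chrom)) {
    chrom <- paste0("Chr", i)
    n_per_ctx <- setNames(pmax(1L, round(cfg$chrom_len / 1000 * cfg$site_density)),
                          names(cfg$site_density))
    n_tot <- sum(n_per_ctx)
    pos <- sort(sample.int(cfg$chrom_len, n_tot) - 1L)
    ctx <- sample(rep(names(n_per_ctx), n_per_ctx))
    out[[i]] <- data.table(chrom = chrom, pos = pos,
                           strand = sample(VALID_STRANDS, n_tot, replace = TRUE),
                           context = ctx)
  }
  n_chl <- max(1L, round(cfg$chloro_len / 1000 * cfg$chloro_site_density))
  out[[cfg$n_chrom + 1L]] <- data.table(
    chrom = cfg$chloro_chrom, pos = sort(sample.int(cfg$chloro_len, n_chl) - 1L),
    strand = sample(VALID_STRANDS, n_chl, replace = TRUE), context = "CG")
  sites <- rbindlist(out)
  sites[, site := .I]
  sites
}

.place_regions <- function(cfg, rm, model_idx, occupied = NULL) {
  set.seed(.str_seed(cfg$seed, paste0("regions:", rm$name)))
  chroms <- paste0("Chr", seq_len(cfg$n_chrom))
  # regions never overlap, within a set or across sets: each locus belongs
  # to exactly one region model
  placed <- if (is.null(occupied))
    data.table(chrom = character(), start = integer(), end = integer())
  else occupied[, .(chrom, start, end)]
  rows <- vector("list", rm$n)
  for (k in seq_len(rm$n)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      chrom <- sample(chroms, 1L)
      len <- if (rm$max_len > rm$min_len)
        sample(rm$min_len:rm$max_len, 1L) else rm$min_len
      lo <- if (rm$pericentromeric) floor(cfg$chrom_len / 3) else 0L
      hi <- if (rm$pericentromeric) floor(2 * cfg$chrom_len / 3) else cfg$chrom_len
      if (hi - lo <= len) next
      start <- lo + sample.int(hi - lo - len, 1L) - 1L
      end <- start + len
      clash <- any(placed$chrom == chrom & placed$start < end &
                     placed$end > start)
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("simulate_dataset: could not place region ", k, " of ", rm$name)
    placed <- rbind(placed, data.table(chrom = chrom, start = start, end = end))
    rows[[k]] <- data.table(chrom = chrom, start = start, end = end,
                            id = sprintf("%s_%03d", rm$name, k))
  }
  rs <- rbindlist(rows)
  rs[, model := rm$name]
  rs[, model_idx := model_idx]
  rs
}

# per-region truth table over (context, cluster, genotype)
.region_truth <- function(cfg, rm, regions) {
  set.seed(.str_seed(cfg$seed, paste0("rescue:", rm$name)))
  n_resc <- if (is.null(rm$rescue)) 0L else round(rm$rescue$fraction * nrow(regions))
  rescued_ids <- if (n_resc > 0L) sample(regions$id, n_resc) else character()
  gclust <- rm$genotype_clusters %||% intersect(cfg$vn_clusters, cfg$clusters)
  grid <- CJ(id = regions$id, context = VALID_CONTEXTS,
             cluster = cfg$clusters, genotype = cfg$genotypes, sorted = FALSE)
  grid[, rescued := id %in% rescued_ids]
  grid[, m := rm$baseline[context]]
  cd <- rm$cluster_deltas
  if (length(cd))
    grid[context == rm$context & cluster %in% names(cd),
         m := m + cd[cluster]]
  gd <- rm$genotype_deltas
  if (length(gd)) {
    grid[context == rm$context & cluster %in% gclust & genotype %in% names(gd),
         m := m + gd[genotype]]
    if (!is.null(rm$rescue)) {
      match_delta <- if (rm$rescue$match %in% names(gd)) gd[[rm$rescue$match]] else 0
      grid[context == rm$context & cluster %in% gclust & rescued &
             genotype == rm$rescue$genotype,
           m := rm$baseline[context] +
             (if (length(cd)) fifelse(cluster %in% names(cd), cd[cluster], 0) else 0) +
             match_delta]
    }
  }
  grid[, m := .clip01(m)]
  grid[, model := rm$name]
  grid[]
}

# --- main generator --------------------------------------------------------

#' Simulate a joint single-nucleus methylome + transcriptome dataset
#'
#' Singleton nuclei are haploid: every site has coverage 0 or 1. Doublets
#' are read-set unions of two independently sampled nuclei, so sites
#' captured by both partners have coverage 2. A captured site's methylation
#' call is Bernoulli(true regional methylation); conversion-failure nuclei
#' additionally read unmethylated cytosines as methylated at rate
#' (1 - conversion), on all chromosomes including the (truly unmethylated)
#' chloroplast. RNA counts are negative binomial with cluster markers
#' elevated by the configured fold; organelle genes receive the configured
#' read fraction.
#'
#' @param cfg a [sim_config].
#' @return list with elements `meth` ([meth_calls] for the whole cohort),
#'   `counts` ([count_matrix]), `regions` (named list of [region_set]),
#'   `markers` (cluster -> marker gene ids), `sheet` ([sample_sheet]),
#'   `truth` (list of `nuclei` and `regions` ground-truth tables),
#'   `chrom_sizes`, `gene_lengths`, `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sites <- .sim_sites(cfg)
  n_sites <- nrow(sites)
  chrom_sizes <- c(setNames(rep(cfg$chrom_len, cfg$n_chrom),
                            paste0("Chr", seq_len(cfg$n_chrom))),
                   setNames(cfg$chloro_len, cfg$chloro_chrom))

  regions_all <- NULL
  for (i in seq_along(cfg$region_models))
    regions_all <- rbind(regions_all,
                         .place_regions(cfg, cfg$region_models[[i]], i,
                                        occupied = regions_all))
  region_sets <- lapply(split(regions_all, by = "model", sorted = FALSE),
                        function(d) region_set(d[, .(chrom, start, end, id)],
                                               name = d$model[1L]))
  names(region_sets) <- vapply(cfg$region_models, `[[`, "", "name")
  region_sets <- region_sets[names(region_sets)]

  truth_regions <- rbindlist(lapply(cfg$region_models, function(rm)
    .region_truth(cfg, rm, regions_all[model == rm$name])))

  # map each site to at most one region (earlier models take priority);
  # foverlaps is closed-interval, so join [start, end - 1] against points
  reg_iv <- regions_all[, .(chrom, start, end = end - 1L, id, model_idx)]
  setkey(reg_iv, chrom, start, end)
  site_iv <- sites[, .(chrom, start = pos, end = pos, site)]
  setkey(site_iv, chrom, start, end)
  ov <- foverlaps(site_iv, reg_iv, type = "any", nomatch = NULL)
  ov <- ov[order(model_idx)][!duplicated(site)]
  sites[, region_id := NA_character_]
  sites[ov$site, region_id := ov$id]
  is_chloro <- sites$chrom == cfg$chloro_chrom

  # true methylation per site for one (cluster, genotype)
  truth_key <- truth_regions[, .(id, context, cluster, genotype, m)]
  setkey(truth_key, cluster, genotype, id, context)
  site_meth <- function(cl, gt) {
    m <- cfg$background_meth[sites$context]
    m[is_chloro] <- 0
    sub <- truth_key[.(cl, gt)]
    idx <- sub[sites[!is.na(region_id), .(id = region_id, context, site)],
               on = c("id", "context")]
    m[idx$site] <- idx$m
    m
  }
  group_meth <- new.env(parent = emptyenv())
  get_meth <- function(cluster, genotype) {
    key <- paste(cluster, genotype, sep = "|")
    if (is.null(group_meth[[key]]))
      group_meth[[key]] <- site_meth(cluster, genotype)
    group_meth[[key]]
  }

  # --- nucleus roster ------------------------------------------------------
  roster <- CJ(cluster = factor(cfg$clusters, levels = cfg$clusters),
               genotype = factor(cfg$genotypes, levels = cfg$genotypes),
               rep = seq_len(cfg$n_per_group), sorted = FALSE)
  setorder(roster, genotype, cluster, rep)
  roster[, `:=`(cluster = as.character(cluster), genotype = as.character(genotype))]
  roster[, nucleus_id := sprintf("%s_%s_%03d", genotype, cluster, rep)]
  roster[, `:=`(is_doublet = FALSE, partner_clusters = NA_character_,
                planted = "none")]

  n_doub <- cfg$plant$doublets %||% round(cfg$doublet_rate * nrow(roster))
  if (n_doub > 0L) {
    set.seed(.str_seed(cfg$seed, "doublets"))
    dgt <- sample(cfg$genotypes, n_doub, replace = TRUE)
    if (cfg$doublet_pairing == "vn_sn") {
      c1 <- sample(intersect(cfg$mature_vn, cfg$clusters), n_doub, replace = TRUE)
      c2 <- rep("SN", n_doub)
    } else {
      c1 <- sample(cfg$clusters, n_doub, replace = TRUE)
      c2 <- sample(cfg$clusters, n_doub, replace = TRUE)
    }
    doub <- data.table(cluster = c1, genotype = dgt, rep = seq_len(n_doub),
                       nucleus_id = sprintf("DBL_%03d", seq_len(n_doub)),
                       is_doublet = TRUE,
                       partner_clusters = paste(c1, c2, sep = "+"),
                       planted = "doublet")
    roster <- rbind(roster, doub)
  }

  # planted QC failures among singletons (disjoint categories)
  set.seed(.str_seed(cfg$seed, "plant"))
  singles <- which(!roster$is_doublet)
  take <- function(n, label) {
    avail <- intersect(singles, which(roster$planted == "none"))
    if (n > length(avail)) stop("sim_config: not enough nuclei to plant ", label)
    pick <- sample(avail, n)
    roster[pick, planted := label]
  }
  if (cfg$plant$low_rna > 0L) take(cfg$plant$low_rna, "low_rna")
  if (cfg$plant$low_genes > 0L) take(cfg$plant$low_genes, "low_genes")
  if (cfg$plant$low_wgbs > 0L) take(cfg$plant$low_wgbs, "low_wgbs")
  if (cfg$plant$high_organelle > 0L) take(cfg$plant$high_organelle, "high_organelle")
  n_conv <- cfg$plant$conversion_fail
  if (n_conv == 0L && cfg$conversion_failure$rate > 0)
    n_conv <- round(cfg$conversion_failure$rate * length(singles))
  if (n_conv > 0L) take(n_conv, "conversion_fail")
  roster[, conversion := fifelse(planted == "conversion_fail",
                                 cfg$conversion_failure$conversion, 1)]

  # --- methylomes ----------------------------------------------------------
  draw_methylome <- function(key, cluster, genotype, conversion) {
    set.seed(.str_seed(cfg$seed, paste0("meth:", key)))
    fac <- rlnorm(1L, 0, cfg$capture_lognorm_sd)
    p_cap <- rep(min(0.95, cfg$capture_prob * fac), n_sites)
    p_cap[is_chloro] <- min(0.95, cfg$chloro_capture_prob * fac)
    cap <- which(runif(n_sites) < p_cap)
    m <- get_meth(cluster, genotype)[cap]
    if (conversion < 1) m <- m + (1 - m) * (1 - conversion)
    data.table(site = cap, mc = rbinom(length(cap), 1L, m), cov = 1L)
  }

  meth <- NULL
  if (cfg$make_meth) {
    tabs <- vector("list", nrow(roster))
    for (i in seq_len(nrow(roster))) {
      r <- roster[i]
      if (r$is_doublet) {
        parts <- strsplit(r$partner_clusters, "+", fixed = TRUE)[[1L]]
        a <- draw_methylome(paste0(r$nucleus_id, "/a"), parts[1L], r$genotype,
                            r$conversion)
        b <- draw_methylome(paste0(r$nucleus_id, "/b"), parts[2L], r$genotype,
                            r$conversion)
        d <- rbind(a, b)[, .(mc = sum(mc), cov = sum(cov)), by = site]
      } else {
        scale <- if (r$planted == "low_wgbs") 0.01 else 1
        d <- draw_methylome(r$nucleus_id, r$cluster, r$genotype, r$conversion)
        if (scale < 1) {
          set.seed(.str_seed(cfg$seed, paste0("thin:", r$nucleus_id)))
          d <- d[runif(.N) < scale]
        }
      }
      d[, nucleus_id := r$nucleus_id]
      tabs[[i]] <- d
    }
    meth <- rbindlist(tabs)
    meth <- sites[meth, on = "site"][, .(nucleus_id, chrom, pos, strand,
                                         context, mc, cov)]
    meth <- meth_calls(meth)
  }

  # --- RNA -----------------------------------------------------------------
  counts <- NULL; markers <- NULL; gene_lengths <- NULL
  if (cfg$make_rna) {
    rn <- cfg$rna
    genes <- sprintf("G%04d", seq_len(rn$n_genes))
    org <- sprintf("ORG%02d", seq_len(rn$n_organelle_genes))
    markers <- setNames(vector("list", length(cfg$clusters)), cfg$clusters)
    for (i in seq_along(cfg$clusters))
      markers[[i]] <- genes[((i - 1L) * rn$markers_per_cluster + 1L):
                              (i * rn$markers_per_cluster)]
    if (length(cfg$clusters) * rn$markers_per_cluster > rn$n_genes)
      stop("sim_config: not enough genes for marker panels")
    set.seed(.str_seed(cfg$seed, "gene_lengths"))
    gene_lengths <- setNames(sample(500:3000, rn$n_genes + rn$n_organelle_genes,
                                    replace = TRUE), c(genes, org))
    cluster_adj <- .cluster_edges(cfg)

    draw_rna <- function(key, cluster, lib_scale = 1, org_frac = rn$organelle_fraction,
                         gene_keep = NULL) {
      set.seed(.str_seed(cfg$seed, paste0("rna:", key)))
      mu <- rep(rn$baseline_mean, rn$n_genes)
      # markers of developmentally adjacent clusters are partially elevated:
      # trajectory stages are continuous, not discrete marker islands
      nb <- cluster_adj[[cluster]]
      if (!is.null(nb))
        for (j in seq_len(nrow(nb))) {
          ma <- match(markers[[nb$nb[j]]], genes)
          mu[ma] <- rn$baseline_mean * rn$marker_fold^nb$w[j]
        }
      mk <- match(markers[[cluster]], genes)
      mu[mk] <- rn$baseline_mean * rn$marker_fold
      if (!is.null(gene_keep)) mu[-gene_keep] <- 0
      mu <- mu * lib_scale * rlnorm(1L, 0, rn$libsize_factor_sd)
      x <- rnbinom(rn$n_genes, mu = mu, size = 1 / rn$dispersion)
      tot <- sum(x)
      mu_org <- tot * org_frac / (1 - org_frac) / rn$n_organelle_genes
      xo <- rnbinom(rn$n_organelle_genes, mu = mu_org, size = 1 / rn$dispersion)
      c(x, xo)
    }
    cm <- matrix(0L, nrow = rn$n_genes + rn$n_organelle_genes,
                 ncol = nrow(roster),
                 dimnames = list(c(genes, org), roster$nucleus_id))
    for (i in seq_len(nrow(roster))) {
      r <- roster[i]
      if (r$is_doublet) {
        parts <- strsplit(r$partner_clusters, "+", fixed = TRUE)[[1L]]
        cm[, i] <- draw_rna(paste0(r$nucleus_id, "/a"), parts[1L]) +
          draw_rna(paste0(r$nucleus_id, "/b"), parts[2L])
      } else if (r$planted == "low_rna") {
        cm[, i] <- draw_rna(r$nucleus_id, r$cluster, lib_scale = 0.25)
      } else if (r$planted == "low_genes") {
        set.seed(.str_seed(cfg$seed, paste0("keep:", r$nucleus_id)))
        keep <- sample.int(rn$n_genes, 150L)
        cm[, i] <- draw_rna(r$nucleus_id, r$cluster, lib_scale = 2,
                            gene_keep = keep)
      } else if (r$planted == "high_organelle") {
        cm[, i] <- draw_rna(r$nucleus_id, r$cluster, org_frac = 0.30)
      } else {
        cm[, i] <- draw_rna(r$nucleus_id, r$cluster)
      }
    }
    counts <- count_matrix(cm, organelle_genes = org)
  }

  # --- sample sheet & ground truth ----------------------------------------
  sheet <- sample_sheet(roster[, .(
    nucleus_id, genotype, experiment = "expt1",
    plate = sprintf("P%02d", ((seq_len(.N) - 1L) %/% 384L) + 1L),
    well = sprintf("%s%02d", LETTERS[((seq_len(.N) - 1L) %% 384L) %/% 24L + 1L],
                   (seq_len(.N) - 1L) %% 24L + 1L))])
  truth_nuclei <- roster[, .(nucleus_id, cluster, genotype, is_doublet,
                             partner_clusters, conversion,
                             conversion_ok = conversion >= 0.99, planted)]

  list(meth = meth, counts = counts, regions = region_sets, markers = markers,
       sheet = sheet,
       truth = list(nuclei = truth_nuclei, regions = truth_regions),
       chrom_sizes = chrom_sizes, gene_lengths = gene_lengths, config = cfg)
}

# --- fixture presets -------------------------------------------------------

.fixture_config <- function(name, seed = 1L) {
  switch(name,
    tiny = sim_config(seed = seed, clusters = c("MN", "VN2", "VN4", "SN"),
                      vn_clusters = c("VN2", "VN4"), mature_vn = "VN4",
                      n_per_group = 8L, n_chrom = 2L, chrom_len = 5e4,
                      capture_prob = 0.1,
                      region_models = list(region_model(
                        "VN_CG_hypo_DMR", n = 10L, min_len = 500L, max_len = 1000L,
                        cluster_deltas = c(MN = 0, VN2 = -0.35, VN4 = -0.55, SN = 0))),
                      plant = list(doublets = 2L)),
    qc_stress = sim_config(seed = seed,
                           clusters = c("MN", "VN2", "VN4", "VN5", "SN"),
                           vn_clusters = c("VN2", "VN4", "VN5"),
                           n_per_group = 12L, chrom_len = 1e5,
                           capture_prob = 0.1, chloro_capture_prob = 0.5,
                           chloro_site_density = 30,
                           capture_lognorm_sd = 0.4,
                           conversion_failure = list(rate = 0, conversion = 0.90),
                           plant = list(low_rna = 4L, low_genes = 4L,
                                        low_wgbs = 4L, high_organelle = 4L,
                                        conversion_fail = 4L, doublets = 5L)),
    trajectory = sim_config(seed = seed, n_per_group = 100L,
                            chrom_len = 1.5e5, capture_prob = 0.15,
                            plant = list(doublets = 30L)),
    rescue = sim_config(seed = seed,
                        clusters = c("MN", "VN1", "VN2", "SN"),
                        vn_clusters = c("VN1", "VN2"), mature_vn = "VN2",
                        genotypes = c("WT", "mutA", "mutAB"),
                        n_per_group = 200L, n_chrom = 2L, chrom_len = 1e5,
                        capture_prob = 0.3, make_rna = FALSE,
                        region_models = list(region_model(
                          "VN_CG_hypo_DMR", n = 30L, min_len = 1000L,
                          max_len = 2000L,
                          cluster_deltas = c(MN = 0, VN1 = -0.15, VN2 = -0.35,
                                             SN = 0),
                          genotype_deltas = c(WT = 0, mutA = -0.3, mutAB = -0.3),
                          rescue = list(genotype = "mutAB", match = "WT",
                                        fraction = 0.5)))),
    stop("make_fixture: unknown preset '", name, "'")
  )
}

#' Generate a named fixture preset, optionally writing it to disk
#'
#' Presets: `tiny` (< 50 nuclei, loads in well under a second),
#' `qc_stress` (known counts of planted failures per QC category),
#' `trajectory` (full 10-cluster trajectory, 100 nuclei/cluster, planted
#' mature-VN+SN doublets), `rescue` (three genotypes; mutAB restores
#' wild-type methylation at a flagged subset of regions).
#'
#' @param name preset id.
#' @param dir output directory; NULL returns the dataset in memory only.
#' @param seed master seed recorded in the emitted config.
#' @return The [simulate_dataset] result (invisibly when written to disk).
#' @export
make_fixture <- function(name, dir = NULL, seed = 1L) {
  cfg <- .fixture_config(name, seed = seed)
  sim <- simulate_dataset(cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(sim$meth)) {
      mdir <- file.path(dir, "meth")
      dir.create(mdir, showWarnings = FALSE)
      for (nid in unique(sim$meth$nucleus_id))
        write_meth_calls(sim$meth[nucleus_id == nid],
                         file.path(mdir, paste0(nid, ".tsv")))
    }
    if (!is.null(sim$counts)) write_counts(sim$counts, file.path(dir, "counts.tsv"))
    for (nm in names(sim$regions))
      write_bed(sim$regions[[nm]], file.path(dir, paste0(nm, ".bed")))
    write_sample_sheet(sim$sheet, file.path(dir, "sample_sheet.tsv"))
    fwrite(sim$truth$nuclei, file.path(dir, "ground_truth.tsv"), sep = "\t")
    fwrite(sim$truth$regions, file.path(dir, "ground_truth_regions.tsv"), sep = "\t")
    fwrite(data.table(chrom = names(sim$chrom_sizes), size = sim$chrom_sizes),
           file.path(dir, "chrom_sizes.tsv"), sep = "\t")
    cfg_out <- c(list(preset = name, seed = seed),
                 list(clusters = cfg$clusters, genotypes = cfg$genotypes,
                      n_per_group = cfg$n_per_group,
                      capture_prob = cfg$capture_prob,
                      doublet_pairing = cfg$doublet_pairing))
    yaml::write_yaml(cfg_out, file.path(dir, "config.resolved.yaml"))
  }
  invisible(sim)
}
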