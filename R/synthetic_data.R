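#' Simulation configuration for the synthetic input bundle
#'
#' Defaults emulate the study conditions the pipeline was built around:
#' a handful of SSR component maps sharing a minority of their markers,
#' distorted by per-map affine scaling plus jitter; veraison QTL observations
#' drawn around true meta-QTL locations in a 1-cluster (LG 1) + 3-cluster
#' (LG 2) layout; a toy genome with anchors and annotated genes; and a
#' 3-year, triplicated pre-veraison FPKM time course with a planted
#' transcriptomic transition.
#'
#' @param seed global seed (default 17).
#' @param n_lgs number of linkage groups.
#' @param lg_length_cm LG length in cM.
#' @param n_maps number of component maps.
#' @param markers_per_map markers sampled per map per LG.
#' @param shared_fraction expected sharing between maps (pool size is
#'   `markers_per_map / shared_fraction`).
#' @param scale_range per-map affine scale range.
#' @param jitter_sd per-marker positional jitter (cM).
#' @param true_metaqtls data.frame `lg`, `pos_cm`, `n_qtls` of planted
#'   meta-QTL locations.
#' @param sd_range range of per-QTL observation standard deviations (cM).
#' @param r2_range range of per-QTL variance explained.
#' @param n_studies number of distinct contributing studies (QTLs cycle
#'   through the first `n_studies` maps).
#' @param n_inversions planted adjacent-marker order conflicts.
#' @param n_isolated_groups planted linkage groups sharing < 2 markers.
#' @param n_duplicates planted same-study redundant QTLs.
#' @param n_unanchored planted QTLs on a shared-marker-free LG.
#' @param bp_per_cm physical expansion of the genetic map (bp per cM).
#' @param genes_per_lg genes per chromosome.
#' @param candidates_per_mqtl positional candidate genes planted under each
#'   true meta-QTL.
#' @param anchor_fraction fraction of shared markers carrying a bp anchor.
#' @param n_multihit planted multi-hit anchors.
#' @param n_incongruent planted anchors with out-of-order bp positions.
#' @param years year labels of the expression time course.
#' @param n_timepoints pre-veraison time points per year.
#' @param transition_timepoint named integer vector: per year, the earlier
#'   time point of the planted transition interval.
#' @param effect_size planted log2 fold change at the transition.
#' @param noise_sd replicate noise on log2 FPKM.
#' @param n_biomarkers transition biomarker genes.
#' @param n_never_expressed background genes kept below 1 FPKM everywhere.
#' @param n_extra_de background genes added to the external DE list.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 17L,
                       n_lgs = 2L,
                       lg_length_cm = 100,
                       n_maps = 10L,
                       markers_per_map = 60L,
                       shared_fraction = 0.4,
                       scale_range = c(0.8, 1.25),
                       jitter_sd = 0.5,
                       true_metaqtls = data.frame(
                         lg = c("1", "2", "2", "2"),
                         pos_cm = c(31, 31, 42, 53),
                         n_qtls = c(2L, 5L, 6L, 7L)
                       ),
                       sd_range = c(0.8, 1.5),
                       r2_range = c(0.05, 0.35),
                       n_studies = 6L,
                       n_inversions = 0L,
                       n_isolated_groups = 0L,
                       n_duplicates = 0L,
                       n_unanchored = 0L,
                       bp_per_cm = 2e5,
                       genes_per_lg = 80L,
                       candidates_per_mqtl = 6L,
                       anchor_fraction = 0.5,
                       n_multihit = 2L,
                       n_incongruent = 2L,
                       years = c("2012", "2013", "2014"),
                       n_timepoints = 6L,
                       transition_timepoint = c("2012" = 3L, "2013" = 4L,
                                                "2014" = 3L),
                       effect_size = 2,
                       noise_sd = 0.2,
                       n_biomarkers = 30L,
                       n_never_expressed = 10L,
                       n_extra_de = 30L) {
  cfg <- as.list(environment())
  stopifnot(cfg$shared_fraction > 0, cfg$shared_fraction <= 1,
            all(cfg$scale_range > 0), cfg$n_maps >= 2L,
            all(cfg$true_metaqtls$n_qtls >= 1L))
  if (any(cfg$true_metaqtls$pos_cm < 0 |
            cfg$true_metaqtls$pos_cm > cfg$lg_length_cm)) {
    stop("true meta-QTL position outside the LG")
  }
  structure(cfg, class = "sim_config")
}

#' Configuration for the exact-recovery (funnel) experiment
#'
#' Same layout as [sim_config()] but with undistorted component maps (scale
#' 1, no jitter), so that projection and anchoring are exact and the
#' candidate funnel can be compared gene-for-gene against the planted truth;
#' what remains stochastic is only the QTL observation scatter.
#'
#' @param seed global seed (default 17).
#' @param ... further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
funnel_config <- function(seed = 17L, ...) {
  sim_config(seed = seed, scale_range = c(1, 1), jitter_sd = 0, ...)
}

#' Simulate distorted component genetic maps with known truth
#'
#' Draws one true map per LG (uniform marker positions), then builds each
#' component map by sampling markers from the pool and applying a per-map
#' affine scale plus truncated positional jitter, order-preserving by
#' construction. Optional plantings: adjacent-marker inversions (order
#' conflicts) and isolated linkage groups.
#'
#' @param cfg a `sim_config`.
#' @return list: `maps` (list of `genetic_map`), `truth` (true map, per-map
#'   scales, planted inversion pairs, isolated LG labels).
#' @export
simulate_maps <- function(cfg) {
  with_seed(cfg$seed, {
    pool_size <- ceiling(cfg$markers_per_map / cfg$shared_fraction)
    if (pool_size < cfg$markers_per_map) {
      stop("infeasible sharing configuration")
    }
    true_rows <- list()
    for (g in seq_len(cfg$n_lgs)) {
      pos <- sort(stats::runif(pool_size, 0, cfg$lg_length_cm))
      true_rows[[g]] <- data.frame(
        lg = as.character(g),
        marker = sprintf("M%d_%03d", g, seq_len(pool_size)),
        pos_cm = pos
      )
    }
    true_map <- genetic_map(do.call(rbind, true_rows), map_id = "true")
    scales <- stats::runif(cfg$n_maps, cfg$scale_range[1L],
                           cfg$scale_range[2L])
    names(scales) <- sprintf("study%d", seq_len(cfg$n_maps))
    maps <- vector("list", cfg$n_maps)
    inversions <- list()
    for (i in seq_len(cfg$n_maps)) {
      rows <- list()
      for (g in seq_len(cfg$n_lgs)) {
        tm <- true_rows[[g]]
        sel <- sort(sample(nrow(tm), cfg$markers_per_map))
        pos <- scales[i] * tm$pos_cm[sel] +
          stats::rnorm(length(sel), 0, cfg$jitter_sd)
        pos <- sort(pos) - min(c(pos, 0))  # order-preserving, nonnegative
        rows[[g]] <- data.frame(lg = tm$lg[sel], marker = tm$marker[sel],
                                pos_cm = pos)
      }
      mk <- do.call(rbind, rows)
      maps[[i]] <- genetic_map(mk, map_id = names(scales)[i])
    }
    # planted order conflicts: swap adjacent marker positions in one map,
    # picking markers shared with at least one other map
    if (cfg$n_inversions > 0L) {
      mk <- maps[[1L]]$markers
      other <- unique(unlist(lapply(maps[-1L],
                                    function(m) m$markers$marker)))
      g1 <- mk[mk$lg == "1", ]
      cand <- which(g1$marker %in% other)
      adj <- cand[which(diff(cand) == 1L)]
      picks <- adj[seq_len(min(cfg$n_inversions, length(adj)))]
      # keep swapped pairs disjoint
      picks <- picks[c(TRUE, diff(picks) > 1L)][seq_len(
        min(cfg$n_inversions, sum(c(TRUE, diff(picks) > 1L))))]
      for (p in picks) {
        i1 <- which(mk$lg == "1" & mk$marker == g1$marker[p])
        i2 <- which(mk$lg == "1" & mk$marker == g1$marker[p + 1L])
        tmp <- mk$pos_cm[i1]
        mk$pos_cm[i1] <- mk$pos_cm[i2]
        mk$pos_cm[i2] <- tmp
        inversions[[length(inversions) + 1L]] <-
          sort(c(g1$marker[p], g1$marker[p + 1L]))
      }
      maps[[1L]] <- genetic_map(mk, map_id = maps[[1L]]$map_id)
    }
    isolated <- character(0)
    if (cfg$n_isolated_groups > 0L) {
      for (k in seq_len(cfg$n_isolated_groups)) {
        lab <- paste0("iso", k)
        extra <- data.frame(
          lg = lab,
          marker = sprintf("ISO%d_%02d", k, 1:5),
          pos_cm = sort(stats::runif(5, 0, 50))
        )
        tgt <- 1L + (k - 1L) %% cfg$n_maps
        maps[[tgt]] <- genetic_map(rbind(maps[[tgt]]$markers, extra),
                                   map_id = maps[[tgt]]$map_id)
        isolated <- c(isolated, lab)
      }
    }
    list(maps = maps,
         truth = list(true_map = true_map, scales = scales,
                      inversions = inversions, isolated_lgs = isolated))
  })
}

#' Simulate QTL observations around the planted meta-QTL locations
#'
#' For each true meta-QTL at `mu`, draws peaks `x ~ N(mu, sigma^2)` with
#' `sigma ~ U(sd_range)`, a 95% CI of length `3.92 * sigma`, and
#' `r2 ~ U(r2_range)`; studies cycle through `n_studies` labels. When
#' component maps are supplied, each QTL is expressed in its source map's
#' coordinates (the map's affine scale applied); otherwise coordinates are in
#' the true frame. Optional plantings: same-study overlapping duplicates and
#' QTLs on an unanchorable LG.
#'
#' @param cfg a `sim_config`.
#' @param sim optional result of [simulate_maps()]; when supplied, QTLs are
#'   written in component-map coordinates.
#' @param trait trait label (default `"ver"`).
#' @return list: `qtls` (validated QTL data.frame), `truth` (`mu` per
#'   cluster, per-QTL cluster index, duplicate and unanchored ids).
#' @export
simulate_qtls <- function(cfg, sim = NULL, trait = "ver") {
  with_seed(cfg$seed + 1L, {
    studies <- sprintf("study%d", seq_len(cfg$n_studies))
    rows <- list()
    cluster_of <- integer(0)
    qn <- 0L
    for (ci in seq_len(nrow(cfg$true_metaqtls))) {
      tm <- cfg$true_metaqtls[ci, ]
      for (j in seq_len(tm$n_qtls)) {
        qn <- qn + 1L
        sigma <- stats::runif(1L, cfg$sd_range[1L], cfg$sd_range[2L])
        x <- stats::rnorm(1L, tm$pos_cm, sigma)
        st <- studies[1L + (qn - 1L) %% cfg$n_studies]
        scale <- if (is.null(sim)) 1 else sim$truth$scales[st]
        rows[[qn]] <- data.frame(
          qtl_id = sprintf("q%03d", qn), trait = trait,
          trait_category = "phenology", study_ref = st,
          population_size = 150L, lg = as.character(tm$lg),
          peak_cm = scale * x,
          ci_start_cm = scale * (x - 1.96 * sigma),
          ci_end_cm = scale * (x + 1.96 * sigma),
          r2 = round(stats::runif(1L, cfg$r2_range[1L], cfg$r2_range[2L]),
                     3L)
        )
        cluster_of <- c(cluster_of, ci)
      }
    }
    qtls <- do.call(rbind, rows)
    dup_ids <- character(0)
    if (cfg$n_duplicates > 0L) {
      for (d in seq_len(cfg$n_duplicates)) {
        src <- qtls[1L + (d - 1L) %% nrow(qtls), , drop = FALSE]
        qn <- qn + 1L
        src$qtl_id <- sprintf("q%03d_dup", qn)
        src$r2 <- max(src$r2 - 0.01, 0)  # strictly lower: always the pruned one
        src$peak_cm <- src$peak_cm + 0.1
        src$ci_start_cm <- src$ci_start_cm + 0.1
        src$ci_end_cm <- src$ci_end_cm + 0.1
        qtls <- rbind(qtls, src)
        dup_ids <- c(dup_ids, src$qtl_id)
      }
    }
    unanchored_ids <- character(0)
    if (cfg$n_unanchored > 0L) {
      for (u in seq_len(cfg$n_unanchored)) {
        qn <- qn + 1L
        id <- sprintf("q%03d_u", qn)
        qtls <- rbind(qtls, data.frame(
          qtl_id = id, trait = trait, trait_category = "phenology",
          study_ref = studies[1L], population_size = 150L,
          lg = "iso1", peak_cm = 10, ci_start_cm = 8, ci_end_cm = 12,
          r2 = 0.1
        ))
        unanchored_ids <- c(unanchored_ids, id)
      }
    }
    list(qtls = validate_qtl_table(qtls),
         truth = list(mu = cfg$true_metaqtls$pos_cm,
                      lg = as.character(cfg$true_metaqtls$lg),
                      cluster_of = cluster_of, duplicate_ids = dup_ids,
                      unanchored_ids = unanchored_ids))
  })
}

#' Simulate the toy genome: gene models, marker anchors and GO annotation
#'
#' Each LG becomes a chromosome of `lg_length_cm * bp_per_cm` bp with a
#' linear cM-to-bp relation. Anchors are placed on a subset of markers shared
#' by at least two component maps (always including the outermost ones), with
#' planted multi-hit and incongruent anchors on top. `candidates_per_mqtl`
#' genes are planted in a tight block centred on each true meta-QTL position;
#' background genes fill the chromosome outside an 8-cM exclusion buffer
#' around every planted location.
#'
#' @param cfg a `sim_config`.
#' @param sim result of [simulate_maps()].
#' @return list: `genes`, `anchors`, `go`, `chrom_lengths`, `truth`
#'   (candidate gene ids per meta-QTL, regulatory subset, planted bad
#'   anchors).
#' @export
simulate_genome <- function(cfg, sim) {
  with_seed(cfg$seed + 2L, {
    true_mk <- sim$truth$true_map$markers
    counts <- table(unlist(lapply(sim$maps, function(m)
      unique(m$markers$marker))))
    shared <- names(counts)[counts >= 2L]
    anchors <- list()
    bad_multi <- character(0)
    bad_incong <- character(0)
    for (g in seq_len(cfg$n_lgs)) {
      tm <- true_mk[true_mk$lg == as.character(g) &
                      true_mk$marker %in% shared, ]
      n_anchor <- max(2L, round(nrow(tm) * cfg$anchor_fraction))
      sel <- unique(c(1L, nrow(tm),
                      sort(sample(nrow(tm), min(n_anchor, nrow(tm))))))
      sub <- tm[sort(sel), ]
      anchors[[g]] <- data.frame(
        marker = sub$marker, chrom = paste0("chr", g),
        pos_bp = round(sub$pos_cm * cfg$bp_per_cm) + 1, n_hits = 1L
      )
    }
    anchors <- do.call(rbind, anchors)
    # planted multi-hit anchors
    if (cfg$n_multihit > 0L) {
      idx <- sample(nrow(anchors), cfg$n_multihit)
      anchors$n_hits[idx] <- 2L
      bad_multi <- anchors$marker[idx]
    }
    # planted incongruent anchors: displace bp far out of local order
    ok <- which(anchors$n_hits == 1L)
    if (cfg$n_incongruent > 0L && length(ok) > 6L) {
      idx <- ok[round(seq(3L, length(ok) - 2L,
                          length.out = cfg$n_incongruent))]
      anchors$pos_bp[idx] <- anchors$pos_bp[idx] + 15 * cfg$bp_per_cm
      bad_incong <- anchors$marker[idx]
    }
    # genes: planted candidate blocks + background
    gene_rows <- list()
    cand_ids <- list()
    gw <- 1500; gap <- 500
    for (ci in seq_len(nrow(cfg$true_metaqtls))) {
      tmq <- cfg$true_metaqtls[ci, ]
      centre <- tmq$pos_cm * cfg$bp_per_cm
      block <- cfg$candidates_per_mqtl * (gw + gap)
      start0 <- round(centre - block / 2)
      ids <- sprintf("GENE_%s_%02d_c%d", tmq$lg,
                     seq_len(cfg$candidates_per_mqtl), ci)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = ids, chrom = paste0("chr", tmq$lg),
        start_bp = start0 + (seq_len(cfg$candidates_per_mqtl) - 1L) *
          (gw + gap),
        end_bp = start0 + (seq_len(cfg$candidates_per_mqtl) - 1L) *
          (gw + gap) + gw - 1L,
        strand = "+", annotation = "planted candidate"
      )
      cand_ids[[ci]] <- ids
    }
    chrom_lengths <- stats::setNames(
      rep(cfg$lg_length_cm * cfg$bp_per_cm, cfg$n_lgs),
      paste0("chr", seq_len(cfg$n_lgs))
    )
    buffer <- 8 * cfg$bp_per_cm
    for (g in seq_len(cfg$n_lgs)) {
      mus <- cfg$true_metaqtls$pos_cm[cfg$true_metaqtls$lg ==
                                        as.character(g)] * cfg$bp_per_cm
      n_bg <- cfg$genes_per_lg -
        sum(cfg$true_metaqtls$lg == as.character(g)) *
        cfg$candidates_per_mqtl
      slots <- seq(1, chrom_lengths[g] - gw, by = 4L * (gw + gap))
      keep <- vapply(slots, function(s) {
        all(abs(s - mus) > buffer & abs(s + gw - mus) > buffer)
      }, logical(1L))
      starts <- sort(sample(slots[keep], n_bg))
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = sprintf("GENE_%d_bg%03d", g, seq_len(n_bg)),
        chrom = paste0("chr", g), start_bp = starts,
        end_bp = starts + gw - 1L, strand = "+",
        annotation = "background gene"
      )
    }
    genes <- do.call(rbind, gene_rows)
    genes <- genes[order(genes$chrom, genes$start_bp), ]
    rownames(genes) <- NULL
    # GO annotation: planted candidates split regulatory / not
    names(cand_ids) <- paste0("cluster", seq_along(cand_ids))
    all_cand <- unlist(cand_ids)
    regulatory <- all_cand[seq_along(all_cand) %% 2L == 1L]
    go_rows <- data.frame(
      gene_id = genes$gene_id,
      go = ifelse(genes$gene_id %in% regulatory,
                  sample(DEFAULT_GO_SLIM, nrow(genes), replace = TRUE),
                  "GO:0008150")
    )
    list(genes = genes, anchors = anchors, go = go_rows,
         chrom_lengths = chrom_lengths,
         truth = list(candidates = cand_ids, regulatory = regulatory,
                      multihit = bad_multi, incongruent = bad_incong))
  })
}

#' Simulate the FPKM time course, biomarkers, DE list and atlas calls
#'
#' Baseline log2 FPKM is normal per gene with replicate noise; biomarker
#' genes and planted modulated candidates step by `effect_size` log2 units
#' at the year-specific transition time point. A planted never-expressed set
#' stays below 1 FPKM everywhere and planted atlas-silent candidates get no
#' expressed-call in berry, rachis or seed.
#'
#' @param cfg a `sim_config`.
#' @param genome result of [simulate_genome()].
#' @return list: `mat` (an `expression_matrix`), `biomarkers`,
#'   `all_genotype_de`, `atlas` (call table), `truth` (per-meta-QTL
#'   atlas-silent / modulated / DE-list gene ids and the expected final
#'   candidate set).
#' @export
simulate_expression <- function(cfg, genome) {
  with_seed(cfg$seed + 3L, {
    cand <- genome$truth$candidates
    atlas_silent <- modulated <- delist <- character(0)
    for (ids in cand) {
      atlas_silent <- c(atlas_silent, ids[1L])
      modulated <- c(modulated, ids[2:4])
      delist <- c(delist, ids[5L])
    }
    bg <- setdiff(genome$genes$gene_id, unlist(cand))
    never <- sample(bg, min(cfg$n_never_expressed, length(bg)))
    extra_de <- sample(setdiff(bg, never),
                       min(cfg$n_extra_de, length(bg) - length(never)))
    biomarkers <- sprintf("BM_%02d", seq_len(cfg$n_biomarkers))
    all_genes <- c(genome$genes$gene_id, biomarkers)

    samples <- expand.grid(
      year = cfg$years, timepoint_order = seq_len(cfg$n_timepoints),
      replicate = 1:3, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    samples$days_before_veraison <-
      10 * (cfg$n_timepoints - samples$timepoint_order)
    samples$sample <- sprintf("%s_T%d_R%d", samples$year,
                              samples$timepoint_order, samples$replicate)

    base <- stats::rnorm(length(all_genes), 3, 1)
    names(base) <- all_genes
    stepped <- union(biomarkers, modulated)
    # biomarkers step either way; planted candidates are induced (positive
    # step), so their fold change survives the pseudocount at any baseline
    sign_of <- stats::setNames(sample(c(-1, 1), length(stepped),
                                      replace = TRUE), stepped)
    sign_of[modulated] <- 1
    vals <- matrix(0, nrow = length(all_genes), ncol = nrow(samples),
                   dimnames = list(all_genes, samples$sample))
    for (j in seq_len(nrow(samples))) {
      y <- samples$year[j]; tp <- samples$timepoint_order[j]
      lv <- base + stats::rnorm(length(all_genes), 0, cfg$noise_sd)
      after <- tp > cfg$transition_timepoint[[y]]
      if (after) {
        lv[stepped] <- lv[stepped] + cfg$effect_size * sign_of[stepped]
      }
      vals[, j] <- 2^lv
    }
    vals[never, ] <- matrix(stats::runif(length(never) * ncol(vals), 0, 0.5),
                            nrow = length(never))
    mat <- expression_matrix(vals, samples)

    atlas <- data.frame(
      gene_id = genome$genes$gene_id,
      berry = !(genome$genes$gene_id %in% atlas_silent),
      rachis = FALSE,
      seed = FALSE,
      leaf = TRUE
    )
    all_genotype_de <- sort(c(delist, extra_de))
    expected_final <- lapply(cand, function(ids) {
      sort(intersect(setdiff(ids, atlas_silent),
                     union(modulated, all_genotype_de)))
    })
    list(mat = mat, biomarkers = biomarkers,
         all_genotype_de = all_genotype_de, atlas = atlas,
         truth = list(atlas_silent = atlas_silent, modulated = modulated,
                      delist = delist, never_expressed = never,
                      expected_final = expected_final))
  })
}

#' Write a gene table as GFF3
#' @param genes gene data.frame (see [read_gff3_genes()] for columns).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, chrom_lengths, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start_bp, end = genes$end_bp),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id, Name = genes$gene_id,
    description = genes$annotation,
    seqlengths = chrom_lengths
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Generate and write the complete synthetic input bundle
#'
#' Emits every pipeline input (component maps, QTL table, synonym table,
#' anchors, GFF3, GO table, FPKM matrix + sample sheet, atlas calls,
#' biomarker and DE gene lists) plus `ground_truth.json`, all re-readable by
#' the package's own readers.
#'
#' @param cfg a `sim_config`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the in-memory bundle: list with `maps`, `qtls`,
#'   `genome`, `expr`, `truth` (merged ground truth), `dir`.
#' @export
simulate_bundle <- function(cfg = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  sim <- simulate_maps(cfg)
  qt <- simulate_qtls(cfg, sim)
  genome <- simulate_genome(cfg, sim)
  expr <- simulate_expression(cfg, genome)

  for (m in sim$maps) {
    write_genetic_map(m, file.path(dir, "maps", paste0(m$map_id, ".tsv")))
  }
  write_qtl_table(qt$qtls[, qtl_columns], file.path(dir, "qtls.tsv"))
  utils::write.table(
    data.frame(variant = character(0), canonical = character(0)),
    file.path(dir, "synonyms.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  utils::write.table(genome$anchors, file.path(dir, "anchors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gff3_genes(genome$genes, genome$chrom_lengths,
                   file.path(dir, "genome.gff3"))
  utils::write.table(genome$go, file.path(dir, "go.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fp <- data.frame(gene_id = rownames(expr$mat$values), expr$mat$values,
                   check.names = FALSE)
  utils::write.table(fp, file.path(dir, "fpkm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr$mat$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$atlas, file.path(dir, "atlas_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(expr$biomarkers, file.path(dir, "biomarkers.txt"))
  writeLines(expr$all_genotype_de, file.path(dir, "all_genotype_de.txt"))

  truth <- list(
    map = sim$truth[c("scales", "isolated_lgs")],
    inversions = sim$truth$inversions,
    qtl = qt$truth,
    genome = genome$truth,
    expression = expr$truth,
    chrom_lengths = as.list(genome$chrom_lengths)
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(maps = sim$maps, qtls = qt$qtls, genome = genome,
                 expr = expr, sim_truth = sim$truth, truth = truth,
                 dir = dir))
}
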