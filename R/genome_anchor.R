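#' Build the congruence-filtered anchor set
#'
#' From a table of marker placements on the genome, excludes markers with
#' multiple hits (`n_hits > 1`), markers hitting a chromosome different from
#' the one expected for their linkage group, and markers breaking the cM/bp
#' monotonicity of their LG. Monotonicity repair is greedy: the anchor
#' involved in the most inverted (cM, bp) pairs is dropped, and the scan
#' repeats until the retained anchors are strictly monotone, maximizing the
#' number kept.
#'
#' @param hits data.frame with columns `marker`, `chrom`, `pos_bp`,
#'   `n_hits`.
#' @param consensus the `consensus_map` providing `lg` and `pos_cm` for each
#'   marker.
#' @param lg_to_chrom named character vector mapping LG label to chromosome
#'   name; default `paste0("chr", lg)`.
#' @return data.frame of retained anchors (`marker`, `lg`, `pos_cm`, `chrom`,
#'   `pos_bp`), sorted by (lg, pos_cm); attributes `"excluded"` (data.frame
#'   `marker`, `reason`) and `"unanchorable"` (LGs left with < 2 anchors).
#' @export
build_anchor_set <- function(hits, consensus, lg_to_chrom = NULL) {
  mk <- consensus$markers
  df <- merge(hits, mk[, c("lg", "marker", "pos_cm")], by = "marker")
  df$pos_bp <- as.numeric(df$pos_bp)
  df$n_hits <- as.integer(df$n_hits)
  excluded <- data.frame(marker = character(0), reason = character(0))
  drop <- function(markers, reason) {
    if (length(markers)) {
      excluded <<- rbind(excluded,
                         data.frame(marker = markers, reason = reason))
    }
  }
  multi <- df$marker[df$n_hits > 1L]
  drop(unique(multi), "not unique")
  df <- df[df$n_hits <= 1L, , drop = FALSE]
  if (is.null(lg_to_chrom)) {
    lgs <- unique(df$lg)
    lg_to_chrom <- stats::setNames(paste0("chr", lgs), lgs)
  }
  wrong <- df$chrom != lg_to_chrom[df$lg]
  drop(df$marker[wrong], "wrong chromosome")
  df <- df[!wrong, , drop = FALSE]

  keep_rows <- list()
  for (g in unique(df$lg)) {
    sub <- df[df$lg == g, , drop = FALSE]
    sub <- sub[order(sub$pos_cm, sub$pos_bp), , drop = FALSE]
    repeat {
      n <- nrow(sub)
      if (n < 2L) break
      cmb <- utils::combn(n, 2L)
      dc <- sub$pos_cm[cmb[2L, ]] - sub$pos_cm[cmb[1L, ]]
      db <- sub$pos_bp[cmb[2L, ]] - sub$pos_bp[cmb[1L, ]]
      bad <- dc * db <= 0  # inversions and bp ties break strict monotonicity
      if (!any(bad)) break
      inv_count <- tabulate(c(cmb[1L, bad], cmb[2L, bad]), nbins = n)
      victim <- which.max(inv_count)
      drop(sub$marker[victim], "incongruent position")
      sub <- sub[-victim, , drop = FALSE]
    }
    keep_rows[[g]] <- sub
  }
  out <- do.call(rbind, keep_rows)
  if (is.null(out)) {
    out <- data.frame(marker = character(0), chrom = character(0),
                      pos_bp = numeric(0), n_hits = integer(0),
                      lg = character(0), pos_cm = numeric(0))
  }
  out <- out[order(out$lg, out$pos_cm), c("marker", "lg", "pos_cm", "chrom",
                                          "pos_bp"), drop = FALSE]
  rownames(out) <- NULL
  counts <- table(out$lg)
  unanchorable <- union(names(counts)[counts < 2L],
                        setdiff(unique(mk$lg), out$lg))
  attr(out, "excluded") <- excluded
  attr(out, "unanchorable") <- unanchorable
  out
}

#' Convert a cM interval to a physical (bp) interval
#'
#' Each cM endpoint is linearly interpolated between the nearest flanking
#' anchors of the LG; endpoints outside the anchored span extrapolate the
#' terminal anchor pair's slope. Results are clamped to
#' `[1, chrom_length]`, swapped if needed so start <= end, and rounded to
#' integer bp.
#'
#' @param lg linkage-group label.
#' @param interval_cm numeric length-2 `(start, end)` in cM.
#' @param anchors anchor data.frame from [build_anchor_set()].
#' @param chrom_length optional chromosome length for the upper clamp.
#' @return named numeric length-2 `(start_bp, end_bp)`.
#' @export
cm_to_bp <- function(lg, interval_cm, anchors, chrom_length = Inf) {
  sub <- anchors[anchors$lg == as.character(lg), , drop = FALSE]
  if (nrow(sub) < 2L) stop("LG ", lg, " is un-anchorable (< 2 anchors)")
  bp <- calibrate_positions(sub$pos_cm, sub$pos_bp, as.numeric(interval_cm))
  bp <- pmin(pmax(round(bp), 1), chrom_length)
  bp <- sort(bp)
  c(start_bp = bp[1L], end_bp = bp[2L])
}

#' Read gene models from a GFF3 file
#'
#' Imports the annotation via rtracklayer and keeps features of the given
#' type. Coordinates stay 1-based inclusive.
#'
#' @param path GFF3 file path.
#' @param feature_type feature type to keep (default `"gene"`).
#' @return data.frame `gene_id`, `chrom`, `start_bp`, `end_bp`, `strand`,
#'   `annotation`.
#' @export
read_gff3_genes <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else
    as.character(seq_along(gr))
  ann <- if ("description" %in% names(md)) as.character(md$description) else
    if ("Name" %in% names(md)) as.character(md$Name) else NA_character_
  data.frame(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    annotation = ann
  )
}

#' Genes overlapping a physical interval
#'
#' Any-overlap convention on closed 1-based intervals: a gene is returned iff
#' `start_bp <= query_end` and `end_bp >= query_start`.
#'
#' @param genes gene-model data.frame (see [read_gff3_genes()]).
#' @param chrom chromosome name.
#' @param interval_bp numeric length-2 `(start, end)` in bp.
#' @return The overlapping genes, sorted by `start_bp`.
#' @export
genes_in_interval <- function(genes, chrom, interval_bp) {
  if (!chrom %in% genes$chrom) stop("unknown chromosome: ", chrom)
  lo <- min(interval_bp); hi <- max(interval_bp)
  sub <- genes[genes$chrom == chrom & genes$start_bp <= hi &
                 genes$end_bp >= lo, , drop = FALSE]
  sub <- sub[order(sub$start_bp), , drop = FALSE]
  rownames(sub) <- NULL
  sub
}

#' Convert meta-QTL cM intervals to physical intervals and fetch candidates
#'
#' @param metaqtls meta-QTL data.frame (see [summarize_metaqtl()]).
#' @param anchors anchor set from [build_anchor_set()].
#' @param genes gene models from [read_gff3_genes()].
#' @param lg_to_chrom named character vector LG -> chromosome; default
#'   `paste0("chr", lg)`.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return `metaqtls` with added `start_bp`, `end_bp`, `n_candidates`
#'   columns; attribute `"candidates"` is a named list (meta-QTL name ->
#'   candidate gene data.frame).
#' @export
anchor_metaqtls <- function(metaqtls, anchors, genes, lg_to_chrom = NULL,
                            chrom_lengths = NULL) {
  if (is.null(lg_to_chrom)) {
    lgs <- unique(metaqtls$lg)
    lg_to_chrom <- stats::setNames(paste0("chr", lgs), lgs)
  }
  metaqtls$start_bp <- NA_real_
  metaqtls$end_bp <- NA_real_
  metaqtls$n_candidates <- NA_integer_
  cands <- list()
  for (i in seq_len(nrow(metaqtls))) {
    g <- metaqtls$lg[i]
    chrom <- lg_to_chrom[[g]]
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      chrom_lengths[[chrom]]
    } else Inf
    bp <- cm_to_bp(g, c(metaqtls$ci_start_cm[i], metaqtls$ci_end_cm[i]),
                   anchors, chrom_length = len)
    metaqtls$start_bp[i] <- bp[1L]
    metaqtls$end_bp[i] <- bp[2L]
    hit <- genes_in_interval(genes, chrom, bp)
    metaqtls$n_candidates[i] <- nrow(hit)
    cands[[metaqtls$name[i]]] <- hit
  }
  attr(metaqtls, "candidates") <- cands
  metaqtls
}

#' Write meta-QTL physical intervals as BED
#'
#' BED is 0-based half-open; 1-based inclusive intervals are converted at
#' write time (`start - 1`, `end`).
#'
#' @param metaqtls anchored meta-QTL data.frame (needs `start_bp`, `end_bp`).
#' @param path output path.
#' @param lg_to_chrom named character vector LG -> chromosome; default
#'   `paste0("chr", lg)`.
#' @return `path`, invisibly.
#' @export
write_metaqtl_bed <- function(metaqtls, path, lg_to_chrom = NULL) {
  if (is.null(lg_to_chrom)) {
    lgs <- unique(metaqtls$lg)
    lg_to_chrom <- stats::setNames(paste0("chr", lgs), lgs)
  }
  bed <- data.frame(
    chrom = unname(lg_to_chrom[metaqtls$lg]),
    start = format(metaqtls$start_bp - 1, scientific = FALSE, trim = TRUE),
    end = format(metaqtls$end_bp, scientific = FALSE, trim = TRUE),
    name = metaqtls$name
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
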