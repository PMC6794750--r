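#' Construct an expression matrix object
#'
#' FPKM values indexed by gene x sample, with sample metadata giving year,
#' ordered time point, days before veraison and replicate index.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids); FPKM >= 0.
#' @param samples data.frame with columns `sample`, `year`,
#'   `timepoint_order`, `days_before_veraison`, `replicate` covering the
#'   matrix columns.
#' @return list of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("FPKM values must be nonnegative")
  need <- c("sample", "year", "timepoint_order", "days_before_veraison",
            "replicate")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns: ", paste(need, collapse = ", "))
  }
  samples <- as.data.frame(samples)
  if (!setequal(samples$sample, colnames(values))) {
    stop("sample metadata does not match matrix columns")
  }
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  reps <- stats::aggregate(samples$replicate,
                           by = list(samples$year, samples$timepoint_order),
                           FUN = length)
  if (any(reps$x < 2L)) {
    warning("some (year, time point) cells have fewer than 2 replicates")
  }
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' Read an expression matrix and its sample metadata from TSV files
#'
#' @param fpkm_path gene x sample FPKM table (first column `gene_id`).
#' @param samples_path sample metadata table (see [expression_matrix()]).
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(fpkm_path, samples_path) {
  fp <- utils::read.delim(fpkm_path, sep = "\t", check.names = FALSE)
  genes <- as.character(fp[[1L]])
  vals <- as.matrix(fp[, -1L, drop = FALSE])
  rownames(vals) <- genes
  storage.mode(vals) <- "double"
  samples <- utils::read.delim(samples_path, sep = "\t",
                               check.names = FALSE,
                               colClasses = "character")
  samples$timepoint_order <- as.integer(samples$timepoint_order)
  samples$days_before_veraison <- as.numeric(samples$days_before_veraison)
  samples$replicate <- as.integer(samples$replicate)
  expression_matrix(vals, samples)
}

#' Filter genes by organ-level expression calls
#'
#' Retains genes with an expressed-call in at least one of the listed organs
#' in the expression atlas. Genes missing from the call table are treated as
#' not expressed (with a warning).
#'
#' @param genes character vector of gene ids.
#' @param calls data.frame with column `gene_id` plus one logical/0-1 column
#'   per organ.
#' @param organs organ columns to consult (default berry, rachis, seed).
#' @return Character vector of retained gene ids (input order).
#' @export
filter_expressed_atlas <- function(genes, calls,
                                   organs = c("berry", "rachis", "seed")) {
  if (!length(organs)) stop("empty organ set")
  missing_org <- setdiff(organs, names(calls))
  if (length(missing_org)) {
    stop("call table lacks organ column(s): ",
         paste(missing_org, collapse = ", "))
  }
  idx <- match(genes, calls$gene_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)),
            " gene(s) absent from the call table; treated as not expressed")
  }
  m <- as.matrix(calls[idx, organs, drop = FALSE]) > 0
  m[is.na(m)] <- FALSE
  genes[rowSums(m) > 0L]
}

#' Filter genes ever expressed in the FPKM time course
#'
#' A gene counts as expressed iff some (year, time point) has at least
#' `min_reps` replicates with FPKM >= `threshold` — the logical negation of
#' the removal rule "FPKM below the threshold in at least 2 replicates at all
#' time points".
#'
#' @param mat an `expression_matrix`.
#' @param threshold FPKM threshold (default 1).
#' @param min_reps replicate quorum (default 2).
#' @return Character vector of expressed gene ids.
#' @export
filter_fpkm_expressed <- function(mat, threshold = 1, min_reps = 2L) {
  sm <- mat$samples
  key <- interaction(sm$year, sm$timepoint_order, drop = TRUE)
  expressed <- rep(FALSE, nrow(mat$values))
  for (cell in levels(key)) {
    cols <- which(key == cell)
    hit <- rowSums(mat$values[, cols, drop = FALSE] >= threshold) >= min_reps
    expressed <- expressed | hit
  }
  rownames(mat$values)[expressed]
}

tp_means <- function(mat, gene, year, tps) {
  sm <- mat$samples
  vapply(tps, function(tp) {
    cols <- sm$sample[sm$year == year & sm$timepoint_order == tp]
    mean(mat$values[gene, cols])
  }, numeric(1L))
}

#' Is a gene differentially expressed across one time-point interval?
#'
#' TRUE iff the absolute log2 ratio of replicate-mean FPKM (with a
#' pseudocount) across the adjacent pair reaches `lfc_threshold`:
#' `|log2((mean_t1 + pc) / (mean_t0 + pc))| >= lfc_threshold`.
#'
#' @param mat an `expression_matrix`.
#' @param gene gene id.
#' @param interval integer length-2: adjacent `timepoint_order` values.
#' @param year year label.
#' @param lfc_threshold log2 fold-change threshold (default 1).
#' @param pseudocount added to both means (default 1).
#' @return logical.
#' @export
de_across_interval <- function(mat, gene, interval, year,
                               lfc_threshold = 1, pseudocount = 1) {
  m <- tp_means(mat, gene, year, interval)
  abs(log2((m[2L] + pseudocount) / (m[1L] + pseudocount))) >= lfc_threshold
}

#' Find the pre-veraison interval where the veraison transcriptomic shift starts
#'
#' For each adjacent pair of pre-veraison time points
#' (`days_before_veraison >= 0`) in the year, counts the biomarker genes
#' differentially expressed across it and returns the pair maximizing the
#' count (ties: earliest pair).
#'
#' @param mat an `expression_matrix`.
#' @param biomarkers character vector of biomarker gene ids (non-empty).
#' @param year year label.
#' @param lfc_threshold,pseudocount passed to [de_across_interval()].
#' @return list: `interval` (integer length-2 of `timepoint_order`),
#'   `counts` (per-pair DE counts, named `t0->t1`).
#' @export
find_onset_interval <- function(mat, biomarkers, year,
                                lfc_threshold = 1, pseudocount = 1) {
  if (!length(biomarkers)) stop("empty biomarker list")
  sm <- mat$samples
  pre <- sm[sm$year == year & sm$days_before_veraison >= 0, , drop = FALSE]
  tps <- sort(unique(pre$timepoint_order))
  if (length(tps) < 2L) stop("fewer than 2 pre-veraison time points in ", year)
  biomarkers <- intersect(biomarkers, rownames(mat$values))
  counts <- vapply(seq_len(length(tps) - 1L), function(i) {
    sum(vapply(biomarkers, function(g) {
      de_across_interval(mat, g, tps[c(i, i + 1L)], year,
                         lfc_threshold, pseudocount)
    }, logical(1L)))
  }, numeric(1L))
  names(counts) <- paste0(tps[-length(tps)], "->", tps[-1L])
  best <- which.max(counts)  # first maximum => earliest pair
  list(interval = tps[c(best, best + 1L)], counts = counts)
}

#' Select transcriptomic candidate genes
#'
#' Genes differentially expressed across the year-specific onset interval in
#' at least `min_years` of the available years, unioned with an externally
#' provided list of genes differentially expressed across veraison in all
#' genotypes.
#'
#' @param mat an `expression_matrix`.
#' @param biomarkers biomarker gene ids used to locate the onset interval.
#' @param all_genotype_de externally defined DE gene list (may be empty).
#' @param min_years minimum number of years (default 2).
#' @param lfc_threshold,pseudocount passed to [de_across_interval()].
#' @return Character vector of candidate gene ids; attribute `"onsets"` is
#'   the per-year onset interval list, `"modulated"` the genes selected by
#'   the year rule alone.
#' @export
select_transcriptomic_candidates <- function(mat, biomarkers,
                                             all_genotype_de = character(0),
                                             min_years = 2L,
                                             lfc_threshold = 1,
                                             pseudocount = 1) {
  years <- sort(unique(mat$samples$year))
  onsets <- lapply(years, function(y) {
    find_onset_interval(mat, biomarkers, y, lfc_threshold, pseudocount)
  })
  names(onsets) <- years
  genes <- rownames(mat$values)
  de_years <- matrix(FALSE, nrow = length(genes), ncol = length(years),
                     dimnames = list(genes, years))
  for (y in years) {
    iv <- onsets[[y]]$interval
    sm <- mat$samples
    c0 <- sm$sample[sm$year == y & sm$timepoint_order == iv[1L]]
    c1 <- sm$sample[sm$year == y & sm$timepoint_order == iv[2L]]
    m0 <- rowMeans(mat$values[, c0, drop = FALSE])
    m1 <- rowMeans(mat$values[, c1, drop = FALSE])
    de_years[, y] <- abs(log2((m1 + pseudocount) / (m0 + pseudocount))) >=
      lfc_threshold
  }
  modulated <- genes[rowSums(de_years) >= min_years]
  out <- union(modulated, all_genotype_de)
  attr(out, "onsets") <- onsets
  attr(out, "modulated") <- modulated
  out
}

#' Intersect positional and transcriptomic candidates
#'
#' @param positional named list: meta-QTL name -> character vector (or
#'   data.frame with `gene_id`) of positional candidate genes.
#' @param transcriptomic character vector of transcriptomic candidates.
#' @return data.frame `gene_id`, `metaqtl`, `evidence` (one row per gene x
#'   meta-QTL); attribute `"funnel"` gives the count funnel (positional,
#'   transcriptomic, final).
#' @export
intersect_candidates <- function(positional, transcriptomic) {
  if (!length(positional) || !length(transcriptomic)) {
    stop("both candidate sets must be non-empty")
  }
  rows <- list()
  for (mq in names(positional)) {
    g <- positional[[mq]]
    if (is.data.frame(g)) g <- g$gene_id
    hit <- intersect(g, transcriptomic)
    if (length(hit)) {
      rows[[mq]] <- data.frame(gene_id = hit, metaqtl = mq,
                               evidence = "positional+transcriptomic")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), metaqtl = character(0),
               evidence = character(0))
  rownames(out) <- NULL
  pos_all <- unique(unlist(lapply(positional, function(g) {
    if (is.data.frame(g)) g$gene_id else g
  })))
  attr(out, "funnel") <- c(
    positional = length(pos_all),
    transcriptomic = length(unique(transcriptomic)),
    final = length(unique(out$gene_id))
  )
  out
}

#' Default GO-slim accessions flagging regulatory/signalling/development genes
#' @export
DEFAULT_GO_SLIM <- c(
  "GO:0000166", "GO:0003676", "GO:0003677", "GO:0003682", "GO:0003700",
  "GO:0005102", "GO:0005634", "GO:0007154", "GO:0007165", "GO:0007275",
  "GO:0009653", "GO:0009719", "GO:0009791", "GO:0009908", "GO:0016301",
  "GO:0030154", "GO:0038023", "GO:0040007"
)

#' Flag candidates annotated with regulatory GO-slim accessions
#'
#' @param candidates character vector of gene ids, or data.frame with
#'   `gene_id`.
#' @param go_table data.frame `gene_id`, `go` (one accession per row).
#' @param slim_set GO accessions defining the regulatory class (default
#'   [DEFAULT_GO_SLIM]).
#' @return data.frame `gene_id`, `regulatory` (logical), `go_hits`
#'   (comma-joined matching accessions).
#' @export
go_slim_filter <- function(candidates, go_table, slim_set = DEFAULT_GO_SLIM) {
  if (is.data.frame(candidates)) candidates <- unique(candidates$gene_id)
  ok <- grepl("^GO:\\d{7}$", go_table$go)
  if (any(!ok)) {
    warning("ignoring ", sum(!ok), " malformed GO accession(s)")
    go_table <- go_table[ok, , drop = FALSE]
  }
  hits <- go_table[go_table$go %in% slim_set, , drop = FALSE]
  joined <- vapply(candidates, function(g) {
    paste(sort(unique(hits$go[hits$gene_id == g])), collapse = ",")
  }, character(1L))
  data.frame(gene_id = candidates, regulatory = nzchar(joined),
             go_hits = joined, row.names = NULL)
}
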