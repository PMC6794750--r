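#' Assemble a pipeline configuration
#'
#' Thresholds default to the quoted projection/expression rules where those
#' exist (scale cut 0.25, FPKM threshold 1 with a 2-replicate quorum, |log2
#' FC| >= 1 in >= 2 years, 5-cM co-localization bins) and to the package's
#' documented choices elsewhere.
#'
#' @param input_dir directory holding the input bundle (see
#'   [simulate_bundle()] for the layout).
#' @param out_dir directory for stage outputs.
#' @param ... overrides of the default fields.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir, ...) {
  cfg <- list(
    input_dir = input_dir, out_dir = out_dir,
    seed = 17L, focal_trait = "ver",
    min_scale = 0.25, max_scale = Inf,
    K_max = 10L, restarts = 10L, tol = 1e-8, ci_level = 0.95,
    cross_trait = TRUE,
    bin_cm = 5,
    fpkm_threshold = 1, min_reps = 2L, lfc_threshold = 1, pseudocount = 1,
    min_years = 2L,
    organs = c("berry", "rachis", "seed"),
    go_slim = DEFAULT_GO_SLIM
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with `input_dir`, `out_dir` and any overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$input_dir), !is.null(y$out_dir))
  do.call(pipeline_config, y)
}

#' Read a consensus map written by [write_consensus_map()]
#' @param path TSV path.
#' @return A `consensus_map` (markers only; no provenance).
#' @export
read_consensus_map <- function(path) {
  df <- read_tsv_checked(path, c("lg", "marker", "pos_cm", "n_maps"))
  df$pos_cm <- as.numeric(df$pos_cm)
  df$n_maps <- as.integer(df$n_maps)
  structure(list(markers = df, provenance = NULL), class = "consensus_map")
}

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

require_upstream <- function(cfg, file, stage) {
  p <- stage_path(cfg, file)
  if (!file.exists(p)) {
    stop("missing upstream output '", file, "'; run stage '", stage,
         "' first")
  }
  p
}

load_input_maps <- function(cfg) {
  paths <- sort(list.files(file.path(cfg$input_dir, "maps"),
                           pattern = "\\.tsv$", full.names = TRUE))
  if (!length(paths)) stop("no component maps found under ",
                           file.path(cfg$input_dir, "maps"))
  maps <- lapply(paths, read_genetic_map)
  syn_path <- file.path(cfg$input_dir, "synonyms.tsv")
  if (file.exists(syn_path)) {
    syn <- read_synonym_table(syn_path)
    maps <- lapply(maps, normalize_marker_names, syn = syn)
  }
  maps
}

#' Run one pipeline stage (or all of them)
#'
#' Stages checkpoint their outputs as TSV under `cfg$out_dir`; later stages
#' consume earlier outputs and fail naming the missing stage. Outputs are
#' deterministic given (inputs, config, seed); a `run_manifest.json`
#' records the configuration and input checksums.
#'
#' @param stage one of `"simulate"`, `"consensus"`, `"project"`,
#'   `"colocalize"`, `"meta"`, `"anchor"`, `"integrate"`, `"all"`.
#' @param cfg a `pipeline_config`.
#' @return `cfg$out_dir`, invisibly.
#' @export
run_stage <- function(stage = c("all", "simulate", "consensus", "project",
                                "colocalize", "meta", "anchor", "integrate"),
                      cfg) {
  stage <- match.arg(stage)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    for (s in c("consensus", "project", "colocalize", "meta", "anchor",
                "integrate")) {
      run_stage(s, cfg)
    }
    write_manifest(cfg)
    return(invisible(cfg$out_dir))
  }
  switch(stage,
    simulate = {
      simulate_bundle(sim_config(seed = cfg$seed), cfg$input_dir)
    },
    consensus = {
      maps <- load_input_maps(cfg)
      cons <- build_consensus(maps)
      write_consensus_map(cons, stage_path(cfg, "consensus_map.tsv"))
      utils::write.table(summarize_consensus(cons),
                         stage_path(cfg, "consensus_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      corr <- do.call(rbind, lapply(maps, function(m) {
        cbind(map_id = m$map_id, map_order_correlation(m, cons))
      }))
      utils::write.table(corr, stage_path(cfg, "map_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      message("consensus: ", nrow(cons$markers), " markers, ",
              sum(cons$markers$n_maps >= 2L), " shared")
    },
    project = {
      cons <- read_consensus_map(
        require_upstream(cfg, "consensus_map.tsv", "consensus"))
      maps <- load_input_maps(cfg)
      qtls <- read_qtl_table(file.path(cfg$input_dir, "qtls.tsv"))
      proj <- project_all(qtls, maps, cons, min_scale = cfg$min_scale,
                          max_scale = cfg$max_scale)
      write_qtl_table(proj, stage_path(cfg, "projected_qtls.tsv"))
      for (tr in unique(proj$trait)) {
        write_qtl_table(proj[proj$trait == tr, , drop = FALSE],
                        stage_path(cfg, paste0("consensus_qtls_",
                                               gsub("[^A-Za-z0-9]", "_", tr),
                                               ".tsv")))
      }
      rates <- attr(proj, "rates")
      message("projected ", sum(proj$status == "projected"), "/",
              nrow(proj), " QTLs (",
              round(100 * rates$overall), "%)")
    },
    colocalize = {
      proj <- read_projected(cfg)
      ok <- proj[proj$status == "projected", , drop = FALSE]
      within <- find_colocated(ok, "within-trait")
      utils::write.table(within, stage_path(cfg, "colocated.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cross <- find_colocated(ok, "cross-trait")
      utils::write.table(cross, stage_path(cfg, "colocated_cross.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      message(sum(within$confirmed), " within-trait cluster(s) confirmed ",
              "in >= 2 populations")
    },
    meta = {
      proj <- read_projected(cfg)
      focal <- cfg$focal_trait
      lgs <- sort(unique(proj$lg[proj$trait == focal &
                                   proj$status == "projected"]))
      rows <- list()
      for (g in lgs) {
        mq <- run_meta_analysis(proj, focal, g, mode = "single-trait",
                                K_max = cfg$K_max, restarts = cfg$restarts,
                                tol = cfg$tol, seed = cfg$seed,
                                ci_level = cfg$ci_level)
        if (nrow(mq)) rows[[paste0("s", g)]] <- cbind(mq,
                                                      mode = "single-trait")
        has_other <- any(proj$trait != focal & proj$lg == g &
                           proj$status == "projected")
        if (cfg$cross_trait && has_other) {
          mqx <- run_meta_analysis(proj, focal, g, mode = "cross-trait",
                                   K_max = cfg$K_max,
                                   restarts = cfg$restarts, tol = cfg$tol,
                                   seed = cfg$seed, ci_level = cfg$ci_level)
          if (nrow(mqx)) rows[[paste0("x", g)]] <- cbind(mqx,
                                                         mode = "cross-trait")
        }
      }
      mq_all <- if (length(rows)) do.call(rbind, rows) else
        cbind(empty_metaqtl_frame(), mode = character(0))
      rownames(mq_all) <- NULL
      write_qtl_table(mq_all, stage_path(cfg, "metaqtls.tsv"))
      message(nrow(mq_all), " meta-QTL(s)")
    },
    anchor = {
      mq <- utils::read.delim(require_upstream(cfg, "metaqtls.tsv", "meta"),
                              colClasses = "character")
      for (col in c("peak_cm", "mean_r2", "ci_start_cm", "ci_end_cm")) {
        mq[[col]] <- as.numeric(mq[[col]])
      }
      mq$lg <- as.character(mq$lg)
      cons <- read_consensus_map(
        require_upstream(cfg, "consensus_map.tsv", "consensus"))
      hits <- utils::read.delim(file.path(cfg$input_dir, "anchors.tsv"),
                                colClasses = "character")
      anchors <- build_anchor_set(hits, cons)
      genes <- read_gff3_genes(file.path(cfg$input_dir, "genome.gff3"))
      anchored <- anchor_metaqtls(mq, anchors, genes)
      write_qtl_table(anchored, stage_path(cfg, "metaqtls_anchored.tsv"))
      write_metaqtl_bed(anchored, stage_path(cfg, "metaqtl_intervals.bed"))
      cands <- attr(anchored, "candidates")
      for (nm in names(cands)) {
        utils::write.table(
          cands[[nm]],
          stage_path(cfg, paste0("candidates_",
                                 gsub("[^A-Za-z0-9._]", "_", nm), ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE
        )
      }
      message(sum(anchored$n_candidates), " positional candidate hits")
    },
    integrate = {
      anchored <- utils::read.delim(
        require_upstream(cfg, "metaqtls_anchored.tsv", "anchor"),
        colClasses = "character")
      positional <- lapply(stats::setNames(anchored$name, anchored$name),
                           function(nm) {
        p <- stage_path(cfg, paste0("candidates_",
                                    gsub("[^A-Za-z0-9._]", "_", nm), ".tsv"))
        df <- utils::read.delim(p, colClasses = "character")
        df$gene_id
      })
      mat <- read_expression_matrix(file.path(cfg$input_dir, "fpkm.tsv"),
                                    file.path(cfg$input_dir, "samples.tsv"))
      atlas <- utils::read.delim(file.path(cfg$input_dir,
                                           "atlas_calls.tsv"))
      biomarkers <- readLines(file.path(cfg$input_dir, "biomarkers.txt"))
      de_list <- readLines(file.path(cfg$input_dir, "all_genotype_de.txt"))
      go_tab <- utils::read.delim(file.path(cfg$input_dir, "go.tsv"),
                                  colClasses = "character")

      pos_all <- unique(unlist(positional))
      pos_expressed <- filter_expressed_atlas(pos_all, atlas,
                                              organs = cfg$organs)
      expressed_rna <- filter_fpkm_expressed(mat,
                                             threshold = cfg$fpkm_threshold,
                                             min_reps = cfg$min_reps)
      transcriptomic <- select_transcriptomic_candidates(
        mat, biomarkers, all_genotype_de = de_list,
        min_years = cfg$min_years, lfc_threshold = cfg$lfc_threshold,
        pseudocount = cfg$pseudocount
      )
      transcriptomic <- intersect(transcriptomic, expressed_rna)
      positional_kept <- lapply(positional, intersect, y = pos_expressed)
      final <- intersect_candidates(positional_kept, transcriptomic)
      reg <- go_slim_filter(final, go_tab, slim_set = cfg$go_slim)
      final$regulatory <- reg$regulatory[match(final$gene_id, reg$gene_id)]
      write_qtl_table(final, stage_path(cfg, "candidates_final.tsv"))
      funnel <- data.frame(
        step = c("positional", "expressed_in_organ", "transcriptomic",
                 "final", "regulatory"),
        n_genes = c(length(pos_all), length(pos_expressed),
                    length(unique(transcriptomic)),
                    length(unique(final$gene_id)),
                    length(unique(final$gene_id[final$regulatory])))
      )
      utils::write.table(funnel, stage_path(cfg, "funnel_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      message("funnel: ", paste(funnel$n_genes, collapse = " -> "))
    }
  )
  invisible(cfg$out_dir)
}

read_projected <- function(cfg) {
  p <- require_upstream(cfg, "projected_qtls.tsv", "project")
  df <- utils::read.delim(p, colClasses = "character", na.strings = c("NA", ""))
  for (col in c("peak_cm", "ci_start_cm", "ci_end_cm", "r2", "scale")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$lg <- as.character(df$lg)
  df
}

write_manifest <- function(cfg) {
  inputs <- list.files(cfg$input_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("qtlmeta")),
    config = cfg[setdiff(names(cfg), c("go_slim"))],
    input_md5 = as.list(tools::md5sum(inputs))
  )
  names(manifest$input_md5) <-
    substring(inputs, nchar(cfg$input_dir) + 2L)
  jsonlite::write_json(manifest, stage_path(cfg, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the complete pipeline end to end
#'
#' Convenience wrapper: [run_stage()] `"all"`, returning the funnel counts.
#'
#' @param cfg a `pipeline_config`.
#' @return data.frame of funnel counts, invisibly the out dir as attribute.
#' @export
run_pipeline <- function(cfg) {
  run_stage("all", cfg)
  funnel <- utils::read.delim(stage_path(cfg, "funnel_counts.tsv"))
  attr(funnel, "out_dir") <- cfg$out_dir
  funnel
}
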