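#' @keywords internal
"_PACKAGE"

#' The eight trait categories used to classify QTLs
#'
#' Every QTL record carries a `trait_category` column restricted to these
#' values. Category assignment is an input (curated upstream), never inferred.
#'
#' @export
TRAIT_CATEGORIES <- c(
  "phenology", "berry_morphology", "berry_metabolites", "cluster",
  "pathogen_resistance", "abiotic_stress", "seeds", "vegetative"
)

#' Construct a genetic map object
#'
#' A genetic map is an ordered list of markers per linkage group (LG), each
#' with a position in centiMorgans (cM). Markers are sorted by position within
#' each LG; ties keep their input order.
#'
#' @param markers data.frame with columns `lg` (character), `marker`
#'   (character) and `pos_cm` (numeric, >= 0).
#' @param map_id short identifier for the map.
#' @param study_ref reference of the study the map comes from.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(markers, map_id = "map", study_ref = map_id) {
  stopifnot(is.data.frame(markers))
  need <- c("lg", "marker", "pos_cm")
  if (!all(need %in% names(markers))) {
    stop("markers must have columns: ", paste(need, collapse = ", "))
  }
  markers$lg <- as.character(markers$lg)
  markers$marker <- as.character(markers$marker)
  markers$pos_cm <- as.numeric(markers$pos_cm)
  if (anyNA(markers$pos_cm)) stop("non-numeric marker position")
  if (any(markers$pos_cm < 0)) {
    bad <- markers$marker[markers$pos_cm < 0][1L]
    stop("negative position for marker '", bad, "'")
  }
  # stable sort by (lg, pos_cm); ties preserve file order
  markers <- markers[order(markers$lg, markers$pos_cm, method = "radix"), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  for (g in unique(markers$lg)) {
    m <- markers$marker[markers$lg == g]
    if (anyDuplicated(m)) {
      stop("duplicate marker(s) in LG ", g, ": ",
           paste(unique(m[duplicated(m)]), collapse = ", "))
    }
  }
  structure(
    list(map_id = map_id, study_ref = study_ref,
         markers = markers[, need, drop = FALSE]),
    class = "genetic_map"
  )
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map> ", x$map_id, ": ", nrow(x$markers), " markers on ",
      length(unique(x$markers$lg)), " linkage group(s)\n", sep = "")
  invisible(x)
}

#' Linkage groups of a map
#' @param map a `genetic_map` or `consensus_map`.
#' @return character vector of LG labels.
#' @export
map_lgs <- function(map) unique(map$markers$lg)

#' Markers of one linkage group
#' @param map a `genetic_map` or `consensus_map`.
#' @param lg linkage-group label.
#' @return data.frame of the LG's markers, ordered by position.
#' @export
lg_markers <- function(map, lg) {
  out <- map$markers[map$markers$lg == as.character(lg), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a genetic map from a tab-delimited file
#'
#' Expects a header row and the columns `lg`, `marker`, `pos_cm` (one map per
#' file). This single canonical dialect replaces the heterogeneous formats of
#' the original publications, whose transcription is an input, not code.
#'
#' @param path file path.
#' @param map_id identifier for the map; default basename without extension.
#' @param study_ref study reference; default `map_id`.
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path, map_id = NULL, study_ref = NULL) {
  if (is.null(map_id)) map_id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(study_ref)) study_ref <- map_id
  df <- read_tsv_checked(path, c("lg", "marker", "pos_cm"))
  pos <- suppressWarnings(as.numeric(df$pos_cm))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    stop("malformed row ", bad + 1L, " in ", path,
         ": position '", df$pos_cm[bad], "' is not numeric")
  }
  df$pos_cm <- pos
  genetic_map(df, map_id = map_id, study_ref = study_ref)
}

#' Write a genetic map to a tab-delimited file
#' @param map a `genetic_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(map$markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read a marker synonym table
#'
#' Two tab-delimited columns `variant`, `canonical`. The mapping must be
#' functional (one canonical per variant) and canonical names must be fixed
#' points, so that applying the table is idempotent.
#'
#' @param path file path.
#' @return data.frame with columns `variant`, `canonical`.
#' @export
read_synonym_table <- function(path) {
  df <- read_tsv_checked(path, c("variant", "canonical"))
  validate_synonym_table(df)
}

validate_synonym_table <- function(df) {
  df$variant <- as.character(df$variant)
  df$canonical <- as.character(df$canonical)
  if (anyDuplicated(df$variant)) {
    amb <- unique(df$variant[duplicated(df$variant)])
    stop("synonym table maps variant(s) to several canonicals: ",
         paste(amb, collapse = ", "))
  }
  # canonical names must be fixed points of the mapping
  hit <- df$canonical %in% df$variant
  if (any(hit)) {
    chained <- df$canonical[hit]
    tgt <- df$canonical[match(chained, df$variant)]
    if (any(tgt != chained)) {
      stop("synonym table is not idempotent; canonical name(s) remapped: ",
           paste(unique(chained[tgt != chained]), collapse = ", "))
    }
  }
  df[, c("variant", "canonical")]
}

#' Normalize marker names using a synonym table
#'
#' Replaces every marker name by its canonical spelling. A normalization that
#' would create a duplicate marker within a linkage group is an error listing
#' the collisions. The replacement report is attached as attribute
#' `"replacements"`.
#'
#' @param map a `genetic_map`.
#' @param syn synonym data.frame (`variant`, `canonical`), e.g. from
#'   [read_synonym_table()]; an empty table is the identity.
#' @return The normalized `genetic_map`.
#' @export
normalize_marker_names <- function(map, syn) {
  stopifnot(inherits(map, "genetic_map"))
  syn <- validate_synonym_table(as.data.frame(syn))
  mk <- map$markers
  idx <- match(mk$marker, syn$variant)
  repl <- which(!is.na(idx) & syn$canonical[idx] != mk$marker)
  report <- data.frame(lg = mk$lg[repl], from = mk$marker[repl],
                       to = syn$canonical[idx[repl]])
  mk$marker[repl] <- syn$canonical[idx[repl]]
  for (g in unique(mk$lg)) {
    m <- mk$marker[mk$lg == g]
    if (anyDuplicated(m)) {
      stop("normalization creates duplicate marker(s) in LG ", g, ": ",
           paste(unique(m[duplicated(m)]), collapse = ", "))
    }
  }
  out <- genetic_map(mk, map_id = map$map_id, study_ref = map$study_ref)
  attr(out, "replacements") <- report
  out
}

qtl_columns <- c("qtl_id", "trait", "trait_category", "study_ref",
                 "population_size", "lg", "peak_cm", "ci_start_cm",
                 "ci_end_cm", "r2")

#' Read a QTL table
#'
#' Tab-delimited with columns `qtl_id`, `trait`, `trait_category`,
#' `study_ref`, `population_size`, `lg`, `peak_cm`, `ci_start_cm`,
#' `ci_end_cm`, `r2`. Confidence-interval bounds and R-squared may be empty;
#' a missing CI is flagged (`ci_missing`) for later estimation from N and R².
#'
#' @param path file path.
#' @return data.frame of validated QTL records with an extra logical column
#'   `ci_missing`.
#' @export
read_qtl_table <- function(path) {
  df <- read_tsv_checked(path, qtl_columns)
  validate_qtl_table(df)
}

validate_qtl_table <- function(df) {
  df <- as.data.frame(df)
  for (col in c("peak_cm", "ci_start_cm", "ci_end_cm", "r2")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$population_size <- suppressWarnings(as.integer(df$population_size))
  df$lg <- as.character(df$lg)
  df$qtl_id <- as.character(df$qtl_id)
  bad_cat <- setdiff(unique(df$trait_category), TRAIT_CATEGORIES)
  if (length(bad_cat)) {
    stop("unknown trait_category: ", paste(bad_cat, collapse = ", "),
         "; allowed: ", paste(TRAIT_CATEGORIES, collapse = ", "))
  }
  if (any(!is.na(df$population_size) & df$population_size <= 0)) {
    stop("population_size must be a positive integer")
  }
  has_ci <- !is.na(df$ci_start_cm) & !is.na(df$ci_end_cm)
  bad <- has_ci & (df$ci_start_cm > df$peak_cm | df$peak_cm > df$ci_end_cm)
  if (any(bad)) {
    stop("QTL peak outside its confidence interval: ",
         paste(df$qtl_id[bad], collapse = ", "))
  }
  bad_r2 <- !is.na(df$r2) & (df$r2 < 0 | df$r2 > 1)
  if (any(bad_r2)) {
    stop("r2 outside [0, 1]: ", paste(df$qtl_id[bad_r2], collapse = ", "))
  }
  df$ci_missing <- !has_ci
  rownames(df) <- NULL
  df
}

#' Write a QTL (or projected-QTL) table
#' @param qtls data.frame of QTL records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qtl_table <- function(qtls, path) {
  out <- qtls
  num <- vapply(out, is.numeric, logical(1L)) &
    !vapply(out, is.integer, logical(1L))
  out[num] <- lapply(out[num], function(x) formatC(x, format = "fg"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write the consensus map table
#'
#' Columns: `lg`, `marker`, `pos_cm` (2 decimals), `n_maps`, `shared_flag`.
#'
#' @param consensus a `consensus_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_map <- function(consensus, path) {
  mk <- consensus$markers
  out <- data.frame(lg = mk$lg, marker = mk$marker,
                    pos_cm = sprintf("%.2f", mk$pos_cm),
                    n_maps = mk$n_maps,
                    shared_flag = as.integer(mk$n_maps >= 2L))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
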