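#' Published veraison meta-QTL coordinates
#'
#' The four veraison meta-QTLs reported for grapevine LGs 1 and 2 (peak,
#' mean R², genetic CI, physical interval and support counts), shipped as a
#' small reference table. Useful for CI-span arithmetic and as a realistic
#' example of the package's output layout.
#'
#' @return data.frame with columns `lg`, `name`, `peak_cm`, `mean_r2`,
#'   `start_cm`, `end_cm`, `start_bp`, `end_bp`, `n_candidates`, `n_qtls`,
#'   `n_studies`.
#' @export
published_ver_metaqtls <- function() {
  path <- system.file("extdata", "published_ver_metaqtls.tsv",
                      package = "qtlmeta")
  df <- utils::read.delim(path, colClasses = "character")
  for (col in c("peak_cm", "mean_r2", "start_cm", "end_cm", "start_bp",
                "end_bp")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("n_candidates", "n_qtls", "n_studies")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$lg <- as.character(df$lg)
  df
}

#' Confidence-interval span summary of a meta-QTL table
#'
#' @param metaqtls data.frame with CI columns (`start_cm`/`end_cm`, or
#'   `ci_start_cm`/`ci_end_cm`).
#' @return list: `spans` (named per meta-QTL), `mean`, `min`, `max`, all cM.
#' @export
metaqtl_ci_spans <- function(metaqtls) {
  s <- if ("start_cm" %in% names(metaqtls)) metaqtls$start_cm else
    metaqtls$ci_start_cm
  e <- if ("end_cm" %in% names(metaqtls)) metaqtls$end_cm else
    metaqtls$ci_end_cm
  spans <- stats::setNames(e - s, metaqtls$name)
  list(spans = spans, mean = mean(spans), min = min(spans),
       max = max(spans))
}
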