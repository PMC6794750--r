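# single-linkage clustering of closed intervals by overlap; returns an
# integer cluster id per interval (touching endpoints count as overlap)
interval_clusters <- function(start, end) {
  n <- length(start)
  if (!n) return(integer(0))
  o <- order(start, end)
  cl <- integer(n)
  cur <- 0L
  reach <- -Inf
  for (i in o) {
    if (start[i] > reach) cur <- cur + 1L
    cl[i] <- cur
    reach <- max(reach, end[i])
  }
  cl
}

#' Prune redundant QTLs (same study, overlapping CIs)
#'
#' QTLs from the same study whose CIs overlap could overestimate that study's
#' effect in the meta-analysis; among each same-study overlap group only the
#' QTL with the highest R² survives (ties: longest CI, then first `qtl_id`).
#'
#' @param qtls projected-QTL data.frame of one trait (needs `study_ref`,
#'   `lg`, `ci_start_cm`, `ci_end_cm`, `r2`, `qtl_id`).
#' @return The pruned data.frame; attribute `"pruned"` lists removed
#'   `qtl_id`s.
#' @export
prune_redundant <- function(qtls) {
  if (!nrow(qtls)) {
    attr(qtls, "pruned") <- character(0)
    return(qtls)
  }
  keep <- logical(nrow(qtls))
  for (st in unique(qtls$study_ref)) {
    for (g in unique(qtls$lg)) {
      idx <- which(qtls$study_ref == st & qtls$lg == g)
      if (!length(idx)) next
      cl <- interval_clusters(qtls$ci_start_cm[idx], qtls$ci_end_cm[idx])
      for (c0 in unique(cl)) {
        members <- idx[cl == c0]
        len <- qtls$ci_end_cm[members] - qtls$ci_start_cm[members]
        r2 <- ifelse(is.na(qtls$r2[members]), -Inf, qtls$r2[members])
        best <- members[order(-r2, -len, seq_along(members))[1L]]
        keep[best] <- TRUE
      }
    }
  }
  out <- qtls[keep, , drop = FALSE]
  attr(out, "pruned") <- qtls$qtl_id[!keep]
  rownames(out) <- NULL
  out
}

#' Find co-located QTL clusters by confidence-interval overlap
#'
#' Single-linkage clustering of closed CIs per linkage group. With scope
#' `"within-trait"` each trait is clustered separately; `"cross-trait"` pools
#' everything on the LG. Clusters supported by at least two populations
#' (distinct `study_ref`) are flagged `confirmed`.
#'
#' @param qtls projected-QTL data.frame.
#' @param scope `"within-trait"` or `"cross-trait"`.
#' @return data.frame with one row per cluster: `cluster_id`, `lg`, `trait`
#'   (comma-joined in cross scope), `members`, `n_qtls`, `n_populations`,
#'   `span_start_cm`, `span_end_cm`, `confirmed`.
#' @export
find_colocated <- function(qtls, scope = c("within-trait", "cross-trait")) {
  scope <- match.arg(scope)
  qtls <- qtls[!is.na(qtls$ci_start_cm) & !is.na(qtls$ci_end_cm), ,
               drop = FALSE]
  groups <- if (scope == "within-trait") {
    split(seq_len(nrow(qtls)), list(qtls$lg, qtls$trait), drop = TRUE)
  } else {
    split(seq_len(nrow(qtls)), qtls$lg, drop = TRUE)
  }
  rows <- list()
  for (idx in groups) {
    cl <- interval_clusters(qtls$ci_start_cm[idx], qtls$ci_end_cm[idx])
    for (c0 in sort(unique(cl))) {
      members <- idx[cl == c0]
      rows[[length(rows) + 1L]] <- data.frame(
        lg = qtls$lg[members[1L]],
        trait = paste(sort(unique(qtls$trait[members])), collapse = ","),
        members = paste(qtls$qtl_id[members], collapse = ","),
        n_qtls = length(members),
        n_populations = length(unique(qtls$study_ref[members])),
        span_start_cm = min(qtls$ci_start_cm[members]),
        span_end_cm = max(qtls$ci_end_cm[members])
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(lg = character(0), trait = character(0),
                      members = character(0), n_qtls = integer(0),
                      n_populations = integer(0),
                      span_start_cm = numeric(0), span_end_cm = numeric(0))
  }
  out <- out[order(out$lg, out$span_start_cm), , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  out$confirmed <- out$n_populations >= 2L
  rownames(out) <- NULL
  out[, c("cluster_id", "lg", "trait", "members", "n_qtls",
          "n_populations", "span_start_cm", "span_end_cm", "confirmed")]
}

bin_coverage <- function(qtls, lg_lengths, bin_cm) {
  covered <- logical(0)
  for (g in names(lg_lengths)) {
    n_bins <- ceiling(lg_lengths[[g]] / bin_cm)
    cov_g <- logical(n_bins)
    sub <- qtls[qtls$lg == g & !is.na(qtls$ci_start_cm), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      lo <- max(1L, floor(sub$ci_start_cm[i] / bin_cm) + 1L)
      hi <- min(n_bins, floor(sub$ci_end_cm[i] / bin_cm) + 1L)
      if (hi >= lo) cov_g[lo:hi] <- TRUE
    }
    covered <- c(covered, cov_g)
  }
  covered
}

#' Test the significance of QTL co-localization between two traits
#'
#' The genome (per-LG lengths in cM) is partitioned into `bin_cm` bins; each
#' bin is scored covered/uncovered by each trait's CIs, giving a 2x2
#' contingency table (both, a only, b only, neither) tested by a chi-square
#' with 1 df and Yates continuity correction. The permutation alternative
#' circularly shifts trait-b QTLs within each LG `n_perm` times and reports
#' the empirical p-value of the observed jointly-covered bin count.
#'
#' @param qtls_a,qtls_b projected-QTL data.frames (non-empty).
#' @param lg_lengths named numeric vector/list of LG lengths in cM.
#' @param bin_cm bin width in cM (default 5).
#' @param method `"chi2"` or `"permutation"`.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed for the permutation method.
#' @return list: `statistic` (chi-square, or observed joint bins), `p_value`,
#'   `table` (2x2 counts), `method`.
#' @export
chi2_colocalization_test <- function(qtls_a, qtls_b, lg_lengths, bin_cm = 5,
                                     method = c("chi2", "permutation"),
                                     n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(nrow(qtls_a) > 0L, nrow(qtls_b) > 0L)
  lg_lengths <- as.list(lg_lengths)
  cov_a <- bin_coverage(qtls_a, lg_lengths, bin_cm)
  cov_b <- bin_coverage(qtls_b, lg_lengths, bin_cm)
  tab <- matrix(c(sum(cov_a & cov_b), sum(cov_a & !cov_b),
                  sum(!cov_a & cov_b), sum(!cov_a & !cov_b)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(a = c("a", "not_a"), b = c("b", "not_b")))
  if (sum(tab > 0L) < 2L) {
    stop("degenerate contingency table (fewer than 2 nonempty cells)")
  }
  if (method == "chi2") {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    list(statistic = unname(ct$statistic), p_value = ct$p.value,
         table = tab, method = "chi2")
  } else {
    obs <- sum(cov_a & cov_b)
    hits <- with_seed(seed, {
      vapply(seq_len(n_perm), function(r) {
        shifted <- qtls_b
        for (g in names(lg_lengths)) {
          idx <- shifted$lg == g
          if (!any(idx)) next
          d <- stats::runif(1L, 0, lg_lengths[[g]])
          L <- lg_lengths[[g]]
          s <- (shifted$ci_start_cm[idx] + d) %% L
          e <- s + (shifted$ci_end_cm[idx] - shifted$ci_start_cm[idx])
          shifted$ci_start_cm[idx] <- s
          shifted$ci_end_cm[idx] <- pmin(e, L)  # truncate wrap-around tail
        }
        sum(cov_a & bin_coverage(shifted, lg_lengths, bin_cm))
      }, numeric(1L))
    })
    p <- (1 + sum(hits >= obs)) / (n_perm + 1)
    list(statistic = obs, p_value = p, table = tab, method = "permutation")
  }
}
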