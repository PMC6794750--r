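#' Estimate a missing 95% confidence interval from N and R-squared
#'
#' Standard fallback in meta-QTL practice for QTLs published without a CI:
#' the expected CI95 length is `530 / (N * r2)` cM for an F2/BC-type design,
#' used here as a single convention for all populations.
#'
#' @param n population size.
#' @param r2 variance explained in `[0, 1]`.
#' @return CI95 length in cM.
#' @export
ci_from_population <- function(n, r2) {
  stopifnot(all(n > 0, na.rm = TRUE))
  ifelse(is.na(n) | is.na(r2) | r2 <= 0, NA_real_, 530 / (n * r2))
}

#' Find the shared flanking markers used to project a QTL
#'
#' Returns the closest markers shared between the QTL's source map and the
#' consensus that bracket the peak (source positions `a_L <= peak <= a_R`,
#' `a_L < a_R`). When the peak lies outside the shared-marker span, the two
#' nearest shared markers on that side form an extrapolation pair. When a
#' shared marker sits exactly on the peak it is paired with its nearest
#' shared neighbour (the side minimizing the bracket width).
#'
#' @param qtl one QTL record (a one-row data.frame or list with `lg` and
#'   `peak_cm`).
#' @param source the source `genetic_map`.
#' @param consensus the `consensus_map`.
#' @return list(`left`, `right`, `a` = source positions, `b` = consensus
#'   positions, `extrapolated`), or `NULL` when fewer than two shared markers
#'   with distinct source positions exist on the LG.
#' @export
find_flanking_shared_markers <- function(qtl, source, consensus) {
  lg <- as.character(qtl$lg)
  src <- lg_markers(source, lg)
  cons <- consensus$markers[consensus$markers$lg == lg, ]
  shared <- intersect(src$marker, cons$marker)
  if (length(shared) < 2L) return(NULL)
  a <- src$pos_cm[match(shared, src$marker)]
  b <- cons$pos_cm[match(shared, cons$marker)]
  # one marker per distinct source position (co-segregating duplicates)
  o <- order(a, shared)
  shared <- shared[o]; a <- a[o]; b <- b[o]
  keep <- !duplicated(a)
  shared <- shared[keep]; a <- a[keep]; b <- b[keep]
  if (length(shared) < 2L) return(NULL)
  x <- qtl$peak_cm
  n <- length(a)
  pick <- function(i, j, extra) {
    list(left = shared[i], right = shared[j], a = c(a[i], a[j]),
         b = c(b[i], b[j]), extrapolated = extra)
  }
  if (x < a[1L]) return(pick(1L, 2L, TRUE))
  if (x > a[n]) return(pick(n - 1L, n, TRUE))
  iL <- max(which(a <= x))
  iR <- min(which(a >= x))
  if (iL < iR) return(pick(iL, iR, FALSE))
  # exact hit on a shared marker: pair with the nearest neighbour
  i <- iL
  if (i == 1L) return(pick(1L, 2L, FALSE))
  if (i == n) return(pick(n - 1L, n, FALSE))
  if ((a[i] - a[i - 1L]) <= (a[i + 1L] - a[i])) pick(i - 1L, i, FALSE)
  else pick(i, i + 1L, FALSE)
}

#' Homothetic projection of one QTL onto the consensus map
#'
#' With flanking source positions `a = (a_L, a_R)` and consensus positions
#' `b = (b_L, b_R)`, the scale is `s = (b_R - b_L) / (a_R - a_L)` and every
#' coordinate maps through `f(x) = b_L + s * (x - a_L)`. The projection is
#' rejected when `s < min_scale` (default 0.25: the consensus flank distance
#' may not shrink below a quarter of the source distance) and optionally when
#' `s > max_scale`.
#'
#' @param qtl one QTL record (one-row data.frame) with `peak_cm`,
#'   `ci_start_cm`, `ci_end_cm`.
#' @param flanks flank pair from [find_flanking_shared_markers()].
#' @param min_scale minimum allowed scale factor (default 0.25).
#' @param max_scale optional maximum allowed scale factor (default `Inf`).
#' @return The record as a one-row data.frame with consensus coordinates and
#'   columns `scale`, `flank_left`, `flank_right`, `extrapolated`, `status`
#'   (`"projected"` or `"rejected"`), `reason`.
#' @export
project_qtl <- function(qtl, flanks, min_scale = 0.25, max_scale = Inf) {
  out <- as.data.frame(qtl)
  out$scale <- NA_real_
  out$flank_left <- NA_character_
  out$flank_right <- NA_character_
  out$extrapolated <- FALSE
  if (is.null(flanks)) {
    out$status <- "rejected"; out$reason <- "no anchoring markers"
    return(out)
  }
  da <- flanks$a[2L] - flanks$a[1L]
  out$flank_left <- flanks$left
  out$flank_right <- flanks$right
  out$extrapolated <- isTRUE(flanks$extrapolated)
  if (da <= 0) {
    out$status <- "rejected"; out$reason <- "degenerate flanks"
    return(out)
  }
  s <- (flanks$b[2L] - flanks$b[1L]) / da
  out$scale <- s
  if (s < min_scale || s > max_scale) {
    out$status <- "rejected"; out$reason <- "scale"
    return(out)
  }
  f <- function(x) flanks$b[1L] + s * (x - flanks$a[1L])
  out$peak_cm <- f(qtl$peak_cm)
  out$ci_start_cm <- f(qtl$ci_start_cm)
  out$ci_end_cm <- f(qtl$ci_end_cm)
  out$status <- "projected"
  out$reason <- NA_character_
  out
}

#' Project all QTLs onto the consensus map
#'
#' Each QTL is looked up in its source map (matched by `study_ref` against
#' the maps' `map_id`), given an estimated CI when missing (via
#' [ci_from_population()]; QTLs with neither CI nor R² are flagged
#' `"no confidence interval"` and excluded from meta-analysis but still
#' carried with a projected peak), and projected through its flanking shared
#' markers. Every QTL appears exactly once in the output, as projected or
#' rejected with a reason.
#'
#' @param qtls QTL data.frame (see [read_qtl_table()]).
#' @param maps list of `genetic_map` whose `map_id`s cover
#'   `qtls$study_ref`.
#' @param consensus the `consensus_map`.
#' @param min_scale,max_scale scale-rejection bounds, see [project_qtl()].
#' @return data.frame of projected/rejected QTLs; attribute `"rates"` holds
#'   per-trait and per-category projection rates.
#' @export
project_all <- function(qtls, maps, consensus, min_scale = 0.25,
                        max_scale = Inf) {
  ids <- vapply(maps, function(m) m$map_id, character(1L))
  unknown <- setdiff(unique(qtls$study_ref), ids)
  if (length(unknown)) {
    stop("QTL(s) reference unknown map(s): ", paste(unknown, collapse = ", "))
  }
  rows <- vector("list", nrow(qtls))
  for (i in seq_len(nrow(qtls))) {
    q <- qtls[i, , drop = FALSE]
    if (isTRUE(q$ci_missing) ||
        is.na(q$ci_start_cm) || is.na(q$ci_end_cm)) {
      len <- ci_from_population(q$population_size, q$r2)
      if (is.na(len)) {
        q$ci_start_cm <- q$ci_end_cm <- NA_real_
      } else {
        q$ci_start_cm <- q$peak_cm - len / 2
        q$ci_end_cm <- q$peak_cm + len / 2
      }
    }
    src <- maps[[match(q$study_ref, ids)]]
    flanks <- find_flanking_shared_markers(q, src, consensus)
    pr <- project_qtl(q, flanks, min_scale = min_scale,
                      max_scale = max_scale)
    if (pr$status == "projected" && is.na(pr$ci_start_cm)) {
      pr$reason <- "no confidence interval"
    }
    rows[[i]] <- pr
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  rate <- function(key) {
    agg <- stats::aggregate(out$status == "projected",
                            by = list(key = out[[key]]), FUN = mean)
    names(agg) <- c(key, "projected_rate")
    agg
  }
  attr(out, "rates") <- list(by_trait = rate("trait"),
                             by_category = rate("trait_category"),
                             overall = mean(out$status == "projected"))
  out
}
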