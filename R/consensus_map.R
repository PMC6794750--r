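#' Orient a component map against a reference map
#'
#' For every linkage group shared with the reference, the LG coordinate axis
#' is flipped (`pos -> max(pos) - pos`) iff the Spearman rank correlation of
#' the shared markers' orders is negative. Groups sharing fewer than two
#' markers with the reference cannot be oriented and are flagged in the
#' `"unorientable"` attribute; ties (rho exactly 0) keep the original
#' orientation.
#'
#' @param component a `genetic_map` to orient.
#' @param reference the reference `genetic_map`.
#' @return The oriented `genetic_map`, with attributes `"flipped"` (LG labels
#'   that were flipped) and `"unorientable"`.
#' @export
orient_groups <- function(component, reference) {
  stopifnot(inherits(component, "genetic_map"),
            inherits(reference, "genetic_map"))
  mk <- component$markers
  flipped <- character(0)
  unorientable <- character(0)
  for (g in unique(mk$lg)) {
    comp <- mk[mk$lg == g, ]
    ref <- lg_markers(reference, g)
    shared <- intersect(comp$marker, ref$marker)
    if (length(shared) < 2L) {
      unorientable <- c(unorientable, g)
      next
    }
    rho <- suppressWarnings(stats::cor(
      comp$pos_cm[match(shared, comp$marker)],
      ref$pos_cm[match(shared, ref$marker)],
      method = "spearman"
    ))
    if (!is.na(rho) && rho < 0) {
      mk$pos_cm[mk$lg == g] <- max(comp$pos_cm) - mk$pos_cm[mk$lg == g]
      flipped <- c(flipped, g)
    }
  }
  out <- genetic_map(mk, map_id = component$map_id,
                     study_ref = component$study_ref)
  attr(out, "flipped") <- flipped
  attr(out, "unorientable") <- unorientable
  out
}

#' Drop linkage groups that cannot be tied to the other maps
#'
#' A retained LG group must share at least two markers with the union of the
#' other maps' markers on the same LG; groups failing this cannot be oriented
#' or calibrated and are removed (reported, not fatal).
#'
#' @param maps list of `genetic_map`.
#' @return list with elements `maps` (pruned) and `removed` (data.frame
#'   `map_id`, `lg`, `n_shared`).
#' @export
drop_unlinked_groups <- function(maps) {
  removed <- data.frame(map_id = character(0), lg = character(0),
                        n_shared = integer(0))
  if (length(maps) == 1L) return(list(maps = maps, removed = removed))
  out <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    mk <- m$markers
    keep <- rep(TRUE, nrow(mk))
    for (g in unique(mk$lg)) {
      others <- unlist(lapply(maps[-i], function(o) lg_markers(o, g)$marker))
      n_shared <- sum(mk$marker[mk$lg == g] %in% others)
      if (n_shared < 2L) {
        keep[mk$lg == g] <- FALSE
        removed <- rbind(removed, data.frame(map_id = m$map_id, lg = g,
                                             n_shared = n_shared))
      }
    }
    out[[i]] <- genetic_map(mk[keep, , drop = FALSE], map_id = m$map_id,
                            study_ref = m$study_ref)
  }
  list(maps = out, removed = removed)
}

#' Detect marker-order conflicts between maps on one linkage group
#'
#' A conflict is a pair of markers present in two maps whose relative order
#' (strictly) differs between them. All map pairs are compared.
#'
#' @param maps list of oriented `genetic_map`.
#' @param lg linkage-group label.
#' @return data.frame with columns `map_a`, `map_b`, `marker_1`, `marker_2`
#'   (marker_1 < marker_2 lexicographically), one row per conflicting pair.
#' @export
detect_order_conflicts <- function(maps, lg) {
  res <- list()
  n <- length(maps)
  if (n < 2L) return(conflict_frame())
  for (i in seq_len(n - 1L)) {
    mi <- lg_markers(maps[[i]], lg)
    for (j in seq(i + 1L, n)) {
      mj <- lg_markers(maps[[j]], lg)
      shared <- intersect(mi$marker, mj$marker)
      if (length(shared) < 2L) next
      pi <- mi$pos_cm[match(shared, mi$marker)]
      pj <- mj$pos_cm[match(shared, mj$marker)]
      cmb <- utils::combn(length(shared), 2L)
      di <- pi[cmb[1L, ]] - pi[cmb[2L, ]]
      dj <- pj[cmb[1L, ]] - pj[cmb[2L, ]]
      bad <- which(di * dj < 0)  # strictly opposite order; ties never conflict
      for (b in bad) {
        pair <- sort(shared[cmb[, b]])
        res[[length(res) + 1L]] <- data.frame(
          map_a = maps[[i]]$map_id, map_b = maps[[j]]$map_id,
          marker_1 = pair[1L], marker_2 = pair[2L]
        )
      }
    }
  }
  if (!length(res)) return(conflict_frame())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

conflict_frame <- function() {
  data.frame(map_a = character(0), map_b = character(0),
             marker_1 = character(0), marker_2 = character(0))
}

marker_occurrence <- function(maps, lg, markers) {
  vapply(markers, function(m) {
    sum(vapply(maps, function(mp) m %in% lg_markers(mp, lg)$marker,
               logical(1L)))
  }, integer(1L))
}

#' Resolve order conflicts by removing the least represented markers
#'
#' While conflicts remain on the LG, the marker involved in at least one
#' conflict with the lowest occurrence count across all maps is removed from
#' every map (ties broken alphabetically for determinism), and conflicts are
#' recomputed. Terminates with a conflict-free LG.
#'
#' @param maps list of oriented `genetic_map`.
#' @param lg linkage-group label.
#' @return list with elements `maps` and `removed` (data.frame `marker`,
#'   `n_maps` giving the occurrence count at removal time).
#' @export
resolve_inversions <- function(maps, lg) {
  removed <- data.frame(marker = character(0), n_maps = integer(0))
  repeat {
    conf <- detect_order_conflicts(maps, lg)
    if (!nrow(conf)) break
    involved <- sort(unique(c(conf$marker_1, conf$marker_2)))
    occ <- marker_occurrence(maps, lg, involved)
    victim <- involved[which.min(occ)]  # which.min takes first tie => alphabetical
    removed <- rbind(removed,
                     data.frame(marker = victim, n_maps = min(occ)))
    maps <- lapply(maps, function(m) {
      mk <- m$markers
      keep <- !(mk$lg == lg & mk$marker == victim)
      genetic_map(mk[keep, , drop = FALSE], map_id = m$map_id,
                  study_ref = m$study_ref)
    })
  }
  list(maps = maps, removed = removed)
}

# Monotone piecewise-linear calibration through (x_shared, y_shared) control
# points; queries outside the shared span use the terminal segment's slope.
calibrate_positions <- function(x_shared, y_shared, x_query) {
  o <- order(x_shared)
  x <- x_shared[o]; y <- y_shared[o]
  # collapse duplicated x (markers at identical source position)
  if (anyDuplicated(x)) {
    y <- tapply(y, x, mean)
    x <- sort(unique(x))
    y <- as.numeric(y)
  }
  if (length(x) < 2L) stop("calibration needs >= 2 distinct shared positions")
  n <- length(x)
  idx <- findInterval(x_query, x, all.inside = TRUE)
  slope <- (y[idx + 1L] - y[idx]) / (x[idx + 1L] - x[idx])
  y[idx] + slope * (x_query - x[idx])
}

#' Build the consensus for one linkage group
#'
#' The component map with the most markers on the LG is the initial
#' calibration frame (ties go to the lexicographically smallest `map_id`).
#' Remaining maps are merged in decreasing order of markers shared with the
#' current frame: each map is calibrated onto the frame by monotone
#' piecewise-linear interpolation through its shared markers, and the
#' consensus position of every marker is refreshed as the arithmetic mean of
#' its calibrated positions across the maps containing it. After merging the
#' LG is shifted so its first marker sits at 0 cM. Equal consensus positions
#' order by descending occupancy (`n_maps`), then marker name.
#'
#' @param maps list of oriented, conflict-free `genetic_map` containing the LG.
#' @param lg linkage-group label.
#' @return A one-LG `consensus_map` object: list with `markers` (data.frame
#'   `lg`, `marker`, `pos_cm`, `n_maps`) and `provenance` (data.frame
#'   `lg`, `marker`, `map_id`, `source_pos_cm`, `calibrated_pos_cm`).
#' @export
build_consensus_lg <- function(maps, lg) {
  lg <- as.character(lg)
  has <- vapply(maps, function(m) nrow(lg_markers(m, lg)) > 0L, logical(1L))
  maps <- maps[has]
  if (!length(maps)) stop("no map contains LG ", lg)
  sizes <- vapply(maps, function(m) nrow(lg_markers(m, lg)), integer(1L))
  ids <- vapply(maps, function(m) m$map_id, character(1L))
  frame_i <- order(-sizes, ids)[1L]

  frame <- lg_markers(maps[[frame_i]], lg)
  # per-map calibrated positions; the frame map is its own calibration
  calib <- list()
  calib[[ids[frame_i]]] <- stats::setNames(frame$pos_cm, frame$marker)
  consensus <- stats::setNames(frame$pos_cm, frame$marker)
  pending <- setdiff(seq_along(maps), frame_i)

  while (length(pending)) {
    shared_n <- vapply(pending, function(i) {
      sum(lg_markers(maps[[i]], lg)$marker %in% names(consensus))
    }, integer(1L))
    pick <- pending[order(-shared_n, ids[pending])[1L]]
    if (max(shared_n) < 2L) {
      stop("disconnected marker graph on LG ", lg, ": map(s) ",
           paste(ids[pending], collapse = ", "),
           " share < 2 markers with the merged frame")
    }
    mk <- lg_markers(maps[[pick]], lg)
    shared <- intersect(mk$marker, names(consensus))
    cal <- calibrate_positions(
      mk$pos_cm[match(shared, mk$marker)],
      unname(consensus[shared]),
      mk$pos_cm
    )
    calib[[ids[pick]]] <- stats::setNames(cal, mk$marker)
    # refresh: mean of calibrated positions across merged maps
    all_mk <- unique(unlist(lapply(calib, names)))
    consensus <- vapply(all_mk, function(m) {
      mean(unlist(lapply(calib, function(v) v[names(v) == m])))
    }, numeric(1L))
    pending <- setdiff(pending, pick)
  }

  n_maps <- vapply(names(consensus), function(m) {
    sum(vapply(calib, function(v) m %in% names(v), logical(1L)))
  }, integer(1L))
  pos <- consensus - min(consensus)
  ord <- order(pos, -n_maps, names(consensus), method = "radix")
  markers <- data.frame(lg = lg, marker = names(consensus)[ord],
                        pos_cm = unname(pos[ord]),
                        n_maps = unname(n_maps[ord]))
  prov <- do.call(rbind, lapply(names(calib), function(id) {
    src <- lg_markers(maps[[which(ids == id)]], lg)
    data.frame(lg = lg, marker = names(calib[[id]]), map_id = id,
               source_pos_cm = src$pos_cm[match(names(calib[[id]]),
                                                src$marker)],
               calibrated_pos_cm = unname(calib[[id]]))
  }))
  rownames(prov) <- NULL
  structure(list(markers = markers, provenance = prov),
            class = "consensus_map")
}

#' Build a consensus map across all linkage groups
#'
#' Runs orientation against a reference (the largest map by default),
#' removal of unlinked groups, iterative conflict resolution and per-LG
#' consensus construction, chromosome by chromosome.
#'
#' @param maps list of `genetic_map`.
#' @param reference optional reference `genetic_map` for orientation; default
#'   is the component with the most markers overall.
#' @return A `consensus_map` covering every LG present in at least one map,
#'   with attributes `"removed_groups"`, `"removed_markers"`.
#' @export
build_consensus <- function(maps, reference = NULL) {
  stopifnot(length(maps) >= 1L)
  if (is.null(reference)) {
    sizes <- vapply(maps, function(m) nrow(m$markers), integer(1L))
    reference <- maps[[which.max(sizes)]]
  }
  oriented <- lapply(maps, orient_groups, reference = reference)
  dropped <- drop_unlinked_groups(oriented)
  maps2 <- dropped$maps
  lgs <- sort(unique(unlist(lapply(maps2, map_lgs))))
  removed_markers <- list()
  parts <- list()
  for (g in lgs) {
    res <- resolve_inversions(maps2, g)
    removed_markers[[g]] <- res$removed
    parts[[g]] <- build_consensus_lg(res$maps, g)
  }
  markers <- do.call(rbind, lapply(parts, function(p) p$markers))
  prov <- do.call(rbind, lapply(parts, function(p) p$provenance))
  rownames(markers) <- rownames(prov) <- NULL
  structure(
    list(markers = markers, provenance = prov),
    class = "consensus_map",
    removed_groups = dropped$removed,
    removed_markers = do.call(rbind, removed_markers)
  )
}

#' @export
print.consensus_map <- function(x, ...) {
  cat("<consensus_map> ", nrow(x$markers), " markers on ",
      length(unique(x$markers$lg)), " linkage group(s); ",
      sum(x$markers$n_maps >= 2L), " shared by >= 2 maps\n", sep = "")
  invisible(x)
}

#' Per-LG summary of a consensus map
#'
#' Mirrors the usual consensus-map feature table: marker counts, unique and
#' shared markers, LG length and number of component maps integrated.
#'
#' @param consensus a `consensus_map`.
#' @return data.frame with one row per LG plus a `Total` row.
#' @export
summarize_consensus <- function(consensus) {
  mk <- consensus$markers
  prov <- consensus$provenance
  rows <- lapply(unique(mk$lg), function(g) {
    sub <- mk[mk$lg == g, ]
    data.frame(
      lg = g,
      n_markers = nrow(sub),
      n_unique = sum(sub$n_maps == 1L),
      n_shared = sum(sub$n_maps >= 2L),
      length_cm = round(max(sub$pos_cm) - min(sub$pos_cm), 2L),
      n_maps = length(unique(prov$map_id[prov$lg == g]))
    )
  })
  out <- do.call(rbind, rows)
  total <- data.frame(lg = "Total", n_markers = sum(out$n_markers),
                      n_unique = sum(out$n_unique),
                      n_shared = sum(out$n_shared),
                      length_cm = round(sum(out$length_cm), 2L),
                      n_maps = NA_integer_)
  rbind(out, total)
}

#' Spearman correlation of marker order between a component and the consensus
#'
#' @param component a `genetic_map`.
#' @param consensus a `consensus_map`.
#' @return data.frame with one row per LG (`lg`, `n_shared`, `rho`; `rho` is
#'   `NA` when fewer than 3 markers are shared) plus an `overall` row pooling
#'   all shared markers.
#' @export
map_order_correlation <- function(component, consensus) {
  rows <- list()
  all_x <- numeric(0); all_y <- numeric(0)
  for (g in map_lgs(component)) {
    comp <- lg_markers(component, g)
    cons <- consensus$markers[consensus$markers$lg == g, ]
    shared <- intersect(comp$marker, cons$marker)
    x <- comp$pos_cm[match(shared, comp$marker)]
    y <- cons$pos_cm[match(shared, cons$marker)]
    rho <- if (length(shared) >= 3L) {
      suppressWarnings(stats::cor(x, y, method = "spearman"))
    } else NA_real_
    rows[[g]] <- data.frame(lg = g, n_shared = length(shared), rho = rho)
    all_x <- c(all_x, x); all_y <- c(all_y, y)
  }
  out <- do.call(rbind, rows)
  overall <- if (length(all_x) >= 3L) {
    suppressWarnings(stats::cor(all_x, all_y, method = "spearman"))
  } else NA_real_
  out <- rbind(out, data.frame(lg = "overall", n_shared = length(all_x),
                               rho = overall))
  rownames(out) <- NULL
  out
}
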