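test_that("orientation flips reversed groups and leaves aligned ones alone", {
  ref <- toy_map(c("A", "B", "C", "D"), c(0, 5, 10, 20))
  rev <- toy_map(c("D", "C", "B", "A"), c(0, 10, 15, 20), map_id = "rev")
  out <- orient_groups(rev, ref)
  expect_equal(attr(out, "flipped"), "1")
  expect_equal(lg_markers(out, "1")$marker, c("A", "B", "C", "D"))
  same <- orient_groups(ref, ref)
  expect_length(attr(same, "flipped"), 0L)
  expect_equal(same$markers, ref$markers)
})

test_that("orientation matches the exhaustive two-option oracle", {
  set.seed(21)
  for (rep in 1:20) {
    ref <- random_map(12, map_id = "ref")
    nm <- paste0("c", sprintf("%02d", 1:12))
    nm[1:6] <- ref$markers$marker[sample(12, 6)]  # overlap of 6 markers
    comp <- toy_map(nm, sort(runif(12, 0, 100)), map_id = "comp")
    shared <- intersect(comp$markers$marker, ref$markers$marker)
    x <- comp$markers$pos_cm[match(shared, comp$markers$marker)]
    y <- ref$markers$pos_cm[match(shared, ref$markers$marker)]
    rho_keep <- suppressWarnings(cor(x, y, method = "spearman"))
    rho_flip <- suppressWarnings(cor(-x, y, method = "spearman"))
    out <- orient_groups(comp, ref)
    flipped <- "1" %in% attr(out, "flipped")
    if (rho_flip > rho_keep) expect_true(flipped)
    if (rho_keep >= rho_flip) expect_false(flipped)
  }
})

test_that("groups sharing fewer than two markers are dropped and reported", {
  m1 <- toy_map(c("A", "B", "C"), c(0, 5, 10))
  m2 <- toy_map(c("A", "B", "X"), c(0, 6, 12), map_id = "m2")
  m3 <- toy_map(c("A", "Y", "Z"), c(0, 3, 9), map_id = "m3")  # 1 shared
  res <- drop_unlinked_groups(list(m1, m2, m3))
  expect_equal(res$removed$map_id, "m3")
  expect_equal(nrow(res$maps[[3L]]$markers), 0L)
  # boundary: exactly two shared markers are enough
  expect_equal(nrow(res$maps[[2L]]$markers), 3L)
})

test_that("order conflicts match a brute-force pairwise oracle", {
  m1 <- toy_map(c("A", "B", "C"), c(0, 5, 10))
  m2 <- toy_map(c("A", "C", "B"), c(0, 4, 9), map_id = "m2")
  conf <- detect_order_conflicts(list(m1, m2), "1")
  expect_equal(nrow(conf), 1L)
  expect_equal(c(conf$marker_1, conf$marker_2), c("B", "C"))
  expect_equal(nrow(detect_order_conflicts(list(m1, m1), "1")), 0L)

  set.seed(7)
  for (rep in 1:5) {
    maps <- lapply(1:3, function(i) {
      m <- random_map(8, map_id = paste0("m", i))
      # random transposition to induce conflicts
      k <- sample(7, 1)
      p <- m$markers$pos_cm
      m$markers$pos_cm[c(k, k + 1L)] <- p[c(k + 1L, k)]
      genetic_map(m$markers, map_id = m$map_id)
    })
    conf <- detect_order_conflicts(maps, "1")
    # independent oracle: enumerate all map pairs x marker pairs
    oracle <- 0L
    for (i in 1:2) for (j in (i + 1):3) {
      mi <- lg_markers(maps[[i]], "1"); mj <- lg_markers(maps[[j]], "1")
      sh <- intersect(mi$marker, mj$marker)
      for (a in seq_along(sh)) for (b in seq_along(sh)) {
        if (a >= b) next
        di <- mi$pos_cm[match(sh[a], mi$marker)] -
          mi$pos_cm[match(sh[b], mi$marker)]
        dj <- mj$pos_cm[match(sh[a], mj$marker)] -
          mj$pos_cm[match(sh[b], mj$marker)]
        if (di * dj < 0) oracle <- oracle + 1L
      }
    }
    expect_equal(nrow(conf), oracle)
  }
})

test_that("inversion resolution removes the least represented marker", {
  # B occurs in 3 maps, C in 2; the B/C conflict must cost C everywhere
  m1 <- toy_map(c("A", "B", "C"), c(0, 5, 10))
  m2 <- toy_map(c("A", "C", "B"), c(0, 4, 9), map_id = "m2")
  m3 <- toy_map(c("A", "B", "D"), c(0, 5, 12), map_id = "m3")
  res <- resolve_inversions(list(m1, m2, m3), "1")
  expect_equal(res$removed$marker, "C")
  expect_false("C" %in% res$maps[[1L]]$markers$marker)
  expect_equal(nrow(detect_order_conflicts(res$maps, "1")), 0L)
  # no conflicts -> no removals
  res0 <- resolve_inversions(list(m1, m3), "1")
  expect_equal(nrow(res0$removed), 0L)
})

test_that("seeded conflict sets always end conflict-free", {
  cfg <- sim_config(seed = 5L, n_lgs = 1L, n_maps = 5L,
                    markers_per_map = 20L, n_inversions = 3L)
  sim <- simulate_maps(cfg)
  expect_gt(nrow(detect_order_conflicts(sim$maps, "1")), 0L)
  res <- resolve_inversions(sim$maps, "1")
  expect_equal(nrow(detect_order_conflicts(res$maps, "1")), 0L)
})

test_that("consensus of identical maps is the identity", {
  m <- random_map(15, map_id = "base")
  maps <- lapply(1:5, function(i) genetic_map(m$markers,
                                              map_id = paste0("c", i)))
  cons <- build_consensus(maps)
  expect_equal(cons$markers$marker, m$markers$marker)
  expect_equal(cons$markers$pos_cm, m$markers$pos_cm, tolerance = 1e-12)
  expect_true(all(cons$markers$n_maps == 5L))
})

test_that("unique markers interpolate linearly between shared flanks", {
  m1 <- toy_map(c("A", "D", "E"), c(0, 10, 30))
  m2 <- toy_map(c("A", "X", "D"), c(0, 10, 20), map_id = "m2")
  cons <- build_consensus_lg(list(m1, m2), "1")
  mk <- cons$markers
  expect_equal(mk$pos_cm[mk$marker == "X"], 5)
  expect_equal(mk$pos_cm[mk$marker == "D"], 10)
  expect_equal(mk$pos_cm[mk$marker == "E"], 30)
})

test_that("disconnected marker sets fail loudly", {
  m1 <- toy_map(c("A", "B"), c(0, 10))
  m2 <- toy_map(c("X", "Y"), c(0, 10), map_id = "m2")
  expect_error(build_consensus_lg(list(m1, m2), "1"), "disconnected")
})

test_that("consensus is idempotent and order-recovering under distortion", {
  cfg <- sim_config(seed = 17L)
  sim <- simulate_maps(cfg)
  cons <- build_consensus(sim$maps)
  for (g in map_lgs(sim$truth$true_map)) {
    mc <- map_order_correlation(sim$truth$true_map, cons)
    rho <- mc$rho[mc$lg == g]
    expect_gte(rho, 0.95)
  }
  # idempotence: feeding the consensus back as a single map changes nothing
  cm <- genetic_map(cons$markers[, c("lg", "marker", "pos_cm")],
                    map_id = "cons")
  cons2 <- build_consensus(list(cm))
  expect_equal(cons2$markers$marker, cons$markers$marker)
  expect_equal(cons2$markers$pos_cm, cons$markers$pos_cm, tolerance = 1e-9)
})

test_that("calibration is order-preserving on its control points", {
  set.seed(31)
  for (rep in 1:10) {
    x <- sort(runif(6, 0, 100))
    y <- sort(runif(6, 0, 120))
    q <- sort(runif(20, -10, 110))
    out <- qtlmeta:::calibrate_positions(x, y, q)
    expect_true(all(diff(out) >= -1e-12))
    expect_equal(qtlmeta:::calibrate_positions(x, y, x), y)
  }
})

test_that("marker-order correlation agrees with the textbook rank formula", {
  cons <- as_consensus(data.frame(lg = "1",
                                  marker = sprintf("mk%02d", 1:10),
                                  pos_cm = seq(0, 90, by = 10)))
  identical_map <- toy_map(sprintf("mk%02d", 1:10), seq(0, 45, by = 5))
  expect_equal(map_order_correlation(identical_map, cons)$rho[1L], 1)
  reversed <- toy_map(sprintf("mk%02d", 10:1), seq(0, 45, by = 5))
  expect_equal(map_order_correlation(reversed, cons)$rho[1L], -1)
  set.seed(13)
  for (rep in 1:5) {
    perm <- sample(10)
    m <- toy_map(sprintf("mk%02d", perm), seq(0, 45, by = 5))
    rho <- map_order_correlation(m, cons)$rho[1L]
    # Spearman via the no-ties closed form 1 - 6*sum(d^2)/(n(n^2-1))
    r1 <- rank(match(sprintf("mk%02d", perm), sprintf("mk%02d", 1:10)))
    d <- r1 - seq_along(r1)
    expect_equal(rho, 1 - 6 * sum(d^2) / (10 * 99), tolerance = 1e-12)
  }
})

test_that("the consensus summary mirrors per-LG marker bookkeeping", {
  cfg <- sim_config(seed = 3L, n_lgs = 2L, n_maps = 4L,
                    markers_per_map = 15L)
  sim <- simulate_maps(cfg)
  cons <- build_consensus(sim$maps)
  sm <- summarize_consensus(cons)
  per_lg <- sm[sm$lg != "Total", ]
  expect_equal(sum(per_lg$n_markers), nrow(cons$markers))
  expect_equal(per_lg$n_markers, per_lg$n_unique + per_lg$n_shared)
})
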