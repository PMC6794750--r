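# a tiny expression matrix: 1 year unless asked, 3 replicates, FPKM given
# per (gene, timepoint) and replicated with no noise
tiny_mat <- function(profile, years = "2012", n_tp = ncol(profile),
                     days = 10 * (n_tp - seq_len(n_tp))) {
  samples <- expand.grid(year = years, timepoint_order = seq_len(n_tp),
                         replicate = 1:3, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  samples$days_before_veraison <- days[samples$timepoint_order]
  samples$sample <- sprintf("%s_T%d_R%d", samples$year,
                            samples$timepoint_order, samples$replicate)
  vals <- matrix(0, nrow(profile), nrow(samples),
                 dimnames = list(rownames(profile), samples$sample))
  for (j in seq_len(nrow(samples))) {
    vals[, j] <- profile[, samples$timepoint_order[j]]
  }
  expression_matrix(vals, samples)
}

test_that("the organ atlas filter keeps genes called in a listed organ", {
  calls <- data.frame(gene_id = c("g1", "g2", "g3"),
                      berry = c(FALSE, FALSE, TRUE),
                      rachis = c(FALSE, TRUE, FALSE),
                      seed = FALSE, leaf = c(TRUE, FALSE, FALSE))
  expect_equal(filter_expressed_atlas(c("g1", "g2", "g3"), calls),
               c("g2", "g3"))  # leaf-only g1 is excluded
  expect_warning(out <- filter_expressed_atlas(c("g2", "missing"), calls),
                 "not expressed")
  expect_equal(out, "g2")
  expect_error(filter_expressed_atlas("g1", calls, organs = character(0)),
               "empty organ set")
})

test_that("FPKM expression rule needs a replicate quorum at one time point", {
  samples <- data.frame(sample = paste0("s", 1:6), year = "2012",
                        timepoint_order = rep(1:2, each = 3),
                        days_before_veraison = rep(c(10, 0), each = 3),
                        replicate = rep(1:3, 2))
  vals <- rbind(
    silent = rep(0.5, 6),
    borderline = c(1.2, 1.1, 0.0, 0.5, 0.5, 0.5),  # 2 reps >= 1 at tp1
    single_rep = c(1.5, 0.2, 0.3, 0.9, 0.8, 0.2)   # never 2 reps >= 1
  )
  colnames(vals) <- samples$sample
  mat <- expression_matrix(vals, samples)
  expect_equal(filter_fpkm_expressed(mat), c("borderline"))
  # brute-force oracle on random matrices
  set.seed(43)
  for (rep in 1:5) {
    v <- matrix(runif(10 * 6, 0, 3), 10, 6,
                dimnames = list(paste0("g", 1:10), samples$sample))
    m <- expression_matrix(v, samples)
    got <- filter_fpkm_expressed(m)
    oracle <- rownames(v)[vapply(seq_len(10), function(i) {
      any(vapply(1:2, function(tp) {
        sum(v[i, samples$timepoint_order == tp] >= 1) >= 2
      }, logical(1L)))
    }, logical(1L))]
    expect_setequal(got, oracle)
  }
})

test_that("differential expression across an interval uses pseudocounted log2", {
  prof <- rbind(flat = c(2, 2), jump = c(1, 7))
  mat <- tiny_mat(prof)
  expect_false(de_across_interval(mat, "flat", c(1, 2), "2012"))
  expect_true(de_across_interval(mat, "jump", c(1, 2), "2012"))
  # log2((7+1)/(1+1)) = 2 exactly; a stricter threshold excludes it
  expect_true(de_across_interval(mat, "jump", c(1, 2), "2012",
                                 lfc_threshold = 2))
  expect_false(de_across_interval(mat, "jump", c(1, 2), "2012",
                                  lfc_threshold = 2.01))
})

test_that("raising the fold-change threshold never adds genes", {
  set.seed(47)
  prof <- matrix(2^runif(20 * 4, 0, 6), 20, 4,
                 dimnames = list(paste0("g", 1:20), NULL))
  mat <- tiny_mat(prof)
  prev <- Inf
  for (th in c(0.5, 1, 1.5, 2)) {
    n <- sum(vapply(rownames(prof), function(g) {
      de_across_interval(mat, g, c(2, 3), "2012", lfc_threshold = th)
    }, logical(1L)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("the onset interval maximizes biomarker DE, ties to the earliest", {
  # biomarkers flat except a planted jump between tp3 and tp4
  prof <- matrix(4, 5, 6, dimnames = list(paste0("bm", 1:5), NULL))
  prof[, 4:6] <- 20
  mat <- tiny_mat(prof)
  res <- find_onset_interval(mat, paste0("bm", 1:5), "2012")
  expect_equal(res$interval, c(3L, 4L))
  # two equal maxima -> earliest pair wins
  prof2 <- matrix(4, 4, 6, dimnames = list(paste0("bm", 1:4), NULL))
  prof2[1:2, 3:6] <- 20    # jump at (2,3)
  prof2[3:4, 5:6] <- 20    # jump at (4,5)
  res2 <- find_onset_interval(tiny_mat(prof2), paste0("bm", 1:4), "2012")
  expect_equal(res2$interval, c(2L, 3L))
  expect_error(find_onset_interval(mat, character(0), "2012"),
               "empty biomarker")
})

test_that("transcriptomic candidates need DE in two years or the external list", {
  years <- c("2012", "2013", "2014")
  profs <- lapply(years, function(y) {
    p <- matrix(4, 4, 4, dimnames = list(c("bm", "two_years", "one_year",
                                           "listed"), NULL))
    p["bm", 3:4] <- 30
    if (y != "2014") p["two_years", 3:4] <- 30
    if (y == "2012") p["one_year", 3:4] <- 30
    p
  })
  samples <- expand.grid(year = years, timepoint_order = 1:4,
                         replicate = 1:3, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  samples$days_before_veraison <- 10 * (4 - samples$timepoint_order)
  samples$sample <- sprintf("%s_T%d_R%d", samples$year,
                            samples$timepoint_order, samples$replicate)
  vals <- matrix(0, 4, nrow(samples),
                 dimnames = list(rownames(profs[[1L]]), samples$sample))
  for (j in seq_len(nrow(samples))) {
    vals[, j] <- profs[[match(samples$year[j], years)]][,
                                          samples$timepoint_order[j]]
  }
  mat <- expression_matrix(vals, samples)
  out <- select_transcriptomic_candidates(mat, "bm",
                                          all_genotype_de = "listed")
  expect_true("two_years" %in% out)
  expect_true("listed" %in% out)
  expect_false("one_year" %in% out)
})

test_that("candidate intersection reports the funnel and its monotonicity", {
  positional <- list(mq1 = c("g1", "g2"), mq2 = c("g3"))
  out <- intersect_candidates(positional, c("g1", "g2", "g3", "g9"))
  expect_setequal(out$gene_id, c("g1", "g2", "g3"))  # positional subset
  funnel <- attr(out, "funnel")
  expect_lte(funnel[["final"]], funnel[["positional"]])
  expect_lte(funnel[["final"]], funnel[["transcriptomic"]])
  out2 <- intersect_candidates(positional, "g9")
  expect_equal(nrow(out2), 0L)
})

test_that("GO slim flags regulatory candidates and tolerates bad accessions", {
  go <- data.frame(gene_id = c("g1", "g2", "g3", "g3"),
                   go = c("GO:0003700", "GO:0008150", "GO:0016301", "bad"))
  expect_warning(out <- go_slim_filter(c("g1", "g2", "g3"), go),
                 "malformed")
  expect_equal(out$regulatory, c(TRUE, FALSE, TRUE))
  expect_equal(out$go_hits[1L], "GO:0003700")
})
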