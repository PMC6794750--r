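test_that("sigma from CI length follows the normal quantile", {
  expect_equal(sd_from_ci(3.92), 1, tolerance = 1e-3)
  expect_equal(sd_from_ci(7.84), 2, tolerance = 1e-3)
  expect_equal(sd_from_ci(3.29, level = 0.90),
               3.29 / (2 * qnorm(0.95)), tolerance = 1e-12)
  expect_equal(sd_from_ci(3.29, level = 0.90), 1, tolerance = 1e-3)
  expect_error(sd_from_ci(0), "> 0")
})

test_that("K = 1 EM equals the inverse-variance weighted mean", {
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    x <- runif(n, 0, 100)
    s <- runif(n, 0.5, 4)
    f <- em_fit(x, s, K = 1L)
    expect_lt(abs(f$mu - weighted.mean(x, 1 / s^2)), 1e-9)
    expect_equal(f$pi, 1)
  }
  # symmetric pair
  f2 <- em_fit(c(30, 32), c(1, 1), K = 1L)
  expect_equal(f2$mu, 31, tolerance = 1e-9)
})

test_that("K = 2 EM attains the grid-search maximum likelihood", {
  set.seed(3)
  x <- c(10.2, 11.1, 9.5, 30.4, 29.8, 31.0)
  s <- rep(1.2, 6)
  f <- em_fit(x, s, K = 2L, seed = 42L)
  loglik <- function(mu1, mu2, p) {
    sum(log(p * dnorm(x, mu1, s) + (1 - p) * dnorm(x, mu2, s)))
  }
  # coarse grid then local refinement around the best cell
  grid <- expand.grid(mu1 = seq(8, 13, by = 0.25),
                      mu2 = seq(28, 33, by = 0.25),
                      p = seq(0.2, 0.8, by = 0.05))
  ll <- mapply(loglik, grid$mu1, grid$mu2, grid$p)
  b <- grid[which.max(ll), ]
  fine <- expand.grid(mu1 = seq(b$mu1 - 0.3, b$mu1 + 0.3, by = 0.01),
                      mu2 = seq(b$mu2 - 0.3, b$mu2 + 0.3, by = 0.01),
                      p = seq(max(0.05, b$p - 0.1), min(0.95, b$p + 0.1),
                              by = 0.01))
  ll_best <- max(mapply(loglik, fine$mu1, fine$mu2, fine$p))
  expect_gte(f$logL, ll_best - 1e-4)
  expect_lt(abs(f$logL - ll_best), 1e-3)
})

test_that("EM log-likelihood is monotone over iterations", {
  set.seed(6)
  for (rep in 1:10) {
    x <- c(rnorm(6, 20, 1.5), rnorm(6, 60, 2))
    s <- runif(12, 1, 3)
    f <- em_fit(x, s, K = sample(1:4, 1), seed = rep)
    expect_true(all(diff(f$logL_trace) >= -1e-9))
  }
})

test_that("information criteria follow their closed forms", {
  x <- c(10, 11, 30, 31)
  s <- rep(1, 4)
  f <- em_fit(x, s, K = 1L)
  attr(f, "x") <- x; attr(f, "sigma") <- s
  f$logL <- -10  # pin the likelihood to make the arithmetic transparent
  cr <- model_criteria(f, n = 4L)
  expect_equal(unname(cr["AIC"]), 22)
  expect_equal(unname(cr["BIC"]), 20 + log(4))
  expect_equal(unname(cr["AIC3"] - cr["AIC"]), 1)  # p = 2K - 1 = 1

  f2 <- em_fit(x, s, K = 2L, seed = 4L)
  attr(f2, "x") <- x; attr(f2, "sigma") <- s
  cr2 <- model_criteria(f2, n = 4L)
  p <- 3
  expect_equal(unname(cr2["AIC"]), -2 * f2$logL + 2 * p)
  expect_equal(unname(cr2["AIC3"] - cr2["AIC"]), p)
  expect_true(is.na(cr2["AICc"]))  # n - p - 1 = 0
  # AWE from an independently coded classification likelihood
  hard <- max.col(f2$z)
  llc <- sum(dnorm(x, f2$mu[hard], s, log = TRUE) + log(f2$pi[hard]))
  expect_equal(unname(cr2["AWE"]), -2 * llc + 2 * p * (1.5 + log(4)))
})

test_that("model selection takes the modal vote, ties to the smaller K", {
  fake <- function(K, crit) {
    structure(list(K = K, criteria = crit), class = "mixture_fit")
  }
  cnames <- c("AIC", "AICc", "AIC3", "BIC", "AWE")
  # unanimous minimum at K = 3
  fits <- lapply(1:4, function(K) {
    v <- setNames(rep(abs(K - 3) + 1, 5), cnames)
    fake(K, v)
  })
  expect_equal(select_model(fits)$K, 3L)
  # votes 2-2-1 across K = 1, 2, 3 -> tie broken toward K = 1
  crit <- rbind(c(1, 1, 2, 2, 2),    # K1 wins AIC, AICc
                c(2, 2, 1, 1, 3),    # K2 wins AIC3, BIC
                c(3, 3, 3, 3, 1))    # K3 wins AWE
  colnames(crit) <- cnames
  fits2 <- lapply(1:3, function(K) fake(K, crit[K, ]))
  expect_equal(select_model(fits2)$K, 1L)
})

test_that("meta-QTL summaries pool member precision", {
  # single member: CI95 spans 2 * 1.96 * sigma
  x <- 31.29; s <- 1.09
  f <- em_fit(x, s, K = 1L)
  attr(f, "x") <- x; attr(f, "sigma") <- s
  mq <- summarize_metaqtl(f, data.frame(qtl_id = "q1", study_ref = "s1",
                                        trait = "ver", r2 = 0.11, lg = "1"),
                          prefix = "ver")
  expect_equal(mq$peak_cm, 31.29, tolerance = 1e-9)
  expect_equal(mq$ci_end_cm - mq$ci_start_cm, 2 * 1.96 * 1.09,
               tolerance = 1e-9)
  expect_equal(mq$name, "ver_1.1")

  # two equal-sigma members: sigma_meta = sigma / sqrt(2)
  x2 <- c(30, 32); s2 <- c(1.5, 1.5)
  f2 <- em_fit(x2, s2, K = 1L)
  attr(f2, "x") <- x2; attr(f2, "sigma") <- s2
  mq2 <- summarize_metaqtl(f2, data.frame(qtl_id = c("a", "b"),
                                          study_ref = c("s1", "s2"),
                                          trait = "ver", r2 = c(0.1, 0.3),
                                          lg = "2"))
  expect_equal(mq2$ci_end_cm - mq2$ci_start_cm,
               2 * 1.96 * 1.5 / sqrt(2), tolerance = 1e-9)
  expect_equal(mq2$mean_r2, 0.2)
  expect_equal(mq2$n_studies, 2L)
})

test_that("sigma_meta never exceeds the best member and peaks stay inside", {
  set.seed(12)
  for (rep in 1:10) {
    x <- c(rnorm(5, 20, 1), rnorm(5, 70, 2))
    s <- runif(10, 0.8, 3)
    fits <- fit_mixture_models(x, s, K_max = 4L, seed = rep)
    best <- select_model(fits)
    obs <- data.frame(qtl_id = paste0("q", 1:10), study_ref = "s1",
                      trait = "ver", r2 = 0.1, lg = "1")
    mq <- summarize_metaqtl(best, obs)
    hard <- max.col(best$z)
    for (i in seq_len(nrow(mq))) {
      members <- which(hard == order(best$mu)[i])
      span <- (mq$ci_end_cm[i] - mq$ci_start_cm[i]) / (2 * 1.96)
      expect_lte(span, min(s[members]) + 1e-12)
      expect_gte(mq$peak_cm[i], min(x[members]) - 1e-9)
      expect_lte(mq$peak_cm[i], max(x[members]) + 1e-9)
    }
  }
})

test_that("the planted 1 + 3 cluster layout yields four meta-QTLs", {
  cfg <- sim_config(seed = 17L)
  qt <- simulate_qtls(cfg)
  q <- qt$qtls
  q$status <- "projected"
  mq1 <- run_meta_analysis(q, "ver", "1", seed = 17L)
  mq2 <- run_meta_analysis(q, "ver", "2", seed = 17L)
  expect_equal(nrow(mq1), 1L)
  expect_equal(nrow(mq2), 3L)
  expect_equal(mq1$name, "ver_1.1")
  expect_equal(mq2$name, c("ver_2.1", "ver_2.2", "ver_2.3"))
  # peaks recover the planted positions
  expect_lt(max(abs(sort(c(mq1$peak_cm, mq2$peak_cm)) -
                      sort(c(31, 31, 42, 53)))), 1.5)
})

test_that("meta-analysis needs two overlapping same-trait QTLs", {
  q <- rbind(qtl_row("a", peak = 10, ci = c(8, 12)),
             qtl_row("b", peak = 50, ci = c(48, 52), study = "s2"))
  expect_equal(nrow(run_meta_analysis(q, "ver", "1")), 0L)
  q2 <- rbind(qtl_row("a", peak = 10, ci = c(8, 12)),
              qtl_row("b", peak = 11, ci = c(9, 13), study = "s2"))
  mq <- run_meta_analysis(q2, "ver", "1")
  expect_gte(nrow(mq), 1L)
  expect_lte(nrow(mq), 2L)
})

test_that("cross-trait pooling with disjoint other traits equals single-trait", {
  q <- rbind(qtl_row("a", peak = 10, ci = c(8, 12)),
             qtl_row("b", peak = 11, ci = c(9, 13), study = "s2"),
             qtl_row("c", trait = "flowering", peak = 60, ci = c(58, 62)))
  single <- run_meta_analysis(q, "ver", "1", mode = "single-trait",
                              seed = 7L)
  cross <- run_meta_analysis(q, "ver", "1", mode = "cross-trait",
                             prefix = "ver", seed = 7L)
  expect_equal(cross[, names(cross) != "name"],
               single[, names(single) != "name"])
})
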