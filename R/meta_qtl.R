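#' Standard deviation of a QTL peak from its confidence-interval length
#'
#' Under the normal observation model, a central CI at level `level` has
#' length `2 * z * sigma` with `z = qnorm((1 + level) / 2)`, so
#' `sigma = ci_length / (2 * z)`; for the default 95% level this is
#' `ci_length / 3.92` (to the usual 2-decimal z).
#'
#' @param ci_length CI length in cM (> 0).
#' @param level confidence level, default 0.95.
#' @return sigma in cM.
#' @export
sd_from_ci <- function(ci_length, level = 0.95) {
  if (any(is.na(ci_length)) || any(ci_length <= 0)) {
    stop("ci_length must be > 0")
  }
  ci_length / (2 * stats::qnorm((1 + level) / 2))
}

# evaluate with a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

em_once <- function(x, sigma, mu0, max_iter, tol) {
  n <- length(x)
  K <- length(mu0)
  mu <- mu0
  pi_k <- rep(1 / K, K)
  prec <- 1 / sigma^2
  ll_old <- -Inf
  ll_trace <- numeric(0)
  z <- NULL
  for (it in seq_len(max_iter)) {
    # E-step: z_ik ~ pi_k * phi(x_i; mu_k, sigma_i^2), stabilized in log space
    lphi <- vapply(seq_len(K), function(k) {
      stats::dnorm(x, mu[k], sigma, log = TRUE) + log(pi_k[k])
    }, numeric(n))
    lphi <- matrix(lphi, nrow = n)
    m <- apply(lphi, 1L, max)
    w <- exp(lphi - m)
    rs <- rowSums(w)
    z <- w / rs
    ll <- sum(m + log(rs))
    ll_trace <- c(ll_trace, ll)
    # M-step: precision-weighted means, mean responsibilities
    mu <- colSums(z * x * prec) / colSums(z * prec)
    pi_k <- colMeans(z)
    if (ll - ll_old < tol && it > 1L) break
    ll_old <- ll
  }
  list(mu = mu, pi = pi_k, z = z, logL = ll_trace[length(ll_trace)],
       logL_trace = ll_trace)
}

#' Fit a K-component Gaussian mixture with known per-observation variances
#'
#' The observation model behind QTL meta-analysis: each projected QTL peak
#' `x_i` is normal around one of `K` true locations `mu_k` with its own known
#' standard deviation `sigma_i` (derived from the QTL's CI). EM maximizes
#' `logL = sum_i log sum_k pi_k * phi(x_i; mu_k, sigma_i^2)`; the M-step mean
#' is the responsibility- and precision-weighted average. The best of
#' `restarts` seeded initializations (one k-means style, the rest random
#' distinct observations) is returned, with means sorted ascending.
#'
#' @param x numeric vector of peak positions (cM).
#' @param sigma per-observation standard deviations (cM, > 0).
#' @param K number of components (`1 <= K <= length(x)`).
#' @param restarts number of initializations (default 10).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter iteration cap per start (default 500).
#' @param seed integer seed making the fit deterministic.
#' @return list of class `mixture_fit`: `K`, `mu`, `pi`, `z` (n x K posterior
#'   matrix), `logL`, `logL_trace`, `degenerate` (TRUE when every start ended
#'   with an empty hard-assigned cluster).
#' @export
em_fit <- function(x, sigma, K, restarts = 10L, tol = 1e-8,
                   max_iter = 500L, seed = 1L) {
  n <- length(x)
  stopifnot(length(sigma) == n, all(sigma > 0))
  if (K < 1L || K > n) stop("K must be in 1..n (n = ", n, ")")
  if (K == 1L) {
    fits <- list(em_once(x, sigma, stats::weighted.mean(x, 1 / sigma^2),
                         max_iter, tol))
  } else {
    fits <- with_seed(seed, {
      inits <- vector("list", restarts)
      km <- tryCatch(
        stats::kmeans(x, centers = K, nstart = 5L)$centers[, 1L],
        error = function(e) NULL
      )
      inits[[1L]] <- if (is.null(km)) sort(sample(x, K)) else sort(km)
      for (r in seq_len(restarts - 1L)) {
        inits[[r + 1L]] <- sort(sample(unique(x), min(K, length(unique(x)))))
      }
      lapply(inits, function(mu0) {
        if (length(mu0) < K) mu0 <- c(mu0, mu0[1L] + seq_len(K - length(mu0)))
        em_once(x, sigma, mu0, max_iter, tol)
      })
    })
  }
  ok <- vapply(fits, function(f) {
    hard <- max.col(f$z, ties.method = "first")
    length(unique(hard)) == K
  }, logical(1L))
  pool <- if (any(ok)) fits[ok] else fits
  best <- pool[[which.max(vapply(pool, `[[`, numeric(1L), "logL"))]]
  o <- order(best$mu)
  structure(
    list(K = K, mu = best$mu[o], pi = best$pi[o],
         z = best$z[, o, drop = FALSE], logL = best$logL,
         logL_trace = best$logL_trace, degenerate = !any(ok)),
    class = "mixture_fit"
  )
}

#' Information criteria for a mixture fit
#'
#' With `p = 2K - 1` free parameters (K means and K - 1 independent weights;
#' variances are known, not estimated):
#' `AIC = -2 logL + 2p`; `AICc = AIC + 2p(p+1)/(n-p-1)` (undefined when
#' `n - p - 1 <= 0`); `AIC3 = -2 logL + 3p`; `BIC = -2 logL + p ln(n)`;
#' `AWE = -2 logL_c + 2p(3/2 + ln(n))` where `logL_c` is the classification
#' log-likelihood under hard assignments `argmax_k z_ik`.
#'
#' @param fit a `mixture_fit`.
#' @param n number of observations.
#' @return named numeric vector `AIC`, `AICc`, `AIC3`, `BIC`, `AWE`.
#' @export
model_criteria <- function(fit, n) {
  K <- fit$K
  p <- 2 * K - 1
  aic <- -2 * fit$logL + 2 * p
  aicc <- if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else NA_real_
  aic3 <- -2 * fit$logL + 3 * p
  bic <- -2 * fit$logL + p * log(n)
  hard <- max.col(fit$z, ties.method = "first")
  x <- attr(fit, "x"); sigma <- attr(fit, "sigma")
  if (is.null(x) || is.null(sigma)) {
    stop("fit lacks the x/sigma attributes needed for AWE; ",
         "use fit_mixture_models() or attach them")
  }
  ll_c <- sum(stats::dnorm(x, fit$mu[hard], sigma, log = TRUE) +
                log(fit$pi[hard]))
  awe <- -2 * ll_c + 2 * p * (3 / 2 + log(n))
  c(AIC = aic, AICc = aicc, AIC3 = aic3, BIC = bic, AWE = awe)
}

#' Fit mixtures for a range of K and compute the selection criteria
#'
#' @param x peak positions (cM).
#' @param sigma per-observation standard deviations.
#' @param K_max largest cluster count scanned; capped at
#'   `min(length(x), K_max)`.
#' @param restarts,tol,seed passed to [em_fit()].
#' @return list of `mixture_fit`s (with `criteria` attached to each) for
#'   `K = 1..K_max`, degenerate fits dropped.
#' @export
fit_mixture_models <- function(x, sigma, K_max = 10L, restarts = 10L,
                               tol = 1e-8, seed = 1L) {
  K_max <- min(length(x), K_max)
  fits <- vector("list", K_max)
  for (K in seq_len(K_max)) {
    f <- em_fit(x, sigma, K, restarts = restarts, tol = tol,
                seed = seed + K)
    attr(f, "x") <- x
    attr(f, "sigma") <- sigma
    f$criteria <- model_criteria(f, length(x))
    fits[[K]] <- f
  }
  Filter(function(f) !f$degenerate, fits)
}

#' Select the number of meta-QTLs by majority vote of the criteria
#'
#' Each defined criterion votes for the K minimizing it; the selected `K*` is
#' the modal vote, ties going to the smallest K among the tied values (then
#' smallest total AIC, which the distinct-K rule already implies).
#'
#' @param fits list of `mixture_fit`s with `criteria`, e.g. from
#'   [fit_mixture_models()].
#' @return The winning `mixture_fit`, with attribute `"votes"` (named integer
#'   vector of votes per K).
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1L)
  Ks <- vapply(fits, `[[`, integer(1L), "K")
  crit <- do.call(rbind, lapply(fits, `[[`, "criteria"))
  votes <- integer(0)
  for (cn in colnames(crit)) {
    v <- crit[, cn]
    if (anyNA(v)) next  # AICc undefined somewhere in the scan: no vote
    votes <- c(votes, Ks[which.min(v)])
  }
  if (!length(votes)) {  # every criterion undefined: fall back to AIC alone
    votes <- Ks[which.min(crit[, "AIC"])]
  }
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  K_star <- min(winners)
  out <- fits[[which(Ks == K_star)]]
  vt <- stats::setNames(integer(length(Ks)), Ks)
  for (v in votes) vt[as.character(v)] <- vt[as.character(v)] + 1L
  attr(out, "votes") <- vt
  out
}

#' Summarize a selected mixture fit into meta-QTLs
#'
#' Members are assigned by `argmax_k z_ik`. The meta-QTL CI95 is
#' `mu_k +/- 1.96 * sigma_meta` with `sigma_meta^2 = 1 / sum(1 / sigma_i^2)`
#' over members (precisions accumulate); `mean_r2` is the unweighted member
#' mean.
#'
#' @param fit a selected `mixture_fit` (needs `x`/`sigma` attributes).
#' @param obs data.frame with one row per observation used in the fit, at
#'   least `qtl_id`, `study_ref`, `trait`, `r2`.
#' @param lg linkage-group label.
#' @param prefix naming prefix; meta-QTLs are named
#'   `<prefix>_<lg>.<rank>` by ascending peak.
#' @return data.frame with one row per (non-empty) cluster: `name`, `lg`,
#'   `peak_cm`, `mean_r2`, `ci_start_cm`, `ci_end_cm`, `n_qtls`, `n_studies`,
#'   `members`, `traits`.
#' @export
summarize_metaqtl <- function(fit, obs, lg = obs$lg[1L], prefix = "mqtl") {
  x <- attr(fit, "x"); sigma <- attr(fit, "sigma")
  stopifnot(!is.null(x), !is.null(sigma), nrow(obs) == length(x))
  hard <- max.col(fit$z, ties.method = "first")
  rows <- list()
  for (k in seq_len(fit$K)) {
    idx <- which(hard == k)
    if (!length(idx)) {
      warning("cluster ", k, " has no members; dropped")
      next
    }
    s_meta <- sqrt(1 / sum(1 / sigma[idx]^2))
    # heavy responsibility overlap can pull a soft mean just outside its
    # hard members' span; the reported peak is clamped onto it
    peak <- min(max(fit$mu[k], min(x[idx])), max(x[idx]))
    rows[[length(rows) + 1L]] <- data.frame(
      name = NA_character_,
      lg = as.character(lg),
      peak_cm = peak,
      mean_r2 = mean(obs$r2[idx], na.rm = TRUE),
      ci_start_cm = peak - 1.96 * s_meta,
      ci_end_cm = peak + 1.96 * s_meta,
      n_qtls = length(idx),
      n_studies = length(unique(obs$study_ref[idx])),
      members = paste(obs$qtl_id[idx], collapse = ","),
      traits = paste(sort(unique(obs$trait[idx])), collapse = ",")
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$peak_cm), , drop = FALSE]
  out$name <- paste0(prefix, "_", as.character(lg), ".",
                     seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Run the meta-QTL analysis for one trait on one linkage group
#'
#' Projected QTLs of the focal trait on the LG are pruned of same-study
#' redundancy ([prune_redundant()]), then restricted to those belonging to a
#' CI-overlap cluster of at least two QTLs. In `"cross-trait"` mode the focal
#' set is pooled with QTLs of the other listed traits whose CIs overlap a
#' focal QTL's CI. Mixtures for `K = 1..K_max` are fitted, the model selected
#' by criteria vote, and clusters summarized into named meta-QTLs.
#'
#' @param projected projected-QTL data.frame (status `"projected"` rows are
#'   used; others ignored).
#' @param trait focal trait.
#' @param lg linkage-group label.
#' @param mode `"single-trait"` or `"cross-trait"`.
#' @param other_traits traits poolable in cross-trait mode (default: all
#'   other traits present).
#' @param prefix naming prefix (default `trait` in single mode,
#'   `paste0(trait, "/ph")` in cross mode).
#' @param K_max,restarts,tol,seed passed to [fit_mixture_models()].
#' @param ci_level level at which member CIs were reported (for
#'   [sd_from_ci()]).
#' @return data.frame of meta-QTLs (possibly 0 rows when fewer than two
#'   overlapping QTLs exist), with attribute `"fit"` holding the selected
#'   `mixture_fit`.
#' @export
run_meta_analysis <- function(projected, trait, lg,
                              mode = c("single-trait", "cross-trait"),
                              other_traits = NULL, prefix = NULL,
                              K_max = 10L, restarts = 10L, tol = 1e-8,
                              seed = 1L, ci_level = 0.95) {
  mode <- match.arg(mode)
  if (is.null(prefix)) {
    prefix <- if (mode == "single-trait") trait else paste0(trait, "/ph")
  }
  lg <- as.character(lg)
  pr <- projected[projected$status == "projected" &
                    projected$lg == lg &
                    !is.na(projected$ci_start_cm), , drop = FALSE]
  focal <- prune_redundant(pr[pr$trait == trait, , drop = FALSE])
  # keep only QTLs that overlap at least one other focal QTL
  focal <- overlapping_subset(focal)
  if (nrow(focal) < 2L) {
    out <- empty_metaqtl_frame()
    attr(out, "fit") <- NULL
    return(out)
  }
  obs <- focal
  if (mode == "cross-trait") {
    if (is.null(other_traits)) {
      other_traits <- setdiff(unique(pr$trait), trait)
    }
    pool <- pr[pr$trait %in% other_traits, , drop = FALSE]
    pool <- prune_redundant(pool)
    hit <- vapply(seq_len(nrow(pool)), function(i) {
      any(pool$ci_start_cm[i] <= focal$ci_end_cm &
            pool$ci_end_cm[i] >= focal$ci_start_cm)
    }, logical(1L))
    obs <- rbind(focal, pool[hit, , drop = FALSE])
  }
  sigma <- sd_from_ci(obs$ci_end_cm - obs$ci_start_cm, level = ci_level)
  fits <- fit_mixture_models(obs$peak_cm, sigma, K_max = K_max,
                             restarts = restarts, tol = tol, seed = seed)
  best <- select_model(fits)
  out <- summarize_metaqtl(best, obs, lg = lg, prefix = prefix)
  attr(out, "fit") <- best
  out
}

empty_metaqtl_frame <- function() {
  data.frame(name = character(0), lg = character(0), peak_cm = numeric(0),
             mean_r2 = numeric(0), ci_start_cm = numeric(0),
             ci_end_cm = numeric(0), n_qtls = integer(0),
             n_studies = integer(0), members = character(0),
             traits = character(0))
}

# QTLs belonging to a CI-overlap cluster of size >= 2
overlapping_subset <- function(qtls) {
  if (nrow(qtls) < 2L) return(qtls[0L, , drop = FALSE])
  cl <- interval_clusters(qtls$ci_start_cm, qtls$ci_end_cm)
  sizes <- table(cl)
  qtls[cl %in% as.integer(names(sizes)[sizes >= 2L]), , drop = FALSE]
}
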