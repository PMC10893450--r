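# Gaussian mixture modelling of Ks-age distributions with BIC component
# selection. The EM is weighted: each Ks entry contributes its redundancy
# weight to responsibilities and to the effective sample size used by BIC.

dnorm_safe <- function(x, mean, sd) stats::dnorm(x, mean, sd) + 1e-300

# k-means++ style seeding on the current RNG stream.
kmeanspp_centers <- function(x, w, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1L, prob = w)]
  if (k > 1) for (j in 2:k) {
    d2 <- vapply(x, function(xi) min((xi - centers[1:(j - 1)])^2), numeric(1))
    if (all(d2 == 0)) centers[j] <- x[sample.int(length(x), 1L, prob = w)]
    else centers[j] <- x[sample.int(length(x), 1L, prob = w * d2)]
  }
  centers
}

em_fit <- function(x, w, k, tol, max_iter, var_floor, trace = FALSE) {
  ll_trace <- if (trace) numeric(0) else NULL
  n_eff <- sum(w)
  mu <- kmeanspp_centers(x, w, k)
  sigma <- rep(max(sqrt(var_floor), stats::sd(x) / max(k, 1)), k)
  if (is.na(sigma[1]) || sigma[1] == 0) sigma <- rep(sqrt(var_floor), k)
  pi_k <- rep(1 / k, k)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      pi_k[j] * dnorm_safe(x, mu[j], sigma[j]), numeric(length(x)))
    dens <- matrix(dens, nrow = length(x))
    rowsum_d <- rowSums(dens)
    ll <- sum(w * log(rowsum_d))
    if (trace) ll_trace <- c(ll_trace, ll)
    resp <- dens / rowsum_d
    wr <- resp * w
    nk <- colSums(wr)
    pi_k <- nk / n_eff
    mu <- colSums(wr * x) / nk
    sigma <- sqrt(pmax(var_floor,
                       colSums(wr * (outer(x, mu, "-"))^2) / nk))
    if (is.finite(ll) && ll - ll_old < tol && iter > 1L) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  o <- order(mu)
  list(weights = pi_k[o], means = mu[o], sds = sigma[o],
       log_likelihood = ll_old, converged = converged, n_iter = iter,
       ll_trace = ll_trace)
}

#' Fit Gaussian mixtures of 1..k_max components to a Ks distribution
#'
#' Weighted EM on the raw Ks values (use `log_transform = TRUE` to fit on
#' log Ks); per component count the best of `n_restarts` k-means++-seeded
#' runs by log-likelihood is kept. BIC is computed as
#' `-2 logL + p log(n_eff)` with `p = 3k - 1` free parameters and `n_eff`
#' the summed redundancy weights, and is minimised by [select_model()].
#'
#' @param dist A [build_ks_distribution()] result, or a numeric vector of
#'   Ks values (unit weights).
#' @param k_max Largest component count to try.
#' @param n_restarts Restarts per component count.
#' @param seed Integer seed; fits are reproducible.
#' @param tol EM log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap (non-convergence is flagged, not an
#'   error).
#' @param var_floor Variance floor preventing singular components.
#' @param log_transform Fit on log(Ks) instead of raw Ks.
#' @return List of `mixture_model` objects, one per k (skipped k are absent,
#'   with a warning).
#' @export
fit_gmm <- function(dist, k_max = 4L, n_restarts = 5L, seed = 1L,
                    tol = 1e-8, max_iter = 500L, var_floor = 1e-4,
                    log_transform = FALSE) {
  if (inherits(dist, "ks_distribution")) {
    x <- dist$entries$Ks
    w <- dist$entries$weight
  } else {
    x <- as.numeric(dist)
    w <- rep(1, length(x))
  }
  if (length(x) < 10L) stop("need at least 10 observations to fit a mixture")
  if (log_transform) x <- log(x)
  n_eff <- sum(w)
  models <- list()
  with_seed(seed, {
    for (k in seq_len(k_max)) {
      p <- 3L * k - 1L
      if (length(x) <= p) {
        warning("k = ", k, " skipped: ", length(x),
                " observations for ", p, " parameters")
        next
      }
      best <- NULL
      for (r in seq_len(n_restarts)) {
        fit <- em_fit(x, w, k, tol, max_iter, var_floor)
        if (is.null(best) || fit$log_likelihood > best$log_likelihood)
          best <- fit
      }
      models[[length(models) + 1L]] <- structure(list(
        k = k,
        components = data.frame(weight = best$weights, mean = best$means,
                                sd = best$sds),
        n_obs = n_eff,
        log_likelihood = best$log_likelihood,
        bic = -2 * best$log_likelihood + p * log(n_eff),
        converged = best$converged,
        n_iter = best$n_iter,
        log_transform = log_transform
      ), class = "mixture_model")
    }
  })
  if (!length(models)) stop("no component count could be fitted")
  models
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model: k = %d, logL = %.3f, BIC = %.3f%s\n",
              x$k, x$log_likelihood, x$bic,
              if (x$converged) "" else " (not converged)"))
  print(format(x$components, digits = 4))
  invisible(x)
}

#' Select the BIC-best mixture model
#'
#' Minimum-BIC model; ties break toward fewer components.
#'
#' @param models List of `mixture_model` objects from [fit_gmm()].
#' @export
select_model <- function(models) {
  if (!length(models)) stop("empty model list")
  bic <- vapply(models, `[[`, numeric(1), "bic")
  k <- vapply(models, `[[`, numeric(1), "k")
  cand <- which(bic <= min(bic) + 1e-9)
  models[[cand[which.min(k[cand])]]]
}

#' Extract candidate WGD peaks from a fitted mixture
#'
#' Components with mixing weight at or above `min_weight` are reported as
#' peaks, sorted by mean Ks.
#'
#' @param model A `mixture_model`.
#' @param min_weight Minimum component weight to call a peak.
#' @param source Label recorded with each peak.
#' @return Data frame `mean_ks`, `sd`, `weight`, `source`.
#' @export
extract_peaks <- function(model, min_weight = 0.1, source = "") {
  comp <- model$components
  comp <- comp[comp$weight >= min_weight, , drop = FALSE]
  if (!nrow(comp))
    return(data.frame(mean_ks = numeric(0), sd = numeric(0),
                      weight = numeric(0), source = character(0)))
  mean_ks <- if (isTRUE(model$log_transform)) exp(comp$mean) else comp$mean
  out <- data.frame(mean_ks = mean_ks, sd = comp$sd, weight = comp$weight,
                    source = source, stringsAsFactors = FALSE)
  out[order(out$mean_ks), , drop = FALSE]
}

#' Place a WGD peak relative to an ortholog-divergence peak
#'
#' The divergence peak is the dominant (highest-weight) component of a
#' BIC-selected fit to the interspecific distribution. A WGD peak at lower
#' Ks than the divergence peak is younger than the speciation
#' (`after_divergence`); at higher Ks it predates it (`before_divergence`);
#' within `tolerance` the two are `coincident`.
#'
#' @param peak One row of [extract_peaks()] output (or a list with
#'   `mean_ks`).
#' @param divergence_dist Interspecific `ks_distribution` (or numeric Ks).
#' @param tolerance Ks half-width treated as coincident.
#' @param k_max,seed Passed to [fit_gmm()] for the divergence fit.
#' @return A list with `peak`, `divergence_peak_ks` and `relation`.
#' @export
place_peak <- function(peak, divergence_dist, tolerance = 0.1,
                       k_max = 3L, seed = 1L) {
  n <- if (inherits(divergence_dist, "ks_distribution"))
    nrow(divergence_dist$entries) else length(divergence_dist)
  if (n == 0L) stop("empty divergence distribution")
  fit <- select_model(fit_gmm(divergence_dist, k_max = k_max, seed = seed))
  dom <- which.max(fit$components$weight)
  div_ks <- fit$components$mean[dom]
  if (isTRUE(fit$log_transform)) div_ks <- exp(div_ks)
  mean_ks <- if (is.data.frame(peak)) peak$mean_ks[1] else peak$mean_ks
  relation <- if (mean_ks < div_ks - tolerance) "after_divergence"
  else if (mean_ks > div_ks + tolerance) "before_divergence"
  else "coincident"
  list(peak = peak, divergence_peak_ks = div_ks, relation = relation,
       tolerance = tolerance)
}
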