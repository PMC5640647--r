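#' Detect PHA subpopulations by Gaussian-mixture fitting
#'
#' Pyr-546 fluorescence histograms of PHA-storing cultures can show one or
#' two discrete populations (low and high granule content). This fits 1- and
#' 2-component Gaussian mixtures to the *log-displayed* intensities by
#' expectation-maximisation (10 seeded random restarts, log-likelihood
#' tolerance 1e-6) and selects the component count by BIC. Components are
#' returned ordered by mean.
#'
#' @param events An [event_table()] with at least 200 events.
#' @param channel Channel to fit (typically `FL1_A` for Pyr-546).
#' @param k_max Maximum number of components (1 or 2).
#' @param k Force a component count instead of BIC selection (optional).
#' @param n_restarts Number of EM restarts for the 2-component model.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param seed Integer seed for the restarts.
#' @return An object of class `mixture_fit`: `k`, `weights`, `means`, `sds`
#'   (log10 units), `bic` (per k), `loglik`, `converged`, `n`, `channel`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' ev <- generate_scenario(load_scenario("magnetic_pha", 5000, seed = 3))
#' fit_subpopulations(ev, "FL1_A")
fit_subpopulations <- function(events, channel = "FL1_A", k_max = 2L,
                               k = NULL, n_restarts = 10L, tol = 1e-6,
                               seed = 1L) {
  check_channel(events, channel)
  if (nrow(events) < 200L) {
    stop_magcyto(sprintf("need >= 200 events for a mixture fit (got %d).",
                         nrow(events)), "magcyto_sample_size_error")
  }
  if (!k_max %in% 1:2) {
    stop_magcyto("`k_max` must be 1 or 2.", "magcyto_param_error")
  }
  x <- log_display(events[[channel]])
  seed <- seed_check(seed)
  fit1 <- gmm_fit_k1(x)
  fit2 <- if (k_max >= 2L) {
    gmm_fit_k2(x, n_restarts = n_restarts, tol = tol, seed = seed)
  } else NULL
  fits <- list(`1` = fit1, `2` = fit2)
  bic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic,
                numeric(1))
  chosen <- if (!is.null(k)) {
    if (!k %in% 1:2 || k > k_max) {
      stop_magcyto("`k` must be 1 or 2 and <= k_max.", "magcyto_param_error")
    }
    as.integer(k)
  } else {
    as.integer(names(which.min(bic)))
  }
  f <- fits[[as.character(chosen)]]
  if (!isTRUE(f$converged)) {
    stop_magcyto(sprintf(
      "mixture EM did not converge for k = %d after %d restarts (best loglik %.4f).",
      chosen, n_restarts, f$loglik), "magcyto_fit_error")
  }
  structure(
    list(k = chosen, weights = f$weights, means = f$means, sds = f$sds,
         bic = bic, loglik = f$loglik, converged = f$converged,
         n = length(x), channel = channel),
    class = "mixture_fit"
  )
}

## single Gaussian: closed-form MLE
gmm_fit_k1 <- function(x) {
  n <- length(x)
  mu <- mean(x)
  s <- max(sqrt(mean((x - mu)^2)), 1e-4)
  ll <- sum(dnorm(x, mu, s, log = TRUE))
  list(weights = 1, means = mu, sds = s, loglik = ll,
       bic = -2 * ll + 2 * log(n), converged = TRUE)
}

## two-component univariate Gaussian mixture, EM with seeded multi-start
gmm_fit_k2 <- function(x, n_restarts = 10L, tol = 1e-6, max_iter = 500L,
                       seed = 1L) {
  n <- length(x)
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      ## initialise means from random quantile pairs, sds from overall spread
      qs <- sort(stats::runif(2))
      mu <- as.numeric(quantile(x, probs = c(qs[1] * 0.5, 0.5 + qs[2] * 0.5)))
      if (diff(mu) < 1e-8) mu <- mu + c(-1e-3, 1e-3)
      s <- rep(max(stats::sd(x) / 2, 1e-3), 2)
      w <- c(0.5, 0.5)
      ll_old <- -Inf
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        d1 <- w[1] * dnorm(x, mu[1], s[1])
        d2 <- w[2] * dnorm(x, mu[2], s[2])
        tot <- d1 + d2
        tot[tot == 0] <- .Machine$double.xmin
        g <- d1 / tot
        ll <- sum(log(tot))
        if (is.finite(ll) && abs(ll - ll_old) < tol) {
          converged <- TRUE
          break
        }
        ll_old <- ll
        n1 <- sum(g); n2 <- n - n1
        if (n1 < 1e-8 || n2 < 1e-8) break  # degenerate responsibility split
        w <- c(n1, n2) / n
        mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
        s <- c(sqrt(sum(g * (x - mu[1])^2) / n1),
               sqrt(sum((1 - g) * (x - mu[2])^2) / n2))
        s <- pmax(s, 1e-4)
      }
      better <- is.null(best) ||
        (converged && (!best$converged || ll > best$loglik)) ||
        (!converged && !best$converged && ll > best$loglik)
      if (better) {
        ord <- order(mu)
        best <- list(weights = w[ord], means = mu[ord], sds = s[ord],
                     loglik = ll, converged = converged)
      }
    }
  })
  best$bic <- -2 * best$loglik + 5 * log(n)
  best
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %s, k = %d (BIC %s), n = %d\n", x$channel, x$k,
              paste(sprintf("k%s: %.1f", names(x$bic), x$bic), collapse = ", "),
              x$n))
  for (i in seq_len(x$k)) {
    cat(sprintf("  component %d: weight %.3f, mean %.3f log10, sd %.3f\n",
                i, x$weights[[i]], x$means[[i]], x$sds[[i]]))
  }
  invisible(x)
}
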