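# Inter-residue distance series and their decomposition into Gaussian
# subpopulations: a 1-D Gaussian mixture fitted by EM with k-means++-style
# seeding, with BIC model selection across component counts. Distance
# populations of paired residues across a trajectory ensemble resolve
# coexisting structural states (e.g. compact/bound vs separated/dynamic
# headpiece arrangements).

#' C-alpha to C-alpha distance series
#'
#' @param traj a `trj_trajectory`.
#' @param res_a,res_b residue references `c(chain, res_seq)`; must be distinct
#'   residues, each carrying a CA atom.
#' @return A [time_series()] of distances in Angstrom.
#' @export
ca_distance_series <- function(traj, res_a, res_b) {
  stopifnot(inherits(traj, "trj_trajectory"))
  if (res_a[1] == res_b[1] && as.integer(res_a[2]) == as.integer(res_b[2])) {
    stop("res_a and res_b must be distinct residues")
  }
  topo <- traj$topology
  find_ca <- function(ref) {
    i <- which(topo$atoms$chain == ref[1] & topo$atoms$res_seq == as.integer(ref[2]) &
                 topo$atoms$atom_name == "CA")
    if (length(i) != 1) {
      stop(sprintf("residue %s/%s has no CA atom", ref[1], ref[2]))
    }
    i
  }
  ia <- find_ca(res_a)
  ib <- find_ca(res_b)
  d <- sqrt(rowSums((traj$coords[, ia, , drop = TRUE] -
                       traj$coords[, ib, , drop = TRUE])^2))
  time_series(frame_times(traj), d,
              label = sprintf("CA dist %s%s-%s%s", res_a[1], res_a[2], res_b[1], res_b[2]),
              units = "A")
}

# k-means++-style seeding: first center uniform, subsequent centers sampled
# with probability proportional to squared distance to the nearest chosen
# center.
kmeanspp_centers <- function(x, K) {
  centers <- numeric(K)
  centers[1] <- x[sample.int(length(x), 1)]
  if (K > 1) {
    d2 <- (x - centers[1])^2
    for (k in 2:K) {
      tot <- sum(d2)
      centers[k] <- if (tot <= 0) x[sample.int(length(x), 1)] else
        x[sample.int(length(x), 1, prob = d2 / tot)]
      d2 <- pmin(d2, (x - centers[k])^2)
    }
  }
  centers
}

# Seeded initialization in R (so the RNG contract lives with the R API), EM
# iterations in compiled code (src/em_gmm.cpp).
em_gmm_once <- function(x, K, max_iter, tol, sigma_floor) {
  n <- length(x)
  centers <- kmeanspp_centers(x, K)
  assign <- max.col(-abs(outer(x, centers, "-")))
  mu <- vapply(seq_len(K), function(k) {
    xs <- x[assign == k]
    if (length(xs) == 0) centers[k] else mean(xs)
  }, numeric(1))
  sdv <- vapply(seq_len(K), function(k) {
    xs <- x[assign == k]
    if (length(xs) < 2) sigma_floor else max(stats::sd(xs), sigma_floor)
  }, numeric(1))
  w <- pmax(tabulate(assign, K) / n, 1e-6)
  w <- w / sum(w)
  em_gmm_cpp(x, w, mu, sdv, max_iter, tol, sigma_floor)
}

#' Fit a 1-D Gaussian mixture by EM
#'
#' Expectation-maximization with k-means++-style seeded initialization;
#' convergence when the log-likelihood changes by less than `tol` (default
#' 1e-8) or after `max_iter` (default 500) iterations. Component standard
#' deviations are floored at `sigma_floor` (default 0.05 A). Model score is
#' `BIC = -2 LL + (3K - 1) ln(n)` (lower is better). Components are reported
#' sorted by ascending mean.
#'
#' Non-convergence is flagged (`converged = FALSE`), not raised; too small a
#' sample (`n < 10 K`) is an error.
#'
#' @param x numeric sample (e.g. a distance series, burn-in removed).
#' @param K number of components.
#' @param seed integer seed for the initialization.
#' @param n_restarts independent seeded restarts; the best log-likelihood fit
#'   is returned (default 1).
#' @param max_iter,tol,sigma_floor EM controls, see above.
#' @return An object of class `mixture_fit`: `K`, `weights`, `means`, `sds`,
#'   `log_likelihood`, `bic`, `converged`, `n_points`; the per-iteration
#'   log-likelihood trace of the winning restart is attached as attribute
#'   `"ll_trace"`.
#' @export
fit_gmm <- function(x, K, seed = 1, n_restarts = 1, max_iter = 500,
                    tol = 1e-8, sigma_floor = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(K >= 1)
  if (n < 10 * K) {
    stop(sprintf("sample too small: %d points for K = %d (need >= %d)", n, K, 10 * K))
  }
  if (stats::sd(x) == 0) {
    warning("degenerate sample: all points identical; variances hit the floor")
    ord <- seq_len(K)
    fit <- structure(list(K = K, weights = rep(1 / K, K), means = rep(x[1], K),
                          sds = rep(sigma_floor, K),
                          log_likelihood = sum(stats::dnorm(x, x[1], sigma_floor, log = TRUE)),
                          bic = NA_real_, converged = TRUE, n_points = n, seed = seed),
                     class = "mixture_fit")
    fit$bic <- -2 * fit$log_likelihood + (3 * K - 1) * log(n)
    return(fit)
  }
  # multiple restarts use the standard short-run strategy: each seeded start
  # runs a capped number of iterations, and only the best is polished to full
  # convergence (EM's log-likelihood is monotone, so the winner of the short
  # phase can only improve).
  short_iter <- if (n_restarts > 1) min(100L, max_iter) else max_iter
  best <- NULL
  for (r in seq_len(n_restarts)) {
    res <- with_seed(substream_seed(seed, paste0("gmm-restart-", r)),
                     em_gmm_once(x, K, short_iter, tol, sigma_floor))
    if (is.null(best) || res$ll > best$ll) best <- res
  }
  if (n_restarts > 1 && !best$converged) {
    polished <- em_gmm_cpp(x, best$w, best$mu, best$sd, max_iter, tol, sigma_floor)
    polished$ll_trace <- c(best$ll_trace, polished$ll_trace)
    best <- polished
  }
  ord <- order(best$mu)
  out <- structure(list(K = K, weights = best$w[ord] / sum(best$w),
                        means = best$mu[ord], sds = best$sd[ord],
                        log_likelihood = best$ll,
                        bic = -2 * best$ll + (3 * K - 1) * log(n),
                        converged = best$converged, n_points = n, seed = seed),
                   class = "mixture_fit")
  attr(out, "ll_trace") <- best$ll_trace
  attr(out, "responsibilities") <- best$resp[, ord, drop = FALSE]
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> K = %d, n = %d, BIC = %.1f%s\n", x$K, x$n_points,
              x$bic, if (x$converged) "" else " (NOT converged)"))
  for (k in seq_len(x$K)) {
    cat(sprintf("  pi = %.3f  mu = %7.3f A  sd = %6.3f A\n",
                x$weights[k], x$means[k], x$sds[k]))
  }
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits `K = 1 .. k_max` (each with `n_restarts` seeded restarts) and returns
#' the minimum-BIC fit; ties break toward smaller K. `k_max` is capped at
#' `floor(n / 10)` to respect the per-fit sample-size precondition (a message
#' notes the cap).
#'
#' @param x numeric sample.
#' @param k_max largest component count to consider (>= 1).
#' @param seed integer seed.
#' @param n_restarts restarts per K (default 5).
#' @param ... further arguments for [fit_gmm()].
#' @return The winning `mixture_fit`, with the full BIC table attached as
#'   attribute `"bic_table"`.
#' @export
select_k <- function(x, k_max, seed = 1, n_restarts = 5, ...) {
  stopifnot(k_max >= 1)
  cap <- floor(length(x) / 10)
  if (cap < 1) stop("sample too small to fit any mixture (need >= 10 points)")
  if (k_max > cap) {
    message(sprintf("select_k: k_max reduced from %d to %d (n = %d, need >= 10 points per component)",
                    k_max, cap, length(x)))
    k_max <- cap
  }
  fits <- lapply(seq_len(k_max), function(K)
    fit_gmm(x, K, seed = substream_seed(seed, paste0("selectK-", K)),
            n_restarts = n_restarts, ...))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  best <- which.min(bic)  # first minimum => smaller K wins ties
  out <- fits[[best]]
  attr(out, "bic_table") <- data.frame(K = seq_len(k_max), bic = bic,
                                       converged = vapply(fits, function(f) f$converged, logical(1)))
  out
}
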