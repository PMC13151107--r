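# Expression gate: expressed / not-expressed calls per gene from a count
# matrix, via a 5-component univariate Gaussian mixture whose components are
# split into low/high groups by k-means on their (weight, mean, sd)
# parameters; the smallest maximum-a-posteriori boundary between the groups
# is the expression cutoff.

#' Read an expression count table
#'
#' Tab-separated file with gene identifiers in the first column and raw
#' counts in subsequent columns. When several count columns exist, `sample`
#' selects one by column name; by default the first count column is used.
#'
#' @param path Path to the table.
#' @param sample Optional column name.
#' @return Named numeric vector of raw counts.
#' @export
read_expression <- function(path, sample = NULL) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE)
  if (ncol(tab) < 2L) stop("expression table needs >= 2 columns", call. = FALSE)
  col <- if (is.null(sample)) 2L else {
    if (!sample %in% names(tab))
      stop("expression column '", sample, "' not found; available: ",
           paste(setdiff(names(tab), names(tab)[1]), collapse = ", "),
           call. = FALSE)
    sample
  }
  stats::setNames(as.numeric(tab[[col]]), as.character(tab[[1L]]))
}

.dmix <- function(x, w, mu, sd) {
  rowSums(vapply(seq_along(w),
                 function(k) w[k] * stats::dnorm(x, mu[k], sd[k]),
                 numeric(length(x))))
}

# One EM run from given initial means; returns NULL on numerical failure.
.em_once <- function(x, ks, mu0, max_iter, tol) {
  n <- length(x)
  mu <- mu0
  sd <- rep(stats::sd(x) / ks, ks)
  sd[sd <= 0] <- 1e-3
  w <- rep(1 / ks, ks)
  sd_floor <- max(1e-4, 1e-4 * stats::sd(x))
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(ks), function(k) w[k] * stats::dnorm(x, mu[k], sd[k]),
                   numeric(n))
    tot <- rowSums(dens)
    if (any(!is.finite(tot)) || any(tot <= 0)) return(NULL)
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)  # component collapsed
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
    sd <- pmax(sd, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      ll_old <- ll
      return(list(weights = w, means = mu, sds = sd, loglik = ll,
                  iterations = iter, converged = TRUE))
    }
    ll_old <- ll
  }
  list(weights = w, means = mu, sds = sd, loglik = ll_old,
       iterations = max_iter, converged = FALSE)
}

#' Fit a univariate Gaussian mixture to log-transformed expression values
#'
#' Expectation-maximisation with k-means initialisation and multiple random
#' restarts, keeping the fit with the best log-likelihood. The default of
#' five components follows the published cutoff procedure; input values are
#' expected on the `log2(count + 1)` scale.
#'
#' @param values Numeric vector of `log2(count + 1)` expression values.
#' @param ks Number of mixture components (default 5).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param n_restarts Number of k-means-initialised EM restarts (default 10).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return An object of class `mixture_fit` with `weights`, `means`, `sds`
#'   (sorted by component mean), `loglik`, `ks`.
#' @export
fit_expression_mixture <- function(values, ks = 5L, seed = 1L,
                                   n_restarts = 10L, max_iter = 2000L,
                                   tol = 1e-6) {
  x <- values[is.finite(values)]
  ks <- as.integer(ks)
  if (ks < 1L) stop("ks must be >= 1", call. = FALSE)
  if (length(x) < 10L * ks) {
    stop(sprintf("need at least %d finite values for ks = %d; got %d. Lower ks.",
                 10L * ks, ks, length(x)), call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("expression values are constant; no mixture can be fitted",
         call. = FALSE)
  }
  best <- NULL
  .with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      mu0 <- if (ks == 1L) mean(x) else {
        km <- tryCatch(stats::kmeans(x, centers = ks, nstart = 1L),
                       error = function(e) NULL)
        if (is.null(km)) sort(sample(x, ks)) else sort(as.numeric(km$centers))
      }
      fit <- .em_once(x, ks, mu0, max_iter, tol)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) {
    stop("Gaussian mixture EM failed to produce a valid fit (", n_restarts,
         " restarts); check the input distribution or lower ks", call. = FALSE)
  }
  if (!best$converged) {
    stop(sprintf(paste0("Gaussian mixture EM did not converge in %d iterations ",
                        "(final loglik %.4f); increase max_iter"),
                 max_iter, best$loglik), call. = FALSE)
  }
  ord <- order(best$means)
  structure(
    list(ks = ks, weights = best$weights[ord] / sum(best$weights),
         means = best$means[ord], sds = best$sds[ord],
         loglik = best$loglik, n = length(x)),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: %d components, n = %d, loglik = %.3f\n",
              x$ks, x$n, x$loglik))
  print(data.frame(weight = round(x$weights, 4), mean = round(x$means, 4),
                   sd = round(x$sds, 4)))
  invisible(x)
}

#' Derive expression cutoffs from a fitted mixture
#'
#' Components are partitioned into two groups by k-means (k = 2) on the
#' `ks x 3` matrix of per-component (weight, mean, sd). The matrix is
#' clustered on its raw scale: the mean axis — the quantity a low/high
#' expression split is about — then dominates the Euclidean distance, whereas
#' column standardisation lets a narrow spike component's extreme weight/sd
#' coordinates hijack the split and collapse the gate. The decision boundary
#' follows the maximum a posteriori rule: the expression value where the
#' summed density mass of the low group equals that of the high group,
#' located on a `grid_points`-point scan between the extreme component means;
#' every crossing is a cutoff and the smallest is the expression gate.
#'
#' @param fit A `mixture_fit` with at least two components.
#' @param grid_points Scan resolution (default 10001).
#' @return List with `cutoffs` (sorted boundaries), `cutoff` (the smallest),
#'   `group_labels` (per-component `"low"`/`"high"`, in mean order).
#' @export
derive_cutoff <- function(fit, grid_points = 10001L) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$ks < 2L) stop("cutoff derivation needs >= 2 mixture components",
                        call. = FALSE)
  par_mat <- cbind(weight = fit$weights, mean = fit$means, sd = fit$sds)
  # deterministic k-means start: the two components most extreme along the
  # mean axis (rows are sorted by mean, so first and last)
  centers <- par_mat[c(1L, fit$ks), , drop = FALSE]
  if (all(centers[1L, ] == centers[2L, ])) {
    stop("mixture components are indistinguishable; no two-group split",
         call. = FALSE)
  }
  cl <- if (fit$ks == 2L) 1:2 else
    stats::kmeans(par_mat, centers = centers)$cluster
  if (length(unique(cl)) < 2L) {
    stop("k-means placed every mixture component in one group; ",
         "try a different seed or ks", call. = FALSE)
  }
  # the group with the smaller mean expression is "low"
  grp_means <- tapply(fit$means, cl, mean)
  low_cl <- as.integer(names(grp_means)[which.min(grp_means)])
  labels <- ifelse(cl == low_cl, "low", "high")

  # MAP rule on a global grid between the extreme component means: the
  # posterior group assignment flips wherever the summed weighted densities
  # of the two groups cross; each sign change is a decision boundary
  grid <- seq(min(fit$means), max(fit$means), length.out = grid_points)
  f_low <- .dmix(grid, fit$weights[labels == "low"],
                 fit$means[labels == "low"], fit$sds[labels == "low"])
  f_high <- .dmix(grid, fit$weights[labels == "high"],
                  fit$means[labels == "high"], fit$sds[labels == "high"])
  d <- f_low - f_high
  flip <- which(d[-length(d)] * d[-1L] <= 0 & (d[-length(d)] != 0))
  cuts <- vapply(flip, function(i) {
    if (abs(d[i]) <= abs(d[i + 1L])) grid[i] else grid[i + 1L]
  }, numeric(1))
  cuts <- sort(unique(cuts))
  if (!length(cuts)) {
    stop("the two component groups' densities never cross between the ",
         "extreme component means; no boundary derivable (check ks)",
         call. = FALSE)
  }
  list(cutoffs = cuts, cutoff = cuts[1L], group_labels = labels)
}

#' Gate genes by an expression cutoff
#'
#' A gene is expressed iff its value is `>= cutoff` ("lower than the smallest
#' cutoff" means not expressed, so equality passes). With `cutoff = -Inf`
#' (e.g. when no expression data are supplied) the gate is the identity.
#'
#' @param values Named numeric vector on the same scale as the cutoff
#'   (`log2(count + 1)`).
#' @param cutoff Finite numeric gate, or `-Inf` for no gating.
#' @return Named logical vector of expressed flags.
#' @export
gate_genes <- function(values, cutoff) {
  if (length(cutoff) != 1L || is.na(cutoff)) {
    stop("cutoff must be a single non-missing number", call. = FALSE)
  }
  stats::setNames(values >= cutoff, names(values))
}

#' Compute expressed flags for a sample, or pass-through when absent
#'
#' Convenience wrapper: transforms raw counts with `log2(count + 1)`, fits
#' the mixture, derives the gate and returns per-gene expressed flags.
#' Returns `NULL` when `counts` is `NULL` (all genes treated as expressed).
#'
#' @param counts Named numeric vector of raw counts, or `NULL`.
#' @param ks,seed Passed to [fit_expression_mixture()].
#' @return Named logical vector, or `NULL`.
#' @export
expression_gate <- function(counts, ks = 5L, seed = 1L) {
  if (is.null(counts)) return(NULL)
  lg <- log2(counts + 1)
  fit <- fit_expression_mixture(lg, ks = ks, seed = seed)
  cut <- derive_cutoff(fit)
  gate_genes(lg, cut$cutoff)
}
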