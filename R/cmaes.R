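#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Minimizes a (possibly noisy) black-box objective with the standard
#' (mu/mu_w, lambda)-CMA-ES: rank-based recombination of the best half of
#' each population, cumulative step-size adaptation, and rank-one plus
#' rank-mu covariance updates. Box constraints are enforced by clipping
#' sampled candidates to the bounds (clipped coordinates are counted and
#' reported).
#'
#' The objective receives `(x, gen, idx)` so that stochastic objectives can
#' derive a deterministic simulation seed per evaluation. The optimizer's
#' own RNG stream is isolated from the objective: the global RNG state is
#' saved before and restored after each population evaluation, so an
#' objective that reseeds the RNG does not perturb the search.
#'
#' @param fn Objective: `function(x, gen, idx)` returning a scalar
#'   (non-finite values are treated as a very bad candidate).
#' @param x0 Numeric start point.
#' @param sigma0 Initial global step size (in the units of `x0`).
#' @param lower,upper Bounds (recycled to `length(x0)`).
#' @param popsize Population size lambda; default `4 + floor(3 log n)`.
#' @param generations Number of generations.
#' @param seed Integer seed for the optimizer's sampling stream.
#' @return List with `par` (best-ever point), `value` (its objective),
#'   `history` (data frame: generation, index, coordinates, value),
#'   `n_clipped` (count of bound-clipped coordinates), `sigma_final`.
#' @references Hansen, N. The CMA evolution strategy: a tutorial.
#' @export
cma_es <- function(fn, x0, sigma0, lower = -Inf, upper = Inf,
                   popsize = NULL, generations = 100, seed = 1) {
  n <- length(x0)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (is.null(popsize)) popsize <- 4L + floor(3 * log(n))
  popsize <- as.integer(popsize)
  mu <- floor(popsize / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- as.numeric(x0)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n)
  best_x <- xmean
  best_f <- Inf
  n_clipped <- 0L
  hist_rows <- vector("list", generations)

  set.seed(seed)
  for (gen in seq_len(generations)) {
    es <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(es$values, 1e-32))
    B <- es$vectors
    X <- matrix(0, n, popsize)
    for (k in seq_len(popsize)) {
      x <- xmean + sigma * as.numeric(B %*% (D * rnorm(n)))
      clip <- x < lower | x > upper
      n_clipped <- n_clipped + sum(clip)
      X[, k] <- pmin(pmax(x, lower), upper)
    }
    # evaluate with the optimizer's RNG stream shielded from fn
    rng_state <- get(".Random.seed", envir = globalenv())
    f <- vapply(seq_len(popsize),
                function(k) as.numeric(fn(X[, k], gen, k)), numeric(1))
    assign(".Random.seed", rng_state, envir = globalenv())
    f[!is.finite(f)] <- .Machine$double.xmax
    ord <- order(f)
    if (f[ord[1]] < best_f) {
      best_f <- f[ord[1]]
      best_x <- X[, ord[1]]
    }
    hist_rows[[gen]] <- data.frame(generation = gen, index = seq_len(popsize),
                                   t(X), value = f)

    sel <- X[, ord[seq_len(mu)], drop = FALSE]
    xold <- xmean
    xmean <- as.numeric(sel %*% w)
    y_w <- (xmean - xold) / sigma
    C_inv_sqrt_y <- as.numeric(B %*% ((1 / D) * crossprod(B, y_w)))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * C_inv_sqrt_y
    hsig <- sum(ps^2) / (1 - (1 - cs)^(2 * gen)) / n < 2 + 4 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * y_w
    Y <- sweep(sel, 1, xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * Y %*% (w * t(Y))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!all(is.finite(C))) {  # numerical safety net
      C <- diag(n)
      sigma <- sigma0
    }
  }
  history <- do.call(rbind, hist_rows)
  names(history)[2 + seq_len(n)] <- paste0("x", seq_len(n))
  list(par = best_x, value = best_f, history = history,
       n_clipped = n_clipped, sigma_final = sigma)
}
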