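# Sequential model-based (Bayesian) hyperparameter optimization: a small
# Gaussian-process surrogate with an expected-improvement acquisition over
# the unit hypercube encoding of each family's search space.

# Decode a unit-hypercube point into a named hyperparameter list.
decode_point <- function(u, space) {
  out <- list()
  for (j in seq_along(space)) {
    dim <- space[[j]]
    v <- u[j]
    out[[dim$name]] <- switch(dim$type,
      num = dim$lower + v * (dim$upper - dim$lower),
      num_log = exp(log(dim$lower) + v * (log(dim$upper) - log(dim$lower))),
      int_log = {
        val <- round(exp(log(dim$lower) + v * (log(dim$upper) -
                                               log(dim$lower))))
        as.integer(min(max(val, dim$lower), dim$upper))
      },
      cat = dim$values[[min(length(dim$values),
                            1L + floor(v * length(dim$values)))]],
      stop("unknown dimension type: ", dim$type))
  }
  out
}

# GP posterior (squared-exponential kernel, fixed lengthscale, nugget) and
# expected improvement for minimization.
gp_expected_improvement <- function(X, y, candidates, lengthscale = 0.3,
                                    nugget = 1e-6) {
  sqdist <- function(A, B) {
    an <- rowSums(A^2)
    bn <- rowSums(B^2)
    outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  }
  K <- exp(-sqdist(X, X) / (2 * lengthscale^2)) + diag(nugget, nrow(X))
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  yc <- (y - mu_y) / sd_y
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, yc, transpose = TRUE))
  Ks <- exp(-sqdist(candidates, X) / (2 * lengthscale^2))
  mu <- as.vector(Ks %*% alpha) * sd_y + mu_y
  v <- backsolve(L, t(Ks), transpose = TRUE)
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2) * sd_y
  ymin <- min(y)
  z <- (ymin - mu) / s
  (ymin - mu) * stats::pnorm(z) + s * stats::dnorm(z)
}

#' Tune hyperparameters by sequential model-based optimization
#'
#' Minimizes the inner-cross-validated misclassification rate over the
#' family's search space using a Gaussian-process surrogate with
#' expected-improvement acquisition: a small Latin-hypercube initial
#' design followed by sequential proposals, spending exactly `budget`
#' objective evaluations (default 15), and returning the best-observed
#' configuration.  Deterministic given the seed.  Run on the first fold's
#' training partition; the found hyperparameters are reused on the
#' remaining folds.
#'
#' @param algorithm One of [algorithm_families()].
#' @param features Training-partition `feature_table` (raw; normalization
#'   is fitted inside each inner fold).
#' @param selected Optional selected-feature columns (for SFS+HYP).
#' @param budget Total objective evaluations (>= 1).
#' @param inner_folds Inner CV folds for the objective.
#' @param seed Seed.
#' @return List with `hyperparameters` (best observed), `objective` (its
#'   inner-CV misclassification) and `trace` (data frame of all `budget`
#'   evaluated configurations with objective values).
#' @export
tune_hyperparameters <- function(algorithm, features, selected = NULL,
                                 budget = 15L, inner_folds = 5L, seed = 1L) {
  if (!is.numeric(budget) || budget < 1L) {
    stop("tuning budget must be >= 1", call. = FALSE)
  }
  budget <- as.integer(budget)
  p <- if (is.null(selected)) ncol(features$x) else length(selected)
  space <- hp_space(algorithm, n = length(features$label), p = p)
  d <- length(space)
  objective <- function(u) {
    hp <- decode_point(u, space)
    cv_misclassification(features, algorithm, hyperparameters = hp,
                         selected = selected, k = inner_folds,
                         seed = substream_seed(seed, "tuneobj"))
  }
  n_init <- min(budget, max(2L, min(5L, d + 2L)))
  X <- with_seed(substream_seed(seed, "tuneinit"),
                 as.matrix(lhs::maximinLHS(n_init, d)))
  y <- apply(X, 1L, objective)
  iter <- n_init
  while (iter < budget) {
    cand <- with_seed(substream_seed(seed, "tunecand", iter),
                      matrix(stats::runif(128L * d), ncol = d))
    ei <- gp_expected_improvement(X, y, cand)
    u <- cand[which.max(ei), , drop = FALSE]
    X <- rbind(X, u)
    y <- c(y, objective(as.vector(u)))
    iter <- iter + 1L
  }
  configs <- lapply(seq_len(nrow(X)), function(i) decode_point(X[i, ], space))
  trace <- cbind(
    do.call(rbind, lapply(configs, function(cfg)
      as.data.frame(cfg, stringsAsFactors = FALSE))),
    objective = y)
  best <- which.min(y)
  list(hyperparameters = configs[[best]], objective = y[best], trace = trace)
}
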