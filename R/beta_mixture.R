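#' Prior specification for the three-component Beta mixture
#'
#' Components: k = 1 is the significant (near-zero p-value) component with
#' a1 fixed at 1 and a large-mean prior on b1; k = 2 is the
#' non-differentially-expressed bulk; k = 3 mirrors component 1 near p = 1
#' (b3 fixed at 1). The mixture weights get a Dirichlet(1, 18, 1) prior,
#' whose mean (0.05, 0.90, 0.05) encodes the expectation that most genes are
#' not regulated. Gamma(shape, rate) priors have mean shape/rate:
#' a2 ~ Gamma(4, 2), b2 ~ Gamma(1, 1), b1 and a3 ~ Gamma(400, 20).
#'
#' @return A list of prior hyperparameters, suitable for
#'   [fit_beta_mixture()]'s `priors` argument.
#' @export
beta_prior_spec <- function() {
  list(dirichlet = c(1, 18, 1),
       a1 = 1, b3 = 1,
       a2 = c(shape = 4, rate = 2),
       b2 = c(shape = 1, rate = 1),
       b1 = c(shape = 400, rate = 20),
       a3 = c(shape = 400, rate = 20))
}

## Split-Rhat over a draws matrix (iterations x chains).
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  half <- floor(nrow(draws) / 2)
  if (half < 2L) return(NA_real_)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[half + seq_len(half), , drop = FALSE])
  m <- ncol(sub); n <- nrow(sub)
  mu <- colMeans(sub)
  B <- n * var(mu)
  W <- mean(apply(sub, 2L, var))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit a three-component Beta mixture to one-sided p-values
#'
#' Models a dataset's one-sided rank-product p-values as a mixture of three
#' Beta densities: a left-skewed component for significant genes (mass near
#' 0), a flexible bulk component for non-regulated genes, and a right-skewed
#' component near 1. Rank-product p-values are not uniform under the null, so
#' the bulk is a free Beta(a2, b2) rather than a uniform. Posterior inference
#' uses Gibbs sampling with data augmentation over component memberships;
#' the constrained shapes (a1 = 1, b3 = 1) make the b1 and a3 updates
#' conjugate Gamma draws, and (a2, b2) are updated by a random-walk
#' Metropolis step on the log scale. The fixed-shape constraints anchor the
#' component labels and prevent label switching.
#'
#' @param pvalues Numeric vector of p-values; values are clamped into
#'   `[1e-6, 1 - 1e-6]` before fitting so Beta log-densities stay finite.
#'   An empty vector returns the prior means (prior-only fit).
#' @param priors Prior hyperparameters, see [beta_prior_spec()].
#' @param dataset_id Identifier carried into the result.
#' @param chains,iter,burnin MCMC layout: `chains` independent chains of
#'   `iter` sweeps each, the first `burnin` discarded.
#' @param seed Integer seed (optional).
#' @param mh_sd Random-walk standard deviation (log scale) for the (a2, b2)
#'   Metropolis update.
#' @return Object of class `mixture_fit`: posterior-mean mixture weights
#'   `theta` (significant, bulk, near-one), `beta_params` (3 x 2 matrix of
#'   Beta shapes), `G` (number of p-values), split-Rhat diagnostics `rhat`,
#'   a `converged` flag (max Rhat < 1.1), retained draw count and the
#'   Metropolis acceptance rate.
#' @export
fit_beta_mixture <- function(pvalues, priors = beta_prior_spec(),
                             dataset_id = "dataset", chains = 2L,
                             iter = 4000L, burnin = 2000L, seed = NULL,
                             mh_sd = 0.05) {
  stopifnot(iter > burnin, chains >= 1L)
  if (length(pvalues) == 0L) {
    d <- priors$dirichlet
    return(structure(
      list(dataset_id = dataset_id, theta = d / sum(d),
           beta_params = cbind(a = c(priors$a1, priors$a2[["shape"]] / priors$a2[["rate"]],
                                     priors$a3[["shape"]] / priors$a3[["rate"]]),
                               b = c(priors$b1[["shape"]] / priors$b1[["rate"]],
                                     priors$b2[["shape"]] / priors$b2[["rate"]],
                                     priors$b3)),
           G = 0L, n_draws = 0L, rhat = c(NA_real_, NA_real_, NA_real_),
           converged = NA, accept_rate = NA_real_, n_clamped = 0L,
           prior_only = TRUE),
      class = "mixture_fit"))
  }
  if (anyNA(pvalues)) stop("p-values contain NA")
  n_clamped <- sum(pvalues < 1e-6 | pvalues > 1 - 1e-6)
  y <- pmin(pmax(pvalues, 1e-6), 1 - 1e-6)
  if (length(unique(y)) == 1L) stop("all p-values are identical; cannot fit")
  G <- length(y)
  ly <- log(y); l1y <- log1p(-y)
  dpr <- priors$dirichlet
  a1 <- priors$a1; b3 <- priors$b3

  keep <- iter - burnin
  theta_draws <- array(NA_real_, c(keep, chains, 3L))
  par_draws <- array(NA_real_, c(keep, chains, 4L))  # b1, a2, b2, a3
  n_accept <- 0L; n_prop <- 0L

  with_seed(seed, {
    for (ch in seq_len(chains)) {
      jit <- function(x) x * exp(rnorm(1L, 0, 0.2))
      b1 <- jit(priors$b1[["shape"]] / priors$b1[["rate"]])
      a3 <- jit(priors$a3[["shape"]] / priors$a3[["rate"]])
      a2 <- jit(priors$a2[["shape"]] / priors$a2[["rate"]])
      b2 <- jit(priors$b2[["shape"]] / priors$b2[["rate"]])
      theta <- c(rdirichlet1(dpr))
      for (it in seq_len(iter)) {
        ## component memberships
        lp1 <- log(theta[1L]) + log(b1) + (b1 - 1) * l1y
        lp2 <- log(theta[2L]) - lbeta(a2, b2) + (a2 - 1) * ly + (b2 - 1) * l1y
        lp3 <- log(theta[3L]) + log(a3) + (a3 - 1) * ly
        mx <- pmax(lp1, lp2, lp3)
        p1 <- exp(lp1 - mx); p2 <- exp(lp2 - mx); p3 <- exp(lp3 - mx)
        u <- runif(G) * (p1 + p2 + p3)
        z <- 1L + (u > p1) + (u > p1 + p2)
        n1 <- sum(z == 1L); n3 <- sum(z == 3L); n2 <- G - n1 - n3
        ## mixture weights
        theta <- c(rdirichlet1(dpr + c(n1, n2, n3)))
        ## conjugate shape updates for the anchored components
        b1 <- rgamma(1L, priors$b1[["shape"]] + n1,
                     rate = priors$b1[["rate"]] - sum(l1y[z == 1L]))
        a3 <- rgamma(1L, priors$a3[["shape"]] + n3,
                     rate = priors$a3[["rate"]] - sum(ly[z == 3L]))
        ## Metropolis update for the bulk component
        s2a <- sum(ly[z == 2L]); s2b <- sum(l1y[z == 2L])
        log_post2 <- function(la, lb) {
          a <- exp(la); b <- exp(lb)
          n2 * (-lbeta(a, b)) + (a - 1) * s2a + (b - 1) * s2b +
            dgamma(a, priors$a2[["shape"]], rate = priors$a2[["rate"]], log = TRUE) +
            dgamma(b, priors$b2[["shape"]], rate = priors$b2[["rate"]], log = TRUE) +
            la + lb  # Jacobian of the log transform
        }
        la <- log(a2); lb <- log(b2)
        la_new <- la + rnorm(1L, 0, mh_sd)
        lb_new <- lb + rnorm(1L, 0, mh_sd)
        n_prop <- n_prop + 1L
        if (log(runif(1L)) < log_post2(la_new, lb_new) - log_post2(la, lb)) {
          a2 <- exp(la_new); b2 <- exp(lb_new)
          n_accept <- n_accept + 1L
        }
        if (it > burnin) {
          theta_draws[it - burnin, ch, ] <- theta
          par_draws[it - burnin, ch, ] <- c(b1, a2, b2, a3)
        }
      }
    }
  })

  theta_hat <- apply(theta_draws, 3L, mean)
  par_hat <- apply(par_draws, 3L, mean)
  rhat <- vapply(seq_len(3L), function(k) split_rhat(theta_draws[, , k]),
                 numeric(1L))
  converged <- all(is.na(rhat) | rhat < 1.1)
  if (!isTRUE(converged)) {
    warning("mixture fit for '", dataset_id,
            "' may not have converged (max split-Rhat = ",
            sprintf("%.3f", max(rhat, na.rm = TRUE)), ")")
  }
  ## sanity check on the anchored ordering of component means
  means <- c(a1 / (a1 + par_hat[1L]),
             par_hat[2L] / (par_hat[2L] + par_hat[3L]),
             par_hat[4L] / (par_hat[4L] + b3))
  if (is.unsorted(means)) {
    warning("component means are not ordered for '", dataset_id,
            "'; labels may be unreliable")
  }
  structure(
    list(dataset_id = dataset_id, theta = theta_hat,
         beta_params = cbind(a = c(a1, par_hat[2L], par_hat[4L]),
                             b = c(par_hat[1L], par_hat[3L], b3)),
         G = G, n_draws = keep * chains, rhat = rhat,
         converged = converged, accept_rate = n_accept / n_prop,
         n_clamped = n_clamped, prior_only = FALSE),
    class = "mixture_fit")
}

## One draw from a Dirichlet distribution.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), alpha, rate = 1)
  g / sum(g)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "mixture_fit '%s': theta = (%.3f, %.3f, %.3f), G = %d, converged: %s\n",
    x$dataset_id, x$theta[1L], x$theta[2L], x$theta[3L], x$G,
    as.character(x$converged)))
  invisible(x)
}

#' Estimated number of genes not regulated in a given direction
#'
#' For a mixture fitted to up-regulation p-values, the significant component
#' (k = 1) carries the up-regulated genes, so the non-up-regulated count is
#' `round(G * (theta2 + theta3))` (analogously for down-regulation p-values).
#' The count is floored at 1 so downstream false-positive rates stay finite,
#' and capped at G.
#'
#' @param fit A [fit_beta_mixture()] result.
#' @param G Number of genes in the dataset.
#' @param direction `"up"` or `"down"` (the direction whose p-values were
#'   fitted; recorded for bookkeeping, the arithmetic is identical).
#' @return Integer count in `[1, G]`.
#' @export
estimate_not_de_counts <- function(fit, G, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(fit, "mixture_fit"), G >= 1L)
  cnt <- round(G * (fit$theta[2L] + fit$theta[3L]))
  as.integer(min(max(cnt, 1L), G))
}
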