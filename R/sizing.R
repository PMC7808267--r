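#' Noncentrality parameter of the chi-squared global test
#'
#' Solves for the noncentrality parameter \eqn{\lambda^*} at which a
#' noncentral chi-squared statistic with `df` degrees of freedom exceeds the
#' central upper-`alpha` critical value with probability \eqn{1-\beta}:
#' the \eqn{\beta}-quantile of \eqn{\chi^2_{df}(\lambda^*)} equals
#' \eqn{\chi^2_{df,\alpha}(0)} (upper-tail critical value).  No closed form
#' exists, so the value is found by an ascending search: expanding bracket
#' from `start`, then bisection to the first \eqn{\lambda} (approaching from
#' below) at which the attained power is within `d` of \eqn{1-\beta}.  The
#' result does not depend on the starting value (a closer start only shortens
#' the search); a smaller `d` gives better accuracy.
#'
#' @param df degrees of freedom of the global test.
#' @param alpha targeted type-I error rate.
#' @param beta targeted type-II error rate (power is `1 - beta`).
#' @param d stopping tolerance on the attained-power difference.
#' @param start initial value of the search.
#' @param max_iter iteration budget for the bisection.
#' @return The noncentrality parameter \eqn{\lambda^*}.
#' @examples
#' getncp(df = 5, alpha = 0.05, beta = 0.20, d = 0.0001, start = 5)
#' @export
getncp <- function(df, alpha = 0.05, beta = 0.20, d = 1e-4, start = 5,
                   max_iter = 200L) {
  stopifnot(df >= 1, alpha > 0, alpha < 1, beta > 0, beta < 1,
            d > 0, start > 0)
  crit <- stats::qchisq(alpha, df, lower.tail = FALSE)
  # the first lambda (searching upward) whose attained power is within d of
  # the target: miss(lambda) = (beta + d) - P(chi2_df(lambda) <= crit),
  # increasing in lambda with root at the band's lower edge
  target <- min(beta + d, 1 - 1e-12)
  miss <- function(lambda) target - stats::pchisq(crit, df, ncp = lambda)
  lo <- 0
  hi <- start
  it <- 0L
  while (miss(hi) < 0) {
    lo <- hi
    hi <- hi * 2
    it <- it + 1L
    if (it > max_iter)
      stop("getncp did not bracket a solution; last bracket [",
           lo, ", ", hi, "]")
  }
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (miss(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-9 * max(1, hi)) break
  }
  if (miss(hi) < 0 || hi - lo > 1e-6 * max(1, hi))
    stop("getncp did not converge to tolerance ", d,
         "; last bracket [", lo, ", ", hi, "]")
  hi
}

#' Design-stage strategy values and covariance from a SIM
#'
#' Computes the targeted strategy values \eqn{\Theta^*} and the per-subject
#' scaled covariance \eqn{\Sigma^*} (i.e. \eqn{n\,\mathrm{Cov}(\hat\Theta)})
#' of the strategy-value estimator implied by a sequence information matrix.
#'
#' Values are \eqn{\theta^*_g = \sum_r P2(a_1,r)\, \mu(a_1, r, d_g(r))}.  For
#' G-computation the covariance follows from the delta method applied to
#' \eqn{\hat\theta_g = \sum_r \hat p_r \bar Y_{r}}: within an arm,
#' \deqn{n\,\mathrm{Cov}(\hat\theta_g,\hat\theta_{g'}) =
#'   \sum_r P2_r^2 \sigma^2_{r}\,/\,q_r \; 1\{d_g(r)=d_{g'}(r)\}
#'   + \sum_{r,r'} \mu_g(r)\mu_{g'}(r')\, P2_r(1\{r=r'\}-P2_{r'})/\pi_1,}
#' with \eqn{q_r = \pi_1 P2_r \pi_2} the probability of the sequence selected
#' by the strategy in category \eqn{r}; across arms the covariance is exactly
#' zero (block-diagonal).  For IPW the covariance is the influence-function
#' variance of the weighted estimator,
#' \eqn{\sum_{r: d_g(r)=d_{g'}(r)} P2_r/(\pi_1\pi_2)\,
#' (\sigma^2_r + (\mu_r-\theta_g)(\mu_r-\theta_{g'}))}.
#' The binomial family derives \eqn{\sigma^2 = \mu(1-\mu)} from the sequence
#' means.
#'
#' @param sim a SIM data frame (see [smart_design()]).
#' @param method `"gcomp"` (G-computation, default) or `"ipw"`.
#' @param family `"gaussian"` or `"binomial"`.
#' @return An object of class `"design_moments"`: list with `theta` (length-G
#'   vector), `sigma` (G-by-G matrix, per-subject scale), `strategies`,
#'   `design`, `method`, `family`.
#' @export
design_moments <- function(sim, method = c("gcomp", "ipw"),
                           family = c("gaussian", "binomial")) {
  method <- normalize_method(method)
  family <- match.arg(family)
  design <- if (inherits(sim, "smart_design")) sim else smart_design(sim)
  tab <- design$sim
  if (anyNA(tab$MEAN))
    stop("SIM must provide MEAN for every sequence")
  if (family == "binomial") {
    if (any(tab$MEAN <= 0 | tab$MEAN >= 1))
      stop("binomial family requires sequence means in (0, 1)")
    sig2 <- tab$MEAN * (1 - tab$MEAN)
  } else {
    if (anyNA(tab$SD)) stop("SIM must provide SD for every sequence")
    sig2 <- tab$SD^2
  }
  strat <- ats_strategies(design)
  G <- nrow(strat)
  theta <- numeric(G)
  # per strategy: sequence row chosen in each of its categories
  seq_of <- vector("list", G)
  for (g in seq_len(G)) {
    a <- strat$d0[g]
    cats <- design$categories[[as.character(a)]]
    idx <- sequence_index(design, rep(a, length(cats)), cats,
                          as.numeric(strat[g, paste0("d0", cats)]))
    seq_of[[g]] <- stats::setNames(idx, as.character(cats))
    theta[g] <- sum(tab$P2[idx] * tab$MEAN[idx])
  }
  q_seq <- tab$PI1 * tab$P2 * tab$PI2
  if (any(q_seq <= 0)) stop("unreachable sequence: SEQ = ",
                            paste(tab$SEQ[q_seq <= 0], collapse = ", "))
  sigma <- matrix(0, G, G)
  for (g in seq_len(G)) for (h in seq_len(g)) {
    if (strat$d0[g] != strat$d0[h]) next
    ig <- seq_of[[g]]; ih <- seq_of[[h]]
    shared <- ig == ih
    if (method == "gcomp") {
      v <- sum((tab$P2[ig]^2 * sig2[ig] / q_seq[ig])[shared])
      p <- tab$P2[ig]
      pi1 <- tab$PI1[ig][1L]
      cov_p <- (diag(p, length(p)) - outer(p, p)) / pi1
      v <- v + drop(t(tab$MEAN[ig]) %*% cov_p %*% tab$MEAN[ih])
    } else {
      v <- sum(((tab$P2[ig] / (tab$PI1[ig] * tab$PI2[ig])) *
                  (sig2[ig] + (tab$MEAN[ig] - theta[g]) *
                     (tab$MEAN[ih] - theta[h])))[shared])
    }
    sigma[g, h] <- sigma[h, g] <- v
  }
  dimnames(sigma) <- list(strat$code, strat$code)
  structure(list(theta = stats::setNames(theta, strat$code), sigma = sigma,
                 strategies = strat, design = design, method = method,
                 family = family),
            class = "design_moments")
}

#' Standardized overall effect size of a SMART design
#'
#' The standardized discrepancy of the targeted strategy values,
#' \eqn{\Delta = (C\Theta^*)^T (C\Sigma^* C^T)^- (C\Theta^*)}, with
#' \eqn{C = (1_{G-1} \,|\, -I_{G-1})} and the Moore-Penrose generalized
#' inverse (the contrast covariance is singular by construction).  The value
#' is invariant to the choice of reference strategy and to adding a constant
#' to all sequence means.
#'
#' @param moments a [design_moments()] object.
#' @return The effect size \eqn{\Delta > 0}.
#' @export
effect_size <- function(moments) {
  stopifnot(inherits(moments, "design_moments"))
  theta <- moments$theta
  G <- length(theta)
  C <- contrast_matrix(G)
  ct <- drop(C %*% theta)
  if (max(abs(ct)) < 1e-12)
    stop("null design: strategies have equal values (effect size 0)")
  V <- C %*% moments$sigma %*% t(C)
  drop(t(ct) %*% MASS::ginv(V) %*% ct)
}

contrast_matrix <- function(G) cbind(1, -diag(G - 1))

normalize_method <- function(method) {
  m <- tolower(method[1L])
  if (m %in% c("gcomp", "gest", "g")) "gcomp"
  else if (m %in% c("ipw", "ip")) "ipw"
  else stop("unknown method '", method[1L], "' (use \"gcomp\" or \"ipw\")")
}

#' Sample size for a SMART
#'
#' Powers a SMART either for the global test of equality of all embedded
#' strategy values (`global = TRUE`) or for a pairwise comparison of two
#' strategies (`global = FALSE`).
#'
#' *Global path.* The required noncentrality parameter \eqn{\lambda^*} is
#' solved with [getncp()]; the total sample size is
#' \eqn{n = \lceil \lambda^*/\Delta \rceil}, where the effect size
#' \eqn{\Delta} is supplied directly via `delta` or computed from a SIM via
#' [design_moments()] and [effect_size()] (in which case `df` is also derived
#' from the design).
#'
#' *Pairwise path.* Classic two-independent-group normal-approximation
#' sizing at standardized difference `delta`:
#' \eqn{n = \lceil 2 (z_{1-\alpha/2} + z_{1-\beta})^2 / \delta^2 \rceil}
#' patients per strategy.  Supplying `ntest` Bonferroni-adjusts the
#' significance level to `alpha / ntest`.
#'
#' @param delta effect size: the standardized overall effect \eqn{\Delta} on
#'   the global path, or the standardized pairwise difference on the pairwise
#'   path.  Optional on the global path when `sim` is given.
#' @param df degrees of freedom of the global test; derived from `sim` when
#'   omitted.
#' @param sim optional sequence information matrix (global path).
#' @param global logical: global-test (default) or pairwise sizing.
#' @param alpha,beta targeted type-I and type-II error rates.
#' @param family,method passed to [design_moments()] when `sim` is used.
#' @param ntest optional number of pairwise tests for Bonferroni adjustment
#'   (pairwise path).
#' @return An object of class `"smartsize"`; on the global path a list with
#'   `NCP`, `delta`, `df`, `N`; on the pairwise path `delta` and `n_per_ats`.
#' @examples
#' smartsize(delta = 0.1213, df = 5)                  # N = 106
#' smartsize(delta = 0.90, global = FALSE)            # 20 per strategy
#' @export
smartsize <- function(delta = NULL, df = NULL, sim = NULL, global = TRUE,
                      alpha = 0.05, beta = 0.20,
                      family = c("gaussian", "binomial"),
                      method = c("gcomp", "ipw"), ntest = NULL) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1)
  family <- match.arg(family)
  if (global) {
    if (is.null(sim) && (is.null(delta) || is.null(df)))
      stop("global sizing needs either 'sim' or both 'delta' and 'df'")
    if (!is.null(sim)) {
      design <- if (inherits(sim, "smart_design")) sim else smart_design(sim)
      if (is.null(df)) df <- smart_df(design)
      if (is.null(delta))
        delta <- effect_size(design_moments(design, method, family))
    }
    stopifnot(delta > 0, df >= 1)
    ncp <- getncp(df = df, alpha = alpha, beta = beta)
    out <- list(NCP = ncp, delta = delta, df = df,
                N = as.integer(ceiling(ncp / delta)),
                alpha = alpha, beta = beta, global = TRUE)
  } else {
    if (is.null(delta))
      stop("pairwise sizing needs 'delta', the standardized difference")
    stopifnot(delta > 0)
    a <- if (is.null(ntest)) alpha else alpha / ntest
    n <- ceiling(2 * (stats::qnorm(1 - a / 2) + stats::qnorm(1 - beta))^2 /
                   delta^2)
    out <- list(delta = delta, n_per_ats = as.integer(n),
                alpha = alpha, beta = beta, global = FALSE, ntest = ntest)
  }
  class(out) <- "smartsize"
  out
}

#' @export
print.smartsize <- function(x, ...) {
  if (x$global) {
    cat("Sample size for a SMART (global test)\n")
    cat(sprintf("  NCP   = %.4f\n", x$NCP))
    cat(sprintf("  delta = %.4f\n", x$delta))
    cat(sprintf("  df    = %d\n", x$df))
    cat(sprintf("  N     = %d total patients\n", x$N))
  } else {
    cat("Sample size for a SMART (pairwise test)\n")
    cat(sprintf("  standardized difference = %.4f\n", x$delta))
    if (!is.null(x$ntest))
      cat(sprintf("  Bonferroni ntest        = %d\n", x$ntest))
    cat(sprintf("  n per strategy          = %d\n", x$n_per_ats))
  }
  invisible(x)
}
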