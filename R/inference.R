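#' Global Wald test of equality of all strategy values
#'
#' Tests \eqn{H_0: \theta_1 = \cdots = \theta_G} with the Wald statistic
#' \eqn{Q = (C\hat\Theta)^T (C\hat\Sigma C^T)^- (C\hat\Theta)}, where
#' \eqn{C = (1_{G-1}\,|\,-I_{G-1})} and \eqn{\hat\Sigma} is the estimated
#' covariance of \eqn{\hat\Theta}.  Because patients contribute to several
#' strategies, \eqn{C\hat\Sigma C^T} is singular by construction, so the
#' Moore-Penrose generalized inverse is used; \eqn{Q} is invariant to the
#' choice of reference strategy.  Under \eqn{H_0}, \eqn{Q} is asymptotically
#' central chi-squared with [smart_df()] degrees of freedom (taken from the
#' design; a warning is issued if the numerical rank of the contrast
#' covariance differs).
#'
#' @param estimates an [atsmeans()] object.
#' @param rank_tol relative singular-value tolerance for the numerical rank.
#' @return A data frame of class `"global_test"` with columns `N`, `nATS`,
#'   `df`, `Q`, `p.value`.
#' @export
global_test <- function(estimates, rank_tol = 1e-8) {
  stopifnot(inherits(estimates, "atsmeans"))
  theta <- estimates$value$value
  G <- length(theta)
  if (G < 2) stop("global test needs at least two strategies")
  sigma <- estimates$covariance
  if (max(abs(sigma)) == 0) stop("covariance matrix is all zero")
  C <- contrast_matrix(G)
  V <- C %*% sigma %*% t(C)
  sv <- svd(V, nu = 0, nv = 0)$d
  num_rank <- sum(sv > rank_tol * max(sv))
  df <- estimates$df
  if (num_rank != df)
    warning("numerical rank of the contrast covariance (", num_rank,
            ") differs from the design degrees of freedom (", df, ")")
  ct <- drop(C %*% theta)
  Q <- drop(t(ct) %*% MASS::ginv(V) %*% ct)
  out <- data.frame(N = estimates$n, nATS = G, df = df, Q = Q,
                    p.value = stats::pchisq(Q, df, lower.tail = FALSE))
  class(out) <- c("global_test", "data.frame")
  out
}

#' All pairwise strategy comparisons with simultaneous confidence intervals
#'
#' For every pair \eqn{j < k} of strategies, the estimated difference
#' \eqn{\hat\theta_j - \hat\theta_k}, its standard error
#' \eqn{\sqrt{\hat\Sigma_{jj} + \hat\Sigma_{kk} - 2\hat\Sigma_{jk}}}, the
#' Z statistic and the unadjusted two-sided normal p-value.  With
#' `adjust = "bon"` the confidence limits use the Bonferroni quantile
#' \eqn{\delta_{jk} = z_{1-\alpha/(2 n_p)}} with \eqn{n_p = G(G-1)/2} (or
#' `ntest` if supplied), producing simultaneous \eqn{1-\alpha} intervals;
#' the corresponding decision threshold for the p-values is
#' \eqn{\alpha / n_p}.
#'
#' @param estimates an [atsmeans()] object.
#' @param alpha overall significance level.
#' @param adjust `"bon"` (Bonferroni simultaneous intervals, default) or
#'   `"none"`.
#' @param ntest optional number of contrasts used for the adjustment.
#' @return A data frame of class `"pairwise_comparisons"` with one row per
#'   pair: `label`, `diff`, `lower`, `upper`, `Z`, `p.value`; attributes
#'   `"n_p"` (number of contrasts) and `"delta_jk"` (critical quantile).
#' @export
pairwise_comparisons <- function(estimates, alpha = 0.05,
                                 adjust = c("bon", "none"), ntest = NULL) {
  stopifnot(inherits(estimates, "atsmeans"))
  adjust <- tolower(adjust[1L])
  adjust <- match.arg(adjust, c("bon", "none"))
  theta <- estimates$value$value
  sigma <- estimates$covariance
  G <- length(theta)
  if (G < 2) stop("pairwise comparisons need at least two strategies")
  pairs <- utils::combn(G, 2)
  n_p <- if (!is.null(ntest)) ntest else ncol(pairs)
  delta_jk <- if (adjust == "bon") stats::qnorm(1 - alpha / (2 * n_p))
              else stats::qnorm(1 - alpha / 2)
  rows <- apply(pairs, 2, function(jk) {
    j <- jk[1L]; k <- jk[2L]
    d <- theta[j] - theta[k]
    se <- sqrt(max(sigma[j, j] + sigma[k, k] - 2 * sigma[j, k], 0))
    if (se == 0) {
      if (abs(d) > 1e-12)
        stop("zero standard error with nonzero difference for pair ",
             j, "-", k)
      z <- 0
    } else z <- d / se
    c(d, d - delta_jk * se, d + delta_jk * se, z,
      2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(label = paste(pairs[1, ], pairs[2, ], sep = "-"),
                    diff = rows[1, ], lower = rows[2, ], upper = rows[3, ],
                    Z = rows[4, ], p.value = rows[5, ])
  attr(out, "n_p") <- n_p
  attr(out, "delta_jk") <- delta_jk
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  class(out) <- c("pairwise_comparisons", "data.frame")
  out
}

#' Global and pairwise comparison of all embedded strategies
#'
#' One-call analysis of a SMART dataset: estimates every strategy value (see
#' [atsmeans()]), runs the global Wald test and all pairwise comparisons with
#' Bonferroni simultaneous confidence intervals.  The global test is intended
#' as a gate-keeper: strategy selection from the pairwise table is only
#' interpreted when the global test rejects; otherwise the conclusion is that
#' no overall difference was found.
#'
#' @inheritParams atsmeans
#' @param adjust,ntest passed to [pairwise_comparisons()].
#' @return An object of class `"smartest"`: list with elements `Strategy`
#'   (strategy listing with consistent-patient counts), `Global.test` and
#'   `Pairwise.comparisons`.
#' @examples
#' smartest(synthetic_codiacs(seed = 1))
#' @export
smartest <- function(data, method = c("gcomp", "ipw"), common = FALSE,
                     alpha = 0.05, adjust = c("bon", "none"), ntest = NULL,
                     design = NULL, family = c("gaussian", "binomial")) {
  est <- atsmeans(data, method = method, common = common, conf = TRUE,
                  alpha = alpha, design = design, family = family)
  strat_cols <- setdiff(names(est$value), c("value", "se", "lower", "upper"))
  structure(list(Strategy = est$value[strat_cols],
                 Global.test = global_test(est),
                 Pairwise.comparisons =
                   pairwise_comparisons(est, alpha = alpha, adjust = adjust,
                                        ntest = ntest),
                 estimates = est),
            class = "smartest")
}

#' @export
print.smartest <- function(x, digits = NULL, ...) {
  cat("SMART strategy comparison",
      "(global test as gate-keeper; pairwise table interpreted on rejection)",
      "", sep = "\n")
  cat("$Strategy\n"); print(x$Strategy, ...)
  cat("\n$Global.test\n")
  print(as.data.frame(x$Global.test), ...)
  cat("\n$Pairwise.comparisons\n")
  pw <- as.data.frame(x$Pairwise.comparisons)
  if (!is.null(digits))
    for (v in c("diff", "lower", "upper", "Z", "p.value"))
      pw[[v]] <- round(pw[[v]], digits)
  print(pw, ...)
  invisible(x)
}
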