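#' Simulate a SMART dataset from a sequence information matrix
#'
#' Draws, per patient and in a fixed order, the stage-1 arm
#' `A1 ~ categorical(PI1)`, the intermediate response `O2 | A1 ~
#' categorical(P2)`, the stage-2 treatment `A2 | A1, O2 ~ categorical(PI2)`
#' (a degenerate branch assigns its single option with probability one), and
#' the outcome `Y ~ Normal(MEAN, SD)` (gaussian family) or
#' `Y ~ Bernoulli(MEAN)` (binomial family).  Output is byte-identical for a
#' fixed seed.
#'
#' @param sim a SIM data frame or `"smart_design"`.
#' @param n number of patients.
#' @param seed optional integer seed.
#' @param family `"gaussian"` or `"binomial"`.
#' @return A data frame with columns `A1`, `O2`, `A2`, `Y`.
#' @examples
#' head(sim_smart(codiacs_sim(), n = 10, seed = 1))
#' @export
sim_smart <- function(sim, n, seed = NULL,
                      family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  design <- if (inherits(sim, "smart_design")) sim else smart_design(sim)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  tab <- design$sim
  if (family == "binomial" && any(tab$MEAN <= 0 | tab$MEAN >= 1))
    stop("binomial family requires sequence means in (0, 1)")
  a1 <- sample_cat(design$arms, n, design$pi1)
  o2 <- a2 <- y <- numeric(n)
  for (a in design$arms) {
    aa <- as.character(a)
    i <- which(a1 == a)
    if (!length(i)) next
    cats <- design$categories[[aa]]
    o2[i] <- sample_cat(cats, length(i), design$p2[[aa]])
    for (r in cats) {
      j <- i[o2[i] == r]
      if (!length(j)) next
      rr <- as.character(r)
      a2[j] <- sample_cat(design$options[[aa]][[rr]], length(j),
                          design$pi2[[aa]][[rr]])
    }
  }
  k <- sequence_index(design, a1, o2, a2)
  y <- if (family == "gaussian") stats::rnorm(n, tab$MEAN[k], tab$SD[k])
       else stats::rbinom(n, 1, tab$MEAN[k])
  data.frame(A1 = a1, O2 = o2, A2 = a2, Y = y)
}

sample_cat <- function(values, n, prob) {
  if (length(values) == 1L) rep(values, n)
  else sample(values, n, replace = TRUE, prob = prob)
}

#' Monte Carlo operating characteristics of the strategy comparison
#'
#' Simulates `reps` SMART datasets of size `n` from a SIM and reports the
#' fraction of replicates in which the analysis rejects at level `alpha`:
#' the global Wald test for `analysis = "global"`, or (for
#' `analysis = "pairwise"`) any pairwise test below the Bonferroni threshold
#' \eqn{\alpha / n_p}.  Under a null SIM (all sequence means equal) the
#' rejection rate estimates the type-I error; under an alternative it
#' estimates power.
#'
#' @param sim SIM data frame or `"smart_design"`.
#' @param n patients per replicate trial.
#' @param reps number of replicate trials (>= 100).
#' @param alpha significance level.
#' @param seed optional integer seed for the whole experiment.
#' @param analysis `"global"` or `"pairwise"`.
#' @param method estimation method, `"gcomp"` or `"ipw"`.
#' @param family outcome family.
#' @return A list with `power` (rejection proportion), `rejection_se`
#'   (binomial standard error), `reps`, `n`.
#' @export
smart_oc <- function(sim, n, reps = 1000L, alpha = 0.05, seed = NULL,
                     analysis = c("global", "pairwise"),
                     method = c("gcomp", "ipw"),
                     family = c("gaussian", "binomial")) {
  analysis <- match.arg(analysis)
  method <- normalize_method(method)
  family <- match.arg(family)
  stopifnot(reps >= 100)
  design <- if (inherits(sim, "smart_design")) sim else smart_design(sim)
  if (!is.null(seed)) set.seed(seed)
  df <- smart_df(design)
  strat <- ats_strategies(design)
  G <- nrow(strat)
  n_p <- G * (G - 1) / 2
  C <- contrast_matrix(G)
  ctx <- design_context(design)
  rej <- logical(reps)
  for (b in seq_len(reps)) {
    dat <- sim_smart(design, n, family = family)
    # replicates where a required sequence is empty (or has a single
    # patient, leaving its variance undefined) cannot reject
    rej[b] <- tryCatch({
      fit <- if (method == "gcomp")
        fit_gcomp(dat, design, family = family, ctx = ctx)
      else fit_ipw(dat, design, family = family, probs = "empirical",
                   ctx = ctx)
      if (!all(is.finite(fit$sigma))) FALSE
      else if (analysis == "global") {
        ct <- drop(C %*% fit$theta)
        V <- C %*% fit$sigma %*% t(C)
        Q <- drop(t(ct) %*% MASS::ginv(V) %*% ct)
        stats::pchisq(Q, df, lower.tail = FALSE) < alpha
      } else {
        se2 <- outer(diag(fit$sigma), diag(fit$sigma), "+") - 2 * fit$sigma
        z <- abs(outer(fit$theta, fit$theta, "-")) /
          sqrt(pmax(se2, .Machine$double.eps))
        zmax <- max(z[upper.tri(z)])
        2 * stats::pnorm(-zmax) < alpha / n_p
      }
    }, error = function(e) FALSE)
  }
  p <- mean(rej)
  list(power = p, rejection_se = sqrt(p * (1 - p) / reps),
       reps = reps, n = n)
}

#' Design-stage SIM of the depression-management worked example
#'
#' The two-arm, binary-response, two-options-per-branch SMART used to size
#' the depression-management (CODIACS-like) trial: equal 0.5 randomization
#' probabilities and response rates, sequence means
#' `(1, 8, 11, 10, 9, 6, 20, 12)` and common standard deviation 10 for the
#' eight sequences `(A1, O2, A2)` in lexicographic order.
#'
#' @return A SIM data frame with 8 rows.
#' @export
codiacs_sim <- function() {
  grid <- expand.grid(A2 = 0:1, O2 = 0:1, A1 = 0:1)[, 3:1]
  grid <- grid[order(grid$A1, grid$O2, grid$A2), ]
  data.frame(SEQ = 1:8, A1 = grid$A1, PI1 = 0.5, O2 = grid$O2, P2 = 0.5,
             A2 = grid$A2, PI2 = 0.5,
             MEAN = c(1, 8, 11, 10, 9, 6, 20, 12), SD = 10)
}

#' Synthetic CODIACS-like SMART dataset
#'
#' Generates a synthetic dataset with the *structure* of the CODIACS
#' depression-management SMART: 108 patients, two stage-1 arms (0 = MED,
#' 1 = PST), a binary intermediate response (BDI reduction of at least three
#' points during the step period), re-randomization between the same two
#' options in every branch, and a continuous outcome (BDI reduction at six
#' months).  Sequence means span roughly 1-15 and standard deviations 7-10.
#' This is simulated data for examples and tests — not the deposited CODIACS
#' records, whose values it does not reproduce.
#'
#' @param seed integer seed.
#' @param n number of patients.
#' @return A trial data frame (`A1`, `O2`, `A2`, `Y`).
#' @export
synthetic_codiacs <- function(seed = 2020, n = 108) {
  grid <- expand.grid(A2 = 0:1, O2 = 0:1, A1 = 0:1)[, 3:1]
  grid <- grid[order(grid$A1, grid$O2, grid$A2), ]
  sim <- data.frame(SEQ = 1:8, A1 = grid$A1, PI1 = 0.5, O2 = grid$O2,
                    P2 = 0.5, A2 = grid$A2, PI2 = 0.5,
                    MEAN = c(1.3, 6, 11, 9, 8, 5, 15, 12),
                    SD = c(7.1, 8, 9, 10, 9, 8, 7, 9))
  sim_smart(sim, n = n, seed = seed)
}
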