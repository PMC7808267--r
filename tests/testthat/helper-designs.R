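# Design fixtures and oracles shared across the suite.

# The two-arm alcohol-addiction SMART: arms 1 = CBT, 2 = MED; response
# category 0 = response, 1 = non-response; stage-2 options per branch follow
# the published strategy table (TMC=3, TM=4, MED=1/2, EM+CBT+MED=5).
# extra_option adds a further option (code 6) to every stage-2 branch.
alcohol_sim <- function(extra_option = FALSE) {
  branch <- function(a1, o2, opts) {
    data.frame(A1 = a1, PI1 = 0.5, O2 = o2, P2 = 0.5, A2 = opts,
               PI2 = 1 / length(opts))
  }
  opt <- function(x) if (extra_option) c(x, 6) else x
  tab <- rbind(branch(1, 0, opt(c(3, 4))), branch(1, 1, opt(c(2, 5))),
               branch(2, 0, opt(c(3, 4))), branch(2, 1, opt(c(1, 5))))
  cbind(SEQ = seq_len(nrow(tab)), tab,
        MEAN = seq_len(nrow(tab)), SD = 1)
}

# A design with a degenerate branch: responders to arm 1 are not
# re-randomized (single option, PI2 = 1).
degenerate_sim <- function() {
  data.frame(
    SEQ = 1:6,
    A1 = c(1, 1, 1, 2, 2, 2), PI1 = 0.5,
    O2 = c(0, 1, 1, 0, 0, 1), P2 = c(0.4, 0.6, 0.6, 0.3, 0.3, 0.7),
    A2 = c(9, 2, 5, 3, 4, 9), PI2 = c(1, 0.5, 0.5, 0.5, 0.5, 1),
    MEAN = c(5, 2, 3, 4, 6, 7), SD = 2)
}

# Random full designs for property tests: 1-3 arms, 1-3 response categories
# per arm, 1-3 stage-2 options per branch (guaranteeing G >= 2).
random_sim <- function() {
  repeat {
    n_arms <- sample(1:3, 1)
    pi1 <- as.numeric(stats::rmultinom(1, 20, rep(1, n_arms)) + 1)
    pi1 <- pi1 / sum(pi1)
    rows <- NULL
    G <- 0
    for (a in seq_len(n_arms)) {
      n_cat <- sample(1:3, 1)
      p2 <- as.numeric(stats::rmultinom(1, 20, rep(1, n_cat)) + 1)
      p2 <- p2 / sum(p2)
      g_arm <- 1
      for (r in seq_len(n_cat) - 1) {
        n_opt <- sample(1:3, 1)
        g_arm <- g_arm * n_opt
        pi2 <- as.numeric(stats::rmultinom(1, 20, rep(1, n_opt)) + 1)
        pi2 <- pi2 / sum(pi2)
        rows <- rbind(rows, data.frame(
          A1 = a, PI1 = pi1[a], O2 = r, P2 = p2[r + 1],
          A2 = seq_len(n_opt), PI2 = pi2,
          MEAN = stats::rnorm(n_opt, 0, 3), SD = stats::runif(n_opt, .5, 3)))
      }
      G <- G + g_arm
    }
    if (G >= 2) return(cbind(SEQ = seq_len(nrow(rows)), rows))
  }
}

# Oracle for the global-test degrees of freedom: the numerical rank of C M,
# where M maps sequence means to strategy values at the design's response
# rates (enumerated by brute force, independent of smart_df's closed form).
df_rank_oracle <- function(design) {
  strat <- ats_strategies(design)
  tab <- design$sim
  G <- nrow(strat)
  M <- matrix(0, G, nrow(tab))
  for (g in seq_len(G)) {
    a <- strat$d0[g]
    for (r in design$categories[[as.character(a)]]) {
      a2 <- strat[[paste0("d0", r)]][g]
      k <- which(tab$A1 == a & tab$O2 == r & tab$A2 == a2)
      M[g, k] <- tab$P2[k]
    }
  }
  C <- cbind(1, -diag(G - 1))
  sv <- svd(C %*% M)$d
  sum(sv > 1e-8 * max(sv))
}

numerical_rank <- function(A, tol = 1e-8) {
  sv <- svd(A, nu = 0, nv = 0)$d
  sum(sv > tol * max(sv))
}
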