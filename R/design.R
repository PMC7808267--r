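#' Build a two-stage SMART design from a sequence information matrix
#'
#' A sequence information matrix (SIM) describes every treatment sequence
#' embedded in a two-stage SMART: the stage-1 arm and its randomization
#' probability, the intermediate response category and its expected rate, the
#' stage-2 treatment and its randomization probability, and the mean and
#' standard deviation of the primary outcome for patients following that
#' sequence.  One row per sequence.
#'
#' @param sim a data frame with columns `SEQ`, `A1`, `PI1`, `O2`, `P2`, `A2`,
#'   `PI2`, `MEAN`, `SD`.  `MEAN`/`SD` may be `NA` when the design is used only
#'   for structural work (enumeration, degrees of freedom, consistency).
#' @param tol numeric tolerance for the probability-sum checks.
#'
#' @return An object of class `"smart_design"`: a list with components
#'   `arms` (stage-1 treatment codes, in order of first appearance),
#'   `categories` (per-arm response-category codes, ascending),
#'   `options` (per arm, per category, the ordered stage-2 option codes),
#'   `pi1`, `p2`, `pi2` (randomization probabilities and response rates),
#'   and `sim` (the validated input table).
#'
#' A branch with a single stage-2 option and `PI2 = 1` is a *degenerate*
#' branch (no re-randomization); such designs are fully supported.
#'
#' @examples
#' d <- smart_design(codiacs_sim())
#' d
#' ats_strategies(d)
#' @seealso [ats_strategies()], [smart_df()], [design_moments()]
#' @export
smart_design <- function(sim, tol = 1e-8) {
  required <- c("SEQ", "A1", "PI1", "O2", "P2", "A2", "PI2", "MEAN", "SD")
  if (!is.data.frame(sim) || nrow(sim) == 0L)
    stop("'sim' must be a non-empty data frame")
  missing_cols <- setdiff(required, names(sim))
  if (length(missing_cols))
    stop("SIM is missing column(s): ", paste(missing_cols, collapse = ", "))
  sim <- as.data.frame(sim)[required]
  for (v in setdiff(required, "SEQ"))
    if (!is.numeric(sim[[v]]))
      stop("SIM column '", v, "' must be numeric")

  key <- paste(sim$A1, sim$O2, sim$A2)
  if (anyDuplicated(key)) {
    dup <- sim$SEQ[duplicated(key)]
    stop("duplicate sequence row(s) for (A1,O2,A2); SEQ = ",
         paste(dup, collapse = ", "))
  }
  if (any(sim$PI1 <= 0 | sim$PI1 > 1) || any(sim$PI2 <= 0 | sim$PI2 > 1))
    stop("randomization probabilities must lie in (0, 1]; offending SEQ = ",
         paste(sim$SEQ[sim$PI1 <= 0 | sim$PI1 > 1 |
                       sim$PI2 <= 0 | sim$PI2 > 1], collapse = ", "))
  if (any(sim$P2 <= 0 | sim$P2 > 1))
    stop("response rates P2 must lie in (0, 1]; offending SEQ = ",
         paste(sim$SEQ[sim$P2 <= 0 | sim$P2 > 1], collapse = ", "))
  if (any(!is.na(sim$SD) & sim$SD <= 0))
    stop("SD must be positive; offending SEQ = ",
         paste(sim$SEQ[!is.na(sim$SD) & sim$SD <= 0], collapse = ", "))

  arms <- unique(sim$A1)
  pi1 <- p2 <- list()
  categories <- options <- pi2 <- list()
  for (a in arms) {
    aa <- as.character(a)
    rows_a <- sim[sim$A1 == a, , drop = FALSE]
    if (length(unique(rows_a$PI1)) != 1L)
      stop("PI1 inconsistent within arm ", a, "; SEQ = ",
           paste(rows_a$SEQ, collapse = ", "))
    pi1[[aa]] <- rows_a$PI1[1L]
    cats <- sort(unique(rows_a$O2))
    categories[[aa]] <- cats
    p2a <- numeric(length(cats))
    options[[aa]] <- pi2[[aa]] <- list()
    for (i in seq_along(cats)) {
      r <- cats[i]
      rr <- as.character(r)
      rows_b <- rows_a[rows_a$O2 == r, , drop = FALSE]
      if (length(unique(rows_b$P2)) != 1L)
        stop("P2 inconsistent within branch (A1=", a, ", O2=", r, "); SEQ = ",
             paste(rows_b$SEQ, collapse = ", "))
      p2a[i] <- rows_b$P2[1L]
      options[[aa]][[rr]] <- rows_b$A2
      pi2[[aa]][[rr]] <- rows_b$PI2
      if (abs(sum(rows_b$PI2) - 1) > tol)
        stop("PI2 does not sum to 1 in branch (A1=", a, ", O2=", r,
             "); sum = ", sum(rows_b$PI2), "; SEQ = ",
             paste(rows_b$SEQ, collapse = ", "))
    }
    if (abs(sum(p2a) - 1) > tol)
      stop("P2 does not sum to 1 over response categories of arm ", a,
           "; sum = ", sum(p2a))
    p2[[aa]] <- stats::setNames(p2a, as.character(cats))
  }
  if (abs(sum(unlist(pi1)) - 1) > tol)
    stop("PI1 does not sum to 1 over stage-1 arms; sum = ", sum(unlist(pi1)))

  structure(
    list(arms = arms, categories = categories, options = options,
         pi1 = unlist(pi1), p2 = p2, pi2 = pi2, sim = sim),
    class = "smart_design")
}

#' @export
print.smart_design <- function(x, ...) {
  G <- nrow(ats_strategies(x))
  nb <- sum(vapply(x$options, length, 1L))
  cat("Two-stage SMART design\n")
  cat("  stage-1 arms:      ", paste(x$arms, collapse = ", "), "\n")
  cat("  branches (A1,O2):  ", nb, "\n")
  cat("  sequences:         ", nrow(x$sim), "\n")
  cat("  embedded strategies:", G, "\n")
  deg <- degenerate_branches(x)
  if (nrow(deg))
    cat("  degenerate branches:",
        paste(sprintf("(A1=%s,O2=%s)", deg$A1, deg$O2), collapse = " "), "\n")
  invisible(x)
}

# branches with a single stage-2 option (no re-randomization)
degenerate_branches <- function(design) {
  out <- data.frame(A1 = numeric(0), O2 = numeric(0))
  for (a in design$arms) {
    aa <- as.character(a)
    for (r in design$categories[[aa]])
      if (length(design$options[[aa]][[as.character(r)]]) == 1L)
        out <- rbind(out, data.frame(A1 = a, O2 = r))
  }
  out
}

#' Enumerate the adaptive treatment strategies embedded in a design
#'
#' For each stage-1 arm, strategies are the Cartesian product of the stage-2
#' option sets over the arm's response categories; the overall count is
#' \eqn{G = \sum_{a_1} \prod_r |\mathrm{options}(a_1, r)|}.  Strategies are
#' ordered by arm, then by option order with the last response category
#' varying fastest, which reproduces the conventional strategy tables of
#' two-stage SMART reports.
#'
#' @param design a `"smart_design"` object.
#' @return A data frame with one row per strategy: `ats` (1-based index),
#'   `code` (display string `"(a1;d_r0,d_r1,...)"`), `d0` (stage-1 treatment)
#'   and one `d0<r>` column per response category `r` (`NA` where an arm lacks
#'   that category).  The design and a list-column-free rule table are kept in
#'   attributes `"design"` and `"rules"`.
#' @export
ats_strategies <- function(design) {
  stopifnot(inherits(design, "smart_design"))
  all_cats <- sort(unique(unlist(design$categories)))
  rows <- list()
  for (a in design$arms) {
    aa <- as.character(a)
    cats <- design$categories[[aa]]
    opts <- lapply(as.character(cats), function(r) design$options[[aa]][[r]])
    # Cartesian product, last category fastest
    grid <- expand.grid(rev(opts), KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, rev(seq_along(opts)), drop = FALSE]
    names(grid) <- as.character(cats)
    for (i in seq_len(nrow(grid))) {
      rules <- rep(NA_real_, length(all_cats))
      names(rules) <- as.character(all_cats)
      rules[names(grid)] <- as.numeric(grid[i, ])
      rows[[length(rows) + 1L]] <- c(a1 = a, rules)
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("d0", paste0("d0", all_cats))
  code <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, -1L]
    sprintf("(%g;%s)", tab$d0[i], paste(r[!is.na(r)], collapse = ","))
  }, "")
  out <- cbind(data.frame(ats = seq_len(nrow(tab)), code = code), tab)
  attr(out, "design") <- design
  out
}

#' Patient-strategy consistency
#'
#' A patient record is consistent with a strategy when the observed treatment
#' sequence is one the strategy could have produced: the stage-1 treatments
#' match and the stage-2 treatment equals the strategy's rule for the observed
#' response category.  A patient is therefore typically consistent with
#' several strategies at once, which is what induces covariance between
#' estimated strategy values.
#'
#' @param a1,o2,a2 vectors of observed stage-1 treatment, response category
#'   and stage-2 treatment (recycled to common length).
#' @param strategy a single row of [ats_strategies()] output.
#' @return Logical vector, one element per record.
#' @export
is_consistent <- function(a1, o2, a2, strategy) {
  design <- attr(strategy, "design")
  if (is.null(design) && !is.null(attr(strategy, "strategies")))
    design <- attr(attr(strategy, "strategies"), "design")
  stopifnot(is.data.frame(strategy), nrow(strategy) == 1L)
  n <- max(length(a1), length(o2), length(a2))
  a1 <- rep_len(a1, n); o2 <- rep_len(o2, n); a2 <- rep_len(a2, n)
  if (!is.null(design)) {
    ok <- a1 %in% design$arms
    if (any(ok)) {
      ok[ok] <- mapply(function(a, r) {
        r %in% design$categories[[as.character(a)]]
      }, a1[ok], o2[ok])
    }
    if (!all(ok))
      stop("record(s) outside the design: ",
           paste(which(!ok), collapse = ", "))
  }
  rule <- as.numeric(strategy[paste0("d0", o2)])
  a1 == strategy$d0 & !is.na(rule) & a2 == rule
}

# n x G consistency matrix for all strategies at once
consistency_matrix <- function(a1, o2, a2, strategies) {
  G <- nrow(strategies)
  out <- matrix(FALSE, length(a1), G)
  rule_cols <- paste0("d0", o2)
  for (g in seq_len(G)) {
    rules <- as.numeric(strategies[g, rule_cols])
    out[, g] <- a1 == strategies$d0[g] & !is.na(rules) & a2 == rules
  }
  out
}

#' Degrees of freedom of the global strategy-comparison test
#'
#' The Wald statistic comparing all embedded strategy values is asymptotically
#' chi-squared with degrees of freedom equal to the rank of the space of
#' achievable strategy-value contrasts.  For a two-stage design this rank has
#' the closed form
#' \deqn{\nu = \Big[\sum_{a_1}\Big(\sum_r |\mathrm{options}(a_1,r)| - R(a_1)
#'   + 1\Big)\Big] - 1,}
#' where \eqn{R(a_1)} is the number of response categories of arm \eqn{a_1}.
#' A degenerate branch (one option) contributes nothing, so degenerate designs
#' are handled automatically.
#'
#' @param design a `"smart_design"` object.
#' @return The integer degrees of freedom \eqn{\nu}.
#' @examples
#' smart_df(smart_design(codiacs_sim()))  # 5
#' @export
smart_df <- function(design) {
  stopifnot(inherits(design, "smart_design"))
  per_arm <- vapply(design$arms, function(a) {
    aa <- as.character(a)
    n_opt <- vapply(design$options[[aa]], length, 1L)
    sum(n_opt) - length(design$categories[[aa]]) + 1L
  }, 1L)
  G <- sum(vapply(design$arms, function(a) {
    prod(vapply(design$options[[as.character(a)]], length, 1L))
  }, 1))
  if (G < 2)
    stop("global test undefined: the design embeds a single strategy")
  sum(per_arm) - 1L
}

# Map each record to its sequence row index in design$sim; NA when the
# combination is not part of the design.  Codes are small non-negative
# integers, so an integer encoding avoids string matching in hot loops.
seq_key <- function(a1, o2, a2) a1 * 1e8 + o2 * 1e4 + a2
sequence_index <- function(design, a1, o2, a2) {
  match(seq_key(a1, o2, a2), seq_key(design$sim$A1, design$sim$O2,
                                     design$sim$A2))
}

# Precomputed per-design quantities shared by the estimation cores.
design_context <- function(design) {
  strat <- ats_strategies(design)
  G <- nrow(strat)
  tab <- design$sim
  seq_of <- vector("list", G)
  for (g in seq_len(G)) {
    a <- strat$d0[g]
    cats <- design$categories[[as.character(a)]]
    seq_of[[g]] <- sequence_index(design, rep(a, length(cats)), cats,
                                  as.numeric(strat[g, paste0("d0", cats)]))
  }
  arm_id <- match(tab$A1, design$arms)
  list(strat = strat, G = G, K = nrow(tab), seq_of = seq_of,
       arm_of = match(strat$d0, design$arms), arm_id = arm_id,
       branch_id = match(seq_key(tab$A1, tab$O2, 0),
                         unique(seq_key(tab$A1, tab$O2, 0))))
}

# Build a design skeleton from observed trial data (empirical probabilities,
# moments left to the estimators).
design_from_data <- function(data) {
  n <- nrow(data)
  tab <- unique(data[c("A1", "O2", "A2")])
  tab <- tab[order(tab$A1, tab$O2, tab$A2), , drop = FALSE]
  n_arm <- table(data$A1)
  n_branch <- table(paste(data$A1, data$O2))
  n_seq <- table(paste(data$A1, data$O2, data$A2))
  sim <- data.frame(
    SEQ = seq_len(nrow(tab)), A1 = tab$A1,
    PI1 = as.numeric(n_arm[as.character(tab$A1)]) / n,
    O2 = tab$O2,
    P2 = as.numeric(n_branch[paste(tab$A1, tab$O2)]) /
      as.numeric(n_arm[as.character(tab$A1)]),
    A2 = tab$A2,
    PI2 = as.numeric(n_seq[paste(tab$A1, tab$O2, tab$A2)]) /
      as.numeric(n_branch[paste(tab$A1, tab$O2)]),
    MEAN = NA_real_, SD = NA_real_)
  smart_design(sim)
}
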