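#' Sequence-level descriptive statistics
#'
#' Summarizes a SMART dataset by treatment sequence `(A1, O2, A2)`: number of
#' patients, sample mean, sample variance (denominator `n - 1`) and standard
#' deviation of the primary outcome.  Every patient follows exactly one
#' sequence, so the counts partition the dataset.
#'
#' @param data a data frame of completed-patient records with columns `A1`,
#'   `O2`, `A2`, `Y` (and optionally `O1`).
#' @param family `"gaussian"` for a continuous outcome, `"binomial"` for a
#'   binary one (the mean is then the response proportion).
#' @param digits optional number of decimals used when printing; computation
#'   is never rounded.
#' @param design optional `"smart_design"`: sequences declared by the design
#'   but unobserved are retained with `NA` moments (with a warning).
#' @return A data frame of class `"seqmeans"` with columns `SEQ`, `A1`, `O2`,
#'   `A2`, `N`, `MEAN`, `VAR`, `SD`.  The records are kept in attribute
#'   `"data"` for the summary plot; see [plot.seqmeans()].
#' @examples
#' sm <- seqmeans(synthetic_codiacs(seed = 1))
#' sm
#' @export
seqmeans <- function(data, family = c("gaussian", "binomial"), digits = NULL,
                     design = NULL) {
  family <- match.arg(family)
  data <- validate_trial(data, family)
  if (is.null(design)) {
    tab <- unique(data[c("A1", "O2", "A2")])
    tab <- tab[order(tab$A1, tab$O2, tab$A2), , drop = FALSE]
  } else {
    stopifnot(inherits(design, "smart_design"))
    tab <- design$sim[c("A1", "O2", "A2")]
  }
  key_tab <- paste(tab$A1, tab$O2, tab$A2)
  key_dat <- paste(data$A1, data$O2, data$A2)
  idx <- match(key_dat, key_tab)
  if (anyNA(idx))
    stop("record(s) follow sequences absent from the design: rows ",
         paste(utils::head(which(is.na(idx)), 5L), collapse = ", "))
  n <- tabulate(idx, nbins = nrow(tab))
  s1 <- rowsum_safe(data$Y, idx, nrow(tab))
  s2 <- rowsum_safe(data$Y^2, idx, nrow(tab))
  mean <- ifelse(n > 0, s1 / n, NA_real_)
  var <- ifelse(n > 1, (s2 - n * mean^2) / (n - 1), NA_real_)
  var <- ifelse(!is.na(var) & var < 0, 0, var)  # guard rounding at constant Y
  if (any(n == 0))
    warning("sequence(s) with no observed patients: ",
            paste(key_tab[n == 0], collapse = "; "))
  out <- data.frame(SEQ = seq_len(nrow(tab)), A1 = tab$A1, O2 = tab$O2,
                    A2 = tab$A2, N = n, MEAN = mean, VAR = var,
                    SD = sqrt(var))
  rownames(out) <- NULL
  structure(out, class = c("seqmeans", "data.frame"),
            family = family, digits = digits, data = data)
}

rowsum_safe <- function(x, idx, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' @export
print.seqmeans <- function(x, digits = attr(x, "digits"), ...) {
  y <- as.data.frame(x)
  if (!is.null(digits))
    for (v in c("MEAN", "VAR", "SD")) y[[v]] <- round(y[[v]], digits)
  print(y, ...)
  invisible(x)
}

validate_trial <- function(data, family = "gaussian") {
  required <- c("A1", "O2", "A2", "Y")
  miss <- setdiff(required, names(data))
  if (length(miss))
    stop("trial data is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stop("no records")
  for (v in required)
    if (!is.numeric(data[[v]]))
      stop("trial data column '", v, "' must be numeric")
  if (any(!is.finite(data$Y))) stop("Y must be finite")
  if (family == "binomial" && !all(data$Y %in% c(0, 1)))
    stop("binomial family requires Y in {0, 1}")
  data
}

#' Strategy-level estimates with covariance
#'
#' Estimates the value of every adaptive treatment strategy embedded in the
#' data, together with the full covariance matrix of the estimates, by
#' G-computation (default) or inverse-probability weighting.
#'
#' *G-computation* combines per-sequence outcome means with the empirical
#' response-category proportions of the arm:
#' \eqn{\hat\theta_g = \sum_r \hat p_r(a_1) \bar Y(a_1, r, d_g(r))}.  Its
#' covariance is the plug-in delta-method form (see [design_moments()]),
#' block-diagonal across stage-1 arms.  *IPW* weights each consistent patient
#' by the reciprocal product of their randomization probabilities,
#' \eqn{\hat\theta_g = \sum_i w_i Y_i 1_i(g) / \sum_i w_i 1_i(g)}, with
#' covariance from empirical cross-products of influence functions.
#'
#' A patient consistent with several strategies contributes to each of them,
#' so the per-strategy counts `N` sum to more than the number of patients.
#'
#' @param data trial records (`A1`, `O2`, `A2`, `Y`).
#' @param method `"gcomp"`/`"Gest"` or `"ipw"`/`"IPW"`.
#' @param common logical; pool the sequence variances across the whole trial
#'   (G-computation only).  With the binomial family the pooled variance is
#'   taken from the pooled response proportion.
#' @param conf logical; attach `1 - alpha` confidence limits (normal
#'   quantiles).
#' @param alpha confidence/test level, default 0.05.
#' @param digits optional print rounding (display only).
#' @param design optional `"smart_design"`; inferred from the data when
#'   omitted.
#' @param family `"gaussian"` or `"binomial"`.
#' @param probs for IPW, `"design"` to use the design's randomization
#'   probabilities (requires `design`) or `"empirical"` (default) to use
#'   observed frequencies.
#' @return An object of class `"atsmeans"`: list with `value` (data frame:
#'   `ats`, `d0`, `d0<r>` columns, `N`, `value`, `se`, `lower`, `upper`),
#'   `covariance` (G-by-G), `n`, `df`, `strategies`, `design`, `method`,
#'   `family`, `alpha`.
#' @examples
#' est <- atsmeans(synthetic_codiacs(seed = 1))
#' est
#' @export
atsmeans <- function(data, method = c("gcomp", "ipw"), common = FALSE,
                     conf = TRUE, alpha = 0.05, digits = NULL, design = NULL,
                     family = c("gaussian", "binomial"),
                     probs = c("empirical", "design")) {
  method <- normalize_method(method)
  family <- match.arg(family)
  probs <- match.arg(probs)
  data <- validate_trial(data, family)
  if (is.null(design)) design <- design_from_data(data)
  fit <- if (method == "gcomp") {
    fit_gcomp(data, design, family = family, common = common)
  } else {
    fit_ipw(data, design, family = family, probs = probs)
  }
  strat <- fit$strategies
  se <- sqrt(diag(fit$sigma))
  z <- stats::qnorm(1 - alpha / 2)
  value <- cbind(strat[setdiff(names(strat), "code")][1L],
                 strat[setdiff(names(strat), c("ats", "code"))],
                 data.frame(N = fit$n_consistent, value = fit$theta, se = se))
  rownames(value) <- NULL
  if (conf) {
    value$lower <- fit$theta - z * se
    value$upper <- fit$theta + z * se
  }
  structure(list(value = value, covariance = fit$sigma, n = nrow(data),
                 df = smart_df(design), strategies = strat, design = design,
                 method = method, family = family, alpha = alpha,
                 digits = digits),
            class = "atsmeans")
}

#' @export
print.atsmeans <- function(x, digits = x$digits, ...) {
  cat(sprintf(
    "Strategy values (%s estimation, %d patients, %d strategies)\n",
    if (x$method == "gcomp") "G-computation" else "IPW",
    x$n, nrow(x$value)))
  v <- x$value
  cv <- x$covariance
  if (!is.null(digits)) {
    for (nm in c("value", "se", "lower", "upper"))
      if (nm %in% names(v)) v[[nm]] <- round(v[[nm]], digits)
    cv <- round(cv, digits)
  }
  cat("\n$value\n"); print(v, ...)
  cat("\n$covariance\n"); print(cv, ...)
  invisible(x)
}

# ---- estimation cores (shared by atsmeans / smartest / simulations) --------

# G-computation values and plug-in delta-method covariance.
fit_gcomp <- function(data, design, family = "gaussian", common = FALSE,
                      ctx = NULL) {
  if (is.null(ctx)) ctx <- design_context(design)
  strat <- ctx$strat
  G <- ctx$G
  K <- ctx$K
  tab <- design$sim
  idx <- sequence_index(design, data$A1, data$O2, data$A2)
  if (anyNA(idx))
    stop("record(s) follow sequences absent from the design: rows ",
         paste(utils::head(which(is.na(idx)), 5L), collapse = ", "))
  n <- nrow(data)
  n_seq <- tabulate(idx, nbins = K)
  ybar <- ifelse(n_seq > 0, rowsum_safe(data$Y, idx, K) / n_seq, NA_real_)
  ss <- rowsum_safe(data$Y^2, idx, K) - n_seq * ifelse(n_seq > 0, ybar^2, 0)
  s2 <- ifelse(n_seq > 1, pmax(ss, 0) / (n_seq - 1), NA_real_)
  if (family == "binomial") s2 <- ybar * (1 - ybar)
  if (common) {
    s2 <- if (family == "binomial") {
      p <- mean(data$Y); rep(p * (1 - p), K)
    } else {
      rep(sum(pmax(ss, 0)) / (n - sum(n_seq > 0)), K)
    }
  }
  n_arm_seq <- rowsum_safe(n_seq, ctx$arm_id, max(ctx$arm_id))    # per arm
  n_branch <- rowsum_safe(n_seq, ctx$branch_id, max(ctx$branch_id))
  p_hat <- (n_branch[ctx$branch_id]) / (n_arm_seq[ctx$arm_id])

  theta <- numeric(G)
  for (g in seq_len(G)) {
    sq <- ctx$seq_of[[g]]
    if (any(n_seq[sq] == 0))
      stop("strategy ", strat$code[g], " requires empty sequence(s): SEQ = ",
           paste(tab$SEQ[sq][n_seq[sq] == 0], collapse = ", "))
    theta[g] <- sum(p_hat[sq] * ybar[sq])
  }
  sigma <- matrix(0, G, G, dimnames = list(strat$code, strat$code))
  for (g in seq_len(G)) for (h in seq_len(g)) {
    if (ctx$arm_of[g] != ctx$arm_of[h]) next
    ig <- ctx$seq_of[[g]]; ih <- ctx$seq_of[[h]]
    shared <- ig == ih
    v <- sum((p_hat[ig]^2 * s2[ig] / n_seq[ig])[shared])
    p <- p_hat[ig]
    na <- n_arm_seq[ctx$arm_of[g]]
    yg <- ybar[ig]; yh <- ybar[ih]
    v <- v + (sum(p * yg * yh) - sum(p * yg) * sum(p * yh)) / na
    sigma[g, h] <- sigma[h, g] <- v
  }
  n_cons <- vapply(ctx$seq_of, function(sq) sum(n_seq[sq]), 1)
  list(theta = stats::setNames(theta, strat$code), sigma = sigma,
       n_consistent = n_cons, strategies = strat, n = n)
}

# IPW (weighted-mean) values and influence-function covariance.
fit_ipw <- function(data, design, family = "gaussian", probs = "empirical",
                    ctx = NULL) {
  if (is.null(ctx)) ctx <- design_context(design)
  strat <- ctx$strat
  G <- ctx$G
  n <- nrow(data)
  tab <- design$sim
  idx <- sequence_index(design, data$A1, data$O2, data$A2)
  if (anyNA(idx))
    stop("record(s) follow sequences absent from the design: rows ",
         paste(utils::head(which(is.na(idx)), 5L), collapse = ", "))
  if (probs == "design") {
    pi1 <- tab$PI1[idx]
    pi2 <- tab$PI2[idx]
  } else {
    n_seq <- tabulate(idx, nbins = ctx$K)
    n_arm <- rowsum_safe(n_seq, ctx$arm_id, max(ctx$arm_id))
    n_branch <- rowsum_safe(n_seq, ctx$branch_id, max(ctx$branch_id))
    pi1 <- (n_arm[ctx$arm_id] / n)[idx]
    pi2 <- (n_seq / n_branch[ctx$branch_id])[idx]
  }
  if (any(pi1 <= 0 | pi2 <= 0)) stop("nonpositive randomization probability")
  w <- 1 / (pi1 * pi2)
  # membership of each record's sequence in each strategy's sequence set
  mem <- matrix(FALSE, ctx$K, G)
  for (g in seq_len(G)) mem[ctx$seq_of[[g]], g] <- TRUE
  theta <- numeric(G)
  IF <- matrix(0, n, G)
  for (g in seq_len(G)) {
    wg <- w * mem[idx, g]
    sw <- sum(wg)
    if (sw <= 0)
      stop("strategy ", strat$code[g], " has zero total weight")
    theta[g] <- sum(wg * data$Y) / sw
    IF[, g] <- wg * (data$Y - theta[g]) / (sw / n)
  }
  sigma <- crossprod(IF) / n / n
  dimnames(sigma) <- list(strat$code, strat$code)
  n_cons <- colSums(mem[idx, , drop = FALSE])
  list(theta = stats::setNames(theta, strat$code), sigma = sigma,
       n_consistent = n_cons, strategies = strat, n = n)
}
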