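# Reference-anchored compositional abundance testing.
#
# A maximum-likelihood Dirichlet-multinomial regression: counts y_s for
# sample s follow DirMult(n_s, alpha_s) with
#   log alpha_{s,c} = beta0_c + beta_c * x_s,
# x_s the binary condition indicator and beta fixed to 0 for a declared
# reference category so relative shifts are identifiable. Each category's
# condition effect is tested by a likelihood-ratio test with BH correction;
# categories with q below the FDR level (default 20%) are flagged.

#' Assemble a samples-by-categories count table for abundance testing
#'
#' @param counts numeric matrix, samples in rows, categories in columns
#'   (named).
#' @param condition factor/character per sample; exactly 2 levels, first
#'   level = reference condition.
#' @param reference reference category (column) whose condition effect is
#'   fixed at zero.
#' @param pseudocount added to every count before fitting (default 0.001).
#' @return a `count_table` list.
#' @export
count_table <- function(counts, condition, reference, pseudocount = 0.001) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop_schema("category columns must be named")
  if (any(counts < 0)) stop_integrity("negative counts")
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) {
    stop_config("condition must have exactly 2 levels")
  }
  if (length(condition) != nrow(counts)) {
    stop_integrity("condition length does not match sample rows")
  }
  if (any(table(condition) < 2)) {
    stop_config("need at least 2 samples per condition")
  }
  if (!reference %in% colnames(counts)) {
    stop_config("reference category '", reference, "' not in columns")
  }
  absent <- colSums(counts) == 0
  if (any(absent)) {
    warning("dropping categories absent everywhere: ",
            paste(colnames(counts)[absent], collapse = ", "))
    counts <- counts[, !absent, drop = FALSE]
    if (!reference %in% colnames(counts)) {
      stop_config("reference category was absent everywhere")
    }
  }
  structure(list(counts = counts, condition = condition,
                 reference = reference, pseudocount = pseudocount),
            class = "count_table")
}

# Dirichlet-multinomial log-likelihood and analytic gradient.
# y: samples x categories (pseudocounted), x: 0/1 vector,
# par = c(beta0 [C], beta[free]) with free = categories excluding the
# reference and any fixed-out category.
dm_loglik <- function(par, y, x, free_idx, C) {
  beta0 <- par[seq_len(C)]
  beta <- rep(0, C)
  beta[free_idx] <- par[-seq_len(C)]
  eta <- outer(x, beta) + matrix(beta0, length(x), C, byrow = TRUE)
  alpha <- exp(eta)
  A <- rowSums(alpha)
  n <- rowSums(y)
  # lgamma(A) - lgamma(n + A) = lbeta(A, n) - lgamma(n), and
  # lgamma(y + a) - lgamma(a) = lgamma(y) - lbeta(a, y): both stable for
  # large concentrations where the raw lgamma difference cancels.
  ll <- sum(lbeta(A, n) - lgamma(n)) + sum(lgamma(y) - lbeta(alpha, y))
  if (!is.finite(ll)) ll <- -1e300
  ll
}

dm_grad <- function(par, y, x, free_idx, C) {
  beta0 <- par[seq_len(C)]
  beta <- rep(0, C)
  beta[free_idx] <- par[-seq_len(C)]
  eta <- outer(x, beta) + matrix(beta0, length(x), C, byrow = TRUE)
  alpha <- exp(eta)
  A <- rowSums(alpha)
  n <- rowSums(y)
  # d ll / d alpha_{s,c}
  dA <- digamma(A) - digamma(n + A)
  dal <- matrix(dA, length(x), C) + digamma(y + alpha) - digamma(alpha)
  dal <- dal * alpha  # chain through alpha = exp(eta)
  g0 <- colSums(dal)
  g1 <- colSums(dal * x)[free_idx]
  c(g0, g1)
}

fit_dm <- function(y, x, free_idx, C, init) {
  fit <- stats::optim(init, fn = dm_loglik, gr = dm_grad,
                      y = y, x = x, free_idx = free_idx, C = C,
                      method = "L-BFGS-B", lower = -50, upper = 50,
                      control = list(fnscale = -1, maxit = 1000,
                                     factr = 1e4))
  if (fit$convergence != 0) {
    stop("Dirichlet-multinomial fit did not converge (optim code ",
         fit$convergence, "): ", fit$message %||% "", call. = FALSE)
  }
  fit
}

#' Test differential abundance between two conditions
#'
#' @param tab a [count_table()].
#' @param fdr flag categories with BH q-value below this level
#'   (default 0.20).
#' @return an `abundance_result` data.frame: one row per category with
#'   `beta` (log-scale condition coefficient, exactly 0 for the reference),
#'   `log2_fc` (log2 fold change of fitted relative abundance),
#'   `p_value` (LRT), `q_value` (BH) and `credible` (q < fdr; reference is
#'   never flagged). Attribute `loglik` carries the full-model fit.
#' @export
test_abundance <- function(tab, fdr = 0.20) {
  stopifnot(inherits(tab, "count_table"))
  y <- tab$counts + tab$pseudocount
  x <- as.numeric(tab$condition == levels(tab$condition)[2])
  C <- ncol(y)
  cats <- colnames(y)
  ref <- match(tab$reference, cats)
  free_idx <- setdiff(seq_len(C), ref)

  props <- colSums(y) / sum(y)
  init <- c(log(props * 50), rep(0, length(free_idx)))
  full <- fit_dm(y, x, free_idx, C, init)

  beta0 <- full$par[seq_len(C)]
  beta <- rep(0, C)
  beta[free_idx] <- full$par[-seq_len(C)]

  p <- rep(NA_real_, C)
  for (c_i in free_idx) {
    sub_free <- setdiff(free_idx, c_i)
    init0 <- c(beta0, beta[sub_free])
    fit0 <- fit_dm(y, x, sub_free, C, init0)
    lrt <- 2 * (full$value - fit0$value)
    p[c_i] <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  }
  q <- rep(NA_real_, C)
  q[free_idx] <- stats::p.adjust(p[free_idx], method = "BH")

  # fold change of fitted relative abundance (proportions)
  a0 <- exp(beta0); a1 <- exp(beta0 + beta)
  pi0 <- a0 / sum(a0); pi1 <- a1 / sum(a1)
  out <- data.frame(category = cats, beta = beta,
                    log2_fc = log2(pi1 / pi0),
                    p_value = p, q_value = q,
                    credible = !is.na(q) & q < fdr,
                    stringsAsFactors = FALSE)
  out$beta[ref] <- 0
  out$credible[ref] <- FALSE
  attr(out, "loglik") <- full$value
  attr(out, "reference") <- tab$reference
  attr(out, "fdr") <- fdr
  class(out) <- c("abundance_result", "data.frame")
  out
}
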