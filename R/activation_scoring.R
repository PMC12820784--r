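# Dual-stimulation synergy algebra, signature derivation, single-sample
# gene-set enrichment, ordered-probit severity association and deconvolution
# marker selection.

#' Additive vs synergistic expectation for a dual stimulus
#'
#' With baseline response `X` and single-stimulus increments `dA`, `dB`, the
#' additive expectation is `X + dA + dB` and the synergistic
#' (multiplicative-fold) expectation is
#' `X * ((X + dA)/X) * ((X + dB)/X) = X + dA + dB + dA*dB/X`,
#' so the two differ by exactly `dA * dB / X`. When an observed dual
#' response is supplied it is classified against the additive expectation
#' with relative tolerance `tol`.
#'
#' @param x_baseline baseline response (> 0).
#' @param delta_a,delta_b increments over baseline under each single
#'   stimulus (each at least `-x_baseline`).
#' @param observed_dual optional measured dual response.
#' @param tol relative tolerance for the additive call (default 0.1).
#' @return a `synergy_result` list with `e_additive`, `e_synergistic`,
#'   `gap` (their difference) and, when observed, `classification` in
#'   `"sub-additive"`, `"additive"`, `"synergistic"`.
#' @export
synergy_statistic <- function(x_baseline, delta_a, delta_b,
                              observed_dual = NULL, tol = 0.1) {
  if (x_baseline <= 0) stop("x_baseline must be > 0", call. = FALSE)
  if (delta_a < -x_baseline || delta_b < -x_baseline) {
    stop("increments cannot drop the response below zero", call. = FALSE)
  }
  e_add <- x_baseline + delta_a + delta_b
  e_syn <- x_baseline * ((x_baseline + delta_a) / x_baseline) *
    ((x_baseline + delta_b) / x_baseline)
  cls <- NULL
  if (!is.null(observed_dual)) {
    cls <- if (observed_dual > e_add * (1 + tol)) "synergistic"
    else if (observed_dual < e_add * (1 - tol)) "sub-additive"
    else "additive"
  }
  structure(list(e_additive = e_add, e_synergistic = e_syn,
                 gap = e_syn - e_add, observed = observed_dual,
                 classification = cls, tol = tol),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("additive expectation:", format(x$e_additive), "\n")
  cat("synergistic expectation:", format(x$e_synergistic), "\n")
  if (!is.null(x$classification)) {
    cat("observed", format(x$observed), "->", x$classification, "\n")
  }
  invisible(x)
}

#' Derive effector and core signature gene sets from multi-assay evidence
#'
#' Effector genes are down in the knockout and up in the activation DE
#' tables at adjusted p below `p_max`; the core signature additionally
#' requires the gene to be bound (e.g. ChIP peaks) and cell-type specific.
#'
#' @param de_ko knockout-vs-control [de_table()] (effectors are down here).
#' @param de_act activation-vs-control [de_table()] (effectors are up here).
#' @param bound_genes genes with regulator-bound peaks.
#' @param specific_genes cell-type-specific transcripts.
#' @param p_max adjusted-p threshold (default 0.05).
#' @return a `signature_set` list with `effector` and `core` gene vectors.
#' @export
derive_signature <- function(de_ko, de_act, bound_genes, specific_genes,
                             p_max = 0.05) {
  for (de in list(de_ko, de_act)) {
    if (!inherits(de, "de_table")) stop_schema("DE input must be a de_table")
    if (all(is.na(de$adjusted_p))) stop_schema("adjusted_p column is empty")
  }
  down_ko <- de_ko$gene[!is.na(de_ko$adjusted_p) & de_ko$adjusted_p < p_max &
                          de_ko$log_fold_change < 0]
  up_act <- de_act$gene[!is.na(de_act$adjusted_p) & de_act$adjusted_p < p_max &
                          de_act$log_fold_change > 0]
  effector <- sort(intersect(unique(down_ko), unique(up_act)))
  core <- sort(intersect(intersect(effector, bound_genes), specific_genes))
  structure(list(effector = effector, core = core), class = "signature_set")
}

#' Refine a core signature to individually severity-predictive genes
#'
#' Each core gene's expression is used alone as the predictor in an ordered
#' probit of severity; genes with one-sided Bonferroni-adjusted p below
#' `alpha` are retained. The refined set is always a subset of the core.
#'
#' @param profiles genes x subjects expression matrix.
#' @param severity ordinal severity per subject.
#' @param core character vector of core signature genes.
#' @param alpha Bonferroni-adjusted significance level (default 0.05).
#' @return character vector of refined signature genes.
#' @export
refine_signature <- function(profiles, severity, core, alpha = 0.05) {
  core <- intersect(core, rownames(profiles))
  if (!length(core)) return(character(0))
  p <- vapply(core, function(g) {
    fit <- try(ordered_probit(profiles[g, ], severity), silent = TRUE)
    if (inherits(fit, "try-error")) 1 else fit$p_one_sided
  }, numeric(1))
  sort(core[pmin(1, p * length(core)) < alpha])
}

#' Single-sample gene-set enrichment score
#'
#' Genes are ranked by expression in descending order (ties broken by gene
#' label) and a running sum accumulates the difference between the weighted
#' in-set ECDF -- in-set steps weighted by `(N - position + 1)^alpha`, i.e.
#' the descending rank raised to `alpha` -- and the unweighted out-of-set
#' ECDF; the score is the sum of that difference over all positions. Being
#' rank-based, the score is invariant under strictly monotone transforms of
#' the expression values.
#'
#' @param profile named expression vector for one sample.
#' @param gene_set character vector; must be a non-empty proper subset of
#'   the profile's genes.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return numeric enrichment score.
#' @export
ssgsea_score <- function(profile, gene_set, alpha = 0.25) {
  if (is.null(names(profile))) stop("profile must be named", call. = FALSE)
  gene_set <- unique(gene_set)
  in_set <- names(profile) %in% gene_set
  if (!any(in_set) || all(in_set)) {
    stop("gene set must be a non-empty proper subset of profile genes",
         call. = FALSE)
  }
  ord <- order(-profile, names(profile))
  in_set <- in_set[ord]
  N <- length(profile)
  w <- (N - seq_len(N) + 1)^alpha
  w[!in_set] <- 0
  ecdf_in <- cumsum(w) / sum(w)
  ecdf_out <- cumsum(!in_set) / sum(!in_set)
  sum(ecdf_in - ecdf_out)
}

#' Score every sample of a matrix against a gene set
#'
#' @param profiles genes x samples matrix.
#' @param gene_set gene set.
#' @param alpha rank-weighting exponent.
#' @param normalize min-max normalize scores across the cohort (flagged in
#'   the result's `normalized` attribute).
#' @return named numeric vector of per-sample scores.
#' @export
ssgsea_matrix <- function(profiles, gene_set, alpha = 0.25,
                          normalize = FALSE) {
  scores <- vapply(seq_len(ncol(profiles)), function(j) {
    ssgsea_score(profiles[, j], gene_set, alpha)
  }, numeric(1))
  names(scores) <- colnames(profiles)
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  attr(scores, "normalized") <- normalize
  scores
}

#' Ordered probit regression of an ordinal response on one predictor
#'
#' Maximum likelihood for `P(y = j) = Phi(tau_j - beta z) -
#' Phi(tau_{j-1} - beta z)` with strictly increasing cutpoints, enforced by
#' optimizing the first cutpoint and the log-gaps between consecutive
#' cutpoints. Reports the slope, cutpoints, standard errors from the
#' observed information, and the one-sided Wald p for `beta > 0`.
#'
#' @param z numeric predictor per subject.
#' @param y ordinal response (ordered factor or integer-coded); every level
#'   in use needs at least one subject, `J >= 2`.
#' @return a `probit_fit` list with `beta`, `cutpoints`, `se_beta`,
#'   `p_one_sided`, `loglik`, `n`.
#' @export
ordered_probit <- function(z, y) {
  z <- as.numeric(z)
  if (is.factor(y)) y <- as.integer(droplevels(y)) else y <- as.integer(factor(y))
  stopifnot(length(z) == length(y), !anyNA(z), !anyNA(y))
  J <- max(y)
  if (J < 2) stop("need at least 2 response categories", call. = FALSE)
  n <- length(y)
  # perfect separation: the predictor completely orders the categories, so
  # the slope MLE diverges
  rng <- vapply(seq_len(J), function(j) range(z[y == j]), numeric(2))
  if (all(rng[2, -J] < rng[1, -1]) || all(rng[1, -J] > rng[2, -1])) {
    stop("perfect separation: predictor completely orders the ",
         "severity categories; the slope estimate is unbounded",
         call. = FALSE)
  }

  nll <- function(par) {
    beta <- par[1]
    tau <- cumsum(c(par[2], exp(par[-(1:2)])))
    lo <- c(-Inf, tau)[y]
    hi <- c(tau, Inf)[y]
    pr <- stats::pnorm(hi - beta * z) - stats::pnorm(lo - beta * z)
    -sum(log(pmax(pr, 1e-300)))
  }
  # initialize cutpoints at the empirical marginal quantiles
  cum <- cumsum(tabulate(y, J))[-J] / n
  tau0 <- stats::qnorm(pmin(pmax(cum, 1e-3), 1 - 1e-3))
  gaps <- diff(tau0)
  init <- c(0, tau0[1], if (J > 2) log(pmax(gaps, 1e-3)))
  fit <- stats::optim(init, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1000, reltol = 1e-12))
  if (fit$convergence != 0) {
    stop("ordered probit did not converge (optim code ", fit$convergence, ")",
         call. = FALSE)
  }
  beta <- fit$par[1]
  tau <- cumsum(c(fit$par[2], exp(fit$par[-(1:2)])))
  vc <- try(solve(fit$hessian), silent = TRUE)
  if (inherits(vc, "try-error") || any(!is.finite(diag(vc))) ||
      any(diag(vc) <= 0) || abs(beta) > 50) {
    stop("ordered probit information matrix is singular; the data may be ",
         "perfectly separated", call. = FALSE)
  }
  se_beta <- sqrt(vc[1, 1])
  zstat <- beta / se_beta
  structure(list(beta = beta, cutpoints = tau, se_beta = se_beta,
                 z = zstat,
                 p_one_sided = stats::pnorm(zstat, lower.tail = FALSE),
                 loglik = -fit$value, n = n, J = J),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("ordered probit: beta =", format(x$beta, digits = 4),
      "(se", format(x$se_beta, digits = 3), "), one-sided p =",
      format(x$p_one_sided, digits = 3), "\n")
  cat("cutpoints:", paste(format(x$cutpoints, digits = 3), collapse = " "),
      "\n")
  invisible(x)
}

#' Select cell-type marker genes for bulk deconvolution
#'
#' Applies the three-way filter: raw `p_value` below `p_max` (default
#' 1e-8), log-scale fold change at least `min_lfc` (default 0.75), and
#' background expressing fraction below `max_frac_bg` (default 0.20).
#'
#' @param de a [de_table()] of one-vs-rest results.
#' @param p_max,min_lfc,max_frac_bg thresholds.
#' @return named list: per cell type, the character vector of marker genes.
#' @export
select_deconv_markers <- function(de, p_max = 1e-8, min_lfc = 0.75,
                                  max_frac_bg = 0.20) {
  stopifnot(inherits(de, "de_table"))
  keep <- de$p_value < p_max & de$log_fold_change >= min_lfc &
    de$frac_bg < max_frac_bg
  sel <- de[keep, ]
  lapply(split(sel$gene, sel$group), sort)
}
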