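# Synthetic bulk cohort with ordinal severity driven by a planted gene
# signature, and Dirichlet-multinomial composition tables for abundance
# testing.

#' Build a cohort simulation configuration
#'
#' Each subject has a latent signature level `s ~ Normal(0, 1)`; signature
#' genes shift with `s`, and ordinal severity is the fixed-threshold bin of
#' `u ~ Normal(beta_true * s, 1)`. Thresholds are the marginal quantiles of
#' `u` so categories are balanced by construction.
#'
#' @param n_subjects cohort size.
#' @param n_signature_genes planted signature size (default 50).
#' @param n_background_genes unrelated genes.
#' @param beta_true latent effect of the signature level on severity.
#' @param gene_effect log-expression shift per unit `s` for signature genes.
#' @param noise_sd log-expression noise.
#' @param n_categories ordinal severity levels `J >= 2`.
#' @param seed master seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 200, n_signature_genes = 50,
                          n_background_genes = 450, beta_true = 2,
                          gene_effect = 1, noise_sd = 0.5,
                          n_categories = 4, seed = 1L) {
  if (n_categories < 2) stop_config("need at least 2 severity categories")
  structure(list(n_subjects = n_subjects,
                 n_signature_genes = n_signature_genes,
                 n_background_genes = n_background_genes,
                 beta_true = beta_true, gene_effect = gene_effect,
                 noise_sd = noise_sd, n_categories = n_categories,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort of bulk profiles with ordinal severity
#'
#' @param config a [cohort_config()].
#' @return list with `profiles` (genes x subjects log-expression matrix),
#'   `severity` (ordered factor, lowest = least severe), and `truth`
#'   (`signature` gene names, per-subject latent `s`, `beta_true`,
#'   thresholds used).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  J <- config$n_categories
  n <- config$n_subjects
  sig_genes <- sprintf("SIG%03d", seq_len(config$n_signature_genes))
  bg_genes <- sprintf("BG%03d", seq_len(config$n_background_genes))
  genes <- c(sig_genes, bg_genes)
  # fixed thresholds: marginal quantiles of u ~ N(0, beta^2 + 1)
  tau <- stats::qnorm(seq_len(J - 1) / J, sd = sqrt(config$beta_true^2 + 1))

  seeds <- seed_stream(config$seed, 3)
  s <- with_seed(seeds[1], stats::rnorm(n))
  u <- with_seed(seeds[2], config$beta_true * s + stats::rnorm(n))
  severity <- cut(u, breaks = c(-Inf, tau, Inf), labels = FALSE)
  severity <- factor(severity, levels = seq_len(J), ordered = TRUE)

  profiles <- with_seed(seeds[3], {
    mu <- stats::runif(length(genes), 1, 3)
    m <- matrix(stats::rnorm(length(genes) * n, mu, config$noise_sd),
                nrow = length(genes),
                dimnames = list(genes, sprintf("subj%04d", seq_len(n))))
    m[sig_genes, ] <- m[sig_genes, ] +
      config$gene_effect * matrix(s, length(sig_genes), n, byrow = TRUE)
    m
  })
  list(profiles = profiles, severity = severity,
       truth = list(signature = sig_genes, s = s,
                    beta_true = config$beta_true, thresholds = tau))
}

#' Simulate a samples-by-categories composition count table
#'
#' Per-sample compositions are Dirichlet draws around condition-specific
#' base proportions; counts are multinomial. Used as ground truth for the
#' differential-abundance model.
#'
#' @param n_per_group integer length-2: samples in the reference and in the
#'   alternative condition.
#' @param base_props named baseline category proportions (sum to 1).
#' @param effect named multipliers applied to `base_props` in the
#'   alternative condition (renormalized); `NULL` for a null table.
#' @param cells_per_sample multinomial total per sample.
#' @param concentration Dirichlet concentration (larger = less
#'   sample-to-sample compositional noise).
#' @param seed integer seed.
#' @return list with `counts` (samples x categories), `condition` (factor,
#'   first level = reference condition).
#' @export
simulate_composition_counts <- function(n_per_group = c(20, 20),
                                        base_props,
                                        effect = NULL,
                                        cells_per_sample = 2000,
                                        concentration = 50,
                                        seed = 1L) {
  stopifnot(abs(sum(base_props) - 1) < 1e-8, !is.null(names(base_props)))
  props2 <- base_props
  if (!is.null(effect)) {
    props2[names(effect)] <- props2[names(effect)] * effect
    props2 <- props2 / sum(props2)
  }
  n <- sum(n_per_group)
  condition <- factor(rep(c("ref_cond", "alt_cond"), n_per_group),
                      levels = c("ref_cond", "alt_cond"))
  counts <- with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      p <- if (condition[i] == "ref_cond") base_props else props2
      a <- stats::rgamma(length(p), shape = concentration * p)
      stats::rmultinom(1, cells_per_sample, a / sum(a))[, 1]
    }, numeric(length(base_props))))
  })
  colnames(counts) <- names(base_props)
  rownames(counts) <- sprintf("s%03d", seq_len(n))
  list(counts = counts, condition = condition)
}
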