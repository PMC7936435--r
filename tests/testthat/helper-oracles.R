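# Independent brute-force oracles, deliberately coded from the definitions
# rather than via the package's own code paths (or the shortcuts it uses).

# average ranks, then the explicit Pearson product-moment formula
oracle_spearman <- function(x, y) {
  cc <- !is.na(x) & !is.na(y)
  xr <- rank(x[cc])
  yr <- rank(y[cc])
  dx <- xr - mean(xr)
  dy <- yr - mean(yr)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# step-up BH from the definition: adj(i) = min_{j >= i} m * p_(j) / j
oracle_bh <- function(p, m) {
  ord <- order(p)
  k <- length(p)
  adj <- numeric(k)
  sorted <- p[ord]
  for (i in seq_len(k)) {
    adj[i] <- min(1, min(m * sorted[i:k] / seq(i, k)))
  }
  out <- numeric(k)
  out[ord] <- adj
  out
}

# per-(region, sample) mean of non-missing betas, plain loops
oracle_region_means <- function(beta, index) {
  index <- index[vapply(index, function(p) any(p %in% rownames(beta)),
                        logical(1))]
  out <- matrix(NA_real_, length(index), ncol(beta),
                dimnames = list(names(index), colnames(beta)))
  for (r in names(index)) {
    probes <- intersect(index[[r]], rownames(beta))
    for (s in colnames(beta)) {
      v <- beta[probes, s]
      out[r, s] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
  }
  out[order(rownames(out)), , drop = FALSE]
}

# small beta_matrix fixture with controllable missingness
random_beta_fixture <- function(n_probes, n_samples, na_frac = 0,
                                seed = 11) {
  set.seed(seed)
  b <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("cg%07d", seq_len(n_probes)),
                              sprintf("CL%04d", seq_len(n_samples))))
  if (na_frac > 0) b[sample(length(b), round(na_frac * length(b)))] <- NA
  b
}

# panel configuration used by the planted-chain studies: one trans
# expression-methylation plant feeding one methylation-drug plant
chain_config <- function(seed, n = 600, rho_meth = 0.7, rho_drug = -0.6) {
  panel_config(
    n_cell_lines = n,
    category_sizes = c(n - 3 * floor(n / 4), rep(floor(n / 4), 3)),
    n_gmds = 12, n_target_genes = 12, probes_per_region = 3,
    n_agents = 15, n_intergenic_probes = 20,
    planted_effects = list(
      planted_effect("expr_meth_trans", "GMD01", "cg0000300", rho_meth),
      planted_effect("meth_drug", "cg0000300", "AGT01@GDSC", rho_drug)),
    detection_fail_rate = 0.01, snp_masked_fraction = 0.05,
    seed = seed)
}

# simulation for the mutation-conditional discrimination study: one
# mediated predictor (associated with response only through BRAF V600E)
# and one independent predictor, fit at n complete cases
simulate_conditional_pair <- function(seed, n = 300) {
  set.seed(seed)
  ids <- sprintf("CL%04d", seq_len(n))
  flag <- rbinom(n, 1, 0.3)
  x_ind <- rnorm(n)
  x_med <- 1.5 * flag + rnorm(n)
  y <- 1.5 * flag + 0.8 * x_ind + rnorm(n)
  names(y) <- names(x_ind) <- names(x_med) <- ids
  mutations <- data.frame(
    sample_id = ids[flag == 1], gene_symbol = "BRAF",
    protein_change = "V600E", variant_class = "non_synonymous",
    stringsAsFactors = FALSE)
  flags <- build_mutation_flags(mutations, ids)
  fit_med <- suppressWarnings(fit_conditional(y, x_med, flags))
  fit_ind <- suppressWarnings(fit_conditional(y, x_ind, flags))
  p_fdr <- bh_adjust(c(fit_med$predictor_p, fit_ind$predictor_p), 2)
  list(mediated_p_fdr = p_fdr[1], independent_p_fdr = p_fdr[2])
}
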