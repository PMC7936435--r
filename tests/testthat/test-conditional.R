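test_that("mutation flags match manual enumeration on a hand-built table", {
  mut <- data.frame(
    sample_id = c("s1", "s2", "s2", "s3", "s4", "s5", "s6", "s7"),
    gene_symbol = c("BRAF", "BRAF", "KRAS", "KRAS", "NRAS", "BRAF",
                    "TP53", "NRAS"),
    protein_change = c("V600E", "D594G", "G12D", "K88K", "Q61K", "p.V600E",
                       "R175H", "Q61Q"),
    variant_class = c("non_synonymous", "non_synonymous", "non_synonymous",
                      "synonymous", "non_synonymous", "non_synonymous",
                      "non_synonymous", "synonymous"),
    stringsAsFactors = FALSE)
  fl <- build_mutation_flags(mut, sprintf("s%d", 1:8))
  expect_equal(fl$braf_v600e,
               c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fl$kras_ns,
               c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(fl$nras_ns,
               c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # s8 absent from the table: wild-type by convention
  expect_false(any(unlist(fl[8, -1])))
})

test_that("with all flags false the fit reduces to the simple regression", {
  set.seed(51)
  n <- 80
  ids <- sprintf("s%03d", 1:n)
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  names(x) <- names(y) <- ids
  flags <- data.frame(sample_id = ids, braf_v600e = FALSE,
                      kras_ns = FALSE, nras_ns = FALSE)
  fit <- suppressWarnings(fit_conditional(y, x, flags))
  simple <- stats::lm(y ~ x)
  expect_equal(fit$predictor_coef, unname(coef(simple)["x"]),
               tolerance = 1e-10)
  expect_equal(fit$predictor_p,
               summary(simple)$coefficients["x", "Pr(>|t|)"],
               tolerance = 1e-10)
  expect_setequal(fit$dropped_flags,
                  c("braf_v600e", "kras_ns", "nras_ns"))
})

test_that("constant flags are dropped with a warning and the model refit", {
  set.seed(52)
  n <- 60
  ids <- sprintf("s%03d", 1:n)
  flag <- rbinom(n, 1, 0.3)
  x <- rnorm(n)
  y <- flag + 0.5 * x + rnorm(n)
  names(x) <- names(y) <- ids
  flags <- data.frame(sample_id = ids, braf_v600e = flag == 1,
                      kras_ns = FALSE, nras_ns = FALSE)
  expect_warning(fit <- fit_conditional(y, x, flags), "kras_ns, nras_ns")
  expect_false("kras_ns" %in% fit$coefficients$term)
  expect_true("braf_v600e" %in% fit$coefficients$term)
  ref <- stats::lm(y ~ flag + x)
  expect_equal(fit$predictor_coef, unname(coef(ref)["x"]),
               tolerance = 1e-10)
})

test_that("a planted predictor effect of 1 SD is recovered", {
  est <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 300
    ids <- sprintf("s%03d", 1:n)
    flag <- rbinom(n, 1, 0.3)
    x <- as.vector(scale(rnorm(n)))
    y <- 1.2 * flag + 1 * x + rnorm(n)
    names(x) <- names(y) <- ids
    flags <- data.frame(sample_id = ids, braf_v600e = flag == 1,
                        kras_ns = FALSE, nras_ns = FALSE)
    suppressWarnings(fit_conditional(y, x, flags))$predictor_coef
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 0.2)
  expect_true(all(abs(est - 1) < 0.3))
})

test_that("predictor p-values are uniform under the conditional null", {
  # predictor associated with the flag but orthogonal to the response
  # given the flag: its conditional p-value must be uniform
  set.seed(53)
  pvals <- vapply(1:200, function(i) {
    n <- 120
    ids <- sprintf("s%03d", 1:n)
    flag <- rbinom(n, 1, 0.3)
    x <- 1.2 * flag + rnorm(n)
    y <- 1.5 * flag + rnorm(n)
    names(x) <- names(y) <- ids
    flags <- data.frame(sample_id = ids, braf_v600e = flag == 1,
                        kras_ns = FALSE, nras_ns = FALSE)
    suppressWarnings(fit_conditional(y, x, flags))$predictor_p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("mediated and independent effects are discriminated", {
  res <- lapply(1:20, simulate_conditional_pair)
  correct <- vapply(res, function(r) {
    r$mediated_p_fdr >= 0.05 && r$independent_p_fdr < 0.05
  }, logical(1))
  expect_gte(mean(correct), 0.80)
})

test_that("conditional_screen adjusts over the candidate family", {
  cfg <- panel_config(
    n_cell_lines = 300, category_sizes = c(150, 150),
    n_gmds = 4, n_target_genes = 8, n_agents = 5,
    planted_effects = list(
      planted_effect("expr_meth_trans", "GMD01", "cg0000100", 0.7),
      planted_effect("meth_drug", "cg0000100", "AGT02@GDSC", -0.65),
      planted_effect("mutation_drug", "BRAF", "AGT02@GDSC", 1.0)),
    seed = 61)
  panel <- generate_panel(cfg)
  res <- run_pipeline(panel, conditional_agent = "AGT02@GDSC")
  cand <- candidates_for_agent(res, "AGT02@GDSC")
  expect_gt(nrow(cand), 0)
  cond <- res$conditional
  expect_equal(nrow(cond), nrow(cand))
  expect_equal(cond$p_fdr, bh_adjust(cond$p_raw, nrow(cond)))
  # candidate set of one: adjusted p equals raw p
  one <- conditional_screen(cand[1, , drop = FALSE], "AGT02@GDSC",
                            panel$drugs, panel$expression, panel$beta,
                            average_regions(panel$beta,
                                            build_region_index(
                                              panel$annotation)),
                            panel$mutations, panel$categories)
  expect_equal(one$p_fdr, one$p_raw)
  # the methylation predictor keeps an independent planted effect
  probe_rows <- cond[cond$kind == "probe" & cond$predictor == "cg0000100", ]
  expect_true(any(probe_rows$p_fdr < 0.05))
})
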