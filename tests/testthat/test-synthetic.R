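test_that("panel configurations are validated", {
  expect_error(panel_config(n_cell_lines = 10, category_sizes = c(4, 4)),
               "sum\\(category_sizes\\)")
  expect_error(panel_config(detection_fail_rate = 1.2), "\\[0, 1\\]")
  expect_error(panel_config(n_gmds = 0), "n_gmds")
  expect_error(panel_config(
    n_cell_lines = 60, category_sizes = c(1, 59),
    planted_effects = list(planted_effect("expr_drug", "GMD01",
                                          "AGT01@GDSC", 0.5,
                                          stratum = "CAT01"))),
    "fewer than 2")
  expect_error(planted_effect("expr_meth_trans", "GMD01", "GMD01|Body", 0.5),
               "own probes")
  expect_error(planted_effect("meth_drug", "cg01", "AGT01@GDSC", 1.5),
               "rho_target")
})

test_that("the same seed reproduces byte-identical panel files", {
  cfg <- panel_config(n_cell_lines = 40, category_sizes = c(20, 20),
                      n_gmds = 4, n_target_genes = 6, n_agents = 5,
                      seed = 77)
  d1 <- file.path(tempdir(), "panel_a")
  d2 <- file.path(tempdir(), "panel_b")
  write_panel(generate_panel(cfg), d1, overwrite = TRUE)
  write_panel(generate_panel(cfg), d2, overwrite = TRUE)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "panel_c")
  cfg2 <- panel_config(n_cell_lines = 40, category_sizes = c(20, 20),
                       n_gmds = 4, n_target_genes = 6, n_agents = 5,
                       seed = 78)
  write_panel(generate_panel(cfg2), d3, overwrite = TRUE)
  expect_false(identical(readLines(file.path(d1, "beta.tsv")),
                         readLines(file.path(d3, "beta.tsv"))))
})

test_that("a planted trans pair realises its target correlation", {
  cfg <- chain_config(seed = 1, n = 600)
  panel <- generate_panel(cfg)
  rho <- oracle_spearman(panel$expression["GMD01", ],
                         panel$beta$beta["cg0000300", ])
  expect_gte(rho, 0.6)
  expect_lte(rho, 0.8)
  led <- panel$ledger$effects
  expect_equal(nrow(led), 2)  # every planted effect appears exactly once
  expect_equal(led$rho_realized[led$kind == "expr_meth_trans"], rho,
               tolerance = 1e-12)
})

test_that("mean realised correlation over seeds tracks the target", {
  realized <- vapply(1:20, function(s) {
    p <- generate_panel(chain_config(seed = s, n = 600))
    p$ledger$effects$rho_realized[1]
  }, numeric(1))
  expect_lt(abs(mean(realized) - 0.7), 0.05)
})

test_that("cis plants repress expression via upstream methylation", {
  cfg <- panel_config(
    n_cell_lines = 300, category_sizes = c(150, 150),
    n_gmds = 4, n_target_genes = 8, n_agents = 4,
    planted_effects = list(
      planted_effect("expr_meth_cis", "GMD02", "GMD02|TSS200", -0.6)),
    seed = 5)
  panel <- generate_panel(cfg)
  idx <- build_region_index(panel$annotation)
  region <- colMeans(panel$beta$beta[idx[["GMD02|TSS200"]], ])
  rho <- oracle_spearman(panel$expression["GMD02", ], region)
  expect_lt(rho, -0.45)
  expect_gt(rho, -0.75)
})

test_that("a null panel is calibrated under the global null", {
  cfg <- panel_config(n_cell_lines = 60, category_sizes = c(30, 30),
                      n_gmds = 6, n_target_genes = 20, n_agents = 10,
                      detection_fail_rate = 0, seed = 99)
  panel <- generate_panel(cfg)
  rec <- screen(panel$expression, panel$beta$beta, min_n = 10)
  # no pair reaches the derived probe threshold
  expect_equal(sum(rec$p_raw < 1.389e-8, na.rm = TRUE), 0)
  # raw p < 0.001 fraction sits inside the 99% binomial band
  k <- sum(rec$p_raw < 1e-3, na.rm = TRUE)
  ci <- qbinom(c(0.005, 0.995), nrow(rec), 1e-3)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("beta values are bimodal by region category and bounded", {
  panel <- generate_panel(panel_config(seed = 3))
  b <- panel$beta$beta
  expect_true(all(b > 0 & b < 1))
  long <- expand_annotation(panel$annotation)
  up <- long$probe_id[long$region == "TSS200"]
  body <- long$probe_id[long$region == "Body"]
  expect_lt(median(b[unique(up), ]), median(b[unique(body), ]))
  expect_true(all(panel$expression >= 0))
})

test_that("mutation plants shift response additively in flagged lines", {
  cfg <- panel_config(
    n_cell_lines = 200, category_sizes = c(100, 100),
    n_gmds = 4, n_target_genes = 8, n_agents = 4,
    planted_effects = list(
      planted_effect("mutation_drug", "BRAF", "AGT01@GDSC", 1.5)),
    drug_missing_rate = 0, seed = 8)
  panel <- generate_panel(cfg)
  dmat <- drug_matrix(panel$drugs)
  flagged <- unique(panel$mutations$sample_id[
    panel$mutations$gene_symbol == "BRAF" &
      panel$mutations$variant_class == "non_synonymous"])
  shift <- mean(dmat["AGT01@GDSC", flagged]) -
    mean(dmat["AGT01@GDSC", setdiff(colnames(dmat), flagged)])
  sd_wt <- sd(dmat["AGT01@GDSC", setdiff(colnames(dmat), flagged)])
  expect_gt(shift / sd_wt, 0.8)  # planted 1.5 SD, allowing sampling noise
  expect_lt(shift / sd_wt, 2.2)
})
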