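test_that("spearman_cor handles identity, antitone and tied inputs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5, 8, 7)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_equal(spearman_cor(x, x)$p_raw, 0)
  # ties use average ranks: agreement with the explicit oracle
  set.seed(21)
  xt <- sample(1:5, 30, replace = TRUE)
  yt <- sample(1:5, 30, replace = TRUE)
  expect_equal(spearman_cor(xt, yt, min_n = 5)$rho, oracle_spearman(xt, yt),
               tolerance = 1e-12)
})

test_that("spearman_cor is invariant to strictly increasing transforms", {
  set.seed(2)
  x <- rexp(40) + 0.1
  y <- rnorm(40)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(log(x), y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman_cor(x, exp(y))$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman_cor(log(x), exp(y))$p_raw, base$p_raw,
               tolerance = 1e-12)
})

test_that("pairs below min_n or without rank variance are skipped", {
  x <- c(1:5, NA, NA, NA)
  y <- c(NA, NA, NA, 1:5)
  r <- spearman_cor(x, y, min_n = 10)
  expect_true(is.na(r$rho))
  expect_identical(r$skip_reason, "min_n")
  r2 <- spearman_cor(rep(1, 12), rnorm(12), min_n = 10)
  expect_identical(r2$skip_reason, "zero_variance")
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(0.01, 1), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03), 3), rep(0.03, 3))
  expect_equal(bh_adjust(0.001, 100), 0.1)     # padded family: 100 * p / 1
  expect_error(bh_adjust(c(0.1, 0.2), 1), "declared family")
  expect_error(bh_adjust(c(0.1, 1.2), 5), "\\[0, 1\\]")
})

test_that("bh_adjust matches the step-up oracle on random families", {
  set.seed(31)
  for (i in 1:50) {
    k <- sample(1:40, 1)
    p <- runif(k)^sample(1:3, 1)
    m <- k + sample(0:60, 1)
    expect_equal(bh_adjust(p, m), oracle_bh(p, m), tolerance = 1e-12)
  }
})

test_that("screen matches per-pair results and is symmetric", {
  set.seed(41)
  A <- matrix(rnorm(15 * 6), 6, 15,
              dimnames = list(paste0("a", 1:6), sprintf("CL%02d", 1:15)))
  B <- matrix(rnorm(15 * 4), 4, 15,
              dimnames = list(paste0("b", 1:4), sprintf("CL%02d", 1:15)))
  B[1, 3:5] <- NA
  rec <- screen(A, B, min_n = 5)
  for (i in seq_len(nrow(rec))) {
    ref <- spearman_cor(A[rec$predictor[i], ], B[rec$target[i], ], min_n = 5)
    expect_equal(rec$rho[i], ref$rho, tolerance = 1e-12)
    expect_equal(rec$p_raw[i], ref$p_raw, tolerance = 1e-12)
    expect_equal(rec$n[i], ref$n)
  }
  swapped <- screen(B, A, min_n = 5)
  key1 <- paste(rec$predictor, rec$target)
  key2 <- paste(swapped$target, swapped$predictor)
  expect_equal(rec$rho, swapped$rho[match(key1, key2)], tolerance = 1e-12)
  expect_equal(rec$p_raw, swapped$p_raw[match(key1, key2)],
               tolerance = 1e-12)
})

test_that("screen enforces shared samples and honours unattainable cuts", {
  A <- matrix(1:4, 2, 2, dimnames = list(c("a1", "a2"), c("s1", "s2")))
  B <- matrix(1:4, 2, 2, dimnames = list(c("b1", "b2"), c("s3", "s4")))
  expect_error(screen(A, B), "no shared samples")
  set.seed(5)
  X <- matrix(rnorm(40), 2, 20,
              dimnames = list(c("a1", "a2"), sprintf("s%02d", 1:20)))
  rec <- screen(X, X, abs_rho_cut = 1.1, p_cut = 1)
  expect_false(any(rec$significant_strong))
  expect_equal(attr(rec, "test_count"), 4)
})

test_that("cis/trans classification follows the target's gene annotation", {
  ann <- data.frame(
    probe_id = c("cgA", "cgB", "cgI"),
    chromosome = "chr10", position = 1:3, cytoband = "10q26.3",
    gene_symbols = c("MGMT;EBF3", "GENEB", ""),
    region_categories = c("5'UTR;Body", "Body", ""),
    stringsAsFactors = FALSE)
  gm <- probe_gene_map(ann)
  expect_identical(
    classify_cis_trans("MGMT", c("cgA", "cgB", "cgI"), gm),
    c("cis", "trans", "trans"))
  # region targets resolve from the embedded gene symbol
  expect_identical(
    classify_cis_trans("MGMT", c("MGMT|5'UTR", "GENEB|Body"), gm),
    c("cis", "trans"))
})

test_that("stratification keeps pancancer plus categories of >= 10 lines", {
  cm <- data.frame(
    sample_id = sprintf("CL%03d", 1:51),
    category = rep(c("A", "B", "C"), times = c(12, 9, 30)),
    stringsAsFactors = FALSE)
  strata <- stratify(cm)
  expect_identical(names(strata), c("pancancer", "A", "C"))
  expect_equal(lengths(strata), c(pancancer = 51L, A = 12L, C = 30L))
  small <- stratify(data.frame(sample_id = c("a", "b"),
                               category = c("X", "Y")))
  expect_identical(names(small), "pancancer")
  # study-shaped map: 23 eligible categories -> 24 strata
  big <- data.frame(sample_id = sprintf("CL%03d", 1:280),
                    category = c(rep(sprintf("T%02d", 1:23), each = 12),
                                 rep("RARE", 4)))
  expect_length(stratify(big), 24)
})

test_that("empirical false-discovery proportion stays controlled", {
  # 5% of GMD-probe pairs carry planted rho = 0.6 effects at n = 300;
  # pooled FDP at p_fdr < 0.05 over 20 seeds must stay at or below 0.10
  n_false <- 0
  n_disc <- 0
  for (seed in 1:20) {
    cfg <- panel_config(
      n_cell_lines = 300, category_sizes = c(150, 150),
      n_gmds = 2, n_target_genes = 30, probes_per_region = 3,
      n_agents = 2, n_intergenic_probes = 20,
      planted_effects = {
        set.seed(seed + 1000)
        probes <- sample(sprintf("cg%07d", 37:576), 60)
        lapply(seq_along(probes), function(i)
          planted_effect("expr_meth_trans", sprintf("GMD%02d", i %% 2 + 1),
                         probes[i], 0.6))
      },
      detection_fail_rate = 0, snp_masked_fraction = 0, seed = seed)
    panel <- generate_panel(cfg)
    rec <- screen(panel$expression, panel$beta$beta, min_n = 10)
    planted <- paste(vapply(cfg$planted_effects, `[[`, "", "source_id"),
                     vapply(cfg$planted_effects, `[[`, "", "target_id"))
    hit <- rec$p_fdr < 0.05 & !is.na(rec$p_fdr)
    keys <- paste(rec$predictor, rec$target)
    n_disc <- n_disc + sum(hit)
    n_false <- n_false + sum(hit & !(keys %in% planted))
  }
  expect_gt(n_disc, 0)
  expect_lte(n_false / n_disc, 0.10)
})
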