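ann_row <- function(probe, genes, cats) {
  data.frame(probe_id = probe, chromosome = "chr1", position = 1L,
             cytoband = "1p36.3", gene_symbols = genes,
             region_categories = cats, stringsAsFactors = FALSE)
}

test_that("annotation pairs expand positionally and deduplicate", {
  ann <- rbind(
    ann_row("cg01", "GENEA;GENEA", "TSS200;Body"),
    ann_row("cg02", "GENEA;GENEA", "Body;Body"),     # duplicate pair
    ann_row("cg03", "", ""),                          # intergenic
    ann_row("cg04", "GENEB", "5'UTR"))
  idx <- build_region_index(ann)
  expect_setequal(names(idx), c("GENEA|TSS200", "GENEA|Body", "GENEB|5'UTR"))
  expect_identical(idx[["GENEA|TSS200"]], "cg01")
  expect_setequal(idx[["GENEA|Body"]], c("cg01", "cg02"))
  expect_false("cg03" %in% unlist(idx))
  # probe with k distinct pairs appears in exactly k entries
  expect_equal(sum(unlist(idx) == "cg01"), 2)
})

test_that("malformed annotation rows are rejected loudly", {
  expect_error(expand_annotation(ann_row("cgBAD", "GENEA;GENEB", "TSS200")),
               "cgBAD")
  expect_error(expand_annotation(ann_row("cgBAD", "GENEA", "Promoter")),
               "unknown region category")
  expect_error(expand_annotation(ann_row("cgBAD", "GE|NE", "Body")),
               "reserved")
})

test_that("hand-built fixture index matches exact enumeration", {
  genes <- c("A;B", "A", "B;B", "", "C", "A;C", "", "B", "C;A", "A")
  cats <- c("TSS200;Body", "Body", "TSS1500;3'UTR", "", "1stExon",
            "5'UTR;5'UTR", "", "TSS200", "Body;Body", "TSS200")
  ann <- do.call(rbind, lapply(1:10, function(i)
    ann_row(sprintf("cg%02d", i), genes[i], cats[i])))
  idx <- build_region_index(ann)
  expect_identical(
    idx[sort(names(idx))],
    list(`A|5'UTR` = "cg06", `A|Body` = c("cg02", "cg09"),
         `A|TSS200` = c("cg01", "cg10"), `B|3'UTR` = "cg03",
         `B|Body` = "cg01", `B|TSS1500` = "cg03", `B|TSS200` = "cg08",
         `C|1stExon` = "cg05", `C|5'UTR` = "cg06", `C|Body` = "cg09")
    [sort(names(idx))])
})

test_that("region averages equal the brute-force oracle exactly", {
  beta <- random_beta_fixture(50, 20, na_frac = 0.15)
  probes <- rownames(beta)
  set.seed(5)
  idx <- lapply(1:12, function(i) sample(probes, sample(1:6, 1)))
  names(idx) <- paste0("G", sprintf("%02d", 1:12), "|Body")
  rm <- average_regions(beta, idx)
  expect_equal(rm$values, oracle_region_means(beta, idx), tolerance = 1e-12)
  # bounds hold wherever defined
  expect_true(all(rm$values >= 0 & rm$values <= 1, na.rm = TRUE))
})

test_that("singleton and simple means are exact, all-missing is NA", {
  beta <- matrix(c(0.2, 0.4, 0.6, NA, NA, NA), 3, 2,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  rm <- average_regions(beta, list("G|Body" = c("p1", "p2", "p3"),
                                   "H|TSS200" = "p2"))
  expect_equal(rm$values["G|Body", "s1"], 0.4)
  expect_true(is.na(rm$values["G|Body", "s2"]))
  expect_equal(rm$values["H|TSS200", "s1"], 0.4)  # singleton mean
  expect_equal(unname(rm$n_probes["G|Body"]), 3L)
  # region with no probes in the matrix is omitted
  rm2 <- average_regions(beta, list("G|Body" = "p1", "Z|Body" = "pX"))
  expect_identical(rownames(rm2$values), "G|Body")
})

test_that("averaging is invariant to probe row order and monotone in betas", {
  beta <- random_beta_fixture(30, 8, na_frac = 0.1, seed = 9)
  idx <- list("G1|Body" = rownames(beta)[1:7],
              "G2|TSS1500" = rownames(beta)[5:30])
  base <- average_regions(beta, idx)
  perm <- beta[sample(nrow(beta)), , drop = FALSE]
  expect_equal(average_regions(perm, idx)$values, base$values)
  up <- beta
  up["cg0000003", 2] <- min(1, beta["cg0000003", 2] + 0.2)
  bumped <- average_regions(up, idx)
  expect_true(all(bumped$values[, 2] >= base$values[, 2], na.rm = TRUE))
})

test_that("epigenome mean matches the oracle and flags empty samples", {
  beta <- random_beta_fixture(40, 6, na_frac = 0.2, seed = 13)
  m <- epigenome_mean(beta)
  manual <- vapply(seq_len(ncol(beta)),
                   function(j) mean(beta[, j], na.rm = TRUE), numeric(1))
  expect_equal(unname(m), manual, tolerance = 1e-12)
  expect_equal(unname(epigenome_mean(matrix(0.5, 3, 2,
    dimnames = list(letters[1:3], c("s1", "s2"))))), c(0.5, 0.5))
  expect_equal(unname(epigenome_mean(matrix(c(0, 1), 2, 1,
    dimnames = list(c("a", "b"), "s1")))), 0.5)
  beta[, 3] <- NA
  expect_warning(m2 <- epigenome_mean(beta), "no non-missing")
  expect_true(is.na(m2[3]))
})
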