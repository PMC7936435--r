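#' Agents-by-samples response matrix from a long drug table
#'
#' Duplicate (agent, sample) measurements are collapsed to their mean
#' before analysis.
#'
#' @param drug_table Long data frame with columns \code{agent_id},
#'   \code{sample_id}, \code{log_ic50}.
#' @return Numeric matrix, agents in rows and samples in columns, \code{NA}
#'   where a pair was not measured.
#' @export
drug_matrix <- function(drug_table) {
  stopifnot(all(c("agent_id", "sample_id", "log_ic50") %in%
                  names(drug_table)))
  agents <- sort(unique(drug_table$agent_id))
  samples <- sort(unique(drug_table$sample_id))
  m <- matrix(NA_real_, length(agents), length(samples),
              dimnames = list(agents, samples))
  key <- paste(drug_table$agent_id, drug_table$sample_id, sep = "\r")
  means <- tapply(drug_table$log_ic50, key, mean)
  ij <- do.call(rbind, strsplit(names(means), "\r", fixed = TRUE))
  m[cbind(match(ij[, 1], agents), match(ij[, 2], samples))] <- means
  m
}

#' Derived probe-level significance thresholds
#'
#' The pancancer threshold for expression-probe correlations divides the
#' epigenome-wide single-gene recommendation of 1e-6 by the number of GMDs
#' screened; the stratified threshold further divides by the number of
#' eligible cancer categories. Both are rounded to 4 significant digits.
#' At the study defaults (72 GMDs, 23 categories) these are 1.389e-8 and
#' 6.039e-10.
#'
#' @param n_gmds Number of GMDs screened (study default 72).
#' @param n_categories Number of eligible cancer categories (study
#'   default 23).
#' @param base_p Epigenome-wide single-gene threshold (1e-6).
#' @param digits Significant digits for rounding.
#' @return List with elements \code{pancancer} and \code{stratified}.
#' @export
derive_probe_thresholds <- function(n_gmds = 72, n_categories = 23,
                                    base_p = 1e-6, digits = 4) {
  pan <- base_p / n_gmds
  list(pancancer = signif(pan, digits),
       stratified = signif(pan / n_categories, digits))
}

# Screen predictors x targets in every stratum. The pancancer stratum is
# its own FDR family of size base_count; the stratified records form a
# family of size base_count x n_categories, either pooled across
# categories (default) or adjusted per category with the same multiplicity
# accounting.
.stratified_screen <- function(predictors, targets, strata, base_count,
                               p_mode = "fdr", p_cut = 0.05,
                               abs_rho_cut = 0.5, min_n = 10,
                               fdr_scope = c("pooled", "per_stratum"),
                               p_cut_pancancer = p_cut,
                               p_cut_stratified = p_cut) {
  fdr_scope <- match.arg(fdr_scope)
  cat_names <- setdiff(names(strata), "pancancer")
  n_cat <- length(cat_names)
  pan <- screen(predictors, targets, stratum = "pancancer",
                sample_ids = strata$pancancer, p_mode = p_mode,
                p_cut = p_cut_pancancer, abs_rho_cut = abs_rho_cut,
                test_count = base_count, min_n = min_n,
                adjust = p_mode == "fdr")
  strat_count <- base_count * max(n_cat, 1L)
  per_cat <- lapply(cat_names, function(cn) {
    screen(predictors, targets, stratum = cn, sample_ids = strata[[cn]],
           p_mode = p_mode, p_cut = p_cut_stratified,
           abs_rho_cut = abs_rho_cut, test_count = strat_count,
           min_n = min_n,
           adjust = p_mode == "fdr" && fdr_scope == "per_stratum")
  })
  strat <- if (length(per_cat)) do.call(rbind, per_cat) else NULL
  if (!is.null(strat) && p_mode == "fdr" && fdr_scope == "pooled") {
    ok <- !is.na(strat$p_raw)
    strat$p_fdr[ok] <- bh_adjust(strat$p_raw[ok], strat_count)
    strat$significant_strong <- !is.na(strat$rho) & !is.na(strat$p_fdr) &
      strat$p_fdr < p_cut_stratified & abs(strat$rho) > abs_rho_cut
  }
  out <- rbind(pan, strat)
  rownames(out) <- NULL
  attr(out, "test_count_pancancer") <- base_count
  attr(out, "test_count_stratified") <- strat_count
  out
}

#' Direct screen: GMD expression versus drug response
#'
#' Spearman correlations of each GMD's expression with each agent's
#' log10(IC50), pancancer and within every eligible cancer category, with
#' BH adjustment over the agents x GMDs family (x categories for the
#' stratified records). A negative rho with log(IC50) means higher
#' expression associates with drug sensitivity. The returned records carry
#' tier flags at |rho| > 0.5, > 0.4 and > 0.3 combined with p_FDR < 0.05.
#'
#' @param expression GMDs x samples expression matrix (RPKM-like; the
#'   screen is rank-based, so any monotone transform of it is equivalent).
#' @param drug_table Long drug-response table (see [drug_matrix()]).
#' @param category_map Data frame \code{sample_id}, \code{category}.
#' @param min_n Minimum pairwise-complete samples per test.
#' @param min_category_size Stratum eligibility floor.
#' @param fdr_scope Stratified family mode: one pooled family across
#'   categories (default) or per-category adjustment, both with the same
#'   x-categories test-count accounting.
#' @return Record data.frame with columns as in [screen()] plus tier flags
#'   \code{tier_05}, \code{tier_04}, \code{tier_03}.
#' @export
run_direct_screen <- function(expression, drug_table, category_map,
                              min_n = 10, min_category_size = 10,
                              fdr_scope = c("pooled", "per_stratum")) {
  fdr_scope <- match.arg(fdr_scope)
  strata <- stratify(category_map, min_category_size)
  dmat <- drug_matrix(drug_table)
  rec <- .stratified_screen(expression, dmat, strata,
                            base_count = nrow(expression) * nrow(dmat),
                            p_mode = "fdr", p_cut = 0.05, abs_rho_cut = 0.4,
                            min_n = min_n, fdr_scope = fdr_scope)
  ok <- !is.na(rec$rho) & !is.na(rec$p_fdr) & rec$p_fdr < 0.05
  rec$tier_05 <- ok & abs(rec$rho) > 0.5
  rec$tier_04 <- ok & abs(rec$rho) > 0.4
  rec$tier_03 <- ok & abs(rec$rho) > 0.3
  rec
}

#' Stage 1: epigenome targets associated with GMD expression
#'
#' Screens GMD expression against methylation of every probe and every
#' gene region, pancancer and per category. Probe-level significance uses
#' the fixed raw-p thresholds derived from 1e-6 / n_gmds (further divided
#' by the category count for stratified records); region-level
#' significance uses BH FDR over the GMDs x regions family. Both require
#' |rho| > 0.5. Every record is classified cis (target annotated to the
#' GMD itself) or trans.
#'
#' @param expression GMDs x samples matrix.
#' @param bm QC'd [beta_matrix()].
#' @param region_meth [average_regions()] output.
#' @param annotation Probe annotation (manifest dialect), used for
#'   cis/trans classification.
#' @param category_map Sample-to-category map.
#' @param min_n,min_category_size,fdr_scope See [run_direct_screen()].
#' @return Object of class \code{stage1_targets}: full probe and region
#'   record sets, their significant-strong subsets, the de-duplicated
#'   target id vectors that feed stage 2, and the derived thresholds.
#' @export
run_stage1 <- function(expression, bm, region_meth, annotation,
                       category_map, min_n = 10, min_category_size = 10,
                       fdr_scope = c("pooled", "per_stratum")) {
  fdr_scope <- match.arg(fdr_scope)
  strata <- stratify(category_map, min_category_size)
  n_cat <- length(strata) - 1L
  thresholds <- derive_probe_thresholds(n_gmds = nrow(expression),
                                        n_categories = max(n_cat, 1L))
  beta <- if (inherits(bm, "beta_matrix")) bm$beta else bm

  probe_rec <- .stratified_screen(
    expression, beta, strata,
    base_count = nrow(expression) * nrow(beta),
    p_mode = "raw", abs_rho_cut = 0.5, min_n = min_n, fdr_scope = fdr_scope,
    p_cut_pancancer = thresholds$pancancer,
    p_cut_stratified = thresholds$stratified)
  region_rec <- .stratified_screen(
    expression, region_meth$values, strata,
    base_count = nrow(expression) * nrow(region_meth$values),
    p_mode = "fdr", p_cut = 0.05, abs_rho_cut = 0.5, min_n = min_n,
    fdr_scope = fdr_scope)

  gene_map <- probe_gene_map(annotation)
  probe_rec$relation <- classify_cis_trans(probe_rec$predictor,
                                           probe_rec$target, gene_map)
  region_rec$relation <- classify_cis_trans(region_rec$predictor,
                                            region_rec$target, gene_map)

  probe_targets <- probe_rec[probe_rec$significant_strong, , drop = FALSE]
  region_targets <- region_rec[region_rec$significant_strong, , drop = FALSE]
  structure(
    list(probe_records = probe_rec, region_records = region_rec,
         probe_targets = probe_targets, region_targets = region_targets,
         unique_probe_targets = sort(unique(probe_targets$target)),
         unique_region_targets = sort(unique(region_targets$target)),
         thresholds = thresholds),
    class = "stage1_targets")
}

#' @export
print.stage1_targets <- function(x, ...) {
  cat("<stage1_targets> ", nrow(x$probe_targets), " probe hits (",
      length(x$unique_probe_targets), " unique probes), ",
      nrow(x$region_targets), " region hits (",
      length(x$unique_region_targets), " unique regions)\n", sep = "")
  cat("  probe thresholds: p < ", format(x$thresholds$pancancer),
      " (pancancer), p < ", format(x$thresholds$stratified),
      " (stratified); |rho| > 0.5\n", sep = "")
  invisible(x)
}

#' Stage 2: methylation of stage-1 targets versus drug response
#'
#' Correlates methylation of each unique stage-1 target (a probe or gene
#' region selected via any GMD or stratum enters once) with each agent's
#' log10(IC50). Probes and regions form two separate FDR families of size
#' agents x n_targets (x categories for stratified records). Records carry
#' tier flags at |rho| > 0.5 and the relaxed |rho| > 0.4 with
#' p_FDR < 0.05.
#'
#' @param stage1 A \code{stage1_targets} object from [run_stage1()].
#' @param bm QC'd [beta_matrix()].
#' @param region_meth [average_regions()] output.
#' @param drug_table Long drug-response table.
#' @param category_map Sample-to-category map.
#' @param min_n,min_category_size,fdr_scope See [run_direct_screen()].
#' @return List with \code{probe_records} and \code{region_records}
#'   (either may be an empty data.frame when stage 1 selected no targets
#'   of that kind).
#' @export
run_stage2 <- function(stage1, bm, region_meth, drug_table, category_map,
                       min_n = 10, min_category_size = 10,
                       fdr_scope = c("pooled", "per_stratum")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(stage1, "stage1_targets"))
  strata <- stratify(category_map, min_category_size)
  dmat <- drug_matrix(drug_table)
  beta <- if (inherits(bm, "beta_matrix")) bm$beta else bm

  tier_flags <- function(rec) {
    ok <- !is.na(rec$rho) & !is.na(rec$p_fdr) & rec$p_fdr < 0.05
    rec$tier_05 <- ok & abs(rec$rho) > 0.5
    rec$tier_04 <- ok & abs(rec$rho) > 0.4
    rec
  }
  empty <- data.frame()
  probe_rec <- empty
  if (length(stage1$unique_probe_targets)) {
    probe_rec <- .stratified_screen(
      beta[stage1$unique_probe_targets, , drop = FALSE], dmat, strata,
      base_count = length(stage1$unique_probe_targets) * nrow(dmat),
      p_mode = "fdr", p_cut = 0.05, abs_rho_cut = 0.5, min_n = min_n,
      fdr_scope = fdr_scope)
    probe_rec <- tier_flags(probe_rec)
  } else {
    message("stage 1 selected no probe targets; probe-level stage 2 is empty")
  }
  region_rec <- empty
  if (length(stage1$unique_region_targets)) {
    region_rec <- .stratified_screen(
      region_meth$values[stage1$unique_region_targets, , drop = FALSE],
      dmat, strata,
      base_count = length(stage1$unique_region_targets) * nrow(dmat),
      p_mode = "fdr", p_cut = 0.05, abs_rho_cut = 0.5, min_n = min_n,
      fdr_scope = fdr_scope)
    region_rec <- tier_flags(region_rec)
  } else {
    message("stage 1 selected no region targets; region-level stage 2 is empty")
  }
  list(probe_records = probe_rec, region_records = region_rec)
}

#' Epigenome-average methylation screens
#'
#' Two screens driven by the per-sample epigenome-average beta: (i) GMD
#' expression versus the average, and (ii) the average versus each agent's
#' log10(IC50), each BH-adjusted over its own family (n_gmds and n_agents
#' respectively, x categories for stratified records). Records carry
#' reporting tiers at p_FDR < 0.05 and the relaxed p_FDR < 0.15.
#'
#' @param epimean Named per-sample vector from [epigenome_mean()].
#' @param expression GMDs x samples matrix.
#' @param drug_table Long drug-response table.
#' @param category_map Sample-to-category map.
#' @param min_n,min_category_size,fdr_scope See [run_direct_screen()].
#' @return List with \code{gmd_records} and \code{agent_records}, each with
#'   logical tier columns \code{tier_fdr05} and \code{tier_fdr15}.
#' @export
run_average_methylation_screens <- function(epimean, expression, drug_table,
                                            category_map, min_n = 10,
                                            min_category_size = 10,
                                            fdr_scope = c("pooled",
                                                          "per_stratum")) {
  fdr_scope <- match.arg(fdr_scope)
  strata <- stratify(category_map, min_category_size)
  dmat <- drug_matrix(drug_table)
  avg <- matrix(epimean, nrow = 1,
                dimnames = list("epigenome_average", names(epimean)))
  tier <- function(rec) {
    ok <- !is.na(rec$rho) & !is.na(rec$p_fdr)
    rec$tier_fdr05 <- ok & rec$p_fdr < 0.05
    rec$tier_fdr15 <- ok & rec$p_fdr < 0.15
    rec
  }
  gmd_rec <- tier(.stratified_screen(
    expression, avg, strata, base_count = nrow(expression),
    p_mode = "fdr", p_cut = 0.05, abs_rho_cut = 0, min_n = min_n,
    fdr_scope = fdr_scope))
  agent_rec <- tier(.stratified_screen(
    avg, dmat, strata, base_count = nrow(dmat),
    p_mode = "fdr", p_cut = 0.05, abs_rho_cut = 0, min_n = min_n,
    fdr_scope = fdr_scope))
  list(gmd_records = gmd_rec, agent_records = agent_rec)
}

#' Run the full screening pipeline on a panel
#'
#' Orchestrates probe QC, gene-region averaging, the direct
#' expression-drug screen, the two-stage expression-methylation-drug
#' screen, the epigenome-average screens and, optionally, the
#' mutation-conditional regression for one agent. All stages are
#' deterministic given the inputs.
#'
#' @param panel A [generate_panel()] result, or any list with elements
#'   \code{expression}, \code{beta} (a [beta_matrix()]), \code{drugs},
#'   \code{mutations}, \code{categories}, \code{annotation},
#'   \code{snp_mask}.
#' @param min_n,min_category_size,fdr_scope See [run_direct_screen()].
#' @param conditional_agent Optional agent id: candidates significantly and
#'   strongly (|rho| > 0.5) associated with this agent's response are
#'   re-tested by OLS conditional on BRAF V600E / non-synonymous KRAS /
#'   NRAS mutation flags.
#' @return Object of class \code{methscreen_results} with elements
#'   \code{qc_report}, \code{region_methylation}, \code{epigenome_mean},
#'   \code{direct}, \code{stage1}, \code{stage2}, \code{average_methylation}
#'   and (if requested) \code{conditional}.
#' @export
run_pipeline <- function(panel, min_n = 10, min_category_size = 10,
                         fdr_scope = c("pooled", "per_stratum"),
                         conditional_agent = NULL) {
  fdr_scope <- match.arg(fdr_scope)
  qc <- run_qc(panel$beta, panel$snp_mask)
  index <- build_region_index(panel$annotation)
  region_meth <- average_regions(qc$beta_matrix, index)
  epimean <- epigenome_mean(qc$beta_matrix)
  direct <- run_direct_screen(panel$expression, panel$drugs,
                              panel$categories, min_n, min_category_size,
                              fdr_scope)
  stage1 <- run_stage1(panel$expression, qc$beta_matrix, region_meth,
                       panel$annotation, panel$categories, min_n,
                       min_category_size, fdr_scope)
  stage2 <- run_stage2(stage1, qc$beta_matrix, region_meth, panel$drugs,
                       panel$categories, min_n, min_category_size,
                       fdr_scope)
  avg <- run_average_methylation_screens(epimean, panel$expression,
                                         panel$drugs, panel$categories,
                                         min_n, min_category_size, fdr_scope)
  res <- list(qc_report = qc$report, region_methylation = region_meth,
              epigenome_mean = epimean, direct = direct, stage1 = stage1,
              stage2 = stage2, average_methylation = avg,
              conditional = NULL)
  if (!is.null(conditional_agent)) {
    res$conditional <- conditional_screen(
      candidates_for_agent(res, conditional_agent),
      agent = conditional_agent, drug_table = panel$drugs,
      expression = panel$expression, bm = qc$beta_matrix,
      region_meth = region_meth, mutations = panel$mutations,
      category_map = panel$categories)
  }
  structure(res, class = "methscreen_results")
}

#' Candidates for the mutation-conditional regression of one agent
#'
#' Collects every predictor significantly and strongly (|rho| > 0.5,
#' significant at its screen's own criterion) associated with the agent's
#' response in any stratum: GMD expression from the direct screen and
#' target probe / gene-region methylation from stage 2.
#'
#' @param results A \code{methscreen_results} object (stage 2 and direct
#'   screens already run).
#' @param agent Agent id.
#' @return Data frame with columns \code{predictor}, \code{kind}
#'   (\code{expression} / \code{probe} / \code{region}) and \code{stratum}.
#' @export
candidates_for_agent <- function(results, agent) {
  pick <- function(rec, kind, pred_col, flag_col) {
    if (!NROW(rec)) return(NULL)
    sel <- rec[[flag_col]] & rec$target == agent
    if (!any(sel)) return(NULL)
    data.frame(predictor = rec[[pred_col]][sel], kind = kind,
               stratum = rec$stratum[sel], stringsAsFactors = FALSE)
  }
  out <- rbind(
    pick(results$direct, "expression", "predictor", "tier_05"),
    pick(results$stage2$probe_records, "probe", "predictor", "tier_05"),
    pick(results$stage2$region_records, "region", "predictor", "tier_05"))
  if (is.null(out)) {
    out <- data.frame(predictor = character(0), kind = character(0),
                      stratum = character(0), stringsAsFactors = FALSE)
  }
  unique(out)
}

#' @export
print.methscreen_results <- function(x, ...) {
  cat("<methscreen_results>\n")
  print(x$qc_report)
  cat("  direct screen records:      ", NROW(x$direct), "\n",
      "  stage-1 probe targets:      ", length(x$stage1$unique_probe_targets),
      "\n  stage-1 region targets:     ",
      length(x$stage1$unique_region_targets), "\n",
      "  stage-2 probe records:      ", NROW(x$stage2$probe_records), "\n",
      "  stage-2 region records:     ", NROW(x$stage2$region_records), "\n",
      sep = "")
  invisible(x)
}
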