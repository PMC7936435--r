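#' Configuration for a synthetic cell-line panel
#'
#' Describes a panel with the statistical structure the screens assume:
#' log-normal RPKM-like expression for the methylation/demethylation genes
#' (GMDs), bimodal beta-values generated on a latent Gaussian scale and
#' squashed by a logistic map (upstream regions skewed unmethylated, gene
#' bodies skewed methylated), per-measurement detection p-values with
#' planted failures, a SNP-overlap probe mask, log10(IC50) drug response,
#' a mutation table, and a cancer-category map. Planted effects are
#' realised by sharing latent Gaussians between the coupled variables, so
#' a target Spearman rho is controlled analytically (Spearman rho is
#' invariant to the monotone maps applied on top of the latents).
#'
#' @param n_cell_lines Number of cell lines.
#' @param category_sizes Integer vector of cancer-category sizes; must sum
#'   to \code{n_cell_lines}. Categories are labelled CAT01, CAT02, ...
#' @param n_gmds Number of GMD genes (labelled GMD01, ...). Each GMD also
#'   owns probes and regions in the annotation, so cis effects can target
#'   its own upstream regions.
#' @param n_target_genes Number of non-GMD target genes (TGT0001, ...).
#' @param probes_per_region Probes annotated to each (gene, region) pair.
#' @param n_agents Number of drug-response agents (AGT01@GDSC, ...; a tail
#'   of agents carries the @CCLE dataset-of-origin suffix).
#' @param n_intergenic_probes Probes annotated to no gene.
#' @param planted_effects List of [planted_effect()] objects.
#' @param detection_fail_rate Fraction of (probe, sample) entries planted
#'   with detection p >= 1e-3.
#' @param snp_masked_fraction Fraction of probe ids listed in the SNP mask.
#' @param n_failing_probes Whole probes planted with median detection
#'   p >= 1e-6 (dropped by QC).
#' @param drug_missing_rate Fraction of (agent, sample) responses missing.
#' @param seed Integer seed feeding a hierarchical per-table stream, so
#'   each table is stable when other tables' sizes change.
#' @return A validated object of class \code{panel_config}.
#' @export
panel_config <- function(n_cell_lines = 120,
                         category_sizes = c(40, 30, 30, 20),
                         n_gmds = 12,
                         n_target_genes = 40,
                         probes_per_region = 3,
                         n_agents = 25,
                         n_intergenic_probes = 20,
                         planted_effects = list(),
                         detection_fail_rate = 0.01,
                         snp_masked_fraction = 0.05,
                         n_failing_probes = 0,
                         drug_missing_rate = 0.05,
                         seed = 1) {
  cfg <- list(n_cell_lines = n_cell_lines,
              category_sizes = as.integer(category_sizes),
              n_cancer_categories = length(category_sizes),
              n_gmds = n_gmds, n_target_genes = n_target_genes,
              probes_per_region = probes_per_region, n_agents = n_agents,
              n_intergenic_probes = n_intergenic_probes,
              planted_effects = planted_effects,
              detection_fail_rate = detection_fail_rate,
              snp_masked_fraction = snp_masked_fraction,
              n_failing_probes = n_failing_probes,
              drug_missing_rate = drug_missing_rate,
              seed = as.integer(seed))
  counts <- c(n_cell_lines = n_cell_lines, n_gmds = n_gmds,
              n_target_genes = n_target_genes,
              probes_per_region = probes_per_region, n_agents = n_agents)
  if (any(counts < 1)) {
    stop("counts must all be >= 1; offending: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  }
  if (sum(cfg$category_sizes) != n_cell_lines) {
    stop("sum(category_sizes) must equal n_cell_lines")
  }
  if (any(cfg$category_sizes < 1)) stop("category sizes must be >= 1")
  fr <- c(detection_fail_rate, snp_masked_fraction, drug_missing_rate)
  if (any(fr < 0 | fr > 1)) stop("rate/fraction parameters must lie in [0, 1]")
  cats <- sprintf("CAT%02d", seq_along(cfg$category_sizes))
  for (eff in planted_effects) {
    if (!inherits(eff, "planted_effect")) {
      stop("planted_effects must be a list of planted_effect() objects")
    }
    if (eff$stratum != "pancancer") {
      i <- match(eff$stratum, cats)
      if (is.na(i)) stop("planted effect stratum \"", eff$stratum,
                         "\" is not a category of this panel")
      if (cfg$category_sizes[i] < 2) {
        stop("category ", eff$stratum, " has fewer than 2 cell lines; ",
             "cannot plant a stratum-level effect there")
      }
    }
  }
  structure(cfg, class = "panel_config")
}

#' A planted ground-truth effect
#'
#' @param kind One of \code{expr_meth_trans}, \code{expr_meth_cis},
#'   \code{meth_drug}, \code{expr_drug}, \code{mutation_drug},
#'   \code{epigenome_average}.
#' @param source_id Source identifier: a GMD for expression effects, a
#'   probe or \code{"GENE|REGION"} id for \code{meth_drug}, a mutation gene
#'   symbol (e.g. BRAF) for \code{mutation_drug}.
#' @param target_id Target identifier: probe or region id for methylation
#'   effects, an agent id for drug effects, \code{"epigenome"} for
#'   \code{epigenome_average}.
#' @param rho_target Target Spearman correlation in \[-1, 1\]. For
#'   \code{mutation_drug} it is instead the additive log10(IC50) shift of
#'   mutated lines, in units of the agent's response standard deviation.
#' @param stratum \code{"pancancer"} or a category label; the effect is
#'   realised only within the stratum's samples.
#' @return An object of class \code{planted_effect}.
#' @export
planted_effect <- function(kind, source_id, target_id, rho_target,
                           stratum = "pancancer") {
  kinds <- c("expr_meth_trans", "expr_meth_cis", "meth_drug", "expr_drug",
             "mutation_drug", "epigenome_average")
  kind <- match.arg(kind, kinds)
  if (kind != "mutation_drug" && (rho_target < -1 || rho_target > 1)) {
    stop("rho_target must lie in [-1, 1]")
  }
  if (kind == "expr_meth_trans" &&
      source_id == sub("\\|.*$", "", target_id)) {
    stop("a trans effect cannot target the source gene's own probes/regions")
  }
  structure(list(kind = kind, source_id = source_id, target_id = target_id,
                 rho_target = rho_target, stratum = stratum),
            class = "planted_effect")
}

#' Deterministic probe/gene/region layout of a panel
#'
#' The structural layout (which probe belongs to which gene and region) is
#' a pure function of the panel sizes, so tests and callers can name valid
#' probe and region ids before generating data. Genes are laid out GMDs
#' first, then target genes; each gene carries all six region categories
#' with \code{probes_per_region} probes each, followed by the intergenic
#' probes.
#'
#' @param config A [panel_config()].
#' @return Data frame with columns \code{probe_id}, \code{gene} (empty
#'   string for intergenic probes) and \code{region}.
#' @export
panel_layout <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  gmds <- sprintf("GMD%02d", seq_len(config$n_gmds))
  tgts <- sprintf("TGT%04d", seq_len(config$n_target_genes))
  genes <- c(gmds, tgts)
  cats <- region_categories()
  ppr <- config$probes_per_region
  gene_col <- rep(genes, each = length(cats) * ppr)
  region_col <- rep(rep(cats, each = ppr), times = length(genes))
  gene_col <- c(gene_col, rep("", config$n_intergenic_probes))
  region_col <- c(region_col, rep("", config$n_intergenic_probes))
  data.frame(probe_id = sprintf("cg%07d", seq_along(gene_col)),
             gene = gene_col, region = region_col, stringsAsFactors = FALSE)
}

# latent correlation giving a target Spearman rho on a Gaussian copula
latent_rho <- function(rho_s) 2 * sin(pi * rho_s / 6)

# probe ids referenced (directly or via a region) by a planted effect
.effect_probe_ids <- function(effects, layout) {
  ids <- character(0)
  for (eff in effects) {
    for (ref in c(eff$source_id, eff$target_id)) {
      if (grepl("^cg", ref)) {
        ids <- c(ids, ref)
      } else if (grepl("|", ref, fixed = TRUE)) {
        g <- sub("\\|.*$", "", ref)
        r <- sub("^.*\\|", "", ref)
        ids <- c(ids, layout$probe_id[layout$gene == g & layout$region == r])
      }
    }
  }
  unique(ids)
}

#' Generate a synthetic cell-line panel
#'
#' Produces the full file-set-in-memory a screen run consumes -- expression,
#' beta-values with detection p-values, drug response, mutations, category
#' map, probe annotation, SNP mask -- plus a ground-truth ledger recording
#' the realised Spearman correlation of every planted effect. Probes that
#' participate in planted effects (and the probes of GMD genes themselves)
#' are kept out of the SNP mask and the planted detection failures, so
#' ground truth remains observable after QC.
#'
#' @param config A [panel_config()].
#' @return An object of class \code{synthetic_panel}: a list with elements
#'   \code{expression} (GMDs x samples matrix), \code{beta}
#'   ([beta_matrix()] with detection p-values), \code{drugs} (long data
#'   frame \code{agent_id}, \code{sample_id}, \code{log_ic50}),
#'   \code{mutations}, \code{categories}, \code{annotation},
#'   \code{snp_mask}, \code{ledger} and \code{config}.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  n <- config$n_cell_lines
  set.seed(config$seed)
  ss <- sample.int(2^31 - 2, 8)

  samples <- sprintf("CL%04d", seq_len(n))
  cats <- sprintf("CAT%02d", seq_len(config$n_cancer_categories))
  categories <- data.frame(
    sample_id = samples,
    category = rep(cats, times = config$category_sizes),
    stringsAsFactors = FALSE
  )
  layout <- panel_layout(config)
  n_probes <- nrow(layout)
  genic <- layout$gene != ""
  region_id <- ifelse(genic, paste(layout$gene, layout$region, sep = "|"), "")
  regions <- unique(region_id[genic])
  gmds <- sprintf("GMD%02d", seq_len(config$n_gmds))
  agents <- sprintf("AGT%02d@%s", seq_len(config$n_agents),
                    ifelse(seq_len(config$n_agents) <=
                             ceiling(0.8 * config$n_agents), "GDSC", "CCLE"))

  stratum_idx <- function(stratum) {
    if (stratum == "pancancer") seq_len(n)
    else which(categories$category == stratum)
  }
  effects <- config$planted_effects
  protected <- .effect_probe_ids(effects, layout)

  # --- annotation (structure stream) --------------------------------------
  set.seed(ss[1])
  genes_all <- unique(layout$gene[genic])
  chrom_of <- stats::setNames(sample(paste0("chr", 1:22), length(genes_all),
                                     replace = TRUE), genes_all)
  arm_of <- stats::setNames(
    paste0(sample(c("p", "q"), length(genes_all), replace = TRUE),
           sample(11:36, length(genes_all), replace = TRUE) / 10),
    genes_all)
  gene_start <- stats::setNames(
    sample.int(2e8, length(genes_all)), genes_all)
  probe_offset <- stats::ave(seq_len(n_probes), region_id,
                             FUN = seq_along) * 50L
  annotation <- data.frame(
    probe_id = layout$probe_id,
    chromosome = ifelse(genic, chrom_of[layout$gene],
                        sample(paste0("chr", 1:22), n_probes, replace = TRUE)),
    position = ifelse(genic,
                      gene_start[layout$gene] +
                        match(layout$region, region_categories()) * 2000L +
                        probe_offset,
                      sample.int(2e8, n_probes)),
    cytoband = ifelse(genic,
                      paste0(sub("chr", "", chrom_of[layout$gene]),
                             arm_of[layout$gene]),
                      "1p36.3"),
    gene_symbols = layout$gene,
    region_categories = layout$region,
    stringsAsFactors = FALSE
  )
  # a sparse set of dual-gene probes exercises annotation-pair expansion
  tgt_rows <- which(grepl("^TGT", layout$gene))
  dual <- tgt_rows[seq_along(tgt_rows) %% 41L == 0L]
  dual <- setdiff(dual, which(layout$probe_id %in% protected))
  if (length(dual)) {
    gi <- match(layout$gene[dual], genes_all) - config$n_gmds
    other <- sprintf("TGT%04d", gi %% config$n_target_genes + 1L)
    planted_region_genes <- unique(sub("\\|.*$", "", unlist(
      lapply(effects, function(e) Filter(function(r)
        grepl("|", r, fixed = TRUE), c(e$source_id, e$target_id))))))
    keep <- other != layout$gene[dual] & !(other %in% planted_region_genes)
    dual <- dual[keep]; other <- other[keep]
    annotation$gene_symbols[dual] <-
      paste(annotation$gene_symbols[dual], other, sep = ";")
    annotation$region_categories[dual] <-
      paste(annotation$region_categories[dual], "Body", sep = ";")
  }

  # --- methylation latents -------------------------------------------------
  set.seed(ss[2])
  f <- stats::rnorm(n)                                   # global factor
  u <- matrix(stats::rnorm(n * length(regions)), n, length(regions),
              dimnames = list(samples, regions))
  upstream <- c("TSS1500", "TSS200", "5'UTR", "1stExon")
  region_cat <- sub("^.*\\|", "", regions)
  p_low <- ifelse(region_cat %in% upstream, 0.8,
                  ifelse(region_cat == "Body", 0.25, 0.4))
  m_r <- stats::setNames(
    ifelse(stats::runif(length(regions)) < p_low,
           stats::rnorm(length(regions), -2.2, 0.6),
           stats::rnorm(length(regions), 2.2, 0.6)),
    regions)
  eps <- matrix(stats::rnorm(n * n_probes), n, n_probes,
                dimnames = list(samples, layout$probe_id))

  # --- expression latents --------------------------------------------------
  set.seed(ss[3])
  zg <- matrix(stats::rnorm(n * config$n_gmds), n, config$n_gmds,
               dimnames = list(samples, gmds))
  for (eff in effects) {
    if (eff$kind == "epigenome_average") {
      g <- eff$source_id
      if (!g %in% gmds) stop("unknown GMD in planted effect: ", g)
      idx <- stratum_idx(eff$stratum)
      rl <- latent_rho(eff$rho_target)
      zg[idx, g] <- rl * f[idx] + sqrt(1 - rl^2) * stats::rnorm(length(idx))
    }
  }

  # assemble probe latents; planted methylation effects rewire them
  w_f <- 0.15; w_r <- 0.75; w_e <- sqrt(1 - w_f^2 - w_r^2)
  L <- w_f * f + w_r * u[, match(region_id, regions), drop = FALSE]
  L[, !genic] <- w_f * f + w_r *
    matrix(stats::rnorm(n * sum(!genic)), n, sum(!genic))
  L <- L + w_e * eps
  colnames(L) <- layout$probe_id

  for (eff in effects) {
    if (!eff$kind %in% c("expr_meth_trans", "expr_meth_cis")) next
    g <- eff$source_id
    if (!g %in% gmds) stop("unknown GMD in planted effect: ", g)
    idx <- stratum_idx(eff$stratum)
    rl <- latent_rho(eff$rho_target)
    v <- rl * zg[idx, g] + sqrt(1 - rl^2) * stats::rnorm(length(idx))
    if (grepl("^cg", eff$target_id)) {
      L[idx, eff$target_id] <- v
    } else {
      cols <- layout$probe_id[region_id == eff$target_id]
      if (!length(cols)) stop("unknown region in planted effect: ",
                              eff$target_id)
      pe <- 0.15  # residual probe-level noise within a planted region
      L[idx, cols] <- sqrt(1 - pe^2) * v +
        pe * matrix(stats::rnorm(length(idx) * length(cols)),
                    length(idx), length(cols))
    }
  }

  tau <- 1.3
  beta <- t(stats::plogis(matrix(ifelse(genic, m_r[region_id], 0),
                                 n, n_probes, byrow = TRUE) + tau * L))
  dimnames(beta) <- list(layout$probe_id, samples)

  expression <- t(exp(2 + 1.0 * zg))  # RPKM-like log-normal abundances

  # --- mutations -----------------------------------------------------------
  set.seed(ss[4])
  mut_rows <- list()
  flags_by_gene <- list()
  for (eff in effects) {
    if (eff$kind != "mutation_drug") next
    gene <- eff$source_id
    idx <- stratum_idx(eff$stratum)
    flag <- stats::rbinom(length(idx), 1, 0.15)
    if (sum(flag) < 2) flag[seq_len(2)] <- 1L
    if (sum(flag) > length(idx) - 2) flag[seq_len(2)] <- 0L
    full <- integer(n); full[idx] <- flag
    flags_by_gene[[gene]] <- pmax(flags_by_gene[[gene]] %||% integer(n), full)
    pc <- switch(gene, BRAF = "V600E", KRAS = "G12D", NRAS = "Q61K", "X100Y")
    mut_rows[[length(mut_rows) + 1L]] <- data.frame(
      sample_id = samples[full == 1L], gene_symbol = gene,
      protein_change = pc, variant_class = "non_synonymous",
      stringsAsFactors = FALSE)
  }
  # background synonymous variants for realism
  bg <- sample(samples, max(1L, round(0.03 * n)))
  mut_rows[[length(mut_rows) + 1L]] <- data.frame(
    sample_id = bg, gene_symbol = "BRAF", protein_change = "L613L",
    variant_class = "synonymous", stringsAsFactors = FALSE)
  mutations <- do.call(rbind, mut_rows)
  rownames(mutations) <- NULL

  # --- drug response -------------------------------------------------------
  set.seed(ss[5])
  za <- matrix(stats::rnorm(n * config$n_agents), n, config$n_agents,
               dimnames = list(samples, agents))
  mu_a <- stats::rnorm(config$n_agents, 0.5, 1)
  sig_a <- stats::runif(config$n_agents, 0.5, 1.5)
  index <- build_region_index(annotation)
  source_latent <- function(id) {
    if (grepl("^cg", id)) {
      s <- L[, id]
    } else if (grepl("|", id, fixed = TRUE)) {
      cols <- index[[id]]
      if (is.null(cols)) stop("unknown region in planted effect: ", id)
      s <- rowMeans(L[, cols, drop = FALSE])
    } else if (id %in% gmds) {
      s <- zg[, id]
    } else stop("unknown source id in planted effect: ", id)
    as.vector(scale(s))
  }
  for (eff in effects) {
    if (!eff$kind %in% c("meth_drug", "expr_drug")) next
    a <- match(eff$target_id, agents)
    if (is.na(a)) stop("unknown agent in planted effect: ", eff$target_id)
    idx <- stratum_idx(eff$stratum)
    rl <- latent_rho(eff$rho_target)
    s <- source_latent(eff$source_id)
    za[idx, a] <- rl * s[idx] + sqrt(1 - rl^2) * stats::rnorm(length(idx))
  }
  ic50 <- t(mu_a + t(za) * sig_a)  # samples x agents
  for (eff in effects) {
    if (eff$kind != "mutation_drug") next
    a <- match(eff$target_id, agents)
    if (is.na(a)) stop("unknown agent in planted effect: ", eff$target_id)
    flag <- flags_by_gene[[eff$source_id]]
    ic50[, a] <- ic50[, a] + eff$rho_target * sig_a[a] * flag
  }
  miss <- matrix(stats::runif(n * config$n_agents) < config$drug_missing_rate,
                 n, config$n_agents)
  ic50[miss] <- NA_real_
  drugs <- data.frame(
    agent_id = rep(agents, each = n),
    sample_id = rep(samples, times = config$n_agents),
    log_ic50 = as.vector(ic50),
    stringsAsFactors = FALSE
  )
  drugs <- drugs[!is.na(drugs$log_ic50), , drop = FALSE]
  rownames(drugs) <- NULL

  # --- detection p-values --------------------------------------------------
  set.seed(ss[6])
  detection_p <- matrix(stats::runif(n_probes * n, 0, 1e-8), n_probes, n,
                        dimnames = list(layout$probe_id, samples))
  gmd_probes <- layout$probe_id[layout$gene %in% gmds]
  fail_pool <- setdiff(layout$probe_id, c(protected, gmd_probes))
  if (config$n_failing_probes > length(fail_pool)) {
    stop("not enough unprotected probes to plant ", config$n_failing_probes,
         " failing probes")
  }
  failing <- sample(fail_pool, config$n_failing_probes)
  if (length(failing)) {
    detection_p[failing, ] <- stats::runif(length(failing) * n, 2e-6, 9e-4)
  }
  entry_fail <- matrix(stats::runif(n_probes * n) < config$detection_fail_rate,
                       n_probes, n)
  detection_p[entry_fail] <- stats::runif(sum(entry_fail), 1e-3, 5e-2)

  # --- SNP mask ------------------------------------------------------------
  set.seed(ss[7])
  snp_pool <- setdiff(fail_pool, failing)
  n_snp <- round(config$snp_masked_fraction * n_probes)
  if (n_snp > length(snp_pool)) {
    stop("snp_masked_fraction too high for the number of unprotected probes")
  }
  snp_mask <- sort(sample(snp_pool, n_snp))

  panel <- structure(
    list(expression = expression,
         beta = beta_matrix(beta, detection_p),
         drugs = drugs, mutations = mutations, categories = categories,
         annotation = annotation, snp_mask = snp_mask,
         ledger = NULL, config = config),
    class = "synthetic_panel")
  panel$ledger <- .build_ledger(panel, index, stratum_idx)
  panel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# realised correlation of each planted effect, measured on the observable
# tables the way the screens will see them
.build_ledger <- function(panel, index, stratum_idx) {
  cfg <- panel$config
  samples <- colnames(panel$expression)
  dmat <- drug_matrix(panel$drugs)
  observe <- function(id, idx) {
    sid <- samples[idx]
    if (grepl("^cg", id)) {
      panel$beta$beta[id, sid]
    } else if (id == "epigenome") {
      colMeans(panel$beta$beta[, sid, drop = FALSE])
    } else if (grepl("|", id, fixed = TRUE)) {
      colMeans(panel$beta$beta[index[[id]], sid, drop = FALSE])
    } else if (id %in% rownames(panel$expression)) {
      panel$expression[id, sid]
    } else if (id %in% rownames(dmat)) {
      dmat[id, sid]
    } else stop("cannot observe id: ", id)
  }
  effects <- cfg$planted_effects
  if (length(effects)) {
    rows <- lapply(effects, function(eff) {
      idx <- stratum_idx(eff$stratum)
      if (eff$kind == "mutation_drug") {
        mut <- unique(panel$mutations$sample_id[
          panel$mutations$gene_symbol == eff$source_id &
            panel$mutations$variant_class == "non_synonymous"])
        x <- as.numeric(samples[idx] %in% mut)
      } else {
        x <- observe(eff$source_id, idx)
      }
      y <- observe(eff$target_id, idx)
      realized <- spearman_cor(x, y, min_n = 3)$rho
      data.frame(kind = eff$kind, source_id = eff$source_id,
                 target_id = eff$target_id, stratum = eff$stratum,
                 rho_target = eff$rho_target, rho_realized = realized,
                 stringsAsFactors = FALSE)
    })
    eff_df <- do.call(rbind, rows)
  } else {
    eff_df <- data.frame(kind = character(0), source_id = character(0),
                         target_id = character(0), stratum = character(0),
                         rho_target = numeric(0), rho_realized = numeric(0),
                         stringsAsFactors = FALSE)
  }
  n_probes <- nrow(panel$beta$beta)
  structure(
    list(effects = eff_df,
         null_counts = list(
           gmd_probe_pairs = cfg$n_gmds * n_probes -
             sum(eff_df$kind %in% c("expr_meth_trans", "expr_meth_cis")),
           gmd_agent_pairs = cfg$n_gmds * cfg$n_agents -
             sum(eff_df$kind == "expr_drug"),
           meth_agent_pairs = n_probes * cfg$n_agents -
             sum(eff_df$kind == "meth_drug"))),
    class = "ground_truth_ledger")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("<synthetic_panel> ", ncol(x$expression), " cell lines, ",
      nrow(x$expression), " GMDs, ", nrow(x$beta$beta), " probes, ",
      length(unique(x$drugs$agent_id)), " agents, ",
      nrow(x$ledger$effects), " planted effects (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}
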