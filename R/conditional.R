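#' Mutation flags for conditional regression
#'
#' From a variant table, builds the three per-sample indicator covariates
#' used when re-testing predictors of MEK-inhibitor response: presence of
#' BRAF V600E, and presence of any non-synonymous KRAS or NRAS variant.
#' Samples absent from the table are wild-type by convention (all flags
#' false).
#'
#' @param mutations Data frame with columns \code{sample_id},
#'   \code{gene_symbol}, \code{protein_change}, \code{variant_class}
#'   (\code{synonymous} / \code{non_synonymous} / \code{other}).
#' @param sample_ids Character vector of all panel samples.
#' @return Data frame with columns \code{sample_id}, \code{braf_v600e},
#'   \code{kras_ns}, \code{nras_ns}.
#' @export
build_mutation_flags <- function(mutations, sample_ids) {
  stopifnot(all(c("sample_id", "gene_symbol", "protein_change",
                  "variant_class") %in% names(mutations)))
  pc <- sub("^p\\.", "", mutations$protein_change)
  braf <- unique(mutations$sample_id[
    mutations$gene_symbol == "BRAF" & pc == "V600E"])
  kras <- unique(mutations$sample_id[
    mutations$gene_symbol == "KRAS" &
      mutations$variant_class == "non_synonymous"])
  nras <- unique(mutations$sample_id[
    mutations$gene_symbol == "NRAS" &
      mutations$variant_class == "non_synonymous"])
  data.frame(sample_id = sample_ids,
             braf_v600e = sample_ids %in% braf,
             kras_ns = sample_ids %in% kras,
             nras_ns = sample_ids %in% nras,
             stringsAsFactors = FALSE)
}

#' Mutation-conditional linear regression of drug response
#'
#' Ordinary least-squares fit of log10(IC50) on the three mutation flags
#' plus one expression or methylation predictor, with two-sided t-tests
#' per coefficient. Flags constant over the complete cases (e.g. no
#' mutated line in a stratum) are dropped from the design with a warning
#' and the model refit; with all flags dropped the fit reduces exactly to
#' the simple regression on the predictor.
#'
#' @param log_ic50 Named numeric response vector.
#' @param predictor Named numeric predictor vector (expression or beta).
#' @param flags Mutation-flag data frame from [build_mutation_flags()].
#' @param sample_ids Optional sample subset (stratum).
#' @return Object of class \code{conditional_fit}: a list with
#'   \code{coefficients} (term, estimate, p_value), \code{predictor_coef},
#'   \code{predictor_p}, \code{n} and \code{dropped_flags}.
#' @export
fit_conditional <- function(log_ic50, predictor, flags, sample_ids = NULL) {
  ids <- intersect(names(log_ic50), names(predictor))
  ids <- intersect(ids, flags$sample_id)
  if (!is.null(sample_ids)) ids <- intersect(ids, sample_ids)
  fl <- flags[match(ids, flags$sample_id), , drop = FALSE]
  d <- data.frame(
    log_ic50 = log_ic50[ids],
    braf_v600e = as.numeric(fl$braf_v600e),
    kras_ns = as.numeric(fl$kras_ns),
    nras_ns = as.numeric(fl$nras_ns),
    predictor = predictor[ids]
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  flag_cols <- c("braf_v600e", "kras_ns", "nras_ns")
  constant <- vapply(d[flag_cols], function(v) length(unique(v)) < 2,
                     logical(1))
  if (any(constant)) {
    warning("flag(s) constant over complete cases, dropped from the design: ",
            paste(flag_cols[constant], collapse = ", "))
    d <- d[, !(names(d) %in% flag_cols[constant]), drop = FALSE]
  }
  n_par <- ncol(d)  # intercept + retained covariates
  if (nrow(d) < n_par + 2) {
    stop("too few complete cases (", nrow(d), ") for ", n_par,
         " parameters; need at least ", n_par + 2)
  }
  if (stats::var(d$predictor) == 0) {
    stop("predictor has zero variance over the complete cases")
  }
  fit <- stats::lm(log_ic50 ~ ., data = d)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      p_value = sm[, "Pr(>|t|)"], stringsAsFactors = FALSE,
                      row.names = NULL)
  structure(
    list(coefficients = coefs,
         predictor_coef = coefs$estimate[coefs$term == "predictor"],
         predictor_p = coefs$p_value[coefs$term == "predictor"],
         n = nrow(d),
         dropped_flags = flag_cols[constant]),
    class = "conditional_fit")
}

#' @export
print.conditional_fit <- function(x, ...) {
  cat("<conditional_fit> n = ", x$n, "; predictor coef = ",
      format(x$predictor_coef, digits = 4), ", p = ",
      format(x$predictor_p, digits = 4), "\n", sep = "")
  if (length(x$dropped_flags)) {
    cat("  dropped constant flags: ",
        paste(x$dropped_flags, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Conditional regression over a candidate set
#'
#' Refits every candidate predictor of one agent's response (those that
#' passed the |rho| > 0.5 screen gate) conditional on the mutation flags.
#' Predictor p-values are BH-adjusted over the candidate family; the flag
#' coefficients' p-values are reported unadjusted.
#'
#' @param candidates Data frame with columns \code{predictor}, \code{kind}
#'   (\code{expression} / \code{probe} / \code{region}) and \code{stratum},
#'   e.g. from [candidates_for_agent()].
#' @param agent Agent id whose response is the dependent variable.
#' @param drug_table Long drug-response table.
#' @param expression GMDs x samples matrix.
#' @param bm QC'd [beta_matrix()] (for probe predictors).
#' @param region_meth [average_regions()] output (for region predictors).
#' @param mutations Variant table (see [build_mutation_flags()]).
#' @param category_map Sample-to-category map resolving strata.
#' @return Data frame with one row per candidate: predictor identity,
#'   stratum, coefficient, raw and BH-adjusted predictor p, unadjusted
#'   flag p-values (NA where a flag was dropped) and the sample count.
#' @export
conditional_screen <- function(candidates, agent, drug_table, expression,
                               bm, region_meth, mutations, category_map) {
  beta <- if (inherits(bm, "beta_matrix")) bm$beta else bm
  dmat <- drug_matrix(drug_table)
  if (!agent %in% rownames(dmat)) stop("agent not in drug table: ", agent)
  y <- dmat[agent, ]
  all_samples <- unique(category_map$sample_id)
  flags <- build_mutation_flags(mutations, all_samples)
  if (nrow(candidates) == 0) {
    return(data.frame(predictor = character(0), kind = character(0),
                      stratum = character(0), coef = numeric(0),
                      p_raw = numeric(0), p_fdr = numeric(0),
                      braf_p = numeric(0), kras_p = numeric(0),
                      nras_p = numeric(0), n = integer(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    x <- switch(cand$kind,
                expression = expression[cand$predictor, ],
                probe = beta[cand$predictor, ],
                region = region_meth$values[cand$predictor, ],
                stop("unknown candidate kind: ", cand$kind))
    ids <- if (cand$stratum == "pancancer") all_samples else
      category_map$sample_id[category_map$category == cand$stratum]
    fit <- suppressWarnings(fit_conditional(y, x, flags, ids))
    flag_p <- function(term) {
      p <- fit$coefficients$p_value[fit$coefficients$term == term]
      if (length(p)) p else NA_real_
    }
    data.frame(predictor = cand$predictor, kind = cand$kind,
               stratum = cand$stratum, coef = fit$predictor_coef,
               p_raw = fit$predictor_p, p_fdr = NA_real_,
               braf_p = flag_p("braf_v600e"), kras_p = flag_p("kras_ns"),
               nras_p = flag_p("nras_ns"), n = fit$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_adjust(out$p_raw, nrow(out))
  rownames(out) <- NULL
  out
}
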