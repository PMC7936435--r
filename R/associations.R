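#' Spearman correlation with pairwise-complete samples
#'
#' Computes the Spearman rank correlation between two paired vectors after
#' pairwise deletion of entries missing in either vector. The p-value uses
#' the large-sample t approximation on \code{rho} with \code{n - 2} degrees
#' of freedom, the standard choice for panel-scale screens where exact
#' permutation nulls are infeasible.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param min_n Minimum number of pairwise-complete observations required;
#'   below this the pair is skipped (\code{rho} and \code{p_raw} are
#'   \code{NA} and \code{skip_reason} records why).
#' @return A list with elements \code{rho}, \code{p_raw}, \code{n} and
#'   \code{skip_reason} (\code{NA} when the pair was testable).
#' @examples
#' spearman_cor(1:10, (1:10)^2)  # rho = 1: monotone transform invariance
#' @export
spearman_cor <- function(x, y, min_n = 10) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length")
  }
  cc <- stats::complete.cases(x, y)
  n <- sum(cc)
  if (n < min_n) {
    return(list(rho = NA_real_, p_raw = NA_real_, n = n, skip_reason = "min_n"))
  }
  xr <- rank(x[cc])
  yr <- rank(y[cc])
  if (stats::var(xr) == 0 || stats::var(yr) == 0) {
    return(list(rho = NA_real_, p_raw = NA_real_, n = n,
                skip_reason = "zero_variance"))
  }
  rho <- stats::cor(xr, yr)
  list(rho = rho, p_raw = spearman_pvalue(rho, n), n = n,
       skip_reason = NA_character_)
}

#' t-approximation p-value for a Spearman coefficient
#'
#' Two-sided p-value for \code{rho} on \code{n} pairs from the statistic
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} referred to a t distribution
#' with \code{n - 2} degrees of freedom. Vectorised over matrices.
#'
#' @param rho Spearman coefficient(s) in \[-1, 1\].
#' @param n Sample size(s) used for each coefficient.
#' @return p-value(s), \code{NA} where \code{rho} is \code{NA} or
#'   \code{n < 3}; exactly 0 at \code{|rho| == 1}.
#' @export
spearman_pvalue <- function(rho, n) {
  df <- n - 2
  tt <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[is.nan(tt) | df < 1] <- NA_real_
  p[!is.na(rho) & abs(rho) == 1 & df >= 1] <- 0
  p
}

#' Benjamini-Hochberg adjustment over an explicit test-count family
#'
#' Step-up BH adjustment where the family size \code{test_count} is declared
#' explicitly as a product of the factors being screened (e.g. agents x
#' genes, optionally x cancer categories). When \code{test_count} exceeds
#' the number of p-values supplied, the family is padded with implicit
#' p = 1 tests: combinations that were skipped (too few samples, zero
#' variance) still count toward the multiplicity burden.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param test_count Declared family size; must be at least \code{length(p)}.
#' @return Adjusted p-values, clipped to \[0, 1\], in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03), 3)  # all 0.03
#' bh_adjust(0.001, 100)              # 0.1
#' @export
bh_adjust <- function(p, test_count) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] and non-missing")
  }
  if (test_count < length(p)) {
    stop("`test_count` (", test_count, ") is smaller than the number of ",
         "p-values (", length(p), "); the declared family must cover every test")
  }
  stats::p.adjust(p, method = "BH", n = test_count)
}

#' All-pairs Spearman screen between two feature-by-sample matrices
#'
#' Tests every predictor x target pair on the shared samples of a stratum,
#' using pairwise-complete observations per pair. Pairs failing the p or
#' |rho| cuts are retained in the output but flagged; the
#' "significant strong" subset satisfies both cuts. Pairs with fewer than
#' \code{min_n} complete observations, or with zero rank variance, are
#' skipped (NA statistics) but still count toward the declared FDR family.
#'
#' @param predictors,targets Numeric matrices with features in rows and
#'   samples in columns; row and column names are required.
#' @param stratum Label recorded on every output record ("pancancer" or a
#'   cancer-category label).
#' @param sample_ids Optional sample subset defining the stratum; default is
#'   all shared samples.
#' @param p_mode Which p-value the significance cut applies to: "fdr"
#'   (BH-adjusted, the default) or "raw" (fixed probe-level thresholds).
#' @param p_cut Significance threshold applied to the selected p-value.
#' @param abs_rho_cut Strength threshold on |rho| (strict inequality).
#' @param test_count Declared FDR family size; defaults to
#'   \code{nrow(predictors) * nrow(targets)}.
#' @param min_n Minimum pairwise-complete sample count per pair.
#' @param adjust If \code{FALSE}, skip the BH step (used when a caller pools
#'   records from several strata into one family before adjusting).
#' @return A data.frame with one row per pair: \code{predictor},
#'   \code{target}, \code{stratum}, \code{rho}, \code{p_raw}, \code{p_fdr},
#'   \code{n}, \code{skip_reason}, \code{significant_strong}. The declared
#'   family size is stored in \code{attr(, "test_count")}.
#' @export
screen <- function(predictors, targets, stratum = "pancancer",
                   sample_ids = NULL,
                   p_mode = c("fdr", "raw"), p_cut = 0.05, abs_rho_cut = 0.5,
                   test_count = NULL, min_n = 10, adjust = TRUE) {
  p_mode <- match.arg(p_mode)
  stopifnot(is.matrix(predictors), is.matrix(targets))
  shared <- intersect(colnames(predictors), colnames(targets))
  if (!is.null(sample_ids)) shared <- intersect(shared, sample_ids)
  if (length(shared) == 0) {
    stop("no shared samples between predictor and target tables",
         if (!is.null(sample_ids)) " within the requested stratum" else "")
  }
  X <- t(predictors[, shared, drop = FALSE])
  Y <- t(targets[, shared, drop = FALSE])
  np <- ncol(X)
  nt <- ncol(Y)
  if (is.null(test_count)) test_count <- np * nt

  nmat <- crossprod(!is.na(X) + 0, !is.na(Y) + 0)
  rho <- suppressWarnings(
    stats::cor(X, Y, method = "spearman", use = "pairwise.complete.obs")
  )
  rho[nmat < min_n] <- NA_real_
  p_raw <- spearman_pvalue(rho, nmat)

  skip <- rep(NA_character_, np * nt)
  skip[as.vector(nmat < min_n)] <- "min_n"
  skip[as.vector(nmat >= min_n & is.na(rho))] <- "zero_variance"

  rec <- data.frame(
    predictor = rep(colnames(X), times = nt),
    target = rep(colnames(Y), each = np),
    stratum = stratum,
    rho = as.vector(rho),
    p_raw = as.vector(p_raw),
    p_fdr = NA_real_,
    n = as.vector(nmat),
    skip_reason = skip,
    stringsAsFactors = FALSE
  )
  if (adjust) {
    ok <- !is.na(rec$p_raw)
    rec$p_fdr[ok] <- bh_adjust(rec$p_raw[ok], test_count)
  }
  p_sel <- if (p_mode == "fdr") rec$p_fdr else rec$p_raw
  rec$significant_strong <- !is.na(rec$rho) & !is.na(p_sel) &
    p_sel < p_cut & abs(rec$rho) > abs_rho_cut
  attr(rec, "test_count") <- test_count
  attr(rec, "p_mode") <- p_mode
  attr(rec, "p_cut") <- p_cut
  attr(rec, "abs_rho_cut") <- abs_rho_cut
  rec
}

#' Classify expression-methylation correlations as cis or trans
#'
#' A correlation is cis when the expression gene's symbol appears among the
#' genes annotated to the target methylation probe (or equals the gene of a
#' target region id of the form \code{"GENE|REGION"}); otherwise it is
#' trans. Probes annotated to no gene (intergenic) are trans.
#'
#' @param gmd_symbol Gene symbol of the expression predictor (recycled).
#' @param target_ids Character vector of probe ids or \code{"GENE|REGION"}
#'   region ids.
#' @param gene_map Named list mapping probe id to a character vector of
#'   annotated gene symbols, as returned by [probe_gene_map()]. Region ids
#'   are resolved from their embedded gene symbol and need no map entry.
#' @return Character vector of \code{"cis"} / \code{"trans"} calls.
#' @export
classify_cis_trans <- function(gmd_symbol, target_ids, gene_map) {
  stopifnot(length(gmd_symbol) == 1 || length(gmd_symbol) == length(target_ids))
  gmd <- rep_len(gmd_symbol, length(target_ids))
  is_region <- grepl("|", target_ids, fixed = TRUE)
  genes <- vector("list", length(target_ids))
  genes[is_region] <- sub("\\|.*$", "", target_ids[is_region])
  genes[!is_region] <- unname(gene_map[target_ids[!is_region]])
  is_cis <- mapply(function(g, gs) g %in% gs, gmd, genes,
                   USE.NAMES = FALSE)
  ifelse(is_cis, "cis", "trans")
}

#' Analysis strata from a cancer-category map
#'
#' Returns the pancancer stratum (all samples) plus every cancer category
#' with at least \code{min_size} samples, each with its sample-id set.
#'
#' @param category_map Data frame with columns \code{sample_id} and
#'   \code{category}.
#' @param min_size Category eligibility floor (default 10 cell lines).
#' @return Named list of sample-id vectors; the first element is always
#'   \code{pancancer}.
#' @export
stratify <- function(category_map, min_size = 10) {
  stopifnot(all(c("sample_id", "category") %in% names(category_map)))
  sizes <- table(category_map$category)
  eligible <- sort(names(sizes)[sizes >= min_size])
  strata <- c(
    list(pancancer = category_map$sample_id),
    lapply(stats::setNames(eligible, eligible), function(cat) {
      category_map$sample_id[category_map$category == cat]
    })
  )
  strata
}

#' Filter a record set to its significant-strong subset
#'
#' @param records A record data.frame from [screen()] or a pipeline stage.
#' @param abs_rho_cut Strength cut on |rho| (strict).
#' @param p_cut Significance cut.
#' @param p_mode Apply the cut to \code{"fdr"} or \code{"raw"} p-values.
#' @return The subset of rows passing both cuts.
#' @export
significant_strong <- function(records, abs_rho_cut = 0.5, p_cut = 0.05,
                               p_mode = c("fdr", "raw")) {
  p_mode <- match.arg(p_mode)
  p_sel <- if (p_mode == "fdr") records$p_fdr else records$p_raw
  keep <- !is.na(records$rho) & !is.na(p_sel) &
    p_sel < p_cut & abs(records$rho) > abs_rho_cut
  records[keep, , drop = FALSE]
}
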