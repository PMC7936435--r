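#' Methylation beta-value matrix with paired detection p-values
#'
#' Container for Infinium-style methylation data: a probes x samples matrix
#' of beta-values (methylated / total signal, in \[0, 1\]) and, optionally, a
#' matrix of per-measurement detection p-values of the same shape. Missing
#' betas are represented by \code{NA}, never by 0 (0 is a valid beta).
#'
#' @param beta Numeric matrix, probes in rows and samples in columns, with
#'   unique row and column names; non-missing values must lie in \[0, 1\].
#' @param detection_p Optional numeric matrix of detection p-values with
#'   identical dimnames.
#' @return An object of class \code{beta_matrix}.
#' @export
beta_matrix <- function(beta, detection_p = NULL) {
  stopifnot(is.matrix(beta), is.numeric(beta))
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("`beta` must have probe row names and sample column names")
  }
  if (anyDuplicated(rownames(beta))) stop("probe ids must be unique")
  if (anyDuplicated(colnames(beta))) stop("sample ids must be unique")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("beta-values must lie in [0, 1]; found range [",
         rng[1], ", ", rng[2], "]")
  }
  if (!is.null(detection_p)) {
    stopifnot(is.matrix(detection_p))
    if (!identical(dim(detection_p), dim(beta)) ||
        !identical(dimnames(detection_p), dimnames(beta))) {
      stop("`detection_p` must have the same dimnames as `beta`")
    }
  }
  structure(list(beta = beta, detection_p = detection_p),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("<beta_matrix> ", nrow(x$beta), " probes x ", ncol(x$beta),
      " samples; ", sum(is.na(x$beta)), " missing betas; detection p-values ",
      if (is.null(x$detection_p)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Mask individual low-confidence beta-values
#'
#' Sets beta to missing wherever the paired detection p-value is at or above
#' the threshold (the boundary is inclusive). Only beta entries are touched;
#' the detection matrix is left intact so that subsequent probe-level
#' filtering operates on the original detection p-values.
#'
#' @param bm A [beta_matrix()] with detection p-values present.
#' @param threshold Detection p-value at or above which an entry is masked;
#'   default \code{1e-3}.
#' @return The masked \code{beta_matrix}; the number of newly masked entries
#'   is recorded in \code{attr(, "n_masked")}.
#' @export
mask_low_confidence <- function(bm, threshold = 1e-3) {
  stopifnot(inherits(bm, "beta_matrix"))
  if (is.null(bm$detection_p)) {
    stop("detection p-values are absent; skip entry masking explicitly ",
         "rather than calling mask_low_confidence()")
  }
  flag <- bm$detection_p >= threshold & !is.na(bm$beta)
  bm$beta[bm$detection_p >= threshold] <- NA_real_
  attr(bm, "n_masked") <- sum(flag)
  bm
}

#' Drop probes whose median detection p-value fails
#'
#' Removes entire probes whose median detection p-value across all samples
#' is at or above the threshold (inclusive). The median is computed on the
#' raw detection matrix, including entries whose betas were masked, so that
#' entry masking and probe dropping commute.
#'
#' @param bm A [beta_matrix()] with detection p-values present.
#' @param threshold Median detection p-value at or above which a probe is
#'   dropped; default \code{1e-6}.
#' @return A list with the filtered \code{beta_matrix} and
#'   \code{dropped_probe_ids}.
#' @export
drop_failing_probes <- function(bm, threshold = 1e-6) {
  stopifnot(inherits(bm, "beta_matrix"))
  if (is.null(bm$detection_p)) {
    stop("detection p-values are absent; probe-level detection filtering ",
         "requires them")
  }
  med <- apply(bm$detection_p, 1, stats::median)
  dropped <- rownames(bm$beta)[med >= threshold]
  keep <- !(rownames(bm$beta) %in% dropped)
  bm$beta <- bm$beta[keep, , drop = FALSE]
  bm$detection_p <- bm$detection_p[keep, , drop = FALSE]
  list(beta_matrix = bm, dropped_probe_ids = dropped)
}

#' Drop probes on a SNP-overlap mask list
#'
#' Removes probes whose ids appear in the mask (e.g. the hg19 SNP-overlap
#' masking recommendations for the 450K array). Mask entries absent from
#' the matrix are counted but are not an error.
#'
#' @param bm A [beta_matrix()].
#' @param mask_list Character vector of probe ids to remove.
#' @return A list with the filtered \code{beta_matrix},
#'   \code{dropped_probe_ids} (mask entries present in the matrix) and
#'   \code{n_mask_absent} (mask entries not found).
#' @export
drop_snp_masked <- function(bm, mask_list) {
  stopifnot(inherits(bm, "beta_matrix"))
  mask_list <- unique(as.character(mask_list))
  dropped <- intersect(rownames(bm$beta), mask_list)
  keep <- !(rownames(bm$beta) %in% dropped)
  bm$beta <- bm$beta[keep, , drop = FALSE]
  if (!is.null(bm$detection_p)) {
    bm$detection_p <- bm$detection_p[keep, , drop = FALSE]
  }
  list(beta_matrix = bm, dropped_probe_ids = dropped,
       n_mask_absent = length(setdiff(mask_list, dropped)))
}

#' Full probe quality-control pipeline
#'
#' Applies, in order: per-entry masking of betas with detection p >= 1e-3,
#' removal of probes with median detection p >= 1e-6, and removal of
#' SNP-overlapping probes. Probe medians are computed on the raw detection
#' matrix, so the three rules commute; the SNP-drop count is taken after
#' the detection drop so the two drop counts are disjoint.
#'
#' @param bm A [beta_matrix()] with detection p-values (unless
#'   \code{mask_entries = FALSE} and no detection filtering is wanted).
#' @param snp_mask Character vector of SNP-overlap probe ids (may be empty).
#' @param entry_threshold,probe_threshold Detection thresholds for entry
#'   masking and probe-median dropping (both inclusive).
#' @return A list with the analysis-ready \code{beta_matrix} and a
#'   \code{qc_report} holding the filtering counts.
#' @export
run_qc <- function(bm, snp_mask = character(),
                   entry_threshold = 1e-3, probe_threshold = 1e-6) {
  stopifnot(inherits(bm, "beta_matrix"))
  n_input <- nrow(bm$beta)
  masked <- mask_low_confidence(bm, entry_threshold)
  n_masked <- attr(masked, "n_masked")
  det <- drop_failing_probes(masked, probe_threshold)
  snp <- drop_snp_masked(det$beta_matrix, snp_mask)
  report <- qc_report(
    n_input_probes = n_input,
    n_betas_masked = n_masked,
    n_probes_dropped_detection = length(det$dropped_probe_ids),
    n_probes_dropped_snp = length(snp$dropped_probe_ids),
    n_output_probes = nrow(snp$beta_matrix$beta)
  )
  list(beta_matrix = snp$beta_matrix, report = report)
}

#' QC filtering report
#'
#' @param n_input_probes,n_betas_masked,n_probes_dropped_detection,n_probes_dropped_snp,n_output_probes
#'   Filtering counts; output probes must equal input probes minus the two
#'   disjoint probe drops.
#' @return An object of class \code{qc_report}.
#' @export
qc_report <- function(n_input_probes, n_betas_masked,
                      n_probes_dropped_detection, n_probes_dropped_snp,
                      n_output_probes) {
  if (n_output_probes !=
      n_input_probes - n_probes_dropped_detection - n_probes_dropped_snp) {
    stop("inconsistent QC report: output probe count must equal input minus ",
         "the two disjoint probe drops")
  }
  structure(
    list(n_input_probes = n_input_probes,
         n_betas_masked = n_betas_masked,
         n_probes_dropped_detection = n_probes_dropped_detection,
         n_probes_dropped_snp = n_probes_dropped_snp,
         n_output_probes = n_output_probes),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Probe QC report\n",
      "  input probes:              ", x$n_input_probes, "\n",
      "  betas masked (entry p):    ", x$n_betas_masked, "\n",
      "  probes dropped (median p): ", x$n_probes_dropped_detection, "\n",
      "  probes dropped (SNP mask): ", x$n_probes_dropped_snp, "\n",
      "  output probes:             ", x$n_output_probes, "\n", sep = "")
  invisible(x)
}
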