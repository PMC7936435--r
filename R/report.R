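#' Directional counts of flagged correlations
#'
#' Counts positive and negative flagged records per predictor, stratum and
#' cis/trans relation -- the tabulation behind "which GMDs have the most
#' strong trans-correlations" style summaries. Positive and negative
#' counts sum to the number of flagged records for each key.
#'
#' @param records Record data.frame from a screen, with a logical flag
#'   column selecting the records to count.
#' @param flag_col Name of the flag column (default
#'   \code{"significant_strong"}).
#' @return Data frame with columns \code{predictor}, \code{stratum},
#'   \code{relation}, \code{n_positive}, \code{n_negative}, sorted by
#'   total count decreasing then predictor.
#' @export
summarize_directions <- function(records, flag_col = "significant_strong") {
  if (!NROW(records)) {
    return(data.frame(predictor = character(0), stratum = character(0),
                      relation = character(0), n_positive = integer(0),
                      n_negative = integer(0), stringsAsFactors = FALSE))
  }
  stopifnot(flag_col %in% names(records))
  sel <- records[records[[flag_col]] %in% TRUE, , drop = FALSE]
  if (!nrow(sel)) {
    return(data.frame(predictor = character(0), stratum = character(0),
                      relation = character(0), n_positive = integer(0),
                      n_negative = integer(0), stringsAsFactors = FALSE))
  }
  if (is.null(sel$relation)) sel$relation <- "not_applicable"
  key <- interaction(sel$predictor, sel$stratum, sel$relation, drop = TRUE,
                     sep = "\r")
  pos <- tapply(sel$rho > 0, key, sum)
  neg <- tapply(sel$rho < 0, key, sum)
  parts <- do.call(rbind, strsplit(names(pos), "\r", fixed = TRUE))
  out <- data.frame(predictor = parts[, 1], stratum = parts[, 2],
                    relation = parts[, 3],
                    n_positive = as.integer(pos),
                    n_negative = as.integer(neg),
                    stringsAsFactors = FALSE)
  out <- out[order(-(out$n_positive + out$n_negative), out$predictor,
                   out$stratum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a record set in supplementary-table style
#'
#' Writes one TSV with columns (stratum, predictor, target, rho, p_raw,
#' p_fdr, n, relation), sorted by adjusted p (raw p where no adjustment
#' was performed), then |rho| descending, then predictor and target
#' lexicographically -- a fixed total order so repeated exports diff
#' cleanly. Numeric columns keep full precision, so re-exporting a
#' re-loaded export reproduces the file byte-identically.
#'
#' @param records Record data.frame.
#' @param path Output TSV path.
#' @return The sorted data frame, invisibly.
#' @export
export_supplementary_style <- function(records, path) {
  cols <- c("stratum", "predictor", "target", "rho", "p_raw", "p_fdr", "n",
            "relation")
  if (!NROW(records)) {
    empty <- data.frame(matrix(ncol = length(cols), nrow = 0))
    names(empty) <- cols
    utils::write.table(empty, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(empty))
  }
  df <- records
  if (is.null(df$relation)) df$relation <- "not_applicable"
  df <- df[, cols, drop = FALSE]
  p_sort <- ifelse(is.na(df$p_fdr), df$p_raw, df$p_fdr)
  ord <- order(p_sort, -abs(df$rho), df$predictor, df$target,
               na.last = TRUE)
  df <- df[ord, , drop = FALSE]
  out <- df
  for (col in c("rho", "p_raw", "p_fdr")) out[[col]] <- fmt_num(df[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Write all pipeline result tables to a directory
#'
#' Emits supplementary-style TSVs for every screen, the QC report as JSON,
#' the conditional-regression table when present, and a JSON manifest with
#' record counts and md5 hashes of the written files.
#'
#' @param results A \code{methscreen_results} object from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param overwrite Overwrite existing files?
#' @return The written file paths, invisibly.
#' @export
write_results <- function(results, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(
    direct = results$direct,
    stage1_probes = results$stage1$probe_records,
    stage1_regions = results$stage1$region_records,
    stage2_probes = results$stage2$probe_records,
    stage2_regions = results$stage2$region_records,
    avgmeth_gmds = results$average_methylation$gmd_records,
    avgmeth_agents = results$average_methylation$agent_records)
  files <- file.path(dir, paste0(names(tables), ".tsv"))
  names(files) <- names(tables)
  qc_path <- file.path(dir, "qc_report.json")
  all_out <- c(files, qc_path)
  clash <- all_out[file.exists(all_out)]
  if (length(clash) && !overwrite) {
    stop("refusing to overwrite existing file(s): ",
         paste(basename(clash), collapse = ", "))
  }
  for (nm in names(tables)) {
    export_supplementary_style(tables[[nm]], files[[nm]])
  }
  write_qc_report(results$qc_report, qc_path)
  if (!is.null(results$conditional)) {
    cond_path <- file.path(dir, "conditional.tsv")
    out <- results$conditional
    for (col in c("coef", "p_raw", "p_fdr", "braf_p", "kras_p", "nras_p")) {
      out[[col]] <- fmt_num(out[[col]])
    }
    utils::write.table(out, cond_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    all_out <- c(all_out, cond_path)
  }
  manifest <- list(
    record_counts = lapply(tables, NROW),
    files = as.list(stats::setNames(
      unname(tools::md5sum(all_out)), basename(all_out))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(all_out, file.path(dir, "manifest.json")))
}
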