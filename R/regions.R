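#' The six gene-region categories of the 450K annotation
#'
#' TSS1500 (200-1500 bases upstream of the transcription start site),
#' TSS200 (0-200 bases upstream), 5'UTR, first exon, gene body, and 3'UTR.
#' Every region-averaging operation is restricted to this vocabulary, so a
#' gene contributes at most six regions.
#'
#' @return Character vector of the six category labels.
#' @export
region_categories <- function() {
  c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
}

#' Expand a probe annotation into (probe, gene, region) triples
#'
#' The annotation follows the 450K manifest dialect: per probe, semicolon-
#' delimited gene symbols positionally paired with semicolon-delimited
#' region categories. A probe with k distinct (gene, region) pairs yields k
#' rows; duplicate pairs are collapsed; intergenic probes (empty gene list)
#' yield none. Malformed rows -- unpaired lists, unknown categories, gene
#' symbols containing the "|" region separator -- are rejected loudly with
#' the probe named.
#'
#' @param annotation Data frame with columns \code{probe_id},
#'   \code{gene_symbols} and \code{region_categories} (plus any genomic
#'   columns, which are ignored here).
#' @return Data frame with columns \code{probe_id}, \code{gene},
#'   \code{region} and \code{region_id} (\code{"GENE|REGION"}).
#' @export
expand_annotation <- function(annotation) {
  stopifnot(all(c("probe_id", "gene_symbols", "region_categories") %in%
                  names(annotation)))
  genes <- strsplit(ifelse(is.na(annotation$gene_symbols), "",
                           annotation$gene_symbols), ";", fixed = TRUE)
  cats <- strsplit(ifelse(is.na(annotation$region_categories), "",
                          annotation$region_categories), ";", fixed = TRUE)
  n_g <- lengths(genes)
  n_c <- lengths(cats)
  bad <- which(n_g != n_c)
  if (length(bad)) {
    stop("annotation row for probe ", annotation$probe_id[bad[1]],
         " has ", n_g[bad[1]], " gene symbols but ", n_c[bad[1]],
         " region categories; lists must be positionally paired")
  }
  out <- data.frame(
    probe_id = rep(annotation$probe_id, n_g),
    gene = unlist(genes),
    region = unlist(cats),
    stringsAsFactors = FALSE
  )
  out <- out[out$gene != "", , drop = FALSE]
  unknown <- !(out$region %in% region_categories())
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop("probe ", out$probe_id[i], " carries unknown region category \"",
         out$region[i], "\"; expected one of: ",
         paste(region_categories(), collapse = ", "))
  }
  if (any(grepl("|", out$gene, fixed = TRUE))) {
    i <- which(grepl("|", out$gene, fixed = TRUE))[1]
    stop("probe ", out$probe_id[i], " has a gene symbol containing \"|\", ",
         "which is reserved as the region-id separator")
  }
  out <- unique(out)
  out$region_id <- paste(out$gene, out$region, sep = "|")
  rownames(out) <- NULL
  out
}

#' Index mapping each (gene, region) to its probe set
#'
#' Follows the IMA-style region summarisation: every probe with k distinct
#' (gene, region) annotation pairs appears in exactly k index entries;
#' intergenic probes appear in none.
#'
#' @param annotation Probe annotation data frame (manifest dialect); an
#'   already-expanded triple table from [expand_annotation()] is also
#'   accepted.
#' @return Named list, \code{"GENE|REGION"} to character vector of probe
#'   ids, sorted by region id.
#' @export
build_region_index <- function(annotation) {
  long <- if (all(c("gene", "region", "region_id") %in% names(annotation))) {
    annotation
  } else {
    expand_annotation(annotation)
  }
  split(long$probe_id, long$region_id)
}

#' Map each probe to its annotated gene symbols
#'
#' @param annotation Probe annotation data frame (manifest dialect).
#' @return Named list, probe id to character vector of gene symbols;
#'   intergenic probes are absent.
#' @export
probe_gene_map <- function(annotation) {
  long <- expand_annotation(annotation)
  lapply(split(long$gene, long$probe_id), unique)
}

#' Gene region-averaged methylation
#'
#' For each (gene, region) in the index and each sample, the value is the
#' unweighted arithmetic mean of the non-missing betas of the region's
#' probes present in the matrix; it is missing when all constituent betas
#' are missing for that sample. Regions with no probes in the matrix are
#' omitted. A one-probe region is valid.
#'
#' @param bm A QC'd [beta_matrix()] (or a plain probes x samples matrix).
#' @param index Region index from [build_region_index()].
#' @return An object of class \code{region_methylation}: list with
#'   \code{values} (regions x samples matrix), \code{n_probes} (named probe
#'   counts per region) and \code{genes} (gene symbol per region).
#' @export
average_regions <- function(bm, index) {
  beta <- if (inherits(bm, "beta_matrix")) bm$beta else bm
  stopifnot(is.matrix(beta))
  present <- lapply(index, intersect, x = rownames(beta))
  # keep regions with at least one probe in the matrix
  keep <- lengths(present) > 0
  present <- present[keep]
  if (length(present) == 0) {
    stop("no region in the index has probes present in the beta matrix")
  }
  region_of <- rep(names(present), lengths(present))
  B <- beta[unlist(present, use.names = FALSE), , drop = FALSE]
  notna <- !is.na(B)
  B[!notna] <- 0
  sums <- rowsum(B, region_of)          # sorted by region id
  cnts <- rowsum(notna + 0, region_of)
  values <- sums / cnts                 # 0/0 -> NaN where all missing
  values[is.nan(values)] <- NA_real_
  n_probes <- lengths(present)[rownames(values)]
  structure(
    list(values = values,
         n_probes = n_probes,
         genes = stats::setNames(sub("\\|.*$", "", rownames(values)),
                                 rownames(values))),
    class = "region_methylation"
  )
}

#' @export
print.region_methylation <- function(x, ...) {
  cat("<region_methylation> ", nrow(x$values), " gene regions x ",
      ncol(x$values), " samples (", length(unique(x$genes)), " genes)\n",
      sep = "")
  invisible(x)
}

#' Epigenome-average methylation per sample
#'
#' One value per sample: the mean beta over all non-missing retained
#' probes. Intended to be run on the QC'd matrix so the average spans
#' exactly the probes that passed filtering.
#'
#' @param bm A QC'd [beta_matrix()] or plain probes x samples matrix.
#' @return Named numeric vector of per-sample means; samples whose betas
#'   are all missing yield \code{NA} with a warning.
#' @export
epigenome_mean <- function(bm) {
  beta <- if (inherits(bm, "beta_matrix")) bm$beta else bm
  stopifnot(is.matrix(beta))
  m <- colMeans(beta, na.rm = TRUE)
  all_missing <- colSums(!is.na(beta)) == 0
  if (any(all_missing)) {
    warning("samples with no non-missing betas: ",
            paste(colnames(beta)[all_missing], collapse = ", "))
    m[all_missing] <- NA_real_
  }
  m
}
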