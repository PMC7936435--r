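# Readers and writers for the panel file set. TSV is the canonical on-disk
# format (portal-style matrices with the feature id in the first column);
# the annotation uses the 450K manifest CSV dialect. Numeric values are
# written with 17 significant digits so a write/read round trip reproduces
# every matrix bit-exactly.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
  names(df) <- id_col
  num <- as.data.frame(matrix(fmt_num(m), nrow(m), ncol(m)),
                       stringsAsFactors = FALSE)
  names(num) <- colnames(m)
  utils::write.table(cbind(df, num), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_matrix_tsv <- function(path, id_col) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != id_col) {
    stop("malformed header in ", path, ": expected first column \"",
         id_col, "\", found \"", names(df)[1], "\"")
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric values in ", path, ", column \"",
         names(df[-1])[bad], "\"")
  }
  rownames(m) <- ids
  m
}

#' Read an RPKM-like expression matrix
#'
#' @param path TSV with first column \code{gene_symbol} and one numeric
#'   column per sample.
#' @return Genes x samples numeric matrix; values must be non-negative.
#' @export
read_expression <- function(path) {
  m <- read_matrix_tsv(path, "gene_symbol")
  if (any(m < 0, na.rm = TRUE)) {
    i <- which(rowSums(m < 0, na.rm = TRUE) > 0)[1]
    stop("negative expression value at gene ", rownames(m)[i],
         " in ", path)
  }
  m
}

#' @rdname write_panel
#' @param expression Genes x samples matrix.
#' @param path Output file.
#' @export
write_expression <- function(expression, path) {
  write_matrix_tsv(expression, path, "gene_symbol")
}

#' Read a beta-value matrix (plus optional detection p-values)
#'
#' Betas outside \[0, 1\] are rejected with the offending probe named.
#'
#' @param path Beta TSV, first column \code{probe_id}.
#' @param detection_path Optional detection p-value TSV of the same shape.
#' @return A [beta_matrix()].
#' @export
read_beta <- function(path, detection_path = NULL) {
  b <- read_matrix_tsv(path, "probe_id")
  out_of_range <- rowSums(b < 0 | b > 1, na.rm = TRUE) > 0
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    stop("beta-value outside [0, 1] at probe ", rownames(b)[i],
         " (row ", i + 1L, " of ", path, ")")
  }
  dp <- if (!is.null(detection_path)) {
    read_matrix_tsv(detection_path, "probe_id")
  }
  beta_matrix(b, dp)
}

#' @rdname write_panel
#' @param bm A [beta_matrix()].
#' @param detection_path Where to write the detection matrix (skipped when
#'   absent or \code{NULL}).
#' @export
write_beta <- function(bm, path, detection_path = NULL) {
  write_matrix_tsv(bm$beta, path, "probe_id")
  if (!is.null(detection_path) && !is.null(bm$detection_p)) {
    write_matrix_tsv(bm$detection_p, detection_path, "probe_id")
  }
}

#' Read a long drug-response table
#'
#' Duplicate (agent, sample) measurements are averaged on load, with a
#' message reporting how many were collapsed.
#'
#' @param path TSV with columns \code{agent_id}, \code{sample_id},
#'   \code{log_ic50}.
#' @return Long data frame, one row per (agent, sample).
#' @export
read_drug_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("agent_id", "sample_id", "log_ic50")
  if (!all(need %in% names(df))) {
    stop("malformed header in ", path, ": need columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) df$log_ic50 <- numeric(0)
  if (!is.numeric(df$log_ic50)) stop("non-numeric log_ic50 in ", path)
  key <- paste(df$agent_id, df$sample_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate (agent, sample) measurement(s) in ",
            basename(path), " collapsed to their mean")
    means <- tapply(df$log_ic50, key, mean)
    first <- !dup
    df <- df[first, , drop = FALSE]
    df$log_ic50 <- as.numeric(means[paste(df$agent_id, df$sample_id,
                                          sep = "\r")])
  }
  rownames(df) <- NULL
  df
}

#' @rdname write_panel
#' @param drugs Long drug-response data frame.
#' @export
write_drug_table <- function(drugs, path) {
  out <- drugs
  out$log_ic50 <- fmt_num(out$log_ic50)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

# MAF Variant_Classification values that change the protein sequence
.maf_non_synonymous <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site")

#' Read a mutation table (native or minimal-MAF dialect)
#'
#' Native columns: \code{sample_id}, \code{gene_symbol},
#' \code{protein_change}, \code{variant_class}. Alternatively a
#' minimal MAF dialect (\code{Hugo_Symbol}, \code{Tumor_Sample_Barcode},
#' \code{HGVSp_Short}, \code{Variant_Classification}) is mapped onto it:
#' protein-changing classes become \code{non_synonymous}, \code{Silent}
#' becomes \code{synonymous}, anything else \code{other}.
#'
#' @param path Mutation TSV.
#' @return Data frame in the native column layout.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  native <- c("sample_id", "gene_symbol", "protein_change", "variant_class")
  maf <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "HGVSp_Short",
           "Variant_Classification")
  if (all(native %in% names(df))) {
    return(df[native])
  }
  if (all(maf %in% names(df))) {
    cls <- ifelse(df$Variant_Classification %in% .maf_non_synonymous,
                  "non_synonymous",
                  ifelse(df$Variant_Classification %in%
                           c("Silent", "Synonymous"), "synonymous", "other"))
    return(data.frame(sample_id = df$Tumor_Sample_Barcode,
                      gene_symbol = df$Hugo_Symbol,
                      protein_change = sub("^p\\.", "", df$HGVSp_Short),
                      variant_class = cls, stringsAsFactors = FALSE))
  }
  stop("malformed header in ", path, ": need either native columns (",
       paste(native, collapse = ", "), ") or MAF columns (",
       paste(maf, collapse = ", "), ")")
}

#' @rdname write_panel
#' @param mutations Mutation data frame (native layout).
#' @export
write_mutations <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a cell-line-to-cancer-category map
#'
#' @param path TSV with columns \code{sample_id}, \code{category}.
#' @return Data frame.
#' @export
read_categories <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "category") %in% names(df))) {
    stop("malformed header in ", path,
         ": need columns sample_id, category")
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in ", path)
  }
  df
}

#' @rdname write_panel
#' @param categories Category-map data frame.
#' @export
write_categories <- function(categories, path) {
  utils::write.table(categories, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a 450K-manifest-dialect probe annotation
#'
#' Validates that the semicolon-delimited gene and region lists are
#' positionally paired and that region categories come from the
#' six-category vocabulary (checked lazily by [expand_annotation()]).
#'
#' @param path CSV with columns \code{probe_id}, \code{chromosome},
#'   \code{position}, \code{cytoband}, \code{gene_symbols},
#'   \code{region_categories}.
#' @return Annotation data frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(gene_symbols = "character",
                                       region_categories = "character"))
  need <- c("probe_id", "chromosome", "position", "cytoband",
            "gene_symbols", "region_categories")
  if (!all(need %in% names(df))) {
    stop("malformed header in ", path, ": need columns ",
         paste(need, collapse = ", "))
  }
  expand_annotation(df)  # validation only; errors name the probe
  df
}

#' @rdname write_panel
#' @param annotation Annotation data frame.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.csv(annotation, path, row.names = FALSE, quote = FALSE)
}

#' Read a SNP-overlap probe mask (one probe id per line)
#'
#' @param path Plain-text mask file.
#' @return Character vector of probe ids.
#' @export
read_snp_mask <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' @rdname write_panel
#' @param snp_mask Character vector of masked probe ids.
#' @export
write_snp_mask <- function(snp_mask, path) {
  writeLines(snp_mask, path)
}

#' Write / read a full panel file set
#'
#' \code{write_panel()} emits the exact file formats the readers consume:
#' \code{expression.tsv}, \code{beta.tsv}, \code{detection.tsv},
#' \code{drugs.tsv}, \code{mutations.tsv}, \code{categories.tsv},
#' \code{annotation.csv}, \code{snp_mask.txt}, \code{ledger.json} and
#' \code{config.yaml}. Existing files are refused unless
#' \code{overwrite = TRUE}. \code{read_panel()} reloads the set; a
#' write/read round trip reproduces all matrices bit-exactly.
#'
#' @param panel A [generate_panel()] result (or compatible list).
#' @param dir Output directory (created if needed).
#' @param overwrite Overwrite existing files?
#' @return \code{write_panel()}: the file paths, invisibly;
#'   \code{read_panel()}: the reloaded panel list.
#' @export
write_panel <- function(panel, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, c("expression.tsv", "beta.tsv", "detection.tsv",
                            "drugs.tsv", "mutations.tsv", "categories.tsv",
                            "annotation.csv", "snp_mask.txt", "ledger.json",
                            "config.yaml"))
  names(files) <- c("expression", "beta", "detection", "drugs", "mutations",
                    "categories", "annotation", "snp_mask", "ledger",
                    "config")
  clash <- files[file.exists(files)]
  if (length(clash) && !overwrite) {
    stop("refusing to overwrite existing file(s): ",
         paste(basename(clash), collapse = ", "),
         "; pass overwrite = TRUE to replace them")
  }
  write_expression(panel$expression, files["expression"])
  write_beta(panel$beta, files["beta"], files["detection"])
  write_drug_table(panel$drugs, files["drugs"])
  write_mutations(panel$mutations, files["mutations"])
  write_categories(panel$categories, files["categories"])
  write_annotation(panel$annotation, files["annotation"])
  write_snp_mask(panel$snp_mask, files["snp_mask"])
  if (!is.null(panel$ledger)) {
    jsonlite::write_json(list(effects = panel$ledger$effects,
                              null_counts = panel$ledger$null_counts),
                         files["ledger"], auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(panel$config)) {
    cfg <- unclass(panel$config)
    cfg$planted_effects <- lapply(cfg$planted_effects, unclass)
    yaml::write_yaml(cfg, files["config"])
  }
  invisible(files)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  detection <- file.path(dir, "detection.tsv")
  ledger_path <- file.path(dir, "ledger.json")
  config_path <- file.path(dir, "config.yaml")
  list(
    expression = read_expression(file.path(dir, "expression.tsv")),
    beta = read_beta(file.path(dir, "beta.tsv"),
                     if (file.exists(detection)) detection),
    drugs = read_drug_table(file.path(dir, "drugs.tsv")),
    mutations = read_mutations(file.path(dir, "mutations.tsv")),
    categories = read_categories(file.path(dir, "categories.tsv")),
    annotation = read_annotation(file.path(dir, "annotation.csv")),
    snp_mask = read_snp_mask(file.path(dir, "snp_mask.txt")),
    ledger = if (file.exists(ledger_path)) {
      jsonlite::read_json(ledger_path, simplifyVector = TRUE)
    },
    config = if (file.exists(config_path)) yaml::read_yaml(config_path)
  )
}

#' Write a QC report as JSON
#'
#' @param report A [qc_report()].
#' @param path Output file.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
}
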