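#' Assemble a multi-omic cohort bundle
#'
#' A cohort bundle holds the four aligned data layers of a tumor cohort —
#' log-scale expression (logTPM), promoter methylation probe beta-values,
#' gene-level copy-number calls — together with the probe-to-gene promoter
#' map and per-sample annotations (tissue, matched pair, molecular subtype).
#' Samples are aligned by id intersection across layers: array platforms
#' rarely cover identical sample sets, so samples absent from the annotation
#' or from a layer are dropped with a warning rather than raising an error.
#'
#' @param expression numeric matrix, genes x samples, log-scale abundance
#'   (logTPM); rownames are gene ids, colnames sample ids.
#' @param methylation numeric matrix, probes x samples, beta-values in
#'   \[0, 1\] (`NA` allowed for missing probes).
#' @param promoter_map data frame with columns `probe_id`, `gene_id` and
#'   optionally `tss_distance` (signed bp, negative = upstream of the TSS).
#' @param cnv integer matrix, genes x samples, copy-number categories in
#'   \{-2, -1, 0, 1, 2\} (`NA` allowed).
#' @param annotation data frame with columns `sample_id`,
#'   `tissue` (`"tumor"` or `"normal"`), `matched_pair_id` (`NA` if
#'   unmatched) and `subtype_label` (`"1"`, `"2"`, `"3"` or `"unknown"`;
#'   always `"unknown"`/`NA` for normals).
#'
#' @return An object of class `cohort_bundle`: a list with elements
#'   `expression`, `methylation`, `promoter_map`, `cnv`, `annotation`.
#' @seealso [read_cohort()], [validate_cohort()], [simulate_cohort()]
#' @export
cohort_bundle <- function(expression, methylation, promoter_map, cnv, annotation) {
  annotation <- tibble::as_tibble(annotation)
  if (!all(c("sample_id", "tissue") %in% names(annotation))) {
    abort("`annotation` needs at least columns `sample_id` and `tissue`")
  }
  if (!"matched_pair_id" %in% names(annotation)) annotation$matched_pair_id <- NA_character_
  if (!"subtype_label" %in% names(annotation)) annotation$subtype_label <- "unknown"
  annotation$subtype_label <- as.character(annotation$subtype_label)
  annotation$subtype_label[is.na(annotation$subtype_label)] <- "unknown"

  keep <- intersect(
    intersect(colnames(expression), colnames(methylation)),
    intersect(colnames(cnv), annotation$sample_id)
  )
  if (length(keep) == 0) abort("no samples shared across all layers and the annotation")
  dropped <- setdiff(
    unique(c(colnames(expression), colnames(methylation), colnames(cnv))), keep
  )
  if (length(dropped) > 0) {
    warn(sprintf("%d sample(s) absent from some layer dropped: %s",
                 length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  inform(sprintf("%d samples retained", length(keep)))

  out <- structure(
    list(
      expression   = expression[, keep, drop = FALSE],
      methylation  = methylation[, keep, drop = FALSE],
      promoter_map = tibble::as_tibble(promoter_map),
      cnv          = cnv[, keep, drop = FALSE],
      annotation   = annotation[match(keep, annotation$sample_id), , drop = FALSE]
    ),
    class = "cohort_bundle"
  )
  out
}

#' @export
print.cohort_bundle <- function(x, ...) {
  ann <- x$annotation
  cat("<cohort_bundle>\n")
  cat(sprintf("  %d genes x %d samples (expression), %d probes (methylation)\n",
              nrow(x$expression), ncol(x$expression), nrow(x$methylation)))
  cat(sprintf("  tumors: %d  normals: %d  labeled tumors: %d\n",
              sum(ann$tissue == "tumor"), sum(ann$tissue == "normal"),
              sum(ann$tissue == "tumor" & ann$subtype_label != "unknown")))
  invisible(x)
}

#' Read a cohort from TSV files
#'
#' Each matrix file is tab-delimited with a header row of sample ids and
#' feature ids in the first column.  The annotation file has columns
#' `sample_id`, `tissue`, `matched_pair_id`, `subtype_label`; the promoter
#' map has `probe_id`, `gene_id` and optionally `tss_distance`.  Missing
#' values are written as the literal token `NA`.
#'
#' @param expression_path,methylation_path,promoter_map_path,cnv_path,annotation_path
#'   paths to the five TSV files.
#' @return A validated [cohort_bundle()].  Beta-values outside \[0, 1\] or
#'   copy-number calls outside \{-2..2\} raise an error naming the offending
#'   feature and sample.
#' @export
read_cohort <- function(expression_path, methylation_path, promoter_map_path,
                        cnv_path, annotation_path) {
  read_m <- function(path) {
    # read as text and convert with base R's correctly rounded strtod so
    # the %.17g representation written by write_cohort round-trips exactly
    df <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                          progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    if (ncol(df) < 2) abort(sprintf("malformed TSV (need id column + samples): %s", path))
    df[-1] <- lapply(df[-1], as.numeric)
    df_to_matrix(df)
  }
  expression  <- read_m(expression_path)
  methylation <- read_m(methylation_path)
  cnv         <- read_m(cnv_path)
  if (all(is.na(cnv) | cnv == round(cnv))) storage.mode(cnv) <- "integer"
  promoter_map <- readr::read_tsv(promoter_map_path, show_col_types = FALSE,
                                  na = "NA", progress = FALSE)
  annotation <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                                na = "NA", progress = FALSE,
                                col_types = readr::cols(.default = readr::col_character()))

  bad <- which(methylation < 0 | methylation > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("beta-value out of [0,1]: probe %s, sample %s (%s)",
                  rownames(methylation)[bad[1, 1]],
                  colnames(methylation)[bad[1, 2]], methylation_path))
  }
  bad <- which(!cnv %in% c(-2:2, NA), arr.ind = FALSE)
  if (length(bad) > 0) {
    idx <- arrayInd(bad[1], dim(cnv))
    abort(sprintf("copy-number call outside {-2..2}: gene %s, sample %s (%s)",
                  rownames(cnv)[idx[1]], colnames(cnv)[idx[2]], cnv_path))
  }
  cohort_bundle(expression, methylation, promoter_map, cnv, annotation)
}

#' Write a cohort bundle to TSV files
#'
#' Inverse of [read_cohort()]: finite values round-trip bit-identically
#' because numbers are serialized at full precision (R's default 15
#' significant digits).
#'
#' @param bundle a [cohort_bundle()].
#' @param dir output directory, created if needed.
#' @return Invisibly, a named character vector of the five file paths.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression   = file.path(dir, "expression.tsv"),
    methylation  = file.path(dir, "methylation.tsv"),
    promoter_map = file.path(dir, "promoter_map.tsv"),
    cnv          = file.path(dir, "cnv.tsv"),
    annotation   = file.path(dir, "annotation.tsv")
  )
  # %.17g guarantees exact double round-trips through the text files
  full_precision <- function(m, col) {
    ch <- matrix(ifelse(is.na(m), NA_character_, sprintf("%.17g", m)),
                 nrow = nrow(m), dimnames = dimnames(m))
    dplyr::bind_cols(tibble::tibble(!!col := rownames(m)),
                     tibble::as_tibble(ch, .name_repair = "minimal"))
  }
  readr::write_tsv(full_precision(bundle$expression, "gene_id"), paths["expression"], na = "NA")
  readr::write_tsv(full_precision(bundle$methylation, "probe_id"), paths["methylation"], na = "NA")
  readr::write_tsv(bundle$promoter_map, paths["promoter_map"], na = "NA")
  readr::write_tsv(matrix_to_tibble(bundle$cnv, "gene_id"), paths["cnv"], na = "NA")
  readr::write_tsv(bundle$annotation, paths["annotation"], na = "NA")
  invisible(paths)
}

#' Validate a cohort bundle against its structural invariants
#'
#' Runs every structural check — unique ids, beta-values in \[0, 1\],
#' copy-number calls in \{-2..2\}, promoter probes mapping to known genes,
#' matched normals referencing existing tumors, subtype labels restricted to
#' tumor samples, at least two tumors per known subtype — and reports each
#' with offending ids rather than stopping at the first failure.
#'
#' @param bundle a [cohort_bundle()].
#' @return A tibble with columns `check`, `pass`, `detail`, one row per
#'   invariant, with attribute `pass` giving the overall flag (also exposed
#'   by [cohort_is_valid()]).
#' @export
validate_cohort <- function(bundle) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  ann <- bundle$annotation
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(check = name, pass = pass, detail = detail)
  }

  dup <- function(x) unique(x[duplicated(x)])
  add("unique gene ids (expression)", !anyDuplicated(rownames(bundle$expression)),
      paste(dup(rownames(bundle$expression)), collapse = ","))
  add("unique probe ids", !anyDuplicated(rownames(bundle$methylation)),
      paste(dup(rownames(bundle$methylation)), collapse = ","))
  add("expression finite", all(is.finite(bundle$expression)), "")
  add("at least 2 samples", ncol(bundle$expression) >= 2,
      sprintf("%d samples", ncol(bundle$expression)))

  bad_beta <- which(bundle$methylation < 0 | bundle$methylation > 1, arr.ind = TRUE)
  add("beta-values in [0,1] or NA", nrow(bad_beta) == 0,
      if (nrow(bad_beta) > 0) {
        sprintf("probe %s sample %s", rownames(bundle$methylation)[bad_beta[1, 1]],
                colnames(bundle$methylation)[bad_beta[1, 2]])
      } else "")

  bad_cnv <- which(!(bundle$cnv %in% c(-2:2)) & !is.na(bundle$cnv))
  add("CNV calls in {-2..2} or NA", length(bad_cnv) == 0,
      if (length(bad_cnv) > 0) {
        idx <- arrayInd(bad_cnv[1], dim(bundle$cnv))
        sprintf("gene %s sample %s", rownames(bundle$cnv)[idx[1]],
                colnames(bundle$cnv)[idx[2]])
      } else "")

  pm <- bundle$promoter_map
  add("promoter map (probe, gene) pairs unique",
      !anyDuplicated(paste(pm$probe_id, pm$gene_id)), "")
  orphan <- setdiff(rownames(bundle$methylation), pm$probe_id)
  add("every probe maps to >= 1 gene", length(orphan) == 0,
      paste(head(orphan, 5), collapse = ","))

  add("annotation covers all matrix samples",
      all(colnames(bundle$expression) %in% ann$sample_id), "")

  normals <- ann[ann$tissue == "normal", ]
  tumors  <- ann[ann$tissue == "tumor", ]
  bad_pair <- normals$sample_id[!is.na(normals$matched_pair_id) &
                                  !(normals$matched_pair_id %in% tumors$sample_id)]
  add("matched normals reference existing tumors", length(bad_pair) == 0,
      paste(head(bad_pair, 5), collapse = ","))

  labeled_normals <- normals$sample_id[normals$subtype_label != "unknown"]
  add("subtype labels only on tumors", length(labeled_normals) == 0,
      paste(head(labeled_normals, 5), collapse = ","))

  known <- table(tumors$subtype_label[tumors$subtype_label != "unknown"])
  add("at least 2 tumors per known subtype", length(known) == 0 || all(known >= 2),
      paste(names(known)[known < 2], collapse = ","))

  out <- dplyr::bind_rows(checks)
  attr(out, "pass") <- all(out$pass)
  class(out) <- c("cohort_validation", class(out))
  out
}

#' @rdname validate_cohort
#' @export
cohort_is_valid <- function(bundle) {
  isTRUE(attr(suppressMessages(validate_cohort(bundle)), "pass"))
}

#' Z-score normalize a matrix
#'
#' Centers and scales each feature (row) or each sample (column) to mean 0
#' and unit sample standard deviation (n - 1 denominator), the display-scale
#' transform used for expression heatmaps.  Constant rows cannot be scaled;
#' they are set to all-zero and flagged in the `constant` attribute.
#'
#' @param x numeric matrix.
#' @param axis `"feature"` (default; normalize each row across samples) or
#'   `"sample"` (each column across features).
#' @return A matrix of z-scores with attribute `constant`, a logical vector
#'   marking degenerate (zero-variance) features or samples.
#' @examples
#' z_normalize(rbind(a = c(1, 2, 3), b = c(5, 5, 5)))
#' @export
z_normalize <- function(x, axis = c("feature", "sample")) {
  axis <- match.arg(axis)
  if (axis == "sample") {
    out <- z_normalize(t(x), axis = "feature")
    res <- t(out)
    attr(res, "constant") <- attr(out, "constant")
    return(res)
  }
  if (ncol(x) < 2) abort("z_normalize needs >= 2 samples per feature")
  mu <- rowMeans(x, na.rm = TRUE)
  sdv <- apply(x, 1, sd, na.rm = TRUE)
  constant <- !is.na(sdv) & sdv == 0
  sdv[constant | sdv == 0] <- 1
  z <- (x - mu) / sdv
  z[constant, ] <- 0
  attr(z, "constant") <- constant
  z
}
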