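#' Read an expression matrix from TSV or GCT
#'
#' TSV dialect: first column holds row identifiers, header row holds sample
#' identifiers, tab-delimited, `.` decimal. GCT follows the 1.2 convention
#' (`#1.2` version line, dimension line, `Name`/`Description` columns).
#'
#' @param path File path.
#' @param format `"tsv"` or `"gct"`.
#' @return An [expression_matrix] with identifiers in file order.
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
  } else {
    lines <- readLines(path)
    if (length(lines) < 3L || trimws(lines[1L]) != "#1.2")
      stop_invalid("not a GCT 1.2 file (missing '#1.2' version line): ", path)
    dims <- as.integer(strsplit(lines[2L], "\t")[[1L]][1:2])
    df <- read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                     header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L])
      stop_invalid(sprintf(
        "GCT header declares %d x %d but body has %d x %d",
        dims[1L], dims[2L], nrow(df), ncol(df) - 2L))
    ids <- as.character(df[[1L]])
    vals <- as.matrix(df[, -(1:2), drop = FALSE])
  }
  storage.mode(vals) <- "double"
  if (anyDuplicated(ids))
    stop_invalid("duplicate row identifier in ", path, ": ",
                 ids[duplicated(ids)][1L])
  if (any(!is.finite(vals))) stop_invalid("non-finite values in ", path)
  if (any(vals < 0))
    stop_invalid("negative values in ", path,
                 " (pipeline requires non-negative expression)")
  rownames(vals) <- ids
  expression_matrix(vals)
}

#' Write an expression matrix to TSV or GCT 1.2
#'
#' @param expr An [expression_matrix].
#' @param path Output path.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  vals <- expr$values
  if (format == "tsv") {
    df <- data.frame(id = rownames(vals), vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(vals), ncol(vals), sep = "\t")), con)
    df <- data.frame(Name = rownames(vals), Description = "na", vals,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Two-level gene-set catalog: pathways -> transcription factors -> targets
#'
#' @param pathways Named list mapping pathway names to character vectors of
#'   transcription-factor (TF) names.
#' @param tf_targets Named list mapping TF names to character vectors of
#'   target gene identifiers. Targets are de-duplicated; every TF referenced
#'   by a pathway must be present.
#' @return An object of class `gene_set_catalog`.
#' @export
gene_set_catalog <- function(pathways, tf_targets) {
  if (!is.list(pathways) || is.null(names(pathways)))
    stop_invalid("`pathways` must be a named list")
  if (!is.list(tf_targets) || is.null(names(tf_targets)))
    stop_invalid("`tf_targets` must be a named list")
  tf_targets <- lapply(tf_targets, function(g) unique(as.character(g)))
  for (pw in names(pathways)) {
    pathways[[pw]] <- as.character(pathways[[pw]])
    missing <- setdiff(pathways[[pw]], names(tf_targets))
    if (length(missing))
      stop_invalid("pathway '", pw, "' references unknown TF: ",
                   paste(missing, collapse = ", "))
  }
  structure(list(pathways = pathways, tf_targets = tf_targets),
            class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat(sprintf("gene_set_catalog: %d pathways, %d TF target sets\n",
              length(x$pathways), length(x$tf_targets)))
  invisible(x)
}

#' Read a gene-set catalog from pathway JSON or GMT
#'
#' The pathway JSON holds the full two-level structure
#' (`{"pathways": {...}, "tf_targets": {...}}`). GMT rows are TF-level sets
#' whose set name encodes the pathway as the prefix before the first `|`
#' (`PATHWAY|TF`); the description field is ignored.
#'
#' @param path File path.
#' @param format `"pathway_json"` or `"gmt"`.
#' @return A [gene_set_catalog].
#' @export
read_catalog <- function(path, format = c("pathway_json", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (format == "pathway_json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$pathways) || is.null(obj$tf_targets))
      stop_invalid("pathway JSON must contain 'pathways' and 'tf_targets'")
    gene_set_catalog(as.list(obj$pathways), as.list(obj$tf_targets))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    pathways <- list()
    tf_targets <- list()
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(parts) < 3L)
        stop_invalid("malformed GMT line (need name, description, genes): ",
                     substr(ln, 1, 50))
      name <- parts[1L]
      bits <- strsplit(name, "|", fixed = TRUE)[[1L]]
      if (length(bits) < 2L)
        stop_invalid("GMT set name lacks 'PATHWAY|TF' structure: ", name)
      pw <- bits[1L]
      tf <- paste(bits[-1L], collapse = "|")
      pathways[[pw]] <- unique(c(pathways[[pw]], tf))
      tf_targets[[tf]] <- unique(c(tf_targets[[tf]], parts[-(1:2)]))
    }
    gene_set_catalog(pathways, tf_targets)
  }
}

#' Write a gene-set catalog to pathway JSON or GMT
#'
#' @inheritParams read_catalog
#' @param catalog A [gene_set_catalog].
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, format = c("pathway_json", "gmt")) {
  format <- match.arg(format)
  if (format == "pathway_json") {
    jsonlite::write_json(list(pathways = catalog$pathways,
                              tf_targets = catalog$tf_targets),
                         path, auto_unbox = FALSE, pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (pw in names(catalog$pathways))
      for (tf in catalog$pathways[[pw]])
        writeLines(paste(c(paste0(pw, "|", tf), "na",
                           catalog$tf_targets[[tf]]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Pathway-level gene set (union of TF target lists)
#'
#' @param catalog A [gene_set_catalog].
#' @param pathway Pathway name.
#' @return Character vector: de-duplicated union of the targets of the
#'   pathway's TFs.
#' @export
pathway_set <- function(catalog, pathway) {
  if (!pathway %in% names(catalog$pathways))
    stop_invalid("unknown pathway: ", pathway)
  unique(unlist(catalog$tf_targets[catalog$pathways[[pathway]]],
                use.names = FALSE))
}

catalog_gene_universe <- function(catalog) {
  unique(unlist(catalog$tf_targets, use.names = FALSE))
}
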