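#' @title Compendium data structures and file formats
#' @description The unit every analysis stage consumes is a *compendium*:
#'   a log2 expression matrix (genes x samples), a sample metadata table, and
#'   optionally a gene-set collection. All on-disk formats are plain text:
#'   tab-separated expression and metadata tables, and the Broad/MSigDB GMT
#'   format for gene sets.
#' @name data_model
NULL

# Canonical superset labels for grouping gene sets into markers of cell
# subsets / canonical pathways.
SUPERSET_LABELS <- c("T_cells", "NK_cells", "B_cells", "monocytes_DCs",
                     "inflammation", "E2F_MYC", "ISGs")

REQUIRED_META_COLS <- c("sample_id", "participant_id", "study_id", "platform",
                        "sample_type", "vaccine", "day")

# Days treated as pre-vaccination throughout the pipeline.
PREVAX_DAYS <- c(-7L, 0L)

is_prevax <- function(day) day %in% PREVAX_DAYS

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene symbols; no empty set,
#'   no duplicate gene within a set, unique set names.
#' @param superset_map optional named character vector mapping set names to
#'   one of the seven superset labels (`T_cells`, `NK_cells`, `B_cells`,
#'   `monocytes_DCs`, `inflammation`, `E2F_MYC`, `ISGs`).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, superset_map = NULL) {
  if (is.null(names(sets)) && length(sets) > 0) stop("sets must be named")
  if (anyDuplicated(names(sets))) {
    stop("duplicate set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  for (nm in names(sets)) {
    g <- sets[[nm]]
    if (!length(g)) stop("empty gene set: ", nm)
    if (anyDuplicated(g)) stop("duplicate genes within set: ", nm)
    if (any(!nzchar(g))) stop("empty gene symbol in set: ", nm)
  }
  if (!is.null(superset_map)) {
    bad <- setdiff(unique(superset_map), SUPERSET_LABELS)
    if (length(bad)) {
      stop("superset_map values must be one of the seven superset labels; got: ",
           paste(bad, collapse = ", "))
    }
    unknown <- setdiff(names(superset_map), names(sets))
    if (length(unknown)) {
      stop("superset_map names not in collection: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(sets = sets, superset_map = superset_map),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets", length(x$sets)))
  if (!is.null(x$superset_map)) {
    cat(sprintf(", %d mapped to supersets", length(x$superset_map)))
  }
  cat("\n")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description (discarded), then gene symbols,
#' tab-separated. Duplicate genes within a line are deduplicated keeping the
#' first occurrence.
#'
#' @param path path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    }
    nm <- fields[[1]]
    if (nm %in% names(sets)) stop("duplicate set name: ", nm)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    sets[[nm]] <- genes[!duplicated(genes)]
  }
  gene_set_collection(sets)
}

#' Write gene sets to a GMT file
#'
#' @param gsc a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, ".", gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct and validate a compendium
#'
#' @param expression numeric matrix of log2 expression values, rows named by
#'   unique gene symbols, columns by sample ids.
#' @param samples data.frame with one row per sample; required columns
#'   `sample_id`, `participant_id`, `study_id`, `platform`, `sample_type`,
#'   `vaccine`, `day`. Sample ids must match the expression columns exactly.
#' @param gene_sets optional [gene_set_collection()].
#' @return An object of class `compendium`.
#' @export
compendium <- function(expression, samples, gene_sets = NULL) {
  expression <- as.matrix(expression)
  if (!is.numeric(expression)) stop("expression must be numeric")
  if (is.null(rownames(expression)) || any(!nzchar(rownames(expression)))) {
    stop("expression rows must be named by non-empty gene symbols")
  }
  if (anyDuplicated(rownames(expression))) {
    stop("duplicate gene symbol(s): ",
         paste(unique(rownames(expression)[duplicated(rownames(expression))]),
               collapse = ", "))
  }
  if (any(!is.finite(expression))) {
    bad <- which(!is.finite(expression), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(expression)[bad[1]], colnames(expression)[bad[2]]))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  missing.cols <- setdiff(REQUIRED_META_COLS, names(samples))
  if (length(missing.cols)) {
    stop("metadata missing required column(s): ",
         paste(missing.cols, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in metadata")
  only.expr <- setdiff(colnames(expression), samples$sample_id)
  only.meta <- setdiff(samples$sample_id, colnames(expression))
  if (length(only.expr) || length(only.meta)) {
    stop("sample mismatch between expression and metadata; ",
         if (length(only.expr)) paste0("expression-only: ",
                                       paste(only.expr, collapse = ", "), "; ") else "",
         if (length(only.meta)) paste0("metadata-only: ",
                                       paste(only.meta, collapse = ", ")) else "")
  }
  if (!all(samples$sample_type %in% c("whole_blood", "pbmc"))) {
    stop("sample_type must be 'whole_blood' or 'pbmc'")
  }
  samples$day <- as.integer(samples$day)
  if (any(is.na(samples$day))) stop("day must be integer")
  samples <- samples[match(colnames(expression), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- samples$sample_id
  structure(list(expression = expression, samples = samples,
                 gene_sets = gene_sets),
            class = "compendium")
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("compendium: %d genes x %d samples, %d studies, %d participants\n",
              nrow(x$expression), ncol(x$expression),
              length(unique(x$samples$study_id)),
              length(unique(x$samples$participant_id))))
  days <- sort(unique(x$samples$day))
  cat("  days:", paste(days, collapse = ", "), "\n")
  if (!is.null(x$gene_sets)) {
    cat(sprintf("  gene sets: %d\n", length(x$gene_sets$sets)))
  }
  invisible(x)
}

#' @export
dim.compendium <- function(x) dim(x$expression)

#' Load a compendium from expression and metadata TSV files
#'
#' The expression file has a header of sample ids and a first column of gene
#' symbols; the metadata file has one row per sample. "NA" and the empty
#' string are the only missing-value tokens.
#'
#' @param expr_path path to the expression TSV.
#' @param meta_path path to the metadata TSV.
#' @param gene_sets optional [gene_set_collection()] to attach.
#' @param missing what to do with missing expression cells: `"reject"`
#'   (default, error naming the coordinates) or `"impute"` (per-gene median).
#' @return A validated [compendium()].
#' @export
load_compendium <- function(expr_path, meta_path, gene_sets = NULL,
                            missing = c("reject", "impute")) {
  missing <- match.arg(missing)
  raw <- utils::read.delim(expr_path, header = TRUE, sep = "\t",
                           check.names = FALSE, na.strings = c("NA", ""),
                           colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs a gene column and >=1 sample")
  genes <- as.character(raw[[1]])
  mat <- raw[, -1, drop = FALSE]
  non.num <- !vapply(mat, is.numeric, logical(1))
  if (any(non.num)) {
    # a character column means some cell failed numeric parsing
    col <- which(non.num)[1]
    vals <- suppressWarnings(as.numeric(mat[[col]]))
    row <- which(is.na(vals) & !is.na(mat[[col]]))[1]
    stop(sprintf("non-numeric expression cell at gene '%s', sample '%s'",
                 genes[row], colnames(mat)[col]))
  }
  mat <- as.matrix(mat)
  rownames(mat) <- genes
  if (anyNA(mat)) {
    if (missing == "reject") {
      bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
      stop(sprintf("missing expression value at gene '%s', sample '%s'",
                   genes[bad[1]], colnames(mat)[bad[2]]))
    }
    for (i in which(rowSums(is.na(mat)) > 0)) {
      med <- stats::median(mat[i, ], na.rm = TRUE)
      mat[i, is.na(mat[i, ])] <- med
    }
  }
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, na.strings = c("NA", ""),
                            stringsAsFactors = FALSE)
  compendium(mat, meta, gene_sets = gene_sets)
}

#' Write a compendium to a directory of plain-text tables
#'
#' Writes `expression.tsv`, `samples.tsv` and, if present, `gene_sets.gmt`.
#' Round-trip guarantee: reloading reproduces expression values to within
#' 1e-9 and identical metadata.
#'
#' @param x a [compendium()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_tables <- function(x, out_dir) {
  stopifnot(inherits(x, "compendium"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop("directory not writable: ", out_dir)
  }
  expr.path <- file.path(out_dir, "expression.tsv")
  meta.path <- file.path(out_dir, "samples.tsv")
  df <- data.frame(gene_symbol = rownames(x$expression),
                   x$expression, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, expr.path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, meta.path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(expression = expr.path, samples = meta.path)
  if (!is.null(x$gene_sets)) {
    gmt.path <- file.path(out_dir, "gene_sets.gmt")
    write_gmt(x$gene_sets, gmt.path)
    paths <- c(paths, gene_sets = gmt.path)
    if (!is.null(x$gene_sets$superset_map)) {
      map.path <- file.path(out_dir, "supersets.tsv")
      utils::write.table(
        data.frame(gene_set = names(x$gene_sets$superset_map),
                   superset = unname(x$gene_sets$superset_map)),
        map.path, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, supersets = map.path)
    }
  }
  paths
}

#' Read a gene-set to superset mapping
#'
#' Two-column TSV (gene_set, superset); superset values must be among the
#' seven canonical labels. The GMT format cannot carry the mapping, so it
#' travels in this sidecar table.
#'
#' @param path path to the mapping TSV.
#' @return Named character vector (set name -> superset label).
#' @export
read_superset_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_set", "superset") %in% names(df))) {
    stop("superset map needs columns gene_set, superset")
  }
  stats::setNames(df$superset, df$gene_set)
}
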