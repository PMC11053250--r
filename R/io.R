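#' Construct a spot-by-gene count matrix
#'
#' Bundles a sparse UMI count matrix with its spot barcodes and gene symbols.
#' Counts are oriented spots x genes throughout the package; the on-disk
#' Matrix Market convention (genes x spots) is handled by the readers and
#' writers.
#'
#' @param counts Matrix-like of non-negative integers, spots x genes.
#' @param barcodes Character vector of unique spot identifiers (one per row).
#' @param genes Character vector of unique gene symbols (one per column).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `barcodes` and `genes`.
#' @export
count_matrix <- function(counts, barcodes, genes) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(barcodes) || ncol(counts) != length(genes)) {
    stop("counts must be length(barcodes) x length(genes), got ",
         nrow(counts), " x ", ncol(counts))
  }
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  if (anyDuplicated(genes)) stop("duplicate gene symbols")
  x <- counts@x
  if (length(x) && (min(x) < 0 || any(x != round(x)))) {
    stop("counts must be non-negative integers")
  }
  dimnames(counts) <- list(as.character(barcodes), as.character(genes))
  structure(list(counts = counts, barcodes = as.character(barcodes),
                 genes = as.character(genes)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d spots x %d genes, %d non-zero entries\n",
              length(x$barcodes), length(x$genes), length(x$counts@x)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# open a text connection, transparently gunzipping by extension
open_text <- function(path, mode = "r") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

find_part <- function(dir, stem) {
  for (p in file.path(dir, c(stem, paste0(stem, ".gz")))) {
    if (file.exists(p)) return(p)
  }
  stop("missing file: ", file.path(dir, stem), "[.gz]")
}

make_unique_symbols <- function(sym) {
  if (!anyDuplicated(sym)) return(sym)
  out <- sym
  dup_idx <- which(duplicated(sym) | duplicated(sym, fromLast = TRUE))
  seen <- new.env(parent = emptyenv())
  for (i in dup_idx) {
    k <- sym[i]
    n <- if (is.null(seen[[k]])) 0L else seen[[k]]
    if (n > 0L) out[i] <- paste0(k, ".", n)
    seen[[k]] <- n + 1L
  }
  out
}

#' Read a 10x-style triplet count matrix
#'
#' Reads `matrix.mtx`, `barcodes.tsv` and `features.tsv` (optionally
#' gzipped) from a directory. The Matrix Market header decides orientation:
#' a genes x spots matrix (the 10x convention) is transposed so the result
#' is always spots x genes. Gene symbols are taken from the second column of
#' the features file when present; duplicated symbols are suffixed
#' `.1`, `.2`, ... in order of appearance.
#'
#' @param directory_path Directory containing the three files.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(directory_path) {
  mtx_path <- find_part(directory_path, "matrix.mtx")
  bc_path <- find_part(directory_path, "barcodes.tsv")
  ft_path <- find_part(directory_path, "features.tsv")

  con <- open_text(mtx_path)
  m <- Matrix::readMM(con)
  close(con)
  barcodes <- readLines(con2 <- open_text(bc_path)); close(con2)
  feats <- utils::read.table(ft_path, sep = "\t", header = FALSE,
                             quote = "", comment.char = "",
                             colClasses = "character")
  genes <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  genes <- make_unique_symbols(genes)

  nb <- length(barcodes); ng <- length(genes)
  if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)
  } else if (!(nrow(m) == nb && ncol(m) == ng)) {
    stop(sprintf(
      "matrix dimensions %d x %d match neither genes x spots (%d x %d) nor spots x genes",
      nrow(m), ncol(m), ng, nb))
  }
  count_matrix(m, barcodes, genes)
}

#' Write a count matrix as a 10x-style triplet directory
#'
#' Emits `matrix.mtx` (Matrix Market coordinate integer, genes x spots per
#' the 10x convention), `barcodes.tsv` and `features.tsv` (gene id and
#' symbol columns), readable by [read_count_matrix()].
#'
#' @param cm A [count_matrix()].
#' @param directory_path Output directory (created if absent).
#' @export
write_count_matrix <- function(cm, directory_path) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory_path)) stop("cannot create directory: ", directory_path)
  Matrix::writeMM(Matrix::t(cm$counts), file.path(directory_path, "matrix.mtx"))
  writeLines(cm$barcodes, file.path(directory_path, "barcodes.tsv"))
  utils::write.table(
    data.frame(id = cm$genes, symbol = cm$genes, type = "Gene Expression"),
    file.path(directory_path, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read a GMT gene-set file
#'
#' Each tab-separated line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are dropped with a warning.
#'
#' @param path Path to a `.gmt` file (optionally gzipped).
#' @return A named list of character vectors of class `gene_sets`, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(con <- open_text(path)); close(con)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   i, length(f)))
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': dropping %d duplicate gene(s)",
                      f[1], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    desc[[f[1]]] <- f[2]
  }
  gene_sets(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (non-empty, no duplicates
#'   within a set).
#' @param descriptions Optional named character vector of set descriptions.
#' @return A `gene_sets` object.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) stop("sets must be named")
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0) stop("empty gene set: ", nm)
    if (anyDuplicated(sets[[nm]])) stop("duplicate genes in set: ", nm)
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions[names(sets)], class = "gene_sets")
}

#' Write a gene-set collection as GMT
#'
#' @param gs A [gene_sets()] collection.
#' @param path Output path.
#' @export
write_gmt <- function(gs, path) {
  desc <- attr(gs, "descriptions")
  lines <- vapply(names(gs), function(nm) {
    paste(c(nm, desc[[nm]], gs[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(NULL)
}

#' Read a tissue-positions table
#'
#' CSV with at least columns `barcode`, `in_tissue`, `row`, `col`
#' (extra columns such as `sample` and `group` are carried through).
#' `in_tissue` must be 0/1. The returned table has `region` set to
#' `"unassigned"` unless a region column is present on disk.
#'
#' @param path Path to the CSV (optionally gzipped).
#' @return A `data.frame` spot table: `barcode`, `row`, `col`, `in_tissue`
#'   (logical), `sample`, `group`, `region`.
#' @export
read_positions <- function(path) {
  con <- open_text(path)
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  df <- utils::read.csv(con, stringsAsFactors = FALSE)
  need <- c("barcode", "in_tissue", "row", "col")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("positions file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$barcode)) stop("duplicate barcode in positions file")
  if (!all(df$in_tissue %in% c(0, 1))) {
    stop("in_tissue must be 0 or 1; offending value(s): ",
         paste(unique(df$in_tissue[!df$in_tissue %in% c(0, 1)]), collapse = ", "))
  }
  spot_table(
    barcode = df$barcode, row = df$row, col = df$col,
    in_tissue = df$in_tissue == 1,
    sample = if ("sample" %in% names(df)) df$sample else NA_character_,
    group = if ("group" %in% names(df)) df$group else NA_character_,
    region = if ("region" %in% names(df)) df$region else "unassigned")
}

REGION_LEVELS <- c("CA1", "CA3", "DG", "other", "unassigned")

#' Construct a spot table
#'
#' @param barcode,row,col,in_tissue,sample,group,region Per-spot fields;
#'   `region` must be one of `CA1`, `CA3`, `DG`, `other`, `unassigned`.
#' @return A `data.frame` with one row per spot.
#' @export
spot_table <- function(barcode, row, col, in_tissue = TRUE,
                       sample = NA_character_, group = NA_character_,
                       region = "unassigned") {
  df <- data.frame(barcode = as.character(barcode),
                   row = as.integer(row), col = as.integer(col),
                   in_tissue = as.logical(in_tissue),
                   sample = as.character(sample),
                   group = as.character(group),
                   region = as.character(region),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("sample", "barcode")])) {
    stop("duplicate (sample, barcode) in spot table")
  }
  bad <- setdiff(unique(df$region), REGION_LEVELS)
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  df
}

#' Write a spot table as a positions CSV
#'
#' @param spots Spot table from [spot_table()] or [read_positions()].
#' @param path Output path.
#' @export
write_positions <- function(spots, path) {
  out <- spots
  out$in_tissue <- as.integer(out$in_tissue)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; the shared on-disk format for all
#' pipeline result tables.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
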