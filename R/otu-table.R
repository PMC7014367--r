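#' Construct an OTU abundance table
#'
#' An `otu_table` holds a taxa-by-samples matrix of non-negative abundances
#' with unique OTU and sample identifiers, and optionally one taxonomy label
#' per OTU (typically the phylum, used for node colouring in network
#' exports).
#'
#' @param counts numeric matrix, OTUs in rows and samples in columns.
#'   Row and column names are used as OTU and sample identifiers; if absent,
#'   `OTU_1..n` / `S1..m` are generated.
#' @param taxonomy optional character vector, one label per OTU.
#' @return an object of class `otu_table`: the validated counts matrix with
#'   a `taxonomy` attribute.
#' @examples
#' m <- matrix(c(5, 0, 1, 2, 0, 7), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("OTU_", 1:3), c("S1", "S2")))
#' tab <- otu_table(m)
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) rownames(counts) <- paste0("OTU_", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (length(taxonomy) != nrow(counts))
      stop("taxonomy must have one entry per OTU")
    names(taxonomy) <- rownames(counts)
  }
  x <- structure(counts, taxonomy = taxonomy, class = c("otu_table", "matrix"))
  validate_otu_table(x)
  x
}

validate_otu_table <- function(x) {
  if (anyNA(x)) stop("OTU table contains NA values")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at OTU '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  if (anyDuplicated(rownames(x))) stop("duplicate OTU ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  invisible(x)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples%s\n", nrow(x), ncol(x),
              if (is.null(attr(x, "taxonomy"))) "" else " (with taxonomy)"))
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
otu_ids <- function(x) rownames(x)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x)

#' @rdname otu_table
#' @export
taxonomy <- function(x) attr(x, "taxonomy")

#' Construct an environmental factor table
#'
#' Holds one row per sample and one numeric column per measured soil factor
#' (e.g. pH, EC, OM, NN, AN, AP, AK).
#'
#' @param values numeric matrix or data frame, samples in rows, factors in
#'   columns; dimnames supply sample ids and factor names.
#' @return an object of class `env_table` (a numeric matrix).
#' @export
env_table <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("F", seq_len(ncol(values)))
  if (anyNA(values) || any(!is.finite(values))) stop("environment table must be finite with no NA")
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate factor names")
  vars <- apply(values, 2, stats::var)
  if (any(vars == 0))
    warning(sprintf("constant environmental factor(s): %s",
                    paste(colnames(values)[vars == 0], collapse = ", ")))
  structure(values, class = c("env_table", "matrix"))
}

#' @export
print.env_table <- function(x, ...) {
  cat(sprintf("env_table: %d samples x %d factors (%s)\n", nrow(x), ncol(x),
              paste(colnames(x), collapse = ", ")))
  invisible(x)
}

#' Read an OTU table from a tab-separated file
#'
#' Expects OTUs in rows: first column the OTU id, remaining numeric columns
#' one per sample. An optional taxonomy column is split off by name.
#'
#' @param path file path to a TSV table.
#' @param taxonomy_column name of a column holding taxonomy labels, or NULL.
#' @param transpose set TRUE if the file stores samples in rows.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, taxonomy_column = NULL, transpose = FALSE) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  tax <- NULL
  if (!is.null(taxonomy_column)) {
    if (!taxonomy_column %in% colnames(df))
      stop(sprintf("taxonomy column '%s' not found", taxonomy_column))
    tax <- as.character(df[[taxonomy_column]])
    df <- df[, setdiff(colnames(df), taxonomy_column), drop = FALSE]
  }
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        i <- which(is.na(vn))[1]
        stop(sprintf("non-numeric count '%s' at OTU '%s', sample '%s'",
                     v[i], ids[i], colnames(df)[j]))
      }
      df[[j]] <- vn
    }
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  if (transpose) {
    m <- t(m)
    tax <- NULL
  }
  otu_table(m, taxonomy = tax)
}

#' Write an OTU table as tab-separated text
#'
#' @param x an [otu_table].
#' @param path output file path.
#' @param id_column header for the id column (default `"OTU_ID"`).
#' @export
write_otu_table <- function(x, path, id_column = "OTU_ID") {
  df <- data.frame(rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  tax <- taxonomy(x)
  if (!is.null(tax)) df$taxonomy <- unname(tax)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an environment table from a tab-separated file
#'
#' First column = sample id, remaining numeric columns = factors.
#'
#' @param path file path.
#' @return an [env_table].
#' @export
read_env_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("environment table has non-numeric entries")
  rownames(m) <- ids
  env_table(m)
}

#' Write an environment table as tab-separated text
#'
#' @param x an [env_table].
#' @param path output file path.
#' @export
write_env_table <- function(x, path) {
  df <- data.frame(sample = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
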