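#' Abundance matrix container
#'
#' The universal exchange object of the package: a features-by-samples
#' numeric matrix (rows = genes or species, columns = samples) tagged with a
#' `kind` describing what the values are. The orientation matches MIDAS2
#' merge output, so MIDAS2 TSVs are ingested without transformation.
#'
#' @param values numeric matrix with unique, non-empty rownames (feature IDs)
#'   and colnames (sample IDs); all values must be non-negative.
#' @param kind one of `"species_relabund"`, `"gene_reads"`, `"gene_copynum"`,
#'   `"gene_presence"`. Presence matrices must be 0/1; relative-abundance
#'   columns must each sum to at most 1 (+1e-6 slack).
#'
#' @return an `abund_matrix`: the matrix with a `kind` attribute.
#' @export
abund_matrix <- function(values, kind = c("species_relabund", "gene_reads",
                                          "gene_copynum", "gene_presence")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) stop("matrix must have row and column names")
  if (anyDuplicated(fid)) {
    stop("duplicate feature IDs: ", paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample IDs: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (anyNA(values)) stop("matrix contains missing values")
  if (any(values < 0)) stop("matrix contains negative values")
  if (kind == "gene_presence" && !all(values %in% c(0, 1))) {
    stop("presence matrix contains values other than 0/1")
  }
  if (kind == "species_relabund") {
    cs <- colSums(values)
    bad <- which(cs > 1 + 1e-6)
    if (length(bad)) {
      stop("relative abundance columns sum to > 1: ", paste(sid[bad], collapse = ", "))
    }
  }
  structure(values, kind = kind, class = c("abund_matrix", class(values)))
}

#' @export
print.abund_matrix <- function(x, ...) {
  cat(sprintf("<abund_matrix [%s]> %d features x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' Matrix kind accessor
#' @param x an `abund_matrix`.
#' @return the kind string.
#' @export
matrix_kind <- function(x) attr(x, "kind")

# subsetting keeps class/kind but always returns a matrix (drop = FALSE)
#' @export
`[.abund_matrix` <- function(x, i, j, ...) {
  k <- attr(x, "kind")
  y <- NextMethod(drop = FALSE)
  structure(y, kind = k, class = c("abund_matrix", class(unclass(y))))
}

#' Read a feature-by-sample matrix from TSV
#'
#' Expects a MIDAS2-merge-style layout: a header row, first column = feature
#' ID, remaining columns = samples.
#'
#' @param path TSV file path.
#' @inheritParams abund_matrix
#' @return an [abund_matrix()].
#' @export
read_matrix <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2L) stop("in ", path, ": header has fewer than 2 columns")
  sid <- hdr[-1]
  if (anyDuplicated(sid)) {
    stop("in ", path, " line 1: duplicate sample column header: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = c("character", rep("numeric", length(sid))),
                          quote = "", comment.char = "")
  fid <- df[[1]]
  for (j in seq_along(sid)) {
    col <- df[[j + 1L]]
    if (anyNA(col)) {
      stop("in ", path, " line ", which(is.na(col))[1] + 1L,
           ": non-numeric or missing value in column ", sid[j])
    }
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- fid
  abund_matrix(values, kind)
}

#' Write an abundance matrix (or any named matrix) as TSV
#'
#' Inverse of [read_matrix()]: feature IDs in the first column
#' (header `feature_id`), one sample per remaining column.
#'
#' @param x matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
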