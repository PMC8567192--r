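#' Construct and validate a community table
#'
#' A community table is an integer matrix of read counts with samples as rows
#' and OTUs as columns. All downstream analyses consume this object; column
#' (OTU) order is preserved throughout.
#'
#' @param counts numeric matrix of non-negative integer counts, samples in
#'   rows, OTUs in columns. Dimnames are used as sample/OTU ids when
#'   `sample_ids`/`otu_ids` are not given.
#' @param sample_ids,otu_ids optional character vectors of unique identifiers.
#' @return an integer matrix of class `comm_table` with sample ids as rownames
#'   and OTU ids as colnames.
#' @examples
#' community_table(matrix(c(1, 2, 3, 4), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("o1", "o2"))))
#' @export
community_table <- function(counts, sample_ids = NULL, otu_ids = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("counts must be integers (read counts)", call. = FALSE)
  }
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(otu_ids)) colnames(counts) <- otu_ids
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU ids", call. = FALSE)
  storage.mode(counts) <- "integer"
  class(counts) <- c("comm_table", class(counts))
  counts
}

#' @export
print.comm_table <- function(x, ...) {
  cat(sprintf(
    "Community table: %d samples x %d OTUs, %s reads (row sums %s)\n",
    nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ","),
    if (length(unique(rowSums(x))) == 1L) {
      paste("all", rowSums(x)[1])
    } else {
      paste0("range ", min(rowSums(x)), "-", max(rowSums(x)))
    }
  ))
  invisible(x)
}

#' Read a community table from a TSV file
#'
#' Expects a tab-delimited file with one header row and the first column
#' holding identifiers. `orientation` declares whether rows are samples
#' (`"rows"`) or OTUs (`"columns"`, i.e. samples are the file's columns).
#'
#' @param path file path.
#' @param orientation `"rows"` if samples are file rows, `"columns"` if
#'   samples are file columns.
#' @return a [community_table()].
#' @export
read_community_table <- function(path, orientation = c("rows", "columns")) {
  orientation <- match.arg(orientation)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate ids in first column of ", path, call. = FALSE)
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path, call. = FALSE)
  rownames(m) <- ids
  if (orientation == "columns") m <- t(m)
  community_table(m)
}

#' Write a community table to TSV
#'
#' @param table a `comm_table`.
#' @param path output file path; samples are written as rows.
#' @export
write_community_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (coordinates)
#'
#' @param path TSV with columns `sample_id`, `latitude`, `longitude` and
#'   optionally `altitude`.
#' @return data.frame with validated coordinates.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "latitude", "longitude")
  if (!all(req %in% names(df))) {
    stop("metadata must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  validate_metadata(df)
}

validate_metadata <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  if (any(!is.finite(df$latitude)) || any(abs(df$latitude) > 90)) {
    stop("latitude must be finite and within [-90, 90]", call. = FALSE)
  }
  if (any(!is.finite(df$longitude)) || any(abs(df$longitude) > 180)) {
    stop("longitude must be finite and within [-180, 180]", call. = FALSE)
  }
  df
}

#' Read a taxonomy table
#'
#' @param path TSV with column `otu_id` followed by rank columns (for example
#'   phylum, class, genus). Missing assignments may be empty or NA.
#' @return data.frame keyed by unique `otu_id`.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"otu_id" %in% names(df)) {
    stop("taxonomy must have an otu_id column", call. = FALSE)
  }
  if (anyDuplicated(df$otu_id)) {
    stop("duplicate otu ids in taxonomy", call. = FALSE)
  }
  df
}

#' Rarefy a community table to even depth
#'
#' Randomly subsamples each sample's reads without replacement down to
#' `depth` (the standard QIIME-style rarefaction). Samples with fewer than
#' `depth` reads are dropped with a warning rather than scaled.
#'
#' @param table a `comm_table`.
#' @param depth target reads per sample (positive integer).
#' @param seed integer seed for reproducibility; NULL uses the current RNG
#'   stream.
#' @return a rarefied `comm_table` in which every row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  if (length(depth) != 1 || !is.finite(depth) || depth <= 0 ||
      depth != round(depth)) {
    stop("depth must be a positive integer", call. = FALSE)
  }
  totals <- rowSums(table)
  low <- totals < depth
  if (any(low)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s", sum(low),
                    depth, paste(rownames(table)[low], collapse = ", ")),
            call. = FALSE)
    table <- table[!low, , drop = FALSE]
  }
  if (nrow(table) == 0) stop("no samples at or above depth", call. = FALSE)
  # rrarefy's "observed counts" warning only flags rows whose total equals
  # the requested depth (left unchanged), which we permit by contract
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(unclass(table),
                                                         depth)))
  community_table(out)
}
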