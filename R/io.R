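#' Read a pool-level count matrix and condition map from TSV
#'
#' The count table is genes x pools with a header row and the gene id in
#' the first column; the map is a two-column TSV (pool, condition). This is
#' the bridge for user-prepared real count data as well as the round-trip
#' format for the generator's output.
#'
#' @param counts_path Path to the TSV count table.
#' @param map_path Path to the two-column pool-to-condition TSV.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, map_path) {
  raw <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("count table needs a gene column plus >= 1 pool column")
  genes <- as.character(raw[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene id(s) in count table: ",
                        paste(unique(dup), collapse = ", "))
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (any(is.na(mat))) {
    stop("non-numeric or missing count at data line(s): ",
         paste(which(rowSums(is.na(mat)) > 0), collapse = ", "))
  }
  if (any(mat < 0) || any(mat != round(mat))) {
    stop("negative or non-integer count at data line(s): ",
         paste(which(rowSums(mat < 0 | mat != round(mat)) > 0), collapse = ", "))
  }
  rownames(mat) <- genes
  map <- read.delim(map_path, stringsAsFactors = FALSE)
  if (!all(c("pool", "condition") %in% names(map))) {
    stop("condition map must have columns 'pool' and 'condition'")
  }
  count_matrix(mat, map)
}

#' Write a count matrix (and its condition map) to TSV
#'
#' @param x A [count_matrix()].
#' @param counts_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_count_matrix <- function(x, counts_path, map_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, map_path))
}

#' Write a generic result table to TSV
#'
#' @param x Data frame. @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
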