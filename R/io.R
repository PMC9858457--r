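#' Read and write TPM CSV files
#'
#' The TPM CSV dialect: first row is a header of state labels; each
#' subsequent row is a state label followed by its N transition
#' probabilities as decimal text (comma separator, `.` decimal point,
#' UTF-8, no locale dependence).
#'
#' @param path File path.
#' @return `read_tpm_csv()`: a [tpm]. `write_tpm_csv()`: `path`, invisibly.
#' @export
read_tpm_csv <- function(path) {
  df <- utils::read.csv(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = c("character", rep(NA, length(count_header_fields(path)) - 1L))
  )
  labels <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (!identical(colnames(m), labels)) {
    # header labels define the column order; rows must use the same set
    if (!setequal(colnames(m), labels)) {
      stop("row labels and header labels differ in ", path)
    }
    m <- m[match(colnames(m), labels), , drop = FALSE]
    labels <- colnames(m)
  }
  tpm(m, labels = labels)
}

count_header_fields <- function(path) {
  strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
}

#' @rdname read_tpm_csv
#' @param x A [tpm] (or [element_system]) to serialize.
#' @export
write_tpm_csv <- function(x, path) {
  x <- as_tpm(x)
  m <- as.matrix(x)
  df <- data.frame(state = state_labels(x), m,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(df)[1L] <- "state"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a distribution CSV (label,probability pairs)
#'
#' @param path File path to a two-column CSV with a header.
#' @return Named numeric probability vector.
#' @export
read_distribution_csv <- function(path) {
  df <- utils::read.csv(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = c("character", "numeric")
  )
  p <- stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
  if (any(p < 0)) stop("negative probability in ", path)
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities in ", path, " do not sum to 1")
  p
}

#' Read and write state-mapping CSV files
#'
#' Two-column CSV `micro_label,macro_label` with a header row.
#'
#' @param path File path.
#' @return `read_state_mapping_csv()`: a [state_mapping].
#' @export
read_state_mapping_csv <- function(path) {
  df <- utils::read.csv(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = "character"
  )
  state_mapping(
    stats::setNames(as.character(df[[2L]]), as.character(df[[1L]])),
    provenance = paste("read from", path)
  )
}

#' @rdname read_state_mapping_csv
#' @param mapping A [state_mapping] to serialize.
#' @export
write_state_mapping_csv <- function(mapping, path) {
  utils::write.csv(
    data.frame(
      micro_label = mapping$micro_labels,
      macro_label = unname(mapping$map[mapping$micro_labels]),
      stringsAsFactors = FALSE
    ),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a weighted edge list (TSV) as an igraph graph
#'
#' Three-column tab-separated file `source`, `target`, `weight` with a
#' header row.
#'
#' @param path File path.
#' @param directed Whether to build a directed graph.
#' @return An igraph graph with a `weight` edge attribute.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("edge list needs columns source, target, weight")
  igraph::graph_from_data_frame(
    data.frame(
      from = as.character(df[[1L]]),
      to = as.character(df[[2L]]),
      weight = as.numeric(df[[3L]]),
      stringsAsFactors = FALSE
    ),
    directed = directed
  )
}

#' Read a square adjacency matrix CSV as an igraph graph
#'
#' Same dialect as [read_tpm_csv] (labelled rows and columns), but rows need
#' not be stochastic: entries are edge weights.
#'
#' @param path File path.
#' @param directed Whether to treat the matrix as directed (otherwise it
#'   must be symmetric).
#' @return An igraph graph with a `weight` edge attribute.
#' @export
read_adjacency_csv <- function(path, directed = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, colnames(m))
  igraph::graph_from_adjacency_matrix(
    m,
    mode = if (directed) "directed" else "undirected", weighted = TRUE
  )
}

#' Read a node-partition CSV (node,community pairs)
#'
#' @param path File path to a two-column CSV with a header.
#' @return Named character vector node -> community.
#' @export
read_partition_csv <- function(path) {
  df <- utils::read.csv(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = "character"
  )
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
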