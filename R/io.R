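#' Read an expression matrix
#'
#' Reads dense CSV/TSV (samples as rows, genes as columns, first column taken
#' as sample ids when non-numeric, header as gene ids) or sparse matrix-market
#' triplet files (`.mtx`; absent entries are zeros). Exact zeros populate the
#' dropout mask. Values must be finite; duplicate gene ids are rejected.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or `"mtx"`.
#' @param transpose set `TRUE` for genes-as-rows dumps.
#' @return An [ajgm_data()].
#' @export
read_expression <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                            transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "mtx") {
    M <- as.matrix(Matrix::readMM(path))
    if (transpose) M <- t(M)
    X <- ajgm_data(M, zero_mask = M == 0)
    return(X)
  }
  dt <- data.table::fread(path, header = TRUE,
                          sep = if (format == "csv") "," else "\t")
  first <- dt[[1L]]
  if (is.character(first)) {
    sample_ids <- first
    M <- as.matrix(dt[, -1L, drop = FALSE])
  } else {
    sample_ids <- NULL
    M <- as.matrix(dt)
  }
  if (!is.numeric(M)) stop("non-numeric values in expression matrix")
  gene_ids <- colnames(M)
  if (transpose) {
    M <- t(M)
    tmp <- gene_ids; gene_ids <- sample_ids; sample_ids <- tmp
  }
  ajgm_data(M, sample_ids = sample_ids, gene_ids = gene_ids,
            zero_mask = M == 0)
}

#' Write an expression matrix
#'
#' Dense CSV with sample ids in the first column and gene ids as header;
#' round-trips exactly through [read_expression()].
#'
#' @param X an [ajgm_data()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path) {
  dt <- data.table::data.table(sample = X$sample_ids)
  dt <- cbind(dt, data.table::as.data.table(X$values))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Log-transform expression values
#'
#' x -> log(x + pseudocount). Raw exact zeros stay flagged in the dropout
#' mask even though log(0 + 1) = 0: the mask records pre-transform zeros, and
#' values that merely become 0 after transformation are not masked.
#'
#' @param X an [ajgm_data()] with non-negative values.
#' @param pseudocount positive offset (default 1).
#' @return A transformed [ajgm_data()] with the mask unchanged.
#' @export
log_transform <- function(X, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(X$values < 0)) stop("log transform requires non-negative values")
  ajgm_data(log(X$values + pseudocount), X$sample_ids, X$gene_ids,
            X$zero_mask)
}

#' Write fitted networks to disk
#'
#' Emits one TSV edge list per network (`gene_i`, `gene_j`, `value` with the
#' precision entry; lexicographic pair order), an `summary.json` with edge
#' counts, and, when labels are supplied, a `clusters.csv` of hard
#' assignments.
#'
#' @param networks a [call_edges()] network set.
#' @param params the matching [mixture_params()].
#' @param out_dir output directory (created if missing).
#' @param gene_ids optional gene labels (defaults to g1..gp).
#' @param labels optional hard cluster assignments to write.
#' @param sample_ids optional sample labels for the cluster file.
#' @return `out_dir`, invisibly.
#' @export
write_networks <- function(networks, params, out_dir, gene_ids = NULL,
                           labels = NULL, sample_ids = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- nrow(networks$overall_adjacency)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  edge_df <- function(A, Om) {
    idx <- which(A & upper.tri(A), arr.ind = TRUE)
    df <- data.frame(gene_i = gene_ids[idx[, 1L]],
                     gene_j = gene_ids[idx[, 2L]],
                     value = Om[idx])
    df[order(df$gene_i, df$gene_j), , drop = FALSE]
  }
  K <- length(networks$subtype_adjacency)
  counts <- list()
  for (k in seq_len(K)) {
    df <- edge_df(networks$subtype_adjacency[[k]], params$precisions[[k]])
    data.table::fwrite(df, file.path(out_dir, sprintf("subtype%d_edges.tsv", k)),
                       sep = "\t")
    counts[[sprintf("subtype%d", k)]] <- nrow(df)
  }
  df_ov <- edge_df(networks$overall_adjacency, params$overall_precision)
  data.table::fwrite(df_ov, file.path(out_dir, "overall_edges.tsv"), sep = "\t")
  sh <- networks$shared_adjacency
  counts$overall <- nrow(df_ov)
  counts$shared <- sum(sh[upper.tri(sh)])
  counts$shared_rule <- networks$rule
  jsonlite::write_json(counts, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(labels)) {
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(labels))
    data.table::fwrite(data.frame(sample = sample_ids, cluster = labels),
                       file.path(out_dir, "clusters.csv"))
  }
  invisible(out_dir)
}

#' Read an edge list written by [write_networks()]
#'
#' @param path TSV edge-list path.
#' @param gene_ids gene labels defining the adjacency dimensions.
#' @return Logical adjacency matrix.
#' @export
read_edge_list <- function(path, gene_ids) {
  df <- data.table::fread(path, sep = "\t")
  p <- length(gene_ids)
  A <- matrix(FALSE, p, p, dimnames = list(gene_ids, gene_ids))
  if (nrow(df) > 0) {
    i <- match(df$gene_i, gene_ids)
    j <- match(df$gene_j, gene_ids)
    if (anyNA(i) || anyNA(j)) stop("edge list names unknown genes")
    A[cbind(i, j)] <- TRUE
    A[cbind(j, i)] <- TRUE
  }
  A
}

#' Read a run configuration
#'
#' JSON (or YAML) file with optional blocks `penalty`, `admm`, `em`,
#' `selection`, `simulation`; each block is validated by the corresponding
#' constructor, and omitted fields take the package defaults.
#'
#' @param path config path (`.json`, `.yml`/`.yaml`).
#' @return List with validated `penalty` ([penalty_config()]), `admm`
#'   ([admm_config()]) and the raw `em`, `selection`, `simulation` blocks.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else stop("unsupported config format: ", ext)
  out <- list()
  out$penalty <- do.call(penalty_config, as.list(raw$penalty))
  out$admm <- do.call(admm_config, as.list(raw$admm))
  out$em <- raw$em
  out$selection <- raw$selection
  out$simulation <- raw$simulation
  out
}
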