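# Readers and writers for the plain-text interchange formats: dense
# CSV/TSV (cells in rows), MTX + barcodes/features TSV, edge-list TSV,
# JSON run manifests.

#' Read a cells-by-features matrix from CSV/TSV
#'
#' @param path file path; first column holds cell identifiers.
#' @param sep field separator; guessed from the extension by default.
#' @return numeric matrix with cell rownames.
#' @export
read_omics_csv <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' Write a cells-by-features matrix to CSV
#'
#' @param x numeric matrix, cells in rows.
#' @param path output path.
#' @export
write_omics_csv <- function(x, path) {
  write.csv(as.matrix(x), path, row.names = TRUE)
  invisible(path)
}

#' Read an MTX sparse matrix with barcode/feature sidecars
#'
#' Expects the common features-in-rows MTX layout and transposes to
#' cells-in-rows; sidecar files are one identifier per line.
#'
#' @param mtx path to the MatrixMarket file.
#' @param barcodes,features optional paths to cell/feature identifier files.
#' @return dense numeric matrix, cells in rows.
#' @export
read_omics_mtx <- function(mtx, barcodes = NULL, features = NULL) {
  m <- as.matrix(Matrix::t(readMM(mtx)))
  if (!is.null(barcodes)) rownames(m) <- readLines(barcodes)
  if (!is.null(features)) colnames(m) <- readLines(features)
  m
}

#' Export a neighbourhood graph
#'
#' Writes the sparse binary adjacency as MTX and the weighted edge list as
#' TSV (`from`, `to`, `dist`).
#'
#' @param graph a `duogate_graph`.
#' @param prefix output path prefix; writes `<prefix>_adjacency.mtx` and
#'   `<prefix>_edges.tsv`.
#' @return the two paths, invisibly.
#' @export
write_graph <- function(graph, prefix) {
  stopifnot(inherits(graph, "duogate_graph"))
  p1 <- paste0(prefix, "_adjacency.mtx")
  p2 <- paste0(prefix, "_edges.tsv")
  writeMM(graph$B, p1)
  utils::write.table(graph$edges, p2, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(p1, p2))
}

#' Write the outputs of a fitted integration to a directory
#'
#' Emits the joint and per-path embeddings (CSV), the loss history (CSV),
#' both graphs (MTX + TSV) and a JSON manifest of every resolved
#' hyperparameter — enough to reproduce the run bit-for-bit.
#'
#' @param fit a fitted `duogate` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_duogate <- function(fit, dir) {
  stopifnot(inherits(fit, "duogate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics_csv(fit$Z, file.path(dir, "Z.csv"))
  write_omics_csv(fit$T_emb, file.path(dir, "T_emb.csv"))
  write_omics_csv(fit$P_emb, file.path(dir, "P_emb.csv"))
  write.csv(fit$history, file.path(dir, "loss_history.csv"),
            row.names = FALSE)
  write_graph(fit$graphs$rna, file.path(dir, "graph_rna"))
  write_graph(fit$graphs$protein, file.path(dir, "graph_protein"))
  jsonlite::write_json(fit$config, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
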