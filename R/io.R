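#' Read / write square connectivity matrices and per-node vectors
#'
#' The on-disk dialect is tab-separated, no header, '.' decimal, UTF-8:
#' connectomes as N x N matrices, states/maps as one value per line,
#' node sets as one node id (1-based index) per line, coordinates as
#' `node TAB x TAB y TAB z TAB hemisphere`.
#'
#' @param path file path.
#' @param n expected dimension; checked when given.
#' @param tol symmetry tolerance for matrices.
#' @return `read_matrix_tsv`: numeric matrix; `read_state_tsv`: numeric
#'   vector; `read_set_tsv`: integer vector.
#' @name io
NULL

#' @rdname io
#' @export
read_matrix_tsv <- function(path, n = NULL, tol = 1e-10) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  if (!is.numeric(m) || anyNA(m))
    stop(sprintf("%s: non-numeric or missing entries", path))
  if (nrow(m) != ncol(m))
    stop(sprintf("%s: matrix is %d x %d, not square", path, nrow(m), ncol(m)))
  if (!is.null(n) && nrow(m) != n)
    stop(sprintf("%s: expected %d rows, found %d", path, n, nrow(m)))
  asym <- abs(m - t(m))
  if (max(asym) > tol) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: asymmetric beyond tolerance at cell (%d, %d): %.3g",
                 path, idx[1], idx[2], max(asym)))
  }
  m
}

#' @param m matrix to write.
#' @rdname io
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(format(m, trim = TRUE, digits = 15, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_state_tsv <- function(path, n = NULL) {
  x <- utils::read.table(path, sep = "\t", header = FALSE)[[1]]
  if (!is.numeric(x) || anyNA(x))
    stop(sprintf("%s: non-numeric or missing entries", path))
  if (!is.null(n) && length(x) != n)
    stop(sprintf("%s: expected %d values, found %d", path, n, length(x)))
  x
}

#' @param x numeric vector to write.
#' @rdname io
#' @export
write_state_tsv <- function(x, path) {
  writeLines(format(x, trim = TRUE, digits = 15, scientific = FALSE), path)
  invisible(path)
}

#' @rdname io
#' @export
read_set_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE)[[1]]
  if (anyNA(x) || any(x != as.integer(x)))
    stop(sprintf("%s: node sets must be integer indices", path))
  as.integer(x)
}

#' @param set integer vector to write.
#' @rdname io
#' @export
write_set_tsv <- function(set, path) {
  writeLines(as.character(as.integer(set)), path)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits one square TSV per subject (`sub-XXX_connectome.tsv`),
#' `coordinates.tsv`, per-task state files
#' (`states/sub-XXX_task-T_state-{A,B}.tsv`), `labels.tsv`, and a JSON
#' manifest recording the config and the planted-core indices.
#'
#' @param cohort output of [generate_cohort].
#' @param config the [cohort_config] used.
#' @param dir output directory (created if needed).
#' @param n_networks number of synthetic network labels (default 8).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, config, dir, n_networks = 8) {
  dir.create(file.path(dir, "states"), recursive = TRUE,
             showWarnings = FALSE)
  template <- attr(cohort, "template")
  for (i in seq_along(cohort)) {
    write_matrix_tsv(cohort[[i]]$weights,
                     file.path(dir, sprintf("sub-%03d_connectome.tsv", i)))
    for (t in seq_len(config$n_tasks)) {
      st <- generate_state_pair(cohort[[i]], config, task_index = t,
                                seed = config$seed + 1000L * i)
      write_state_tsv(st$A, file.path(dir, "states",
        sprintf("sub-%03d_task-%d_state-A.tsv", i, t)))
      write_state_tsv(st$B, file.path(dir, "states",
        sprintf("sub-%03d_task-%d_state-B.tsv", i, t)))
    }
  }
  coords <- template$coordinates
  utils::write.table(
    data.frame(node = seq_len(nrow(coords)), x = coords[, 1],
               y = coords[, 2], z = coords[, 3],
               hemisphere = template$hemisphere),
    file.path(dir, "coordinates.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  labels <- generate_network_labels(coords, n_networks, seed = config$seed)
  writeLines(as.character(labels), file.path(dir, "labels.tsv"))
  manifest <- list(config = unclass(config),
                   core_nodes = attr(cohort, "core_nodes"),
                   n_networks = n_networks)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
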