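#' Export a pipeline product to CSV, JSON or GraphML
#'
#' Supported products: `RateMatrix` (edge list: donor, acceptor, k_ps1,
#' tau_ps, level), `CofactorInventory` (per-class counts + residue table),
#' `BinnedEdgeList`, `Hamiltonian` (square CSV with a site-id header) and
#' plain data.frames. Rate-matrix and inventory round-trips through CSV/JSON
#' are lossless to 1e-9 relative.
#'
#' @param object The product to export.
#' @param path Output file path.
#' @param format `"csv"`, `"json"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_tables <- function(object, path, format = c("csv", "json",
                                                   "graphml")) {
  format <- match.arg(format)
  if (inherits(object, "RateMatrix")) {
    df <- rate_edge_df(object)
    switch(format,
      csv = utils::write.csv(df, path, row.names = FALSE),
      json = jsonlite::write_json(
        list(level = object$level, nodes = object$nodes, edges = df),
        path, dataframe = "rows", auto_unbox = TRUE, digits = NA),
      graphml = write_edge_graphml(df, object$nodes, path))
  } else if (inherits(object, "CofactorInventory")) {
    switch(format,
      csv = utils::write.csv(object$residues, path, row.names = FALSE),
      json = jsonlite::write_json(
        list(counts = as.list(object$counts),
             residues = object$residues, unmapped = object$unmapped),
        path, dataframe = "rows", auto_unbox = TRUE, digits = NA),
      graphml = stop("GraphML export is not defined for inventories"))
  } else if (inherits(object, "Hamiltonian")) {
    switch(format,
      csv = utils::write.csv(
        data.frame(site_id = object$site_ids, object$matrix,
                   check.names = FALSE),
        path, row.names = FALSE),
      json = jsonlite::write_json(
        list(site_ids = object$site_ids,
             matrix = apply(object$matrix, 1, as.numeric,
                            simplify = FALSE)),
        path, auto_unbox = TRUE, digits = NA),
      graphml = stop("GraphML export is not defined for Hamiltonians"))
  } else if (inherits(object, "BinnedEdgeList") || is.data.frame(object)) {
    df <- as.data.frame(object)
    switch(format,
      csv = utils::write.csv(df, path, row.names = FALSE),
      json = jsonlite::write_json(df, path, dataframe = "rows",
                                  auto_unbox = TRUE, digits = NA),
      graphml = {
        if (!all(c("from", "to") %in% names(df))) {
          stop("GraphML export needs 'from'/'to' columns")
        }
        write_edge_graphml(df, unique(c(df$from, df$to)), path)
      })
  } else {
    stop("unsupported export type: ", paste(class(object), collapse = "/"))
  }
  invisible(path)
}

rate_edge_df <- function(rm) {
  idx <- which(row(rm$k) != col(rm$k) & rm$k > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(donor = rm$nodes[idx[, 1]], acceptor = rm$nodes[idx[, 2]],
             k_ps1 = rm$k[idx], tau_ps = rm$tau[idx], level = rm$level,
             stringsAsFactors = FALSE)
}

#' Read a rate-matrix edge-list CSV back into a RateMatrix
#' @param path CSV written by [export_tables()].
#' @param nodes Optional node order; defaults to nodes seen in the file.
#' @export
read_rate_matrix <- function(path, nodes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- unique(c(df$donor, df$acceptor))
  k <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  k[cbind(match(df$donor, nodes), match(df$acceptor, nodes))] <- df$k_ps1
  new_rate_matrix(nodes, k, unique(df$level)[1])
}

write_edge_graphml <- function(df, nodes, path) {
  g <- igraph::graph_from_data_frame(df, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  igraph::write_graph(g, path, format = "graphml")
}
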