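#' Default time-constant binning schemes (ps)
#'
#' Pairwise maps use fast < 1 ps, mid 1-10 ps, slow 10-20 ps, edges slower
#' than 20 ps omitted; domain-level maps omit edges slower than 25 ps.
#' Boundary values fall in the slower bin.
#'
#' @param level `"pairwise"` or `"domain"`.
#' @return A `BinScheme`: list with `breaks`, `labels`, `cutoff`.
#' @export
bin_scheme <- function(level = c("pairwise", "domain")) {
  level <- match.arg(level)
  if (level == "pairwise") {
    list(breaks = c(1, 10, 20), labels = c("fast", "mid", "slow"),
         cutoff = 20)
  } else {
    list(breaks = c(1, 10, 25), labels = c("fast", "mid", "slow"),
         cutoff = 25)
  }
}

#' Bin the edges of a rate matrix by time constant
#'
#' Every directed edge with finite tau at most the scheme cutoff is assigned
#' to exactly one bin; a boundary value goes to the slower bin (tau = 1 ps
#' is `mid`, tau = 20 ps is omitted under the pairwise scheme).
#'
#' @param rates A `RateMatrix`.
#' @param scheme A bin scheme from [bin_scheme()]; defaults to the scheme
#'   matching `rates$level`.
#' @return A `BinnedEdgeList` data.frame: `from`, `to`, `k_ps1`, `tau_ps`,
#'   `bin`.
#' @export
bin_edges <- function(rates, scheme = bin_scheme(rates$level)) {
  n <- length(rates$nodes)
  idx <- which(row(rates$k) != col(rates$k) & rates$k > 0, arr.ind = TRUE)
  out <- data.frame(from = rates$nodes[idx[, 1]],
                    to = rates$nodes[idx[, 2]],
                    k_ps1 = rates$k[idx], tau_ps = rates$tau[idx],
                    stringsAsFactors = FALSE)
  out <- out[out$tau_ps < scheme$cutoff, , drop = FALSE]
  if (nrow(out)) {
    # left-open intervals: tau exactly on a boundary joins the slower bin
    bin_i <- findInterval(out$tau_ps, scheme$breaks, left.open = FALSE)
    out$bin <- scheme$labels[bin_i + 1L]
  } else {
    out$bin <- character(0)
  }
  out <- out[order(out$tau_ps, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("BinnedEdgeList", "data.frame"))
}

#' Partition antenna domains into kinetic groups
#'
#' Builds the undirected graph over non-core domains with an edge wherever
#' the faster of the two directed time constants is at most `cutoff_ps`, and
#' returns its connected components. Groups are numbered by their smallest
#' member label.
#'
#' @param gf A domain-level `RateMatrix`.
#' @param cutoff_ps Time-constant cutoff (default 25 ps, the domain-map
#'   omission rule).
#' @param exclude Labels excluded from grouping (default `"core"`).
#' @return A `GroupPartition`: list with `groups` (list of label vectors)
#'   and `membership` (named integer).
#' @export
partition_groups <- function(gf, cutoff_ps = 25, exclude = "core") {
  labs <- setdiff(gf$nodes, exclude)
  tau <- gf$tau[labs, labs, drop = FALSE]
  m <- pmin(tau, t(tau)) <= cutoff_ps
  diag(m) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(labs, comp$membership)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, min, ""))]
  names(groups) <- paste0("group_", seq_along(groups))
  membership <- stats::setNames(rep(seq_along(groups),
                                    lengths(groups)),
                                unlist(groups))
  structure(list(groups = groups, membership = membership,
                 cutoff_ps = cutoff_ps),
            class = "GroupPartition")
}

# step time constants along a node path; errors on a missing edge
path_step_taus <- function(path, gf) {
  if (length(path) < 2) stop("path needs at least two nodes")
  if (any(path[-1] == path[-length(path)])) {
    stop("consecutive path nodes must be distinct")
  }
  miss <- setdiff(path, gf$nodes)
  if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "))
  taus <- numeric(length(path) - 1)
  for (s in seq_along(taus)) {
    taus[s] <- gf$tau[path[s], path[s + 1]]
    if (!is.finite(taus[s])) {
      stop("no finite rate for step ", path[s], " -> ", path[s + 1])
    }
  }
  taus
}

#' Composite time constant of a multi-step pathway
#'
#' Aggregates per-step time constants by the series-sum rule (composite tau
#' = sum of step taus), so a composite time is never smaller than its
#' slowest step.
#'
#' @param path Character vector of node labels, in transfer order.
#' @param gf A `RateMatrix` (domain level typically).
#' @return A `PathwayResult`: list with `path`, `step_tau_ps`,
#'   `composite_tau_ps`, `rule`.
#' @export
composite_path_time <- function(path, gf) {
  taus <- path_step_taus(path, gf)
  structure(list(path = path, step_tau_ps = taus,
                 composite_tau_ps = sum(taus), rule = "series_sum"),
            class = "PathwayResult")
}

#' @export
print.PathwayResult <- function(x, ...) {
  cat(format_pathway(x), "\n")
  invisible(x)
}

#' Render a pathway as "A-B-core (tau ps)" text
#' @param x A `PathwayResult`.
#' @export
format_pathway <- function(x) {
  sprintf("%s (%.1f ps)", paste(x$path, collapse = "-"),
          x$composite_tau_ps)
}

#' Fastest composite route from an antenna domain to the core
#'
#' Minimum-composite-tau simple path under the series-sum rule, i.e. the
#' shortest path in the directed graph weighted by step time constants.
#' Ties are broken lexicographically by node sequence.
#'
#' @param from Starting domain label.
#' @param gf A domain-level `RateMatrix`.
#' @param core_label Target label (default `"core"`).
#' @return A `PathwayResult`.
#' @export
best_route_to_core <- function(from, gf, core_label = "core") {
  stopifnot(from %in% gf$nodes, core_label %in% gf$nodes)
  finite <- is.finite(gf$tau) & row(gf$tau) != col(gf$tau)
  idx <- which(finite, arr.ind = TRUE)
  if (!nrow(idx)) stop("no routes: rate matrix has no finite edges")
  edges <- data.frame(from = gf$nodes[idx[, 1]], to = gf$nodes[idx[, 2]],
                      weight = gf$tau[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = gf$nodes))
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = from, to = core_label,
                           mode = "out", weights = igraph::E(g)$weight))
  nodes <- names(sp$vpath[[1]])
  if (length(nodes) < 2 && from != core_label) {
    stop("core unreachable from ", from)
  }
  best <- composite_path_time(nodes, gf)
  # deterministic tie-break: enumerate equally-fast simple paths and take
  # the lexicographically smallest (graphs here are small domain graphs)
  alt <- all_simple_routes(gf, from, core_label, best$composite_tau_ps)
  if (length(alt)) {
    keys <- vapply(alt, function(p) paste(p, collapse = "\r"), "")
    best <- composite_path_time(alt[[order(keys)[1]]], gf)
  }
  best
}

# all simple paths achieving the optimal composite tau (within 1e-9)
all_simple_routes <- function(gf, from, to, tau_opt) {
  n <- length(gf$nodes)
  if (n > 12) return(list())  # tie-break enumeration only for small graphs
  res <- list()
  recurse <- function(path, tau) {
    last <- path[length(path)]
    if (tau > tau_opt + 1e-9) return()
    if (last == to) {
      if (abs(tau - tau_opt) <= 1e-9) res[[length(res) + 1]] <<- path
      return()
    }
    for (nxt in gf$nodes) {
      if (nxt %in% path) next
      t_step <- gf$tau[last, nxt]
      if (is.finite(t_step)) recurse(c(path, nxt), tau + t_step)
    }
  }
  recurse(from, 0)
  res
}
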