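#' Domain partition of the pigment network
#'
#' Maps pigment sites to antenna / core domains (e.g. `LHC-1` ... `LHC-15`,
#' `core`), either site-by-site or — the common case for a supercomplex —
#' chain-by-chain.
#'
#' @param map Named character vector: names are site ids (`by = "site"`) or
#'   chain ids (`by = "chain"`), values are domain labels.
#' @param by `"chain"` or `"site"`.
#' @return A `DomainPartition`.
#' @export
domain_partition <- function(map, by = c("chain", "site")) {
  by <- match.arg(by)
  stopifnot(is.character(map), !is.null(names(map)), all(nzchar(map)))
  structure(list(map = map, by = by, labels = unique(unname(map))),
            class = "DomainPartition")
}

domain_of <- function(partition, site) {
  key <- if (partition$by == "chain") site$chain else site$site_id
  if (!key %in% names(partition$map)) return(NA_character_)
  unname(partition$map[[key]])
}

#' Read a domain partition from 2-column TSV (chain <TAB> domain label)
#' @param path TSV path; lines starting with `#` are comments.
#' @export
read_domain_partition <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("chain", "domain"))
  domain_partition(stats::setNames(df$domain, df$chain), by = "chain")
}

#' Group site ids by domain label
#' @param siteset A `PigmentSiteSet` or site list.
#' @param partition A `DomainPartition`.
#' @return Named list of character vectors of site ids; errors if any site
#'   is uncovered.
#' @export
partition_site_ids <- function(siteset, partition) {
  sites <- as_site_list(siteset)
  lab <- vapply(sites, function(s) domain_of(partition, s), "")
  ids <- vapply(sites, `[[`, "", "site_id")
  if (anyNA(lab)) {
    stop("partition does not cover site(s): ",
         paste(utils::head(ids[is.na(lab)], 5), collapse = ", "))
  }
  split(ids, lab)
}
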