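#' Construct a bipartite host-parasite network
#'
#' The central data object of the package: an ordered host set, an ordered
#' parasite set, and a set of host-parasite interactions. Parasites must have
#' at least one host (a parasite with no host cannot exist), hosts may be
#' uninfected (degree 0), and the two identifier sets must be disjoint.
#' Duplicate interactions are an error, never silently deduplicated, because
#' they would corrupt downstream richness counts.
#'
#' @param edges a two-column data frame (host, parasite) of interactions, one
#'   row per interaction. Column names are taken positionally.
#' @param hosts optional character vector of host identifiers. Hosts appearing
#'   in `edges` but not listed here are appended in first-appearance order;
#'   listing extra identifiers declares degree-0 (uninfected) hosts.
#' @param parasites optional character vector fixing parasite order; must
#'   contain exactly the parasites present in `edges`.
#' @return an object of class `bipartite_network` with elements `hosts`,
#'   `parasites` (character vectors) and `edges` (data frame with columns
#'   `host`, `parasite`).
#' @examples
#' net <- bipartite_network(data.frame(
#'   host = c("h1", "h1", "h2"), parasite = c("p1", "p2", "p2")))
#' summary(net)
#' @seealso [read_edge_list()], [read_adjacency_matrix()], [write_network()]
#' @export
bipartite_network <- function(edges, hosts = NULL, parasites = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    stopf("`edges` must be a data frame with at least two columns")
  }
  h <- as.character(edges[[1L]])
  p <- as.character(edges[[2L]])
  if (length(h) == 0L) stopf("empty edge set: a network needs at least one interaction")
  if (anyNA(h) || anyNA(p) || any(h == "") || any(p == "")) {
    stopf("edge list contains missing or empty identifiers")
  }
  key <- paste(h, p, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    pair <- strsplit(d, "\r", fixed = TRUE)[[1L]]
    stopf("duplicate edge: (%s, %s)", pair[1L], pair[2L])
  }
  host_ids <- unique(h)
  if (!is.null(hosts)) {
    hosts <- as.character(hosts)
    if (anyDuplicated(hosts)) stopf("duplicate identifiers in `hosts`")
    host_ids <- c(hosts, setdiff(host_ids, hosts))
  }
  par_ids <- unique(p)
  if (!is.null(parasites)) {
    parasites <- as.character(parasites)
    extra <- setdiff(parasites, par_ids)
    if (length(extra)) {
      stopf("parasite(s) declared but absent from the edge list (a parasite needs >= 1 host): %s",
            paste(extra, collapse = ", "))
    }
    par_ids <- c(parasites, setdiff(par_ids, parasites))
  }
  clash <- intersect(host_ids, par_ids)
  if (length(clash)) {
    stopf("identifier(s) used both as host and as parasite: %s",
          paste(head(clash, 5L), collapse = ", "))
  }
  structure(
    list(hosts = host_ids, parasites = par_ids,
         edges = data.frame(host = h, parasite = p, stringsAsFactors = FALSE)),
    class = "bipartite_network")
}

#' Number of hosts, parasites and edges
#'
#' @param net a [bipartite_network()]
#' @return integer count.
#' @export
n_hosts <- function(net) length(net$hosts)

#' @rdname n_hosts
#' @export
n_parasites <- function(net) length(net$parasites)

#' @rdname n_hosts
#' @export
n_edges <- function(net) nrow(net$edges)

#' Binary incidence matrix of a network
#'
#' Hosts are rows, parasites are columns, in the network's identifier order.
#'
#' @param net a [bipartite_network()]
#' @return a 0/1 integer matrix with dimnames.
#' @export
incidence_matrix <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  m <- matrix(0L, length(net$hosts), length(net$parasites),
              dimnames = list(net$hosts, net$parasites))
  m[cbind(match(net$edges$host, net$hosts),
          match(net$edges$parasite, net$parasites))] <- 1L
  m
}

# Build a network from an incidence matrix already known to be valid.
network_from_matrix <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  bipartite_network(
    data.frame(host = rownames(m)[idx[, 1L]], parasite = colnames(m)[idx[, 2L]],
               stringsAsFactors = FALSE),
    hosts = rownames(m), parasites = colnames(m)[colSums(m != 0) > 0])
}

#' Host and parasite degrees
#'
#' `host_degrees()` counts parasites per host (parasite richness of the
#' host); `parasite_degrees()` counts hosts per parasite (the parasite's
#' host range).
#'
#' @param net a [bipartite_network()]
#' @return named integer vector in network order.
#' @export
host_degrees <- function(net) {
  d <- table(factor(net$edges$host, levels = net$hosts))
  stats::setNames(as.integer(d), net$hosts)
}

#' @rdname host_degrees
#' @export
parasite_degrees <- function(net) {
  d <- table(factor(net$edges$parasite, levels = net$parasites))
  stats::setNames(as.integer(d), net$parasites)
}

#' Read a bipartite network from a delimited edge list
#'
#' The expected format is a delimited text file with a header and one
#' interaction per row. Column names are configurable so that externally
#' produced tables (e.g. converted host-parasite database exports) load
#' without editing. Degree-0 hosts can be declared either through
#' `extra_hosts` or through a node sidecar file with columns `id,role`
#' (`role` in `host`/`parasite`), the format [write_network()] emits.
#'
#' @param path path to the edge-list file.
#' @param host_column,parasite_column header names of the host and parasite
#'   columns (defaults `"host"`, `"parasite"`).
#' @param extra_hosts optional character vector of hosts with no
#'   interactions.
#' @param node_file optional path to a node sidecar (`id,role` CSV); hosts
#'   listed there are added (possibly at degree 0) and the parasite list is
#'   checked for consistency.
#' @param sep field separator, default comma.
#' @return a [bipartite_network()].
#' @export
read_edge_list <- function(path, host_column = "host", parasite_column = "parasite",
                           extra_hosts = NULL, node_file = NULL, sep = ",") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  for (col in c(host_column, parasite_column)) {
    if (!col %in% names(df)) stopf("column '%s' not found in %s", col, path)
  }
  hosts <- NULL; declared_p <- NULL
  if (!is.null(node_file)) {
    if (!file.exists(node_file)) stopf("node file not found: %s", node_file)
    nodes <- read.csv(node_file, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("id", "role") %in% names(nodes))) {
      stopf("node file must have columns `id` and `role`")
    }
    bad <- setdiff(nodes$role, c("host", "parasite"))
    if (length(bad)) stopf("unknown role(s) in node file: %s", paste(bad, collapse = ", "))
    hosts <- nodes$id[nodes$role == "host"]
    declared_p <- nodes$id[nodes$role == "parasite"]
    missing_p <- setdiff(declared_p, unique(df[[parasite_column]]))
    if (length(missing_p)) {
      stopf("parasite(s) declared in node file but absent from the edge list: %s",
            paste(missing_p, collapse = ", "))
    }
  }
  if (!is.null(extra_hosts)) {
    # first-appearance order, declared-only hosts appended
    extra <- as.character(extra_hosts)
    hosts <- if (is.null(hosts)) c(unique(df[[host_column]]), extra)
             else unique(c(hosts, extra))
  }
  if (!is.null(hosts) && any(hosts %in% df[[parasite_column]])) {
    clash <- intersect(hosts, df[[parasite_column]])
    stopf("identifier(s) declared as host but used as parasite: %s",
          paste(clash, collapse = ", "))
  }
  # node-file order wins when present, else first-appearance order
  if (is.null(hosts)) hosts <- unique(df[[host_column]])
  bipartite_network(df[, c(host_column, parasite_column)], hosts = hosts,
                    parasites = declared_p)
}

#' Read a bipartite network from a 0/1 adjacency matrix
#'
#' Tab-separated: first header row holds parasite identifiers, first column
#' holds host identifiers, cells are 0 or 1. Hosts may have all-zero rows
#' (uninfected); an all-zero parasite column is an error.
#'
#' @param path path to the TSV file.
#' @return a [bipartite_network()].
#' @export
read_adjacency_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   row.names = 1L)
  m <- as.matrix(df)
  suppressWarnings(storage.mode(m) <- "numeric")
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    stopf("non-binary cell in adjacency matrix %s: all cells must be 0 or 1", path)
  }
  zero_p <- colnames(m)[colSums(m) == 0]
  if (length(zero_p)) {
    stopf("all-zero parasite column(s) (a parasite needs >= 1 host): %s",
          paste(zero_p, collapse = ", "))
  }
  network_from_matrix(m)
}

#' Write a network to disk
#'
#' `format = "edge_list"` writes one CSV of interactions (`host,parasite`)
#' plus, when the network has degree-0 hosts, a node sidecar
#' `<path basename>.nodes.csv` (`id,role`) so the uninfected hosts survive a
#' round trip. `format = "adjacency"` writes the full 0/1 TSV matrix, which
#' preserves degree-0 hosts by itself. Reading back what was written
#' reproduces hosts, parasites and edges exactly.
#'
#' @param net a [bipartite_network()]
#' @param path output file path.
#' @param format `"edge_list"` or `"adjacency"`.
#' @return invisibly, the path(s) written.
#' @export
write_network <- function(net, path, format = c("edge_list", "adjacency")) {
  stopifnot(inherits(net, "bipartite_network"))
  format <- match.arg(format)
  if (format == "edge_list") {
    write.csv(net$edges, path, row.names = FALSE, quote = FALSE)
    # node sidecar preserves degree-0 hosts and identifier order exactly
    side <- paste0(tools::file_path_sans_ext(path), ".nodes.csv")
    nodes <- data.frame(
      id = c(net$hosts, net$parasites),
      role = rep(c("host", "parasite"), c(length(net$hosts), length(net$parasites))))
    write.csv(nodes, side, row.names = FALSE, quote = FALSE)
    paths <- c(path, side)
  } else {
    m <- incidence_matrix(net)
    out <- data.frame(host = rownames(m), m, check.names = FALSE)
    write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- path
  }
  invisible(paths)
}

#' Randomly subsample interactions (incomplete-information emulation)
#'
#' Keeps `round(keep_fraction * E)` interactions chosen uniformly without
#' replacement, emulating incompletely sampled networks. Parasites left with
#' no interactions are dropped (they cannot be observed at all); hosts are
#' always retained, at degree 0 if need be, so the host axis of a
#' disassembly curve is unchanged.
#'
#' @param net a [bipartite_network()]
#' @param keep_fraction fraction of interactions to keep, in (0, 1].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a [bipartite_network()].
#' @export
subsample_interactions <- function(net, keep_fraction, seed) {
  stopifnot(inherits(net, "bipartite_network"))
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1L ||
      keep_fraction <= 0 || keep_fraction > 1) {
    stopf("`keep_fraction` must be a single number in (0, 1]")
  }
  if (keep_fraction == 1) return(net)
  E <- n_edges(net)
  k <- round(keep_fraction * E)
  if (k < 1L) stopf("keep_fraction %.3f would retain zero of %d edges", keep_fraction, E)
  keep <- with_seed(seed, sort(sample.int(E, k)))
  kept <- net$edges[keep, , drop = FALSE]
  bipartite_network(kept, hosts = net$hosts,
                    parasites = intersect(net$parasites, kept$parasite))
}

#' Summarize a bipartite network
#'
#' @param object a [bipartite_network()]
#' @param ... unused.
#' @return an object of class `network_summary` with fields `n_hosts`,
#'   `n_parasites`, `n_edges` and `connectance` = E / (H * P).
#' @export
summary.bipartite_network <- function(object, ...) {
  H <- n_hosts(object); P <- n_parasites(object); E <- n_edges(object)
  structure(list(n_hosts = H, n_parasites = P, n_edges = E,
                 connectance = E / (H * P)),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Bipartite network: %d hosts, %d parasites, %d interactions (connectance %.3f)\n",
              x$n_hosts, x$n_parasites, x$n_edges, x$connectance))
  invisible(x)
}

#' @export
print.bipartite_network <- function(x, ...) {
  print(summary(x))
  dh <- host_degrees(x); dp <- parasite_degrees(x)
  cat(sprintf("  host parasite-richness: %d-%d (median %g); parasite host-range: %d-%d (median %g)\n",
              min(dh), max(dh), stats::median(dh), min(dp), max(dp), stats::median(dp)))
  invisible(x)
}

#' Plot the incidence matrix of a network
#'
#' Hosts on the vertical axis, parasites on the horizontal, filled cells are
#' interactions. A quick structural fingerprint (nestedness and modular
#' blocks are visible by eye once rows/columns are degree-sorted).
#'
#' @param x a [bipartite_network()]
#' @param sort_degrees sort hosts and parasites by decreasing degree first.
#' @param ... passed to [graphics::image()].
#' @export
plot.bipartite_network <- function(x, sort_degrees = TRUE, ...) {
  m <- incidence_matrix(x)
  if (sort_degrees) {
    m <- m[order(rowSums(m), decreasing = TRUE),
           order(colSums(m), decreasing = TRUE), drop = FALSE]
  }
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = c("white", "grey20"), xlab = "parasites", ylab = "hosts",
                  axes = FALSE, ...)
  graphics::box()
  invisible(x)
}
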