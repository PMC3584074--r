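#' Construct a bipartite network
#'
#' A bipartite network records binary interactions between a set of consumer
#' species (pollinators, parasites, herbivores) and a set of resource species
#' (plants, hosts). The adjacency matrix is oriented with rows = resources
#' and columns = consumers, so entry `A[j, i] = 1` means consumer `i`
#' interacts with resource `j`.
#'
#' @param adjacency numeric matrix of 0/1 entries, rows = resources,
#'   columns = consumers. Dimnames, if present, are used as labels.
#' @param consumer_labels,resource_labels optional character vectors of
#'   unique species labels; defaults are taken from `dimnames(adjacency)`
#'   or generated (`C1..`, `R1..`).
#' @return An object of class `bipartite_network`: a list with elements
#'   `adjacency` (integer 0/1 matrix with labels as dimnames),
#'   `consumer_labels`, `resource_labels`.
#' @examples
#' net <- bipartite_network(matrix(c(1, 1, 0, 1), 2, 2))
#' n_links(net)
#' @export
bipartite_network <- function(adjacency, consumer_labels = NULL,
                              resource_labels = NULL) {
  if (!is.matrix(adjacency)) adjacency <- as.matrix(adjacency)
  mode(adjacency) <- "numeric"
  if (anyNA(adjacency)) {
    stop("adjacency matrix contains missing values", call. = FALSE)
  }
  if (!all(adjacency %in% c(0, 1))) {
    stop("adjacency entries must all be 0 or 1", call. = FALSE)
  }
  if (is.null(resource_labels)) {
    resource_labels <- rownames(adjacency)
    if (is.null(resource_labels)) {
      resource_labels <- paste0("R", seq_len(nrow(adjacency)))
    }
  }
  if (is.null(consumer_labels)) {
    consumer_labels <- colnames(adjacency)
    if (is.null(consumer_labels)) {
      consumer_labels <- paste0("C", seq_len(ncol(adjacency)))
    }
  }
  consumer_labels <- as.character(consumer_labels)
  resource_labels <- as.character(resource_labels)
  if (length(resource_labels) != nrow(adjacency) ||
      length(consumer_labels) != ncol(adjacency)) {
    stop("label lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(consumer_labels) || anyDuplicated(resource_labels)) {
    stop("species labels must be unique within each side", call. = FALSE)
  }
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(resource_labels, consumer_labels)
  structure(
    list(adjacency = adjacency,
         consumer_labels = consumer_labels,
         resource_labels = resource_labels),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d resources x %d consumers, %d links (connectance %.3f)\n",
              n_resources(x), n_consumers(x), n_links(x),
              connectance_empirical(x)))
  zc <- sum(colSums(x$adjacency) == 0)
  zr <- sum(rowSums(x$adjacency) == 0)
  if (zc + zr > 0) {
    cat(sprintf("  note: %d consumer(s) and %d resource(s) have zero links\n", zc, zr))
  }
  invisible(x)
}

#' Network dimensions and link count
#'
#' @param net a `bipartite_network`.
#' @return `n_consumers`: number of consumer species (columns);
#'   `n_resources`: number of resource species (rows); `n_links`: total
#'   number of realized interactions.
#' @export
n_consumers <- function(net) ncol(net$adjacency)

#' @rdname n_consumers
#' @export
n_resources <- function(net) nrow(net$adjacency)

#' @rdname n_consumers
#' @export
n_links <- function(net) sum(net$adjacency)

validate_network <- function(net, require_links = TRUE) {
  stopifnot(inherits(net, "bipartite_network"))
  if (require_links && n_links(net) < 1) {
    stop("network has zero links; analysis requires at least one interaction",
         call. = FALSE)
  }
  invisible(net)
}

#' Read a bipartite network from file
#'
#' Two plain-text dialects are supported. `"adjacency-csv"` is a labeled CSV:
#' a header row of consumer labels, a leading column of resource labels, and
#' 0/1 cells. `"edgelist-tsv"` is a two-column tab-separated file with one
#' interaction per line, `resource_label<TAB>consumer_label`; lines starting
#' with `#` are treated as comments and duplicated edges are collapsed.
#'
#' @param path path to the file.
#' @param format `"adjacency-csv"` or `"edgelist-tsv"`.
#' @return a [bipartite_network()].
#' @export
read_network <- function(path, format = c("adjacency-csv", "edgelist-tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "adjacency-csv") {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) {
      stop("adjacency CSV contains non-numeric cells", call. = FALSE)
    }
    net <- bipartite_network(m)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) == 0) stop("edge list is empty", call. = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2)) {
      stop("edge list lines must have two tab-separated columns", call. = FALSE)
    }
    res <- vapply(parts, `[[`, character(1), 1)
    con <- vapply(parts, `[[`, character(1), 2)
    resource_labels <- unique(res)
    consumer_labels <- unique(con)
    m <- matrix(0L, length(resource_labels), length(consumer_labels),
                dimnames = list(resource_labels, consumer_labels))
    m[cbind(match(res, resource_labels), match(con, consumer_labels))] <- 1L
    net <- bipartite_network(m)
  }
  validate_network(net)
}

#' Write a bipartite network to file
#'
#' Inverse of [read_network()]; the adjacency-CSV round trip reproduces the
#' matrix exactly.
#'
#' @param net a `bipartite_network`.
#' @param path output path.
#' @param format see [read_network()].
#' @export
write_network <- function(net, path, format = c("adjacency-csv", "edgelist-tsv")) {
  format <- match.arg(format)
  validate_network(net, require_links = FALSE)
  if (format == "adjacency-csv") {
    df <- as.data.frame(net$adjacency)
    utils::write.csv(df, path, row.names = TRUE, quote = FALSE)
  } else {
    idx <- which(net$adjacency == 1L, arr.ind = TRUE)
    lines <- c("# resource\tconsumer",
               paste(net$resource_labels[idx[, 1]],
                     net$consumer_labels[idx[, 2]], sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Sort a network by marginal totals
#'
#' Reorders rows (resources) and columns (consumers) in descending order of
#' their marginal totals (degrees). Ties keep the original relative order, so
#' the operation is a stable permutation: link count and the degree multisets
#' are unchanged. This is the canonical ordering used by nestedness metrics.
#'
#' @param net a `bipartite_network`.
#' @return the sorted `bipartite_network`.
#' @export
sort_by_marginals <- function(net) {
  validate_network(net, require_links = FALSE)
  a <- net$adjacency
  ro <- order(-rowSums(a))   # order() is stable: ties keep original order
  co <- order(-colSums(a))
  bipartite_network(a[ro, co, drop = FALSE])
}

#' Empirical connectance
#'
#' The realized fraction of all possible links, `L / (S_C * S_R)`.
#'
#' @param net a `bipartite_network`.
#' @return a fraction in (0, 1].
#' @export
connectance_empirical <- function(net) {
  validate_network(net, require_links = FALSE)
  n_links(net) / (n_consumers(net) * n_resources(net))
}
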