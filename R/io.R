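#' Read / write edge lists
#'
#' Weighted edge lists are 3-column TSVs (`gene_a`, `gene_b`, `weight`);
#' binary interaction lists are 2-column (`gene_a`, `gene_b`).
#'
#' @param path file path.
#' @return data frame of edges.
#' @export
read_edge_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_a", "gene_b"), names(tab))
  if (length(miss)) {
    stop("edge TSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  tab
}

#' @rdname read_edge_tsv
#' @param edges data frame of edges.
#' @export
write_edge_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write expression matrices
#'
#' Genes as rows (first column `gene`), samples as the remaining header
#' columns.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (names(tab)[1] != "gene") {
    stop("expression TSV must have 'gene' as its first column")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param x numeric matrix with gene rownames.
#' @export
write_expression_tsv <- function(x, path) {
  tab <- data.frame(gene = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a gene network
#'
#' Full symmetric matrix TSV: first column `gene`, remaining columns the
#' gene labels in order.
#'
#' @param path file path.
#' @param kind network kind to restore (`"weighted"` or `"binary"`).
#' @return a `"gene_network"`.
#' @export
read_network_tsv <- function(path, kind = "weighted") {
  m <- read_expression_tsv(path)
  gene_network(rownames(m), m, kind = kind)
}

#' @rdname read_network_tsv
#' @param net a `"gene_network"`.
#' @export
write_network_tsv <- function(net, path) {
  write_expression_tsv(net$weights, path)
}

#' Relabel a network or ligand-set collection through an ortholog map
#'
#' Identifiers are replaced according to a two-column mapping table;
#' unmapped entities are dropped with a message reporting the count.  When
#' several sources map to one target, the best (maximum) edge weight is
#' kept, with a warning.
#'
#' @param x a `"gene_network"` or a named list of [ligand_set()] objects.
#' @param mapping data frame with columns `from`, `to`.
#' @return the relabeled object.
#' @export
map_orthologs <- function(x, mapping) {
  stopifnot(all(c("from", "to") %in% names(mapping)), nrow(mapping) > 0)
  mapping <- mapping[!duplicated(mapping$from), , drop = FALSE]
  lut <- stats::setNames(mapping$to, mapping$from)
  if (inherits(x, "gene_network")) {
    mapped <- lut[x$genes]
    drop_n <- sum(is.na(mapped))
    if (drop_n) message(drop_n, " unmapped gene(s) dropped")
    keep <- which(!is.na(mapped))
    w <- x$weights[keep, keep, drop = FALSE]
    new <- mapped[keep]
    targets <- sort(unique(new))
    if (length(targets) < length(new)) {
      warning("many-to-one ortholog collisions resolved by maximum weight")
    }
    out <- matrix(0, length(targets), length(targets),
                  dimnames = list(targets, targets))
    for (i in seq_along(new)) {
      for (j in seq_along(new)) {
        ti <- new[i]; tj <- new[j]
        out[ti, tj] <- max(out[ti, tj], w[i, j])
      }
    }
    if (all(diag(x$weights) == 1)) diag(out) <- 1  # keep the convention
    gene_network(targets, out, kind = x$kind)
  } else if (is.list(x) && all(vapply(x, inherits, logical(1),
                                      "ligand_set"))) {
    mapped <- lut[names(x)]
    drop_n <- sum(is.na(mapped))
    if (drop_n) message(drop_n, " unmapped target(s) dropped")
    keep <- which(!is.na(mapped))
    x <- x[keep]
    new <- mapped[keep]
    if (anyDuplicated(new)) {
      warning("many-to-one ortholog collisions: first ligand set kept")
      first <- !duplicated(new)
      x <- x[first]; new <- new[first]
    }
    out <- Map(function(s, id) { s$target_id <- id; s }, x, new)
    names(out) <- new
    out
  } else {
    stop("map_orthologs handles gene networks and ligand-set collections")
  }
}

#' Write / read a resolved run configuration
#'
#' A flat JSON file recording the tunable parameters of a run (seeds,
#' cutoffs, fold counts, term-size bounds, paths) so every output is
#' reproducible from its config.
#'
#' @param config named list of scalar settings.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
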