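#' Ontology DAG of functional terms
#'
#' Terms linked to parent terms (is-a / part-of alike; both are propagated
#' by default), each assigned to a branch (`BP`, `MF`, `CC` or `other`).
#' Acyclicity is validated at construction.
#'
#' @param parent_table data frame with columns `term`, `parent` and
#'   optionally `branch` (`NA` parent rows declare roots / branches only).
#' @return object of class `"ontology_dag"`: list with `terms`, `parents`
#'   (named list of character vectors) and `branch` (named character).
#' @export
ontology_dag <- function(parent_table) {
  stopifnot(all(c("term", "parent") %in% names(parent_table)))
  has_par <- !is.na(parent_table$parent) & parent_table$parent != ""
  terms <- sort(unique(c(parent_table$term,
                         parent_table$parent[has_par])))
  parents <- lapply(terms, function(t) {
    unique(parent_table$parent[has_par & parent_table$term == t])
  })
  names(parents) <- terms
  branch <- rep("other", length(terms))
  names(branch) <- terms
  if ("branch" %in% names(parent_table)) {
    b <- parent_table$branch
    ok <- !is.na(b) & b != ""
    branch[parent_table$term[ok]] <- b[ok]
  }
  dag <- structure(list(terms = terms, parents = parents, branch = branch),
                   class = "ontology_dag")
  for (t in terms) term_ancestors(dag, t, seen = t)  # cycle check
  dag
}

# all strict ancestors of a term; errors on a cycle
term_ancestors <- function(dag, term, seen = character(0)) {
  ps <- dag$parents[[term]]
  out <- character(0)
  for (p in ps) {
    if (p %in% seen) stop("ontology contains a cycle through term '", p, "'")
    out <- c(out, p, term_ancestors(dag, p, seen = c(seen, p)))
  }
  unique(out)
}

#' Boolean gene-by-term annotation matrix
#'
#' @param genes ordered character gene labels.
#' @param terms ordered character term ids.
#' @param values logical genes-by-terms matrix.
#' @param evidence character matrix of the same shape: evidence-code tag
#'   for each positive (`""` where not annotated).
#' @param branch optional named character, branch per term.
#' @return object of class `"annotation_matrix"`.
#' @export
annotation_matrix <- function(genes, terms, values, evidence = NULL,
                              branch = NULL) {
  genes <- as.character(genes); terms <- as.character(terms)
  stopifnot(is.matrix(values), is.logical(values),
            nrow(values) == length(genes), ncol(values) == length(terms),
            !anyDuplicated(genes), !anyDuplicated(terms))
  dimnames(values) <- list(genes, terms)
  if (is.null(evidence)) {
    evidence <- matrix("", nrow(values), ncol(values))
    evidence[values] <- "synthetic"
  }
  stopifnot(all(dim(evidence) == dim(values)))
  dimnames(evidence) <- dimnames(values)
  if (is.null(branch)) {
    branch <- rep("other", length(terms))
    names(branch) <- terms
  }
  structure(list(genes = genes, terms = terms, values = values,
                 evidence = evidence, branch = branch[terms]),
            class = "annotation_matrix")
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat("annotation_matrix: ", length(x$genes), " genes x ", length(x$terms),
      " terms, ", sum(x$values), " positives\n", sep = "")
  invisible(x)
}

#' Propagate annotations up the ontology
#'
#' A gene annotated to a term becomes annotated to all of that term's
#' ancestors, carrying the evidence tag upward (the first tag to reach a
#' cell wins).  The operation is monotone and idempotent.  Annotations to
#' terms absent from the DAG are skipped with a warning.
#'
#' @param annotations data frame with columns `gene`, `term` and
#'   optionally `evidence`.
#' @param dag an [ontology_dag()].
#' @param genes gene universe (defaults to genes in `annotations`).
#' @return an [annotation_matrix()] over all DAG terms.
#' @export
propagate <- function(annotations, dag, genes = NULL) {
  stopifnot(inherits(dag, "ontology_dag"),
            all(c("gene", "term") %in% names(annotations)))
  if (is.null(genes)) genes <- sort(unique(annotations$gene))
  ev <- if ("evidence" %in% names(annotations)) {
    annotations$evidence
  } else {
    rep("synthetic", nrow(annotations))
  }
  unknown <- !(annotations$term %in% dag$terms)
  if (any(unknown)) {
    warning(sum(unknown), " annotation(s) to terms absent from the ",
            "ontology skipped")
  }
  anc <- lapply(dag$terms, function(t) c(t, term_ancestors(dag, t)))
  names(anc) <- dag$terms

  values <- matrix(FALSE, length(genes), length(dag$terms),
                   dimnames = list(genes, dag$terms))
  evid <- matrix("", length(genes), length(dag$terms),
                 dimnames = list(genes, dag$terms))
  for (r in which(!unknown)) {
    g <- annotations$gene[r]
    if (!(g %in% genes)) next
    ts <- anc[[annotations$term[r]]]
    fresh <- ts[!values[g, ts]]
    values[g, ts] <- TRUE
    evid[g, fresh] <- ev[r]
  }
  annotation_matrix(genes, dag$terms, values, evid, branch = dag$branch)
}

#' Build an annotation matrix from sparse triplets
#'
#' Assembles gene / term / evidence rows (the shape written by
#' [write_annotation_triplets()] and read by [read_annotation_tsv()]) into
#' an [annotation_matrix()].  With duplicated gene--term rows the first
#' evidence tag wins.
#'
#' @param triplets data frame with columns `gene`, `term` and optionally
#'   `evidence`.
#' @param genes gene universe (defaults to the genes present in
#'   `triplets`); genes never annotated must be supplied here to be part
#'   of the matrix.
#' @return an [annotation_matrix()].
#' @export
annotation_from_triplets <- function(triplets, genes = NULL) {
  stopifnot(all(c("gene", "term") %in% names(triplets)))
  if (is.null(genes)) genes <- sort(unique(triplets$gene))
  terms <- sort(unique(triplets$term))
  ev <- if ("evidence" %in% names(triplets)) {
    triplets$evidence
  } else {
    rep("synthetic", nrow(triplets))
  }
  outside <- !(triplets$gene %in% genes)
  if (any(outside)) {
    warning(sum(outside), " annotation(s) to genes outside the universe ",
            "skipped")
  }
  values <- matrix(FALSE, length(genes), length(terms),
                   dimnames = list(genes, terms))
  evid <- matrix("", length(genes), length(terms),
                 dimnames = list(genes, terms))
  for (r in which(!outside)) {
    g <- triplets$gene[r]; t <- triplets$term[r]
    if (!values[g, t]) {
      values[g, t] <- TRUE
      evid[g, t] <- ev[r]
    }
  }
  annotation_matrix(genes, terms, values, evid)
}

#' Filter terms by annotation count
#'
#' Keeps terms annotating between `min_genes` and `max_genes` genes
#' (inclusive at both ends), counted over the matrix's gene universe.
#'
#' @param A an [annotation_matrix()].
#' @param min_genes,max_genes inclusive size bounds (defaults 20 and
#'   1000).
#' @return the restricted [annotation_matrix()].
#' @export
filter_terms <- function(A, min_genes = 20L, max_genes = 1000L) {
  stopifnot(inherits(A, "annotation_matrix"))
  sizes <- colSums(A$values)
  keep <- sizes >= min_genes & sizes <= max_genes
  annotation_matrix(A$genes, A$terms[keep],
                    A$values[, keep, drop = FALSE],
                    A$evidence[, keep, drop = FALSE],
                    branch = A$branch[keep])
}

known_evidence_classes <- c("TAS", "ISS", "IEA", "EXP", "IDA", "IPI",
                            "IMP", "IGI", "IEP", "NAS", "IC", "ND",
                            "synthetic", "nonIEA")

#' Partition annotations by evidence class
#'
#' Selects, for each requested class, the positives whose evidence tag is
#' in the class.  `"nonIEA"` means every code other than `IEA`, so the
#' partitions are independent selections, not a disjoint split.  Terms
#' left with fewer than `min_genes` positives are dropped per partition.
#'
#' @param A an [annotation_matrix()].
#' @param classes character vector of evidence classes (codes or
#'   `"nonIEA"`).
#' @param min_genes,max_genes term-size bounds re-applied per partition
#'   (defaults keep any non-empty term; pass the analysis bounds to mirror
#'   the global filter).
#' @return named list of [annotation_matrix()] objects, one per class.
#' @export
partition_by_evidence <- function(A, classes, min_genes = 1L,
                                  max_genes = Inf) {
  stopifnot(inherits(A, "annotation_matrix"))
  valid <- union(known_evidence_classes, unique(A$evidence[A$values]))
  bad <- setdiff(classes, valid)
  if (length(bad)) {
    stop("unknown evidence class(es): ", paste(bad, collapse = ", "))
  }
  out <- lapply(classes, function(cl) {
    mask <- if (cl == "nonIEA") {
      A$values & A$evidence != "IEA"
    } else {
      A$values & A$evidence == cl
    }
    ev <- A$evidence
    ev[!mask] <- ""
    filter_terms(annotation_matrix(A$genes, A$terms, mask, ev,
                                   branch = A$branch),
                 min_genes = min_genes, max_genes = max_genes)
  })
  names(out) <- classes
  out
}

#' Median number of annotations per gene
#'
#' @param A an [annotation_matrix()].
#' @return median of per-gene annotation counts.
#' @export
median_annotations <- function(A) {
  stopifnot(inherits(A, "annotation_matrix"))
  stats::median(rowSums(A$values))
}

#' Read / write annotation tables
#'
#' `read_annotation_tsv` expects columns `gene`, `term`, `evidence`;
#' `read_dag_tsv` expects `term`, `parent`, `branch`.
#' `write_annotation_triplets` emits the positives of a matrix as sparse
#' `gene / term / evidence` rows, the format `read_annotation_tsv`
#' consumes.
#'
#' @param path file path.
#' @export
read_annotation_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "term")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("annotation TSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  tab
}

#' @rdname read_annotation_tsv
#' @export
read_dag_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term", "parent") %in% names(tab))) {
    stop("DAG TSV needs columns term, parent (and optionally branch)")
  }
  ontology_dag(tab)
}

#' @rdname read_annotation_tsv
#' @param A an [annotation_matrix()].
#' @export
write_annotation_triplets <- function(A, path) {
  idx <- which(A$values, arr.ind = TRUE)
  tab <- data.frame(gene = A$genes[idx[, 1]],
                    term = A$terms[idx[, 2]],
                    evidence = A$evidence[idx],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene, tab$term), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
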