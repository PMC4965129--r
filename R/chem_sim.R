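#' Ligand records and ligand sets
#'
#' Ligands are represented as plain data frames with one row per ligand:
#' columns `ligand_id` (character), `mol_weight` (daltons), `n_oxygen`,
#' `n_nitrogen` (atom counts) and `fingerprint`, a list column of integer
#' vectors giving the indices of the set bits of a topological fingerprint.
#' The fingerprint is treated as an abstract finite set of feature indices;
#' no chemistry toolkit is required.
#'
#' A `ligand_set` bundles a target identifier with such a table, collapsing
#' duplicated `ligand_id`s (first record wins).
#'
#' @param target_id single character target identifier.
#' @param ligands data frame of ligand records as described above.
#' @return An object of class `"ligand_set"`: a list with elements
#'   `target_id` and `ligands`.
#' @examples
#' lig <- ligand_frame(c("l1", "l2"), list(c(1L, 2L), c(2L, 3L)),
#'                     mol_weight = c(300, 400))
#' ls1 <- ligand_set("T1", lig)
#' @export
ligand_set <- function(target_id, ligands) {
  stopifnot(is.character(target_id), length(target_id) == 1L)
  ligands <- as_ligand_frame(ligands)
  if (nrow(ligands) < 1L) {
    stop("ligand set for target '", target_id, "' is empty")
  }
  dup <- duplicated(ligands$ligand_id)
  if (any(dup)) ligands <- ligands[!dup, , drop = FALSE]
  structure(list(target_id = target_id, ligands = ligands),
            class = "ligand_set")
}

#' @export
print.ligand_set <- function(x, ...) {
  cat("ligand_set '", x$target_id, "': ", nrow(x$ligands), " ligands\n",
      sep = "")
  invisible(x)
}

#' Build a ligand record table
#'
#' Convenience constructor for the ligand data-frame layout used throughout
#' the package.
#'
#' @param ligand_id character vector of ligand identifiers.
#' @param fingerprint list of integer vectors (set bit indices).
#' @param mol_weight,n_oxygen,n_nitrogen numeric property vectors, recycled
#'   to length of `ligand_id`.
#' @return data frame with a `fingerprint` list column.
#' @export
ligand_frame <- function(ligand_id, fingerprint,
                         mol_weight = 300, n_oxygen = 2, n_nitrogen = 2) {
  n <- length(ligand_id)
  stopifnot(length(fingerprint) == n)
  out <- data.frame(ligand_id = as.character(ligand_id),
                    mol_weight = rep_len(mol_weight, n),
                    n_oxygen = rep_len(n_oxygen, n),
                    n_nitrogen = rep_len(n_nitrogen, n),
                    stringsAsFactors = FALSE)
  out$fingerprint <- lapply(fingerprint, function(f) sort(unique(as.integer(f))))
  out
}

as_ligand_frame <- function(x) {
  need <- c("ligand_id", "mol_weight", "n_oxygen", "n_nitrogen", "fingerprint")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("ligand table is missing column(s): ", paste(miss, collapse = ", "))
  }
  x
}

#' Filter ligands on physicochemical properties
#'
#' Retains ligands with molecular weight below 550 daltons, fewer than 15
#' oxygen atoms and fewer than 15 nitrogen atoms (all strict inequalities).
#' Records with a missing property value are dropped with a warning rather
#' than causing an error.  Input order is preserved.
#'
#' @param ligands ligand record data frame (see [ligand_frame()]).
#' @param max_weight,max_oxygen,max_nitrogen exclusive upper bounds.
#' @return the retained subset of `ligands`.
#' @export
filter_ligands <- function(ligands, max_weight = 550,
                           max_oxygen = 15, max_nitrogen = 15) {
  ligands <- as_ligand_frame(ligands)
  if (nrow(ligands) == 0L) return(ligands)
  props <- ligands[c("mol_weight", "n_oxygen", "n_nitrogen")]
  bad <- !stats::complete.cases(props)
  if (any(bad)) {
    warning(sum(bad), " ligand record(s) with missing properties dropped")
    ligands <- ligands[!bad, , drop = FALSE]
  }
  keep <- ligands$mol_weight < max_weight &
    ligands$n_oxygen < max_oxygen &
    ligands$n_nitrogen < max_nitrogen
  ligands[keep, , drop = FALSE]
}

#' Tanimoto coefficient between two fingerprints
#'
#' Set-overlap similarity: the number of shared features divided by the
#' total number of distinct features in either fingerprint.
#'
#' @param fp_a,fp_b integer vectors of set bit indices.
#' @return a coefficient in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  fp_a <- unique(as.integer(fp_a))
  fp_b <- unique(as.integer(fp_b))
  if (length(fp_a) == 0L && length(fp_b) == 0L) {
    stop("tanimoto of two empty fingerprints is undefined")
  }
  n_int <- length(intersect(fp_a, fp_b))
  n_int / (length(fp_a) + length(fp_b) - n_int)
}

# All cross-pair Tanimoto coefficients between two fingerprint lists,
# computed through a sparse bit matrix so large set pairs stay cheap.
cross_tanimoto <- function(fps_a, fps_b) {
  size_a <- lengths(fps_a)
  size_b <- lengths(fps_b)
  if (any(size_a == 0L) || any(size_b == 0L)) {
    stop("all fingerprints entering scoring must be non-empty")
  }
  bits <- sort(unique(c(unlist(fps_a), unlist(fps_b))))
  ma <- fp_bit_matrix(fps_a, bits)
  mb <- fp_bit_matrix(fps_b, bits)
  inter <- as.matrix(Matrix::tcrossprod(ma, mb))
  union <- outer(size_a, size_b, `+`) - inter
  inter / union
}

fp_bit_matrix <- function(fps, bits) {
  i <- rep.int(seq_along(fps), lengths(fps))
  j <- match(unlist(fps), bits)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(fps), length(bits)))
}

#' Raw ligand-set similarity score
#'
#' The sum of all cross-pair Tanimoto coefficients between the ligands of
#' two targets, restricted to pairs whose coefficient reaches `tc_cutoff`
#' (inclusive).  Every one of the `|A| * |B|` ligand pairs is compared; the
#' comparison count is attached as attribute `n_comparisons`.
#'
#' @param set_a,set_b objects of class `"ligand_set"` (already filtered).
#' @param tc_cutoff Tanimoto cutoff in `(0, 1)`; pairs at or above it
#'   contribute to the sum.
#' @return non-negative numeric score with attribute `n_comparisons`.
#' @export
raw_score <- function(set_a, set_b, tc_cutoff = 0.28) {
  stopifnot(inherits(set_a, "ligand_set"), inherits(set_b, "ligand_set"),
            tc_cutoff > 0, tc_cutoff < 1)
  for (s in list(set_a, set_b)) {
    if (nrow(s$ligands) == 0L) {
      stop("target '", s$target_id, "' has no ligands after filtering")
    }
  }
  tc <- cross_tanimoto(set_a$ligands$fingerprint, set_b$ligands$fingerprint)
  score <- sum(tc[tc >= tc_cutoff])
  structure(score, n_comparisons = length(tc))
}

#' Read a ligand table from TSV
#'
#' Expects a header with columns `target_id`, `ligand_id`, `fingerprint`
#' (comma-separated integer indices), `mol_weight`, `n_oxygen`,
#' `n_nitrogen`.
#'
#' @param path file path.
#' @return named list of [ligand_set()] objects, one per target.
#' @export
read_ligand_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("target_id", "ligand_id", "fingerprint",
            "mol_weight", "n_oxygen", "n_nitrogen")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("ligand TSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  fps <- lapply(strsplit(tab$fingerprint, ","), as.integer)
  lig <- ligand_frame(tab$ligand_id, fps,
                      mol_weight = as.numeric(tab$mol_weight),
                      n_oxygen = as.numeric(tab$n_oxygen),
                      n_nitrogen = as.numeric(tab$n_nitrogen))
  split_idx <- split(seq_len(nrow(lig)), tab$target_id)
  sets <- lapply(names(split_idx), function(t) {
    ligand_set(t, lig[split_idx[[t]], , drop = FALSE])
  })
  names(sets) <- names(split_idx)
  sets
}

#' Write ligand sets to TSV
#'
#' Inverse of [read_ligand_tsv()].
#'
#' @param sets named list of [ligand_set()] objects.
#' @param path file path.
#' @export
write_ligand_tsv <- function(sets, path) {
  rows <- lapply(sets, function(s) {
    data.frame(target_id = s$target_id,
               ligand_id = s$ligands$ligand_id,
               fingerprint = vapply(s$ligands$fingerprint,
                                    function(f) paste(f, collapse = ","),
                                    character(1)),
               mol_weight = s$ligands$mol_weight,
               n_oxygen = s$ligands$n_oxygen,
               n_nitrogen = s$ligands$n_nitrogen,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
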