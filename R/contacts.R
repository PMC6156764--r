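#' Read an atom set from a PDB file
#'
#' Parses a PDB file (via bio3d, tolerant of missing occupancy/B-factor
#' columns) into a plain atom table. HETATM records are excluded by
#' default; optionally only C-alpha atoms are kept.
#'
#' @param path PDB file path.
#' @param het include HETATM records (default FALSE).
#' @param ca_only keep only C-alpha atoms (default FALSE).
#' @param chain optional chain identifier filter.
#' @return data frame with columns `resno`, `resid`, `elety`, `chain`,
#'   `x`, `y`, `z` (angstroms).
#' @export
read_atom_set <- function(path, het = FALSE, ca_only = FALSE, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (!het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (ca_only) at <- at[at$elety == "CA", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  out <- data.frame(resno = at$resno, resid = at$resid, elety = at$elety,
                    chain = at$chain, x = at$x, y = at$y, z = at$z)
  if (!all(is.finite(as.matrix(out[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  out
}

#' Restrict an atom set to a residue interval
#'
#' @param atoms atom table from [read_atom_set()].
#' @param start,end 1-based inclusive residue numbers.
#' @return the atoms with `start <= resno <= end`; errors if the interval
#'   selects no atoms.
#' @export
restrict_residues <- function(atoms, start, end) {
  stopifnot(start <= end)
  out <- atoms[atoms$resno >= start & atoms$resno <= end, , drop = FALSE]
  if (!nrow(out))
    stop(sprintf("residue interval %d-%d selects no atoms", start, end))
  out
}

#' Minimum inter-atomic distance between two atom sets
#'
#' Minimum Euclidean distance (angstroms) over all atom pairs, computed
#' over all atoms of both sets.
#'
#' @param a,b atom tables (columns `x`, `y`, `z`), both non-empty.
#' @return the minimum distance in angstroms.
#' @export
#' @examples
#' a <- data.frame(x = 0, y = 0, z = 0)
#' b <- data.frame(x = 3, y = 4, z = 0)
#' min_distance(a, b)  # 5
min_distance <- function(a, b) {
  if (!nrow(a) || !nrow(b)) stop("atom sets must be non-empty")
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Contact parameters for docking-model clustering
#'
#' @param cutoff contact distance cutoff in angstroms (> 0); default 10.
#' @param reference_start,reference_end residue interval of the receptor
#'   reference motif; default 376-382 (the VDHLFQK stretch at the
#'   N-terminus of the GBP-1 alpha9 helix).
#' @return object of class `contact_params`.
#' @export
contact_params <- function(cutoff = 10, reference_start = 376L,
                           reference_end = 382L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (reference_start > reference_end) stop("invalid reference interval")
  structure(list(cutoff = cutoff,
                 reference_start = as.integer(reference_start),
                 reference_end = as.integer(reference_end)),
            class = "contact_params")
}

#' Per-model minimum distances to a receptor reference motif
#'
#' For every docking model, the minimum atomic distance to the receptor
#' atoms of the reference residue interval.
#'
#' @param models list of atom tables (one docking pose each).
#' @param receptor receptor atom table; the reference interval of
#'   `params` is extracted from it.
#' @param params a [contact_params()].
#' @return data frame `model`, `min_distance`, `contact` (strictly below
#'   the cutoff).
#' @export
model_distances <- function(models, receptor, params = contact_params()) {
  if (!length(models)) stop("no docking models given")
  ref <- restrict_residues(receptor, params$reference_start,
                           params$reference_end)
  d <- vapply(models, function(m) min_distance(m, ref), numeric(1))
  nm <- names(models)
  if (is.null(nm)) nm <- paste0("m", seq_along(models))
  data.frame(model = nm, min_distance = d, contact = d < params$cutoff)
}

#' Count docking models contacting the reference motif
#'
#' Number of models whose minimum atomic distance to the receptor
#' reference residues is strictly below the cutoff.
#'
#' @inheritParams model_distances
#' @return integer count.
#' @export
count_contact_models <- function(models, receptor,
                                 params = contact_params()) {
  sum(model_distances(models, receptor, params)$contact)
}
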