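#' Load a protein(-DNA) structure from a PDB file
#'
#' Thin wrapper around \pkg{bio3d}'s PDB parser keeping only what the
#' distance-feature functions need: one atom table for the first model, with
#' HETATM records retained but flagged. Hydrogens are excluded from all
#' distance computations downstream ("heavy atom" semantics); nucleic-acid
#' chains parse as ordinary residues.
#'
#' @param pdb Path to a PDB file.
#' @return Object of class \code{sge_structure}: \code{data.frame} of atoms
#'   (\code{chain}, \code{resno}, \code{resid}, \code{elety}, \code{x},
#'   \code{y}, \code{z}, \code{het}).
#' @export
load_structure <- function(pdb) {
  p <- bio3d::read.pdb(pdb, multi = FALSE, verbose = FALSE)
  a <- p$atom
  if (nrow(a) == 0L) stop("no ATOM records found", call. = FALSE)
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, resid = a$resid, elety = a$elety,
    x = a$x, y = a$y, z = a$z, het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  structure(list(atoms = atoms), class = "sge_structure")
}

#' @export
print.sge_structure <- function(x, ...) {
  cat(sprintf("<sge_structure> %d atoms, chains: %s\n", nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

heavy_atoms <- function(struct) {
  a <- struct$atoms
  a[!grepl("^[0-9]*H", a$elety), , drop = FALSE]
}

residue_key <- function(chain, resno) paste(chain, resno, sep = ":")

#' Residue-by-residue distance matrix
#'
#' Distances in Angstrom between all residue pairs, either as the minimum
#' over heavy-atom pairs (contact-map semantics, the default) or between
#' C-alpha atoms.
#'
#' @param struct An \code{sge_structure}.
#' @param mode \code{"min_heavy_atom"} or \code{"c_alpha"}.
#' @param chains Optional chain subset.
#' @return Symmetric matrix with zero diagonal; dimnames are
#'   \code{"chain:resno"} keys.
#' @export
residue_distance_matrix <- function(struct,
                                    mode = c("min_heavy_atom", "c_alpha"),
                                    chains = NULL) {
  mode <- match.arg(mode)
  a <- heavy_atoms(struct)
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  if (mode == "c_alpha") {
    a <- a[a$elety == "CA", , drop = FALSE]
  }
  key <- residue_key(a$chain, a$resno)
  res <- unique(key)
  if (length(res) < 2L) stop("need at least two residues", call. = FALSE)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  # all atom-pair distances, then reduce to per-residue-pair minimum
  d_atoms <- as.matrix(stats::dist(xyz))
  idx <- match(key, res)
  n <- length(res)
  out <- matrix(Inf, n, n, dimnames = list(res, res))
  for (i in seq_len(n)) {
    ai <- which(idx == i)
    for (j in i:n) {
      aj <- which(idx == j)
      out[i, j] <- out[j, i] <- min(d_atoms[ai, aj])
    }
  }
  diag(out) <- 0
  out
}

#' Mean distance from one residue to a reference residue set
#'
#' Arithmetic mean of the pairwise residue distances. When the residue is
#' itself a member of the reference set, its zero self-distance is included
#' (deterministic convention, flagged by the \code{self} attribute).
#'
#' @param dmat Distance matrix from \code{\link{residue_distance_matrix}}.
#' @param residue Residue key (\code{"chain:resno"}) or row index.
#' @param reference Vector of residue keys.
#' @return Mean distance in Angstrom.
#' @export
mean_distance_to_set <- function(dmat, residue, reference) {
  missing <- setdiff(as.character(reference), rownames(dmat))
  if (length(missing)) {
    stop("reference residues absent from structure: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- mean(dmat[residue, as.character(reference)])
  attr(d, "self") <- residue %in% as.character(reference)
  d
}

#' Residues at an interaction interface
#'
#' Returns the residues (outside the partner chains) having any heavy atom
#' within \code{cutoff} Angstrom of any heavy atom of the partner chains.
#'
#' @param struct An \code{sge_structure}.
#' @param partner_chains Chains forming the binding partner (e.g. the DNA
#'   duplex).
#' @param cutoff Distance cutoff in Angstrom (inclusive).
#' @param chains Optional restriction of the query side.
#' @return Character vector of residue keys.
#' @export
interface_residues <- function(struct, partner_chains, cutoff = 10,
                               chains = NULL) {
  a <- heavy_atoms(struct)
  part <- a[a$chain %in% partner_chains, , drop = FALSE]
  if (nrow(part) == 0L) stop("partner chains not found", call. = FALSE)
  q <- a[!a$chain %in% partner_chains, , drop = FALSE]
  if (!is.null(chains)) q <- q[q$chain %in% chains, , drop = FALSE]
  if (nrow(q) == 0L) return(character(0))
  qx <- as.matrix(q[, c("x", "y", "z")])
  px <- as.matrix(part[, c("x", "y", "z")])
  # squared distances of every query atom to its nearest partner atom
  min_d2 <- vapply(seq_len(nrow(qx)), function(i) {
    min(colSums((t(px) - qx[i, ])^2))
  }, numeric(1))
  keys <- residue_key(q$chain, q$resno)
  sort(unique(keys[min_d2 <= cutoff^2]))
}

#' Per-residue geometric feature table for a protein-DNA complex
#'
#' Convenience wrapper computing, for every residue of \code{chain}, the mean
#' distance to three reference residue sets on that chain - the DNA-binding
#' surface (TOP), the opposite pole (BOTTOM) and the domain core (CENTER) -
#' plus membership of the interaction interface with the partner chains
#' (any heavy atom within \code{cutoff} Angstrom).
#'
#' @param struct An \code{sge_structure}.
#' @param chain Protein chain to profile.
#' @param top,bottom,center Residue numbers (on \code{chain}) of the three
#'   reference sets; defaults are the p53 DNA-binding-domain anchors
#'   (TOP 248/273/277/280, BOTTOM 153/225/260, CENTER 195/236/253).
#' @param partner_chains Chains of the binding partner for the interface
#'   call (optional).
#' @param cutoff Interface cutoff in Angstrom.
#' @return \code{data.frame}: \code{resno}, \code{top}, \code{bottom},
#'   \code{center}, \code{is_interface}.
#' @export
structure_features <- function(struct, chain,
                               top = c(248, 273, 277, 280),
                               bottom = c(153, 225, 260),
                               center = c(195, 236, 253),
                               partner_chains = NULL, cutoff = 10) {
  dmat <- residue_distance_matrix(struct, chains = chain)
  resnos <- sort(unique(heavy_atoms(struct)$resno[
    heavy_atoms(struct)$chain == chain]))
  keys <- residue_key(chain, resnos)
  ref <- function(set) residue_key(chain, set)
  iface <- if (!is.null(partner_chains)) {
    interface_residues(struct, partner_chains, cutoff, chains = chain)
  } else character(0)
  data.frame(
    resno = resnos,
    top = vapply(keys, function(k)
      as.numeric(mean_distance_to_set(dmat, k, ref(top))), numeric(1)),
    bottom = vapply(keys, function(k)
      as.numeric(mean_distance_to_set(dmat, k, ref(bottom))), numeric(1)),
    center = vapply(keys, function(k)
      as.numeric(mean_distance_to_set(dmat, k, ref(center))), numeric(1)),
    is_interface = keys %in% iface,
    row.names = NULL
  )
}
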