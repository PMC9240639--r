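## Multi-model NMR ensemble coordinate metrics.

#' Read a multi-model structure into an ensemble
#'
#' Parses a (possibly multi-MODEL) PDB file via bio3d and validates that
#' every model carries an identical atom table; heteroatoms (ligands) are
#' retained. Alternate locations are resolved by keeping the first-listed
#' conformer (deposited PDB files list the highest-occupancy altloc first).
#'
#' @param path PDB file
#' @return object of class `nmr_ensemble`: list with `atoms` (the shared
#'   atom table: chain, resno, resid, elety, elesy), `xyz` (n_models x
#'   3 n_atoms coordinate matrix), `n_models`, `n_atoms`
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    # strict cross-model consistency check on the atom identifier columns
    # (name, altloc, resname, chain, resno) before handing off to bio3d
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      stop("unbalanced MODEL/ENDMDL records")
    }
    ids <- lapply(seq_along(model_starts), function(k) {
      blk <- lines[(model_starts[k] + 1):(model_ends[k] - 1)]
      blk <- blk[grepl("^(ATOM  |HETATM)", blk)]
      substr(blk, 13, 27)
    })
    for (k in seq_along(ids)[-1]) {
      if (length(ids[[k]]) != length(ids[[1]]) ||
          !all(ids[[k]] == ids[[1]])) {
        bad <- if (length(ids[[k]]) == length(ids[[1]])) {
          paste(utils::head(trimws(ids[[1]][ids[[k]] != ids[[1]]]), 5),
                collapse = "; ")
        } else {
          sprintf("atom counts differ (%d vs %d)",
                  length(ids[[1]]), length(ids[[k]]))
        }
        stop(sprintf("inconsistent atom tables across models (model %d): %s",
                     k, bad))
      }
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- nrow(pdb$atom)
  structure(list(atoms = pdb$atom, xyz = xyz,
                 n_models = nrow(xyz), n_atoms = n_atoms),
            class = "nmr_ensemble")
}

#' Select atoms of an ensemble
#'
#' Conjunction of simple predicates over the shared atom table. All
#' arguments are optional; the default (`heavy = TRUE` only) selects every
#' non-hydrogen atom.
#'
#' @param ensemble an `nmr_ensemble` from [read_ensemble()]
#' @param chain chain identifier(s)
#' @param resno residue number(s)
#' @param resname residue / ligand name(s), e.g. "SAH"
#' @param atom_names atom name(s), e.g. c("N", "CA", "SD")
#' @param heavy drop hydrogens (default TRUE)
#' @return integer vector of atom indices (1-based into the atom table)
#' @export
select_atoms <- function(ensemble, chain = NULL, resno = NULL, resname = NULL,
                         atom_names = NULL, heavy = TRUE) {
  stopifnot(inherits(ensemble, "nmr_ensemble"))
  at <- ensemble$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(resname)) keep <- keep & trimws(at$resid) %in% resname
  if (!is.null(atom_names)) keep <- keep & trimws(at$elety) %in% atom_names
  if (heavy) {
    elem <- trimws(at$elesy)
    is_h <- elem %in% c("H", "D") |
      (elem == "" & grepl("^[0-9]*[HD]", trimws(at$elety)))
    keep <- keep & !is_h
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    stop("empty selection: chain=", paste(chain, collapse = ","),
         " resno=", paste(resno, collapse = ","),
         " resname=", paste(resname, collapse = ","),
         " atoms=", paste(atom_names, collapse = ","),
         " heavy=", heavy)
  }
  idx
}

#' Heavy-atom names of the two SAH fragments
#'
#' The cofactor product S-adenosyl-L-homocysteine is conventionally split
#' into its amino-acid ("methionine") moiety and its adenosine moiety.
#' The methionine fragment is taken as N, CA, CB, CG, SD, C, O (plus OXT
#' when present); the adenosine fragment is all remaining heavy atoms
#' (ribose and adenine).
#'
#' @param fragment "methionine" or "adenosine"
#' @return character vector of atom names
#' @export
sah_fragment_atoms <- function(fragment = c("methionine", "adenosine")) {
  fragment <- match.arg(fragment)
  if (fragment == "methionine") {
    c("N", "CA", "CB", "CG", "SD", "C", "O", "OXT")
  } else {
    c("C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'",
      "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4")
  }
}

#' Pairwise RMSD over an ensemble
#'
#' RMSD_ab = sqrt(sum_i |x_i^a - x_i^b|^2 / n) over the selected atoms for
#' every unordered model pair; reports the mean and SD over the
#' N(N-1)/2 pairs. Superposition modes: `"none"` uses the coordinates as
#' deposited (NMR families are already aligned on their ordered core),
#' `"selection"` performs a least-squares (Kabsch) fit of each pair on the
#' selection itself before measuring, `"reference"` first superposes every
#' model onto the first model over `ref_selection` (e.g. core CA atoms) and
#' then measures on `selection` without further fitting.
#'
#' @param ensemble an `nmr_ensemble` (>= 2 models)
#' @param selection atom indices from [select_atoms()]
#' @param superpose "none" (default), "selection" or "reference"
#' @param ref_selection atom indices to superpose on when
#'   `superpose = "reference"`
#' @return list with `mean`, `sd` (Angstrom), `pairs` (data.frame a, b,
#'   rmsd), `n_atoms`, `n_models`, `superpose`
#' @export
pairwise_rmsd <- function(ensemble, selection,
                          superpose = c("none", "selection", "reference"),
                          ref_selection = NULL) {
  stopifnot(inherits(ensemble, "nmr_ensemble"))
  superpose <- match.arg(superpose)
  if (length(selection) == 0) stop("empty selection")
  if (ensemble$n_models < 2) stop("pairwise RMSD needs >= 2 models")
  xyz <- ensemble$xyz
  xi <- bio3d::atom2xyz(selection)

  if (superpose == "reference") {
    if (is.null(ref_selection) || length(ref_selection) == 0) {
      stop("superpose = \"reference\" requires ref_selection")
    }
    ri <- bio3d::atom2xyz(ref_selection)
    xyz <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                          fixed.inds = ri, mobile.inds = ri)
  }

  n <- nrow(xyz)
  pairs <- utils::combn(n, 2)
  rms <- apply(pairs, 2, function(p) {
    va <- xyz[p[1], xi]
    vb <- xyz[p[2], xi]
    if (superpose == "selection") {
      vb <- as.vector(bio3d::fit.xyz(fixed = xyz[p[1], ],
                                     mobile = xyz[p[2], , drop = FALSE],
                                     fixed.inds = xi, mobile.inds = xi))[xi]
    }
    sqrt(sum((va - vb)^2) / length(selection))
  })
  list(mean = mean(rms), sd = stats::sd(rms),
       pairs = data.frame(a = pairs[1, ], b = pairs[2, ], rmsd = rms),
       n_atoms = length(selection), n_models = n, superpose = superpose)
}
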