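#' Construct a conformer object
#'
#' A conformer is one member of the ensemble: `m` identical polypeptide
#' chains (aggregation number) with atomic coordinates. Chains must all have
#' the same residue count.
#'
#' @param id character identifier.
#' @param m aggregation number (number of chains).
#' @param subclass free-form subclass label (e.g. "1A", "3B").
#' @param atoms data.frame with columns `chain` (integer 1..m), `resno`
#'   (1-based residue index within the chain), `resname`, `elety` (atom name,
#'   e.g. "CA"), `element` (element symbol) and `x`, `y`, `z` in Angstrom.
#' @return object of class `conformer` with a cached radius of gyration.
#' @export
conformer <- function(id, m, subclass, atoms) {
  stopifnot(is.character(id), length(id) == 1)
  m <- as.integer(m)
  if (is.na(m) || m < 1) stop("conformer '", id, "': m must be a positive integer")
  need <- c("chain", "resno", "resname", "elety", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("conformer '", id, "': atoms must have columns ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("conformer '", id, "': non-finite coordinates")
  }
  chains <- sort(unique(atoms$chain))
  if (length(chains) != m) {
    stop("conformer '", id, "': declared m = ", m, " but found ",
         length(chains), " chains")
  }
  nres <- vapply(chains, function(ch) length(unique(atoms$resno[atoms$chain == ch])),
                 integer(1))
  if (length(unique(nres)) != 1) {
    stop("conformer '", id, "': chains have inconsistent residue counts (",
         paste(nres, collapse = ", "), ")")
  }
  obj <- structure(list(id = id, m = m, subclass = subclass, atoms = atoms,
                        n_res = nres[1]), class = "conformer")
  obj$rg <- radius_of_gyration(obj)
  obj
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer %s>  m = %d (%s), %d residues/chain, %d atoms, Rg = %.2f A\n",
              x$id, x$m, x$subclass, x$n_res, nrow(x$atoms), x$rg))
  invisible(x)
}

#' Assemble an ensemble from conformers
#'
#' Groups conformers into classes by aggregation number m and builds the
#' bidirectional index maps between the global conformer index i and the
#' (class, within-class) pair (m_i, j_i). Classes are sorted by ascending m;
#' the conformer order of the input is preserved.
#'
#' @param conformers list of [conformer()] objects.
#' @return object of class `ensemble` with elements `conformers`, `classes`
#'   (data.frame m, N_m), `class_of` (m_i per conformer), `j_of` (within-class
#'   index), and `members` (list of global indices per class).
#' @export
ensemble <- function(conformers) {
  if (length(conformers) < 1) stop("ensemble must contain ≥ 1 conformer")
  stopifnot(all(vapply(conformers, inherits, logical(1), "conformer")))
  m_i <- vapply(conformers, `[[`, integer(1), "m")
  ms <- sort(unique(m_i))
  members <- lapply(ms, function(m) which(m_i == m))
  names(members) <- as.character(ms)
  j_of <- integer(length(conformers))
  for (k in seq_along(ms)) j_of[members[[k]]] <- seq_along(members[[k]])
  structure(list(
    conformers = conformers,
    classes = data.frame(m = ms, N_m = lengths(members)),
    class_of = m_i,
    j_of = j_of,
    members = members,
    n = length(conformers)
  ), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble>  N = %d conformers, M = %d classes\n", x$n,
              nrow(x$classes)))
  for (k in seq_len(nrow(x$classes))) {
    cat(sprintf("  m = %d : N_m = %d (%.1f%%)\n", x$classes$m[k],
                x$classes$N_m[k], 100 * x$classes$N_m[k] / x$n))
  }
  invisible(x)
}

#' Load a conformer ensemble from a manifest
#'
#' The manifest is a TSV file (or data.frame) with columns `path`, `m`,
#' `subclass`; each `path` is a PDB file containing the `m` chains of that
#' conformer. Non-amino-acid records (waters, ligands) are dropped with a
#' message; the first alternate location is kept; insertion codes are
#' rejected.
#'
#' @param manifest path to a TSV manifest or a data.frame with columns
#'   `path`, `m`, `subclass`.
#' @param base_dir directory against which relative PDB paths are resolved;
#'   defaults to the manifest's directory (or "." for data.frame input).
#' @return an [ensemble()].
#' @export
load_ensemble <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- utils::read.table(manifest, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  need <- c("path", "m", "subclass")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(manifest) < 1) stop("ensemble must contain ≥ 1 conformer")
  confs <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, manifest$path[i])
    id <- tools::file_path_sans_ext(basename(manifest$path[i]))
    if (!file.exists(p)) stop("conformer '", id, "': file not found: ",
                              manifest$path[i])
    atoms <- read_pdb_atoms(p, id)
    conformer(id, manifest$m[i], as.character(manifest$subclass[i]), atoms)
  })
  ensemble(confs)
}

# Parse the ATOM records of one PDB file into the atoms data.frame used by
# conformer(). Chains are renumbered 1..m in order of first appearance.
read_pdb_atoms <- function(path, id) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("conformer '", id,
                                           "': unparseable PDB: ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("conformer '", id, "': no ATOM records")
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("conformer '", id, "': insertion codes are not supported")
  }
  # keep first altloc per (chain, resno, atom name)
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    at <- at[!duplicated(key), , drop = FALSE]
  }
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  drop <- !(at$resid %in% aa3)
  if (any(drop)) {
    message("conformer '", id, "': dropped ", sum(drop),
            " non-amino-acid atom records")
    at <- at[!drop, , drop = FALSE]
  }
  if (nrow(at) == 0) stop("conformer '", id, "': no amino-acid atoms")
  chain_ids <- unique(at$chain)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1)
  }
  data.frame(
    chain = match(at$chain, chain_ids),
    resno = at$resno,
    resname = at$resid,
    elety = at$elety,
    element = toupper(trimws(elem)),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
}

#' Backbone dihedral angles of a conformer
#'
#' Computes phi and psi for residues 2..N_aa-1 of every chain from the N, CA
#' and C backbone atoms (IUPAC sign convention, degrees in (-180, 180]).
#' Residues with missing backbone atoms in themselves or their neighbors get
#' NA angles rather than zeros.
#'
#' @param conf a [conformer()].
#' @return data.frame with columns `chain`, `resno`, `resname`, `phi`, `psi`.
#' @export
compute_dihedrals <- function(conf) {
  stopifnot(inherits(conf, "conformer"))
  out <- list()
  for (ch in seq_len(conf$m)) {
    at <- conf$atoms[conf$atoms$chain == ch, , drop = FALSE]
    resnos <- sort(unique(at$resno))
    if (length(resnos) < 3) {
      stop("conformer '", conf$id, "': chain ", ch,
           " has fewer than 3 residues")
    }
    coord <- function(resno, name) {
      i <- which(at$resno == resno & at$elety == name)
      if (length(i) == 0) return(NULL)
      as.numeric(at[i[1], c("x", "y", "z")])
    }
    n_in <- length(resnos) - 2
    phi <- rep(NA_real_, n_in)
    psi <- rep(NA_real_, n_in)
    rn <- character(n_in)
    for (k in seq_len(n_in)) {
      r <- resnos[k + 1]
      rn[k] <- at$resname[which(at$resno == r)[1]]
      c_prev <- coord(resnos[k], "C")
      n_cur <- coord(r, "N"); ca_cur <- coord(r, "CA"); c_cur <- coord(r, "C")
      n_next <- coord(resnos[k + 2], "N")
      if (!is.null(c_prev) && !is.null(n_cur) && !is.null(ca_cur) &&
          !is.null(c_cur)) {
        phi[k] <- dihedral_angle(c_prev, n_cur, ca_cur, c_cur)
      }
      if (!is.null(n_cur) && !is.null(ca_cur) && !is.null(c_cur) &&
          !is.null(n_next)) {
        psi[k] <- dihedral_angle(n_cur, ca_cur, c_cur, n_next)
      }
    }
    out[[ch]] <- data.frame(chain = ch, resno = resnos[2:(length(resnos) - 1)],
                            resname = rn, phi = phi, psi = psi,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Radius of gyration
#'
#' Unweighted root-mean-square distance of the heavy (non-hydrogen) atoms
#' from their centroid. This quantity is used only for ordering and display,
#' never in the scattering model, so no mass weighting is applied.
#'
#' @param conf a [conformer()] or an n x 3 coordinate matrix.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(conf) {
  if (inherits(conf, "conformer")) {
    at <- conf$atoms[conf$atoms$element != "H", , drop = FALSE]
    xyz <- as.matrix(at[, c("x", "y", "z")])
  } else {
    xyz <- as.matrix(conf)
  }
  if (nrow(xyz) < 2) {
    warning("radius of gyration of a single atom is 0")
    return(0)
  }
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}
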