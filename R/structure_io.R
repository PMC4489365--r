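# Structure and ensemble containers, PDB I/O, superposition, RMSF.

#' Construct a conformation
#'
#' A conformation is an ordered all-atom structure: one row per atom with
#' serial number, atom name, element, 1-based sequential residue index,
#' residue name, chain id and Cartesian coordinates in Angstrom.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `residue_index`, `residue_name`, `chain_id`, `x`, `y`, `z`.
#' @param identifier character label.
#' @return An object of class `conformation`.
#' @export
conformation <- function(atoms, identifier = "structure") {
  req <- c("serial", "name", "element", "residue_index", "residue_name",
           "chain_id", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1L) stop("conformation must contain at least one atom")
  if (anyDuplicated(atoms$serial)) stop("atom serial numbers must be unique")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, identifier = identifier), class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation '%s': %d atoms, %d residues>\n", x$identifier,
              nrow(x$atoms), length(unique(paste(x$atoms$chain_id, x$atoms$residue_index)))))
  invisible(x)
}

coords_matrix <- function(conf) {
  as.matrix(conf$atoms[, c("x", "y", "z")])
}

set_coords <- function(conf, xyz) {
  conf$atoms$x <- xyz[, 1]; conf$atoms$y <- xyz[, 2]; conf$atoms$z <- xyz[, 3]
  conf
}

#' Construct a conformation ensemble
#'
#' Frames share one atom table; coordinates live in an
#' `atoms x 3 x frames` array.
#'
#' @param template a [conformation] providing the shared atom ordering.
#' @param coords numeric array `(n_atoms, 3, n_frames)`.
#' @param weights optional non-negative frame weights summing to 1.
#' @return An object of class `conformation_ensemble`.
#' @export
conformation_ensemble <- function(template, coords, weights = NULL) {
  stopifnot(inherits(template, "conformation"))
  d <- dim(coords)
  if (length(d) != 3L || d[2] != 3L) stop("coords must be (atoms x 3 x frames)")
  if (d[1] != nrow(template$atoms)) stop("coords atom count does not match template")
  if (!is.null(weights)) {
    if (length(weights) != d[3] || any(weights < 0))
      stop("weights must be non-negative, one per frame")
    if (abs(sum(weights) - 1) > 1e-9) stop("frame weights must sum to 1")
  }
  structure(list(template = template, coords = coords, weights = weights),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble '%s': %d frames x %d atoms>\n",
              x$template$identifier, n_frames(x), dim(x$coords)[1]))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a [conformation_ensemble].
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Extract one frame of an ensemble as a conformation
#' @param ensemble a [conformation_ensemble].
#' @param i frame index.
#' @export
get_frame <- function(ensemble, i) {
  stopifnot(i >= 1, i <= n_frames(ensemble))
  conf <- set_coords(ensemble$template, ensemble$coords[, , i])
  conf$identifier <- sprintf("%s/frame%d", ensemble$template$identifier, i)
  conf
}

# ------------------------------------------------------------------
# PDB I/O
# ------------------------------------------------------------------

#' Read a PDB structure
#'
#' Parses a fixed-column PDB file (v3.3) through `bio3d::read.pdb` and
#' returns the selected model as a [conformation].  Residue indices are
#' re-assigned sequentially (1-based, in file order) per chain.
#'
#' @param path PDB file.
#' @param model_index model to extract from a multi-model file (default 1).
#' @return A [conformation].
#' @export
read_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no ATOM/HETATM records in ", path)
  nmod <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > nmod)
    stop("model_index ", model_index, " out of range (file has ", nmod, " models)")
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  # sequential 1-based residue index per chain, file order
  key <- paste(chain, at$resno, at$insert)
  ridx <- integer(nrow(at))
  for (ch in unique(chain)) {
    sel <- which(chain == ch)
    ridx[sel] <- as.integer(factor(key[sel], levels = unique(key[sel])))
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- gsub("[^A-Za-z].*", "", substr(trimws(at$elety), 1, 1))
  atoms <- data.frame(
    serial = seq_len(nrow(at)),
    name = trimws(at$elety),
    element = trimws(ifelse(is.na(elem) | elem == "",
                            substr(trimws(at$elety), 1, 1), elem)),
    residue_index = ridx,
    residue_name = trimws(at$resid),
    chain_id = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE)
  conformation(atoms, identifier = basename(path))
}

#' Read a multi-model PDB file as an ensemble
#' @param path PDB file with MODEL/ENDMDL blocks.
#' @return A [conformation_ensemble].
#' @export
read_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nmod <- nrow(pdb$xyz)
  template <- read_structure(path, model_index = 1L)
  coords <- array(0, c(nrow(template$atoms), 3, nmod))
  for (m in seq_len(nmod))
    coords[, , m] <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  conformation_ensemble(template, coords)
}

format_pdb_atom <- function(serial, name, resname, chain, resno, x, y, z, element) {
  # v3.3 fixed columns; names of up to 3 characters start in column 14
  aname <- ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name))
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, aname, resname, chain, resno, x, y, z, 1, 0, element)
}

#' Write a conformation or ensemble as fixed-column PDB
#'
#' Ensembles are written as MODEL/ENDMDL blocks.  Coordinates are stored to
#' PDB precision (0.001 Angstrom).
#'
#' @param x a [conformation] or [conformation_ensemble].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "conformation")) {
    lines <- c(atom_lines(x$atoms), "END")
  } else if (inherits(x, "conformation_ensemble")) {
    lines <- character(0)
    for (m in seq_len(n_frames(x))) {
      at <- x$template$atoms
      at$x <- x$coords[, 1, m]; at$y <- x$coords[, 2, m]; at$z <- x$coords[, 3, m]
      lines <- c(lines, sprintf("MODEL %8d", m), atom_lines(at), "ENDMDL")
    }
    lines <- c(lines, "END")
  } else stop("x must be a conformation or conformation_ensemble")
  writeLines(lines, path)
  invisible(path)
}

atom_lines <- function(at) {
  format_pdb_atom(at$serial, at$name, at$residue_name, at$chain_id,
                  at$residue_index, at$x, at$y, at$z, at$element)
}

# ------------------------------------------------------------------
# superposition and fluctuations
# ------------------------------------------------------------------

kabsch_rotation <- function(mob, ref) {
  # proper rotation minimising |ref - mob R|; reflections rejected
  s <- svd(crossprod(mob, ref))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Least-squares rigid-body superposition
#'
#' Superposes `mobile` onto `reference` over the atom selection using the
#' closed-form Kabsch (SVD) solution; only proper rotations are allowed.
#'
#' @param mobile,reference [conformation] objects with identical atom counts.
#' @param selection integer atom indices used for the fit (default all).
#' @return list with the fitted `conformation` and the post-fit `rmsd`
#'   (Angstrom) over the selection.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  stopifnot(inherits(mobile, "conformation"), inherits(reference, "conformation"))
  xm <- coords_matrix(mobile); xr <- coords_matrix(reference)
  if (nrow(xm) != nrow(xr)) stop("atom counts differ")
  if (is.null(selection)) selection <- seq_len(nrow(xm))
  if (length(selection) < 3L)
    stop("selection must contain at least 3 atoms (rotation is underdetermined)")
  a <- xm[selection, , drop = FALSE]; b <- xr[selection, , drop = FALSE]
  ca <- colMeans(a); cb <- colMeans(b)
  R <- kabsch_rotation(sweep(a, 2, ca), sweep(b, 2, cb))
  fitted <- sweep(sweep(xm, 2, ca), 2, rep(0, 3)) %*% R
  fitted <- sweep(fitted, 2, cb, `+`)
  rmsd <- sqrt(mean(rowSums((fitted[selection, , drop = FALSE] - b)^2)))
  list(conformation = set_coords(mobile, fitted), rmsd = rmsd)
}

#' Per-residue root mean square fluctuation
#'
#' Iteratively superposes every frame onto the ensemble mean over
#' `fit_selection` (to 1e-6 Angstrom convergence of the mean), then reports
#' the RMSF of each selected atom about its mean position, averaged within
#' residues.
#'
#' @param ensemble a [conformation_ensemble] with at least two frames.
#' @param selection atoms whose fluctuations are reported (default C-alpha).
#' @param fit_selection atoms used for the superposition (default `selection`).
#' @param fit superpose frames before measuring (default TRUE).
#' @return data.frame with `residue_index`, `chain_id`, `rmsf` plus the
#'   per-atom values as attribute `"atom_rmsf"`.
#' @export
compute_rmsf <- function(ensemble, selection = NULL, fit_selection = NULL,
                         fit = TRUE) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  nf <- n_frames(ensemble)
  if (nf < 2L) stop("RMSF requires at least 2 frames")
  at <- ensemble$template$atoms
  if (is.null(selection)) {
    selection <- which(at$name == "CA")
    if (!length(selection)) selection <- seq_len(nrow(at))
  }
  if (is.null(fit_selection)) fit_selection <- selection
  co <- ensemble$coords
  if (fit) {
    mean_xyz <- apply(co, c(1, 2), mean)
    for (iter in 1:50) {
      for (f in seq_len(nf)) {
        a <- co[fit_selection, , f, drop = FALSE][, , 1]
        b <- mean_xyz[fit_selection, , drop = FALSE]
        ca <- colMeans(a); cb <- colMeans(b)
        R <- kabsch_rotation(sweep(a, 2, ca), sweep(b, 2, cb))
        co[, , f] <- sweep(sweep(co[, , f], 2, ca) %*% R, 2, cb, `+`)
      }
      new_mean <- apply(co, c(1, 2), mean)
      if (max(abs(new_mean - mean_xyz)) < 1e-6) { mean_xyz <- new_mean; break }
      mean_xyz <- new_mean
    }
  } else {
    mean_xyz <- apply(co, c(1, 2), mean)
  }
  dev2 <- matrix(0, length(selection), nf)
  for (f in seq_len(nf))
    dev2[, f] <- rowSums((co[selection, , f, drop = FALSE][, , 1] -
                            mean_xyz[selection, , drop = FALSE])^2)
  atom_rmsf <- sqrt(rowMeans(dev2))
  df <- data.frame(residue_index = at$residue_index[selection],
                   chain_id = at$chain_id[selection], rmsf = atom_rmsf)
  out <- aggregate(rmsf ~ residue_index + chain_id, data = df, FUN = mean)
  out <- out[order(out$chain_id, out$residue_index), c("residue_index", "chain_id", "rmsf")]
  rownames(out) <- NULL
  attr(out, "atom_rmsf") <- data.frame(atom = selection, rmsf = atom_rmsf)
  out
}
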