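# Synthetic peptides, jittered frame ensembles with controllable H-bond
# occupancy, paired variant systems, random body-bar graphs, and synthetic
# heat-capacity fitting targets.

.one_to_three <- c(A = "ALA", G = "GLY", S = "SER", P = "PRO")

.fold_phi_psi <- function(template, n) {
  phi <- numeric(n); psi <- numeric(n)
  if (template == "helix") {
    phi[] <- -57; psi[] <- -47
  } else if (template == "coil") {
    phi[] <- -120; psi[] <- 140
  } else if (template == "hairpin") {
    phi[] <- -119; psi[] <- 113
    t1 <- floor(n / 2); t2 <- t1 + 1
    phi[t1] <- -60; psi[t1] <- -30
    phi[t2] <- -90; psi[t2] <- 0
  } else if (template == "mixed") {
    # helix - loop - helix; the loop is the editable cross-linking region
    h1 <- max(5L, floor(0.4 * n)); loop <- max(3L, floor(0.2 * n))
    phi[] <- -57; psi[] <- -47
    phi[(h1 + 1):(h1 + loop)] <- -120
    psi[(h1 + 1):(h1 + loop)] <- 140
  } else stop("unknown fold template: ", template)
  list(phi = phi, psi = psi)
}

#' Specification of a synthetic peptide system
#'
#' @param sequence one-letter amino-acid string (supported: A, G, S, P);
#'   at least 5 residues.
#' @param fold_template one of "helix" (phi/psi -57/-47), "hairpin"
#'   (strands -119/113 with a canonical turn), "coil" (extended, no
#'   backbone H-bonds) or "mixed" (helix-loop-helix).
#' @param jitter_sigma isotropic Gaussian coordinate jitter per atom within
#'   a conformational substate (Angstrom).
#' @param n_frames ensemble size.
#' @param n_centers number of conformational substates (cluster centres);
#'   frames scatter around centres, emulating the cluster structure of a
#'   molecular-dynamics ensemble.  With `n_centers = 1` frames are pure
#'   i.i.d. jitter around the base conformation.
#' @param center_sigma isotropic Gaussian displacement of the substate
#'   centres from the base conformation (Angstrom).
#' @param center_decay geometric decay of substate occupancies (occupancy
#'   of centre k proportional to `center_decay^k`); the default gives the
#'   ten largest clusters over 90 percent of the frames.
#' @param hbond_edits list of edits, each
#'   `list(op = "add"|"remove", donor_residue =, acceptor_residue =,
#'   propensity =)`; donors use the backbone amide, acceptors the backbone
#'   carbonyl oxygen.
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_system_spec`.
#' @export
synthetic_system_spec <- function(sequence, fold_template = "helix",
                                  jitter_sigma = 0.08, n_frames = 300L,
                                  n_centers = 20L, center_sigma = 0.12,
                                  center_decay = 0.75,
                                  hbond_edits = list(), seed = 1L) {
  letters1 <- strsplit(sequence, "")[[1]]
  if (length(letters1) < 5L) stop("sequence must have at least 5 residues")
  bad <- setdiff(letters1, names(.one_to_three))
  if (length(bad)) stop("unsupported residue letter(s): ", paste(bad, collapse = ", "))
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  for (e in hbond_edits) {
    stopifnot(e$op %in% c("add", "remove"),
              e$propensity >= 0, e$propensity <= 1)
  }
  stopifnot(n_centers >= 1, center_sigma >= 0, center_decay > 0, center_decay <= 1)
  structure(list(sequence = sequence, fold_template = fold_template,
                 jitter_sigma = jitter_sigma, n_frames = as.integer(n_frames),
                 n_centers = as.integer(n_centers), center_sigma = center_sigma,
                 center_decay = center_decay,
                 hbond_edits = hbond_edits, seed = as.integer(seed)),
            class = "synthetic_system_spec")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# natural extension of reference frame: new atom bonded to c with
# angle(b, c, x) and dihedral(a, b, c, x)
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m2 <- cross3(n, bc)
  d <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + bc * d[1] + m2 * d[2] + n * d[3]
}

#' Build an idealized all-atom peptide
#'
#' Constructs the peptide from internal coordinates (standard bond lengths
#' and angles, template phi/psi, trans peptide bonds) with amide and
#' hydroxyl hydrogens placed; deterministic given the spec.
#'
#' @param spec a [synthetic_system_spec].
#' @return A [conformation].
#' @export
build_peptide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_system_spec"))
  seq1 <- strsplit(spec$sequence, "")[[1]]
  n <- length(seq1)
  tp <- .fold_phi_psi(spec$fold_template, n)
  res3 <- .one_to_three[seq1]

  atoms <- list()
  pos <- list()  # named per-residue coordinate store
  add_atom <- function(ri, name, element, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      serial = length(atoms) + 1L, name = name, element = element,
      residue_index = ri, residue_name = res3[[ri]], chain_id = "A",
      x = xyz[1], y = xyz[2], z = xyz[3])
    pos[[paste(ri, name)]] <<- xyz
  }
  p <- function(ri, name) pos[[paste(ri, name)]]

  for (i in seq_len(n)) {
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- c(1.458, 0, 0)
      th <- (180 - 111.2) * pi / 180
      C <- CA + 1.525 * c(cos(th), sin(th), 0)
    } else {
      N <- place_atom(p(i - 1, "N"), p(i - 1, "CA"), p(i - 1, "C"),
                      1.329, 116.2, tp$psi[i - 1])
      CA <- place_atom(p(i - 1, "CA"), p(i - 1, "C"), N, 1.458, 121.7, 180)
      C <- place_atom(p(i - 1, "C"), N, CA, 1.525, 111.2, tp$phi[i])
    }
    add_atom(i, "N", "N", N)
    if (res3[[i]] != "PRO") {
      H <- if (i == 1L) place_atom(C, CA, N, 1.01, 114, 180)
           else place_atom(p(i - 1, "CA"), p(i - 1, "C"), N, 1.01, 119, 0)
      add_atom(i, "H", "H", H)
    }
    add_atom(i, "CA", "C", CA)
    add_atom(i, "C", "C", C)
    O <- place_atom(N, CA, C, 1.231, 120.8, tp$psi[i] + 180)
    add_atom(i, "O", "O", O)
    if (res3[[i]] %in% c("ALA", "SER", "PRO")) {
      CB <- place_atom(N, C, CA, 1.521, 110.4, -122.6)
      add_atom(i, "CB", "C", CB)
      if (res3[[i]] == "SER") {
        OG <- place_atom(N, CA, CB, 1.417, 110.8, -65)
        add_atom(i, "OG", "O", OG)
        add_atom(i, "HG", "H", place_atom(CA, CB, OG, 0.96, 109.5, 180))
      }
      if (res3[[i]] == "PRO") {
        CG <- place_atom(N, CA, CB, 1.515, 104.5, 30)
        add_atom(i, "CG", "C", CG)
        add_atom(i, "CD", "C", place_atom(CA, CB, CG, 1.510, 106.0, -35))
      }
    }
    if (i == n) add_atom(i, "OXT", "O",
                         place_atom(N, CA, C, 1.25, 117, tp$psi[i]))
  }
  conformation(do.call(rbind, atoms),
               identifier = sprintf("%s-%s", spec$fold_template, spec$sequence))
}

resolve_edit_atoms <- function(conf, edit) {
  at <- conf$atoms
  don <- which(at$residue_index == edit$donor_residue & at$name == "N")
  hyd <- which(at$residue_index == edit$donor_residue & at$name == "H")
  acc <- which(at$residue_index == edit$acceptor_residue & at$name == "O")
  if (length(don) != 1L || length(hyd) != 1L || length(acc) != 1L)
    stop("cannot resolve edit atoms for residues ", edit$donor_residue,
         " -> ", edit$acceptor_residue)
  c(donor = don, hydrogen = hyd, acceptor = acc)
}

#' Generate a jittered ensemble with controllable H-bond occupancy
#'
#' Frames are the base conformation plus isotropic Gaussian jitter.  Each
#' H-bond edit then fixes the geometry of its donor/acceptor pair in exactly
#' `round(propensity * n_frames)` randomly chosen frames ("add": the
#' acceptor oxygen is placed at ideal geometry along the donor N-H vector;
#' "remove": in the remaining frames the acceptor is displaced out of range),
#' so the detected propensity matches its target.
#'
#' @param base a [conformation]; typically [build_peptide()] output.
#' @param spec a [synthetic_system_spec] (jitter, frame count, edits, seed).
#' @return A [conformation_ensemble] with attribute `"ground_truth"`
#'   recording the applied edits.
#' @export
perturb_ensemble <- function(base, spec) {
  stopifnot(inherits(base, "conformation"), inherits(spec, "synthetic_system_spec"))
  if (spec$n_frames < 2L) stop("n_frames must be >= 2")
  set.seed(spec$seed)
  na <- nrow(base$atoms)
  xyz0 <- coords_matrix(base)
  # conformational substates: centres displaced from the base structure,
  # occupancies decaying geometrically (cluster-size skew of MD ensembles)
  K <- spec$n_centers
  centers <- vector("list", K)
  centers[[1]] <- if (K == 1) xyz0 else
    xyz0 + matrix(rnorm(3 * na, sd = spec$center_sigma), na, 3)
  if (K > 1)
    for (k in 2:K)
      centers[[k]] <- xyz0 + matrix(rnorm(3 * na, sd = spec$center_sigma), na, 3)
  pk <- spec$center_decay^(seq_len(K))
  assign_k <- sample.int(K, spec$n_frames, replace = TRUE, prob = pk / sum(pk))
  coords <- array(0, c(na, 3, spec$n_frames))
  for (f in seq_len(spec$n_frames))
    coords[, , f] <- centers[[assign_k[f]]] +
      matrix(rnorm(3 * na, sd = spec$jitter_sigma), na, 3)
  truth <- list()
  for (e in spec$hbond_edits) {
    idx <- resolve_edit_atoms(base, e)
    n_on <- round(e$propensity * spec$n_frames)
    on <- sample.int(spec$n_frames, n_on)
    for (f in seq_len(spec$n_frames)) {
      d <- coords[idx["donor"], , f]; h <- coords[idx["hydrogen"], , f]
      u <- h - d; u <- u / sqrt(sum(u^2))
      if (f %in% on) {
        # exact linear N-H...O geometry (N-H 1.01 A, H...O 2.1 A,
        # backbone-like bond strength)
        coords[idx["hydrogen"], , f] <- d + 1.01 * u
        coords[idx["acceptor"], , f] <- d + (1.01 + 2.1) * u
      } else if (e$op == "remove") {
        coords[idx["acceptor"], , f] <- d + 6.5 * u
      }
    }
    truth[[length(truth) + 1L]] <- c(as.list(e), list(
      donor_atom = unname(idx["donor"]), hydrogen_atom = unname(idx["hydrogen"]),
      acceptor_atom = unname(idx["acceptor"]), frames_on = n_on))
  }
  ens <- conformation_ensemble(base, coords)
  attr(ens, "ground_truth") <- truth
  ens
}

#' Generate a paired (wild-type, variant) system
#'
#' System A is the base spec; system B applies the H-bond edit list.  The
#' two ensembles use distinct seeds.  This emulates a germline /
#' affinity-matured pair differing by a prescribed set of H-bond network
#' changes.
#'
#' @param spec a [synthetic_system_spec] for the base system.
#' @param edits H-bond edit list applied to system B (see
#'   [synthetic_system_spec()]).
#' @return list with `A`, `B` ([conformation_ensemble]s) and `edits`
#'   (ground truth).
#' @export
make_variant_pair <- function(spec, edits) {
  base <- build_peptide(spec)
  spec_b <- spec
  spec_b$hbond_edits <- c(spec$hbond_edits, edits)
  spec_b$seed <- spec$seed + 1L
  A <- perturb_ensemble(base, spec)
  B <- perturb_ensemble(base, spec_b)
  list(A = A, B = B, edits = attr(B, "ground_truth"))
}

#' Random connected body-bar multigraph
#'
#' Spanning tree first (tree edges carry `tree_multiplicity` bars), then
#' `n_bars` extra bars with uniform endpoints and multiplicities.  Used as
#' fixtures for the pebble-game / rigidity-matrix oracle equivalence.
#'
#' @param n_vertices number of bodies.
#' @param n_bars number of extra bars beyond the spanning tree.
#' @param multiplicity_range integer range for extra-bar multiplicities.
#' @param seed RNG seed.
#' @param tree_multiplicity bars per spanning-tree edge (default 6).
#' @return list of class `bodybar_graph` with `n_vertices` and expanded
#'   per-bar vectors `u`, `v`.
#' @export
random_bodybar_graph <- function(n_vertices, n_bars = 0L,
                                 multiplicity_range = c(1L, 6L), seed = 1L,
                                 tree_multiplicity = 6L) {
  stopifnot(n_vertices >= 1)
  set.seed(seed)
  u <- integer(0); v <- integer(0)
  if (n_vertices >= 2) {
    for (k in 2:n_vertices) {
      parent <- if (k == 2) 1L else sample.int(k - 1L, 1L)
      u <- c(u, rep(parent, tree_multiplicity))
      v <- c(v, rep(k, tree_multiplicity))
    }
  }
  for (b in seq_len(n_bars)) {
    pair <- sample.int(n_vertices, 2L)
    m <- sample(seq(multiplicity_range[1], multiplicity_range[2]), 1L)
    u <- c(u, rep(pair[1], m)); v <- c(v, rep(pair[2], m))
  }
  structure(list(n_vertices = n_vertices, u = u, v = v),
            class = "bodybar_graph")
}

#' Synthetic single-peak heat-capacity target
#'
#' Gaussian peak centred exactly at `T_m`, used as a fitting target for
#' [fit_parameters()].
#'
#' @param T_m peak temperature (K).
#' @param width Gaussian width (K).
#' @param n_points grid size over `T_m +/- 4 width`.
#' @return list of class `heat_capacity_curve` with `T`, `Cp`, `T_m`.
#' @export
synthetic_cp_target <- function(T_m, width = 12, n_points = 121L) {
  stopifnot(width > 0)
  Tg <- seq(T_m - 4 * width, T_m + 4 * width, length.out = n_points)
  structure(list(T = Tg, Cp = exp(-(Tg - T_m)^2 / (2 * width^2)), T_m = T_m),
            class = "heat_capacity_curve")
}
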