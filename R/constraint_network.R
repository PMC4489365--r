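# Constraint inventory: covalent topology, hydrogen bonds, torsion sites,
# and assembly of body-bar frameworks.
#
# Conventions (body-bar): atoms are rigid bodies; a non-rotatable covalent
# bond contributes 6 bars, a rotatable one 5 bars (leaving the dihedral
# degree of freedom), each hydrogen bond contributes 5 bars between the
# donor hydrogen and the acceptor, and each torsion constraint is one bar
# between the two outer atoms of the dihedral.

# Residue templates (polar hydrogens only).  Bonds are non-rotatable when
# they are part of the rigid peptide unit, a ring, or end in a terminal atom.
.residue_templates <- list(
  GLY = list(
    atoms = data.frame(name = c("N", "H", "CA", "C", "O"),
                       element = c("N", "H", "C", "C", "O")),
    bonds = data.frame(a = c("N", "N", "CA", "C"),
                       b = c("H", "CA", "C", "O"),
                       rotatable = c(FALSE, TRUE, TRUE, FALSE))),
  ALA = list(
    atoms = data.frame(name = c("N", "H", "CA", "C", "O", "CB"),
                       element = c("N", "H", "C", "C", "O", "C")),
    bonds = data.frame(a = c("N", "N", "CA", "C", "CA"),
                       b = c("H", "CA", "C", "O", "CB"),
                       rotatable = c(FALSE, TRUE, TRUE, FALSE, FALSE))),
  SER = list(
    atoms = data.frame(name = c("N", "H", "CA", "C", "O", "CB", "OG", "HG"),
                       element = c("N", "H", "C", "C", "O", "C", "O", "H")),
    bonds = data.frame(a = c("N", "N", "CA", "C", "CA", "CB", "OG"),
                       b = c("H", "CA", "C", "O", "CB", "OG", "HG"),
                       rotatable = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))),
  PRO = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "CD"),
                       element = c("N", "C", "C", "O", "C", "C", "C")),
    bonds = data.frame(a = c("N", "CA", "C", "CA", "CB", "CG", "CD"),
                       b = c("CA", "C", "O", "CB", "CG", "CD", "N"),
                       rotatable = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)))
)

#' Detect the covalent bond topology of a conformation
#'
#' Bonds come from per-residue templates (20 standard amino acids are not all
#' required; the generator emits GLY/ALA/SER/PRO) plus inter-residue peptide
#' bonds.  Rotatability follows chemistry: sp3-sp3 single bonds rotate;
#' peptide bonds, ring bonds and bonds to terminal atoms do not.  Proline
#' has no rotatable N-CA bond, so it carries no phi torsion.
#'
#' @param conformation a [conformation].
#' @return data.frame with atom indices `i`, `j`, logical `rotatable` and
#'   `bar_count` (5 if rotatable else 6).
#' @export
detect_covalent_topology <- function(conformation) {
  at <- conformation$atoms
  unknown <- setdiff(unique(at$residue_name), names(.residue_templates))
  if (length(unknown))
    stop("unknown residue name(s): ", paste(unknown, collapse = ", "))
  res_key <- paste(at$chain_id, at$residue_index)
  out <- list()
  for (rk in unique(res_key)) {
    rows <- which(res_key == rk)
    tmpl <- .residue_templates[[at$residue_name[rows[1]]]]
    idx <- setNames(rows[match(tmpl$atoms$name, at$name[rows])], tmpl$atoms$name)
    for (b in seq_len(nrow(tmpl$bonds))) {
      ia <- idx[[tmpl$bonds$a[b]]]; ib <- idx[[tmpl$bonds$b[b]]]
      if (!is.na(ia) && !is.na(ib))
        out[[length(out) + 1L]] <- c(ia, ib, tmpl$bonds$rotatable[b])
    }
    # C-terminal carboxylate
    ioxt <- rows[match("OXT", at$name[rows])]
    if (!is.na(ioxt) && !is.na(idx[["C"]]))
      out[[length(out) + 1L]] <- c(idx[["C"]], ioxt, FALSE)
  }
  # peptide bonds between consecutive residues of the same chain
  for (ch in unique(at$chain_id)) {
    rs <- sort(unique(at$residue_index[at$chain_id == ch]))
    for (k in seq_along(rs)[-1]) {
      if (rs[k] != rs[k - 1] + 1L) next  # chain gap: no bond
      ic <- which(at$chain_id == ch & at$residue_index == rs[k - 1] & at$name == "C")
      inn <- which(at$chain_id == ch & at$residue_index == rs[k] & at$name == "N")
      if (length(ic) == 1L && length(inn) == 1L)
        out[[length(out) + 1L]] <- c(ic, inn, FALSE)
    }
  }
  m <- do.call(rbind, out)
  df <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                   rotatable = as.logical(m[, 3]))
  df$bar_count <- ifelse(df$rotatable, 5L, 6L)
  df
}

#' Hydrogen-bond detection criteria
#'
#' Geometric gates plus a Mayo-style distance/angular energy.  A candidate
#' donor(-H)/acceptor pair is accepted when H...A <= `r_ha_max`,
#' D...A <= `r_da_max`, the D-H...A angle >= `theta_min` degrees, and the
#' energy `v0 * (5 (r0/R)^12 - 6 (r0/R)^10) cos^2(theta)` (R = donor-acceptor
#' distance) is at most `e_cutoff` kcal/mol.
#'
#' @param r_ha_max,r_da_max distance gates (Angstrom).
#' @param theta_min D-H...A angle gate (degrees).
#' @param e_cutoff energy cutoff (kcal/mol, negative = favourable).
#' @param v0 well depth scale (kcal/mol).
#' @param r0 equilibrium donor-acceptor distance (Angstrom).
#' @return list of criteria.
#' @export
hbond_criteria <- function(r_ha_max = 2.6, r_da_max = 3.6, theta_min = 100,
                           e_cutoff = -0.1, v0 = 8, r0 = 2.8) {
  list(r_ha_max = r_ha_max, r_da_max = r_da_max, theta_min = theta_min,
       e_cutoff = e_cutoff, v0 = v0, r0 = r0)
}

# donors/acceptors/exclusions derived from topology; computed once per
# atom table and reused across ensemble frames
hbond_candidates <- function(conformation) {
  at <- conformation$atoms
  bonds <- tryCatch(detect_covalent_topology(conformation), error = function(e) NULL)
  xyz <- coords_matrix(conformation)
  if (is.null(bonds)) {
    # unknown residues: infer bonds from distances (covalent radii)
    n <- nrow(at)
    cand <- which(as.matrix(stats::dist(xyz)) < 1.9, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keep <- !(at$element[cand[, 1]] == "H" & at$element[cand[, 2]] == "H")
    hpair <- at$element[cand[, 1]] == "H" | at$element[cand[, 2]] == "H"
    d <- sqrt(rowSums((xyz[cand[, 1], , drop = FALSE] - xyz[cand[, 2], , drop = FALSE])^2))
    keep <- keep & (!hpair | d < 1.25)
    bonds <- data.frame(i = cand[keep, 1], j = cand[keep, 2])
  }
  n <- nrow(at)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  donors <- list()
  for (a in which(at$element %in% c("N", "O"))) {
    hs <- adj[[a]][at$element[adj[[a]]] == "H"]
    for (h in hs) donors[[length(donors) + 1L]] <- c(a, h)
  }
  donors <- if (length(donors)) do.call(rbind, donors) else matrix(0L, 0, 2)
  acceptors <- which(at$element == "O")
  # exclude pairs closer than 4 covalent bonds
  excl <- vector("list", n)
  for (d in unique(donors[, 1])) {
    seen <- d; frontier <- d
    for (depth in 1:3) {
      frontier <- setdiff(unlist(adj[frontier]), seen)
      seen <- c(seen, frontier)
    }
    excl[[d]] <- seen
  }
  list(donors = donors, acceptors = acceptors, excl = excl, atoms = at)
}

mayo_energy <- function(r_da, cos_theta, criteria) {
  x <- criteria$r0 / r_da
  criteria$v0 * (5 * x^12 - 6 * x^10) * cos_theta^2
}

hbonds_from_coords <- function(xyz, cand, criteria) {
  at <- cand$atoms
  out <- list()
  for (k in seq_len(nrow(cand$donors))) {
    d <- cand$donors[k, 1]; h <- cand$donors[k, 2]
    acc <- setdiff(cand$acceptors, c(cand$excl[[d]], d, h))
    if (!length(acc)) next
    va <- xyz[acc, , drop = FALSE]
    r_da <- sqrt(rowSums(sweep(va, 2, xyz[d, ])^2))
    r_ha <- sqrt(rowSums(sweep(va, 2, xyz[h, ])^2))
    ok <- r_da <= criteria$r_da_max & r_ha <= criteria$r_ha_max
    if (!any(ok)) next
    acc <- acc[ok]; r_da <- r_da[ok]; r_ha <- r_ha[ok]
    hd <- xyz[d, ] - xyz[h, ]
    ha <- sweep(xyz[acc, , drop = FALSE], 2, xyz[h, ])
    cos_dha <- (ha %*% hd) /
      (sqrt(rowSums(ha^2)) * sqrt(sum(hd^2)))
    theta <- acos(pmin(1, pmax(-1, cos_dha))) * 180 / pi
    ok2 <- theta >= criteria$theta_min
    if (!any(ok2)) next
    acc <- acc[ok2]; r_da <- r_da[ok2]; theta <- theta[ok2]
    e <- mayo_energy(r_da, cos(theta * pi / 180), criteria)
    ok3 <- e <= criteria$e_cutoff
    if (!any(ok3)) next
    for (m in which(ok3)) {
      a <- acc[m]
      sb <- at$name[d] %in% c("NH1", "NH2", "NE", "NZ", "ND1", "NE2") &&
        at$residue_name[d] %in% c("ARG", "LYS", "HIS") &&
        at$name[a] %in% c("OD1", "OD2", "OE1", "OE2") &&
        at$residue_name[a] %in% c("ASP", "GLU")
      out[[length(out) + 1L]] <- data.frame(
        donor = d, hydrogen = h, acceptor = a, energy = e[m],
        is_salt_bridge = sb,
        donor_residue = at$residue_index[d], acceptor_residue = at$residue_index[a])
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), energy = numeric(0),
                      is_salt_bridge = logical(0), donor_residue = integer(0),
                      acceptor_residue = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$donor, res$acceptor), , drop = FALSE]
}

#' Detect hydrogen bonds and salt bridges
#'
#' Scores donor(-H)/acceptor pairs with the Mayo-style potential described
#' in [hbond_criteria()].  Salt bridges (charged donor/acceptor side-chain
#' groups) are flagged as a special case of hydrogen bonds.
#'
#' @param conformation a [conformation] with polar hydrogens present.
#' @param criteria see [hbond_criteria()].
#' @return data.frame with `donor`, `hydrogen`, `acceptor` atom indices,
#'   `energy` (kcal/mol), `is_salt_bridge`, and donor/acceptor residue indices.
#' @export
detect_hbonds <- function(conformation, criteria = hbond_criteria()) {
  cand <- hbond_candidates(conformation)
  if (nrow(cand$donors) == 0L) {
    warning("no donors with attached hydrogens; returning empty result")
    return(hbonds_from_coords(coords_matrix(conformation), cand, criteria))
  }
  hbonds_from_coords(coords_matrix(conformation), cand, criteria)
}

#' Enumerate torsion constraint sites
#'
#' One site per rotatable covalent bond that has heavy atoms on both outer
#' positions of the dihedral.  Backbone sites are labelled phi (N-CA) and
#' psi (CA-C); prolines contribute no phi site.
#'
#' @param bonds covalent topology from [detect_covalent_topology()].
#' @param conformation the [conformation] the bonds refer to.
#' @return data.frame with outer/central atom indices `a`, `u`, `v`, `d`,
#'   `backbone_kind` (phi/psi/sidechain), `residue_index`, `chain_id`.
#' @export
enumerate_torsion_sites <- function(bonds, conformation) {
  at <- conformation$atoms
  n <- nrow(at)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  heavy <- at$element != "H"
  out <- list()
  for (k in which(bonds$rotatable)) {
    u <- bonds$i[k]; v <- bonds$j[k]
    a <- sort(setdiff(adj[[u]][heavy[adj[[u]]]], v))
    d <- sort(setdiff(adj[[v]][heavy[adj[[v]]]], u))
    if (!length(a) || !length(d)) next
    a <- a[1]; d <- d[1]
    kind <- "sidechain"
    if (at$name[u] == "N" && at$name[v] == "CA") kind <- "phi"
    if (at$name[u] == "CA" && at$name[v] == "C") kind <- "psi"
    out[[length(out) + 1L]] <- data.frame(
      a = a, u = u, v = v, d = d, backbone_kind = kind,
      residue_index = at$residue_index[u], chain_id = at$chain_id[u])
  }
  if (!length(out))
    return(data.frame(a = integer(0), u = integer(0), v = integer(0),
                      d = integer(0), backbone_kind = character(0),
                      residue_index = integer(0), chain_id = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Component entropy of a hydrogen bond
#'
#' Affine map of bond energy onto `[0, gamma_max]`: the strongest bond
#' (`e_min`) gets 0, bonds at the detection cutoff get `gamma_max`; weaker
#' bonds never exceed `gamma_max`.  Monotonically non-decreasing in energy.
#'
#' @param energy H-bond energies (kcal/mol).
#' @param gamma_max upper bound of the map (pure number).
#' @param e_min,e_cutoff energy anchors (kcal/mol).
#' @export
component_entropy_gamma <- function(energy, gamma_max = 2.0, e_min = -8,
                                    e_cutoff = -0.1) {
  g <- gamma_max * (energy - e_min) / (e_cutoff - e_min)
  pmin(gamma_max, pmax(0, g))
}

#' Build the full constraint inventory of a conformation
#'
#' Convenience bundle consumed by the rigidity engine and the macrostate
#' sampler: covalent bars, candidate H-bonds with component entropies, and
#' torsion sites.
#'
#' @param conformation a [conformation].
#' @param criteria H-bond criteria, see [hbond_criteria()].
#' @param params DCM parameters, see [dcm_parameters()].
#' @return An object of class `constraint_inventory`.
#' @export
constraint_inventory <- function(conformation, criteria = hbond_criteria(),
                                 params = dcm_parameters()) {
  bonds <- detect_covalent_topology(conformation)
  hb <- detect_hbonds(conformation, criteria)
  hb$gamma <- component_entropy_gamma(hb$energy, params$gamma_max,
                                      params$gamma_e_min, criteria$e_cutoff)
  sites <- enumerate_torsion_sites(bonds, conformation)
  cov_bars <- bonds[rep(seq_len(nrow(bonds)), bonds$bar_count), c("i", "j")]
  structure(list(
    conformation = conformation,
    V = nrow(conformation$atoms),
    bonds = bonds,
    cov_bars = as.matrix(cov_bars),
    cov_pairs = cbind(bonds$i, bonds$j, as.integer(bonds$rotatable)),
    sites = sites,
    hbonds = hb,
    criteria = criteria,
    params = params), class = "constraint_inventory")
}

#' @export
print.constraint_inventory <- function(x, ...) {
  cat(sprintf("<constraint inventory: %d atoms, %d bonds, %d H-bonds, %d torsion sites>\n",
              x$V, nrow(x$bonds), nrow(x$hbonds), nrow(x$sites)))
  invisible(x)
}

#' Assemble a body-bar framework for a chosen constraint topology
#'
#' Emits covalent bars (6 per non-rotatable bond, 5 per rotatable), 5 bars
#' per present H-bond (between hydrogen and acceptor), and one torsion bar
#' per site between the outer dihedral atoms -- component entropy
#' `delta_nat` for sites in `native_subset`, `delta_dis` otherwise.  The
#' preferential order sorts bars by ascending component entropy (covalent
#' bars first at entropy 0), ties broken by inventory position.
#'
#' @param inventory a [constraint_inventory].
#' @param hbond_subset integer indices into `inventory$hbonds` (present bonds).
#' @param native_subset integer indices into `inventory$sites` (native torsions).
#' @param params see [dcm_parameters()].
#' @return An object of class `bodybar_framework` with `n_vertices`, a per-bar
#'   table `bars` (`u`, `v`, `kind`, `owner`, `entropy`) and
#'   `preferential_order`.
#' @export
build_framework <- function(inventory, hbond_subset = integer(0),
                            native_subset = integer(0),
                            params = inventory$params) {
  stopifnot(inherits(inventory, "constraint_inventory"))
  if (length(hbond_subset) && (min(hbond_subset) < 1 ||
                               max(hbond_subset) > nrow(inventory$hbonds)))
    stop("hbond_subset outside the candidate inventory")
  if (length(native_subset) && (min(native_subset) < 1 ||
                                max(native_subset) > nrow(inventory$sites)))
    stop("native_subset outside the torsion-site inventory")
  delta_dis <- params$delta_nat + params$delta_dis_offset
  cov <- data.frame(u = inventory$cov_bars[, 1], v = inventory$cov_bars[, 2],
                    kind = "covalent",
                    owner = rep(seq_len(nrow(inventory$bonds)),
                                inventory$bonds$bar_count),
                    entropy = 0)
  s <- inventory$sites
  tor <- data.frame(u = s$a, v = s$d, kind = "torsion", owner = seq_len(nrow(s)),
                    entropy = ifelse(seq_len(nrow(s)) %in% native_subset,
                                     params$delta_nat, delta_dis))
  hb <- inventory$hbonds[hbond_subset, , drop = FALSE]
  hbb <- if (nrow(hb)) {
    data.frame(u = rep(hb$hydrogen, each = 5), v = rep(hb$acceptor, each = 5),
               kind = "hbond", owner = rep(hbond_subset, each = 5),
               entropy = rep(hb$gamma, each = 5))
  } else NULL
  bars <- rbind(cov, tor, hbb)
  rownames(bars) <- NULL
  structure(list(
    n_vertices = inventory$V,
    bars = bars,
    preferential_order = order(bars$entropy, seq_len(nrow(bars))),
    inventory = inventory,
    hbond_subset = sort(hbond_subset),
    native_subset = sort(native_subset),
    params = params), class = "bodybar_framework")
}

#' @export
print.bodybar_framework <- function(x, ...) {
  cat(sprintf("<body-bar framework: %d bodies, %d bars (%d covalent, %d torsion, %d H-bond)>\n",
              x$n_vertices, nrow(x$bars), sum(x$bars$kind == "covalent"),
              sum(x$bars$kind == "torsion"), sum(x$bars$kind == "hbond")))
  invisible(x)
}

#' Hydrogen-bond propensity over an ensemble
#'
#' Propensity of a donor-acceptor pair is the fraction of frames in which
#' [detect_hbonds()] reports it (1 when present in every frame, 0.5 when
#' present in half).  The residue-level value is the sum of all pair
#' propensities formed by the residue's atoms (as donor or acceptor).
#'
#' @param ensemble a [conformation_ensemble].
#' @param criteria see [hbond_criteria()].
#' @return An object of class `hbond_propensity`: list with `pairs`
#'   (per donor-acceptor fraction) and `residues` (per-residue sums,
#'   covering every residue of the template).
#' @export
hbond_propensity <- function(ensemble, criteria = hbond_criteria()) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  cand <- hbond_candidates(ensemble$template)
  nf <- n_frames(ensemble)
  counts <- new.env(hash = TRUE)
  for (f in seq_len(nf)) {
    hb <- hbonds_from_coords(ensemble$coords[, , f], cand, criteria)
    if (!nrow(hb)) next
    keys <- paste(hb$donor, hb$acceptor, sep = "_")
    for (k in keys) {
      counts[[k]] <- if (is.null(counts[[k]])) 1L else counts[[k]] + 1L
    }
  }
  keys <- ls(counts)
  at <- ensemble$template$atoms
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "_"))
    pairs <- data.frame(donor = as.integer(parts[, 1]),
                        acceptor = as.integer(parts[, 2]))
    pairs$propensity <- vapply(keys, function(k) counts[[k]], 1L) / nf
    pairs$donor_residue <- at$residue_index[pairs$donor]
    pairs$acceptor_residue <- at$residue_index[pairs$acceptor]
    pairs <- pairs[order(pairs$donor, pairs$acceptor), ]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(donor = integer(0), acceptor = integer(0),
                        propensity = numeric(0), donor_residue = integer(0),
                        acceptor_residue = integer(0))
  }
  resdf <- unique(at[, c("residue_index", "chain_id")])
  resdf$propensity <- 0
  for (k in seq_len(nrow(pairs))) {
    for (col in c("donor", "acceptor")) {
      a <- pairs[[col]][k]
      hit <- which(resdf$residue_index == at$residue_index[a] &
                     resdf$chain_id == at$chain_id[a])
      resdf$propensity[hit] <- resdf$propensity[hit] + pairs$propensity[k]
    }
  }
  rownames(resdf) <- NULL
  structure(list(pairs = pairs, residues = resdf, n_frames = nf),
            class = "hbond_propensity")
}
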