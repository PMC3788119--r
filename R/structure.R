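# Structural interface metrics: Shrake-Rupley solvent-accessible surface
# area, interface burial and energetics, inter-chain contacts, and mapping
# of protected regions onto coordinates.

#' Build an atom table
#'
#' The atomic coordinate container used by the structural operations: one
#' row per heavy atom with chain id, residue number, residue name
#' (one- or three-letter), atom name, element and coordinates in Angstrom.
#' Radii are assigned from a fixed van der Waals set (C 1.70, N 1.55,
#' O 1.52, S 1.80) unless supplied.
#'
#' @param chain,resno,resid,atom,element,x,y,z Per-atom vectors.
#' @param radius Optional explicit radii (Angstrom).
#' @return Tibble of class `atom_table`.
#' @export
#' @examples
#' atom_table("A", 1, "GLY", "CA", "C", 0, 0, 0)
atom_table <- function(chain, resno, resid, atom, element, x, y, z,
                       radius = NULL) {
  out <- tibble(
    chain = as.character(chain), resno = as.integer(resno),
    resid = as.character(resid), atom = as.character(atom),
    element = toupper(as.character(element)),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)
  )
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    abort("atom coordinates must be finite")
  }
  out$radius <- if (is.null(radius)) {
    r <- VDW_RADII[out$element]
    r[is.na(r)] <- VDW_RADIUS_DEFAULT
    unname(r)
  } else {
    as.numeric(radius)
  }
  if (any(out$radius <= 0)) abort("atomic radii must be positive")
  class(out) <- c("atom_table", class(out))
  out
}

#' Read heavy atoms from a PDB file
#'
#' Standard columnar ATOM/HETATM ingestion via `bio3d`: hydrogens and
#' waters are dropped, alternate location A (or blank) is kept, and only
#' the first model of a multi-model file is used.
#'
#' @param path Path to a PDB file.
#' @param keep_hetatm Keep non-water HETATM records (default `FALSE`).
#' @return An [atom_table()].
#' @export
read_structure <- function(path, keep_hetatm = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" | (keep_hetatm & at$type == "HETATM" & at$resid != "HOH")
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  at <- at[elem != "H" & elem != "D", , drop = FALSE]
  elem <- elem[elem != "H" & elem != "D"]
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  atom_table(chain, at$resno, at$resid, trimws(at$elety), elem,
             at$x, at$y, at$z)
}

# deterministic quasi-uniform unit sphere points (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  zc <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - zc^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = zc)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere (default radius 1.4 Angstrom) over the atomic
#' spheres by testing a deterministic Fibonacci lattice of `n_points`
#' directions on each atom's expanded sphere against occlusion by
#' neighbouring expanded spheres. An isolated atom recovers the closed
#' form `4 * pi * (r + probe)^2`.
#'
#' @param atoms An [atom_table()] (>= 1 atom).
#' @param probe_radius Probe radius, Angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 960).
#' @return The atom table with an `area` column (Angstrom^2) appended.
#' @export
#' @examples
#' a <- atom_table("A", 1, "ALA", "CA", "C", 0, 0, 0)
#' sasa(a)$area  # ~ 4*pi*3.1^2
sasa <- function(atoms, probe_radius = 1.4, n_points = 960L) {
  if (nrow(atoms) == 0) abort("at least one atom required")
  stopifnot(probe_radius >= 0, n_points >= 12)
  sphere <- fibonacci_sphere(n_points)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  rad <- atoms$radius + probe_radius
  n <- nrow(xyz)
  area <- numeric(n)
  # neighbour prefilter on pairwise centre distances
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    pts <- sweep(sphere * rad[i], 2, xyz[i, ], `+`)
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 >= rad[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * mean(acc)
  }
  out <- atoms
  out$area <- area
  out
}

# one-letter residue code from resid (accepts one- or three-letter)
residue_letter <- function(resid) {
  up <- toupper(resid)
  out <- ifelse(nchar(up) == 1, up, unname(AA3_TO_1[up]))
  ifelse(is.na(out), "X", out)
}

#' Per-residue SASA summary
#'
#' @param atoms_with_area Output of [sasa()].
#' @return Tibble with `chain`, `resno`, `resid`, `area`.
#' @export
residue_sasa <- function(atoms_with_area) {
  atoms_with_area %>%
    group_by(.data$chain, .data$resno, .data$resid) %>%
    summarise(area = sum(.data$area), .groups = "drop")
}

#' Buried interface surface of a complex
#'
#' Computes the total surface buried on complex formation,
#' `sum over chains of SASA(chain isolated) - SASA(complex)`, together with
#' the per-residue burial profile (isolated vs in-complex SASA, their
#' difference, and a hydrophobicity flag).
#'
#' @param atoms An [atom_table()] with at least two chains.
#' @inheritParams sasa
#' @return An object of class `burial_profile`: list with `total`
#'   (Angstrom^2), `profile` (per-residue tibble with `chain`, `resno`,
#'   `resid`, `sasa_isolated`, `sasa_complex`, `delta_sasa`,
#'   `hydrophobic`), `per_chain` (buried area per chain), and the
#'   parameters used. Supports [tidy()], [glance()] and [autoplot()].
#' @export
buried_surface <- function(atoms, probe_radius = 1.4, n_points = 960L) {
  chains <- unique(atoms$chain)
  if (length(chains) < 2) abort("buried surface requires at least two chains")
  cx <- residue_sasa(sasa(atoms, probe_radius, n_points)) %>%
    rename(sasa_complex = "area")
  iso <- purrr::map_dfr(chains, function(ch) {
    residue_sasa(sasa(atoms[atoms$chain == ch, , drop = FALSE],
                      probe_radius, n_points))
  }) %>% rename(sasa_isolated = "area")
  profile <- inner_join(iso, cx, by = c("chain", "resno", "resid")) %>%
    mutate(
      delta_sasa = .data$sasa_isolated - .data$sasa_complex,
      hydrophobic = is_hydrophobic(residue_letter(.data$resid))
    ) %>%
    arrange(.data$chain, .data$resno)
  per_chain <- profile %>%
    group_by(.data$chain) %>%
    summarise(buried = sum(.data$delta_sasa), .groups = "drop")
  structure(list(
    total = sum(profile$delta_sasa),
    profile = profile,
    per_chain = per_chain,
    probe_radius = probe_radius,
    n_points = n_points
  ), class = "burial_profile")
}

#' @export
print.burial_profile <- function(x, ...) {
  cat("Interface burial:", round(x$total, 1), "A^2 total (",
      paste(sprintf("%s: %.1f", x$per_chain$chain, x$per_chain$buried),
            collapse = ", "), ")\n")
  cat("  hydrophobic share:",
      round(sum(x$profile$delta_sasa[x$profile$hydrophobic]), 1), "A^2\n")
  invisible(x)
}

#' @rdname buried_surface
#' @param x A `burial_profile`.
#' @param ... Unused.
#' @method tidy burial_profile
#' @export
tidy.burial_profile <- function(x, ...) x$profile

#' @rdname buried_surface
#' @method glance burial_profile
#' @export
glance.burial_profile <- function(x, ...) {
  tibble(
    total_buried = x$total,
    hydrophobic_buried = sum(x$profile$delta_sasa[x$profile$hydrophobic]),
    n_interface_residues = sum(x$profile$delta_sasa > 1),
    probe_radius = x$probe_radius,
    n_points = x$n_points
  )
}

#' Buried surface averaged over an ensemble of snapshots
#'
#' @param snapshots List of [atom_table()]s (e.g. trajectory snapshots).
#' @inheritParams sasa
#' @return Tibble with `mean_buried`, `sd_buried`, `n_snapshots`.
#' @export
buried_surface_ensemble <- function(snapshots, probe_radius = 1.4,
                                    n_points = 960L) {
  vals <- vapply(snapshots, function(a) {
    buried_surface(a, probe_radius, n_points)$total
  }, numeric(1))
  tibble(mean_buried = mean(vals),
         sd_buried = if (length(vals) > 1) sd(vals) else NA_real_,
         n_snapshots = length(vals))
}

#' Burial free-energy estimate
#'
#' Converts buried surface into a stabilization free-energy estimate via a
#' linear surface coefficient. The default coefficient,
#' 11.1 cal mol^-1 A^-2, is back-calculated so that 900 Angstrom^2 of
#' hydrophobic burial corresponds to about 10 kcal/mol; reports state this
#' provenance.
#'
#' @param profile A `burial_profile` from [buried_surface()], or a number
#'   of Angstrom^2 directly.
#' @param coefficient Surface free-energy coefficient, cal mol^-1 A^-2.
#' @param hydrophobic_only Use hydrophobic buried surface only (default
#'   `TRUE`; ignored when `profile` is numeric).
#' @return Stabilization estimate in kcal/mol.
#' @export
#' @examples
#' burial_energy(900)  # ~ 10
burial_energy <- function(profile, coefficient = 11.1, hydrophobic_only = TRUE) {
  stopifnot(coefficient > 0)
  area <- if (is.numeric(profile)) {
    profile
  } else if (inherits(profile, "burial_profile")) {
    p <- profile$profile
    if (hydrophobic_only) sum(p$delta_sasa[p$hydrophobic]) else sum(p$delta_sasa)
  } else {
    abort("profile must be a burial_profile or a numeric area")
  }
  coefficient * area / 1000
}

#' Inter-chain residue contacts
#'
#' Lists residue pairs from two chains with any heavy-atom distance at or
#' below `cutoff` (default 4.5 Angstrom), flagging potential salt bridges
#' (Arg/Lys side-chain nitrogen within `salt_bridge_cutoff` of an Asp/Glu
#' side-chain carboxylate oxygen).
#'
#' @param atoms An [atom_table()].
#' @param chain_a,chain_b Chain ids to compare (default: the first two).
#' @param cutoff Heavy-atom contact cutoff, Angstrom.
#' @param salt_bridge_cutoff Salt-bridge N-O cutoff, Angstrom (default 4.0).
#' @return Tibble with `resno_a`, `resid_a`, `resno_b`, `resid_b`,
#'   `min_dist`, `n_atom_pairs`, `salt_bridge`.
#' @export
contact_profile <- function(atoms, chain_a = NULL, chain_b = NULL,
                            cutoff = 4.5, salt_bridge_cutoff = 4.0) {
  chains <- unique(atoms$chain)
  if (is.null(chain_a)) chain_a <- chains[1]
  if (is.null(chain_b)) chain_b <- chains[2]
  if (!all(c(chain_a, chain_b) %in% chains)) {
    abort(paste0("unknown chain id(s): ",
                 paste(setdiff(c(chain_a, chain_b), chains), collapse = ", ")))
  }
  a <- atoms[atoms$chain == chain_a, , drop = FALSE]
  b <- atoms[atoms$chain == chain_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) abort("empty chain selection")
  dx <- outer(a$x, b$x, `-`); dy <- outer(a$y, b$y, `-`); dz <- outer(a$z, b$z, `-`)
  dmat <- sqrt(dx^2 + dy^2 + dz^2)
  hit <- which(dmat <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble(resno_a = integer(), resid_a = character(),
                  resno_b = integer(), resid_b = character(),
                  min_dist = numeric(), n_atom_pairs = integer(),
                  salt_bridge = logical()))
  }
  basic_n <- c("NH1", "NH2", "NE", "NZ")
  acidic_o <- c("OD1", "OD2", "OE1", "OE2")
  is_basic <- function(res, at) res %in% c("ARG", "LYS", "R", "K") & at %in% basic_n
  is_acidic <- function(res, at) res %in% c("ASP", "GLU", "D", "E") & at %in% acidic_o
  pairs <- tibble(
    resno_a = a$resno[hit[, 1]], resid_a = a$resid[hit[, 1]],
    atom_a = a$atom[hit[, 1]],
    resno_b = b$resno[hit[, 2]], resid_b = b$resid[hit[, 2]],
    atom_b = b$atom[hit[, 2]],
    dist = dmat[hit]
  ) %>%
    mutate(sb_pair = .data$dist <= salt_bridge_cutoff &
             ((is_basic(.data$resid_a, .data$atom_a) & is_acidic(.data$resid_b, .data$atom_b)) |
              (is_acidic(.data$resid_a, .data$atom_a) & is_basic(.data$resid_b, .data$atom_b))))
  pairs %>%
    group_by(.data$resno_a, .data$resid_a, .data$resno_b, .data$resid_b) %>%
    summarise(min_dist = min(.data$dist), n_atom_pairs = dplyr::n(),
              salt_bridge = any(.data$sb_pair), .groups = "drop") %>%
    arrange(.data$resno_a, .data$resno_b)
}

#' Map protected regions onto a structure
#'
#' Selects the residues of each protected region that are present in the
#' coordinates (after applying the numbering offset between reporting and
#' structure numbering) and classifies them as hydrophobic or not. Regions
#' partially or wholly absent from the coordinates (e.g. flexible linkers
#' unresolved in the crystal) produce a warning and a partial mapping.
#'
#' @param regions Tibble with `start`, `end` (reporting numbering), as from
#'   [merge_regions()].
#' @param atoms An [atom_table()].
#' @param offset Number added to structure residue numbers to obtain
#'   reporting numbers (default 0: numbering already reconciled).
#' @return Tibble with one row per (region, residue): `region_start`,
#'   `region_end`, `resno`, `resid`, `letter`, `hydrophobic`, `in_structure`.
#' @export
map_regions_to_structure <- function(regions, atoms, offset = 0L) {
  res <- distinct(atoms, .data$chain, .data$resno, .data$resid) %>%
    mutate(report_no = .data$resno + as.integer(offset))
  out <- purrr::pmap_dfr(
    list(regions$start, regions$end),
    function(rs, re) {
      wanted <- tibble(report_no = seq.int(rs, re))
      found <- res %>%
        filter(.data$report_no >= rs, .data$report_no <= re) %>%
        distinct(.data$report_no, .keep_all = TRUE)
      joined <- left_join(wanted, found, by = "report_no")
      n_miss <- sum(is.na(joined$resno))
      if (n_miss > 0) {
        warn(paste0("region ", rs, "-", re, ": ", n_miss,
                    " residue(s) absent from the structure; partial mapping"))
      }
      joined %>%
        mutate(region_start = rs, region_end = re,
               letter = ifelse(is.na(.data$resid), NA_character_,
                               residue_letter(.data$resid)),
               hydrophobic = ifelse(is.na(.data$letter), NA,
                                    is_hydrophobic(.data$letter)),
               in_structure = !is.na(.data$resno))
    }
  )
  out %>%
    select("region_start", "region_end", resno = "report_no", "resid",
           "letter", "hydrophobic", "in_structure")
}

#' Write a residue-range selection file
#'
#' Emits protected regions as a generic residue-range selection text
#' (one `start-end` range per line), usable in molecular viewers.
#'
#' @param regions Tibble with `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_selection <- function(regions, path) {
  writeLines(sprintf("%d-%d", regions$start, regions$end), path)
  invisible(path)
}
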