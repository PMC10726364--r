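## Grid-search partial-charge parametrization in the additive force-field
## style: exhaustive enumeration of charge sets on a fixed grid under
## symmetry-group and total-charge constraints, filtering by dipole
## overestimation relative to a quantum reference, and scoring against
## reference water-probe interaction energies.

E_ANGSTROM_TO_DEBYE <- 4.80320      # 1 e*Angstrom in Debye
COULOMB_KCAL <- 332.0636            # kcal*Angstrom/(mol*e^2)

#' Define a partial-charge fitting problem
#'
#' Atoms that are chemically equivalent share a symmetry group and hence a
#' single charge variable, which controls the combinatorics of the grid
#' enumeration. Backbone atoms whose charges are already fixed are simply
#' omitted (or given equal bounds). Quantum reference quantities (the
#' dipole magnitude and the probe interaction energies) are inputs, never
#' computed here.
#'
#' @param atoms data.frame with one row per fitted atom: `name`, `x`, `y`,
#'   `z` (Angstrom), `group` (symmetry group id), `q_min`, `q_max` (bounds
#'   in e), and -- if probes carry Lennard-Jones terms -- `eps` (well depth,
#'   kcal/mol, positive; force-field tables often print it negated) and
#'   `rmin2` (r_min/2, Angstrom).
#' @param total_charge target sum of charges in e.
#' @param grid charge grid spacing in e (default 0.05).
#' @param reference_dipole quantum reference dipole magnitude in Debye.
#' @param dipole_factor_range acceptable dipole overestimation band
#'   (default c(1.2, 1.5), inclusive).
#' @param probes list of water-probe poses; each a list with `atoms` (a
#'   data.frame `x`, `y`, `z`, `charge`, and optionally `eps`, `rmin2`) and
#'   `e_ref` (reference interaction energy, kcal/mol).
#' @param tolerance per-probe pass band in kcal/mol (default 0.2).
#' @param max_sets enumeration cap: refuse if the unconstrained lattice
#'   exceeds this many points (default 1e7).
#' @return a `charge_fit_problem`.
#' @export
charge_fit_problem <- function(atoms, total_charge, grid = 0.05,
                               reference_dipole = NULL,
                               dipole_factor_range = c(1.2, 1.5),
                               probes = list(), tolerance = 0.2,
                               max_sets = 1e7) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "x", "y", "z", "group", "q_min", "q_max") %in%
                  names(atoms)),
            grid > 0, tolerance > 0)
  if (any(atoms$q_min > atoms$q_max)) stop("q_min > q_max for some atom")
  # bounds must agree within a symmetry group
  for (g in unique(atoms$group)) {
    sub <- atoms[atoms$group == g, ]
    if (length(unique(sub$q_min)) > 1L || length(unique(sub$q_max)) > 1L) {
      stop("atoms in symmetry group '", g, "' have inconsistent bounds")
    }
  }
  structure(list(atoms = atoms, total_charge = total_charge, grid = grid,
                 reference_dipole = reference_dipole,
                 dipole_factor_range = dipole_factor_range,
                 probes = probes, tolerance = tolerance,
                 max_sets = max_sets),
            class = "charge_fit_problem")
}

#' Per-group grid values and multiplicities
#' @noRd
group_lattice <- function(problem) {
  atoms <- problem$atoms
  groups <- unique(atoms$group)
  lapply(groups, function(g) {
    sub <- atoms[atoms$group == g, ]
    lo <- ceiling(round(sub$q_min[1] / problem$grid, 9))
    hi <- floor(round(sub$q_max[1] / problem$grid, 9))
    if (lo > hi) stop("no grid point inside the bounds of group '", g, "'")
    list(group = g, mult = nrow(sub), n = lo:hi)
  })
}

#' Enumerate all feasible charge sets on the grid
#'
#' Generates every combination of per-group grid charges within bounds
#' whose multiplicity-weighted sum equals the molecular charge. The search
#' runs in exact integer grid units with remaining-sum pruning, emits a
#' deterministic (lexicographic by group order) sequence, and refuses
#' upfront if the unconstrained lattice exceeds the problem's cap.
#'
#' @param problem a [charge_fit_problem()].
#' @return a `charge_set_collection`: numeric matrix with one row per
#'   feasible set and one column per atom (named); zero rows (with a
#'   diagnostic attribute) when the sum constraint is infeasible.
#' @export
enumerate_charge_sets <- function(problem) {
  stopifnot(inherits(problem, "charge_fit_problem"))
  lat <- group_lattice(problem)
  n_lattice <- prod(vapply(lat, function(l) length(l$n), numeric(1)))
  if (n_lattice > problem$max_sets) {
    stop("enumeration refused: unconstrained lattice has ",
         format(n_lattice, big.mark = ","), " points, exceeding the cap of ",
         format(problem$max_sets, big.mark = ","),
         "; coarsen the grid, tighten bounds or merge symmetry groups")
  }
  target <- round(problem$total_charge / problem$grid)
  if (abs(problem$total_charge / problem$grid - target) > 1e-6) {
    stop("total_charge is not a multiple of the grid spacing")
  }
  k <- length(lat)
  mult <- vapply(lat, `[[`, numeric(1), "mult")
  # suffix bounds for pruning
  lo_suffix <- rev(cumsum(rev(vapply(lat, function(l) min(l$n), numeric(1)) * mult)))
  hi_suffix <- rev(cumsum(rev(vapply(lat, function(l) max(l$n), numeric(1)) * mult)))
  acc <- list()
  recurse <- function(i, remaining, prefix) {
    if (i > k) {
      if (remaining == 0) acc[[length(acc) + 1L]] <<- prefix
      return(invisible())
    }
    for (n in lat[[i]]$n) {
      rem <- remaining - n * mult[i]
      if (i < k) {
        if (rem < lo_suffix[i + 1L] || rem > hi_suffix[i + 1L]) next
      } else if (rem != 0) next
      recurse(i + 1L, rem, c(prefix, n))
    }
  }
  recurse(1L, target, integer(0))
  groups <- vapply(lat, `[[`, vector(mode = mode(problem$atoms$group), 1L), "group")
  out <- if (length(acc)) {
    per_group <- do.call(rbind, acc) * problem$grid
    per_group[, match(problem$atoms$group, groups), drop = FALSE]
  } else {
    matrix(numeric(0), 0L, nrow(problem$atoms))
  }
  colnames(out) <- problem$atoms$name
  if (!length(acc)) {
    attr(out, "diagnostic") <- paste0(
      "no grid combination sums to ", problem$total_charge,
      " e within the given bounds")
  }
  class(out) <- c("charge_set_collection", class(out))
  out
}

#' Dipole moment magnitude of a charge set
#'
#' |sum q_i r_i| converted at 1 e*Angstrom = 4.80320 Debye. For neutral
#' sets the result is origin-independent.
#'
#' @param charges numeric vector of per-atom charges in e.
#' @param positions n x 3 matrix of positions in Angstrom.
#' @return dipole magnitude in Debye.
#' @export
compute_dipole <- function(charges, positions) {
  positions <- as_mat3(positions)
  stopifnot(length(charges) == nrow(positions), all(is.finite(positions)))
  mu <- colSums(charges * positions)
  sqrt(sum(mu^2)) * E_ANGSTROM_TO_DEBYE
}

#' Filter charge sets by dipole overestimation
#'
#' Additive force fields compensate missing polarisation by requiring the
#' molecular dipole to overestimate the gas-phase quantum value; sets whose
#' dipole is between 1.2 and 1.5 times the reference (inclusive) are
#' retained, all others rejected.
#'
#' @param sets a matrix of charge sets (rows) as from
#'   [enumerate_charge_sets()].
#' @param problem the [charge_fit_problem()] (provides positions, the
#'   reference dipole and the factor band).
#' @return the retained subset of rows, with a `dipole_ratio` attribute.
#' @export
dipole_filter <- function(sets, problem) {
  stopifnot(inherits(problem, "charge_fit_problem"))
  if (is.null(problem$reference_dipole) || problem$reference_dipole <= 0) {
    stop("dipole filtering requires a positive reference_dipole")
  }
  pos <- as.matrix(problem$atoms[, c("x", "y", "z")])
  ratio <- apply(sets, 1L, function(q) compute_dipole(q, pos)) /
    problem$reference_dipole
  keep <- ratio >= problem$dipole_factor_range[1] &
    ratio <= problem$dipole_factor_range[2]
  out <- sets[keep, , drop = FALSE]
  attr(out, "dipole_ratio") <- ratio[keep]
  class(out) <- c("charge_set_collection", class(out))
  out
}

#' Pairwise nonbonded interaction energy (Coulomb + Lennard-Jones)
#' @noRd
interaction_energy <- function(q1, pos1, q2, pos2,
                               eps1 = NULL, rmin2_1 = NULL,
                               eps2 = NULL, rmin2_2 = NULL) {
  pos1 <- as_mat3(pos1); pos2 <- as_mat3(pos2)
  d <- sqrt(outer(rowSums(pos1^2), rowSums(pos2^2), "+") -
              2 * pos1 %*% t(pos2))
  if (any(d < 1e-10)) stop("degenerate geometry: coincident atoms (r = 0)")
  e <- COULOMB_KCAL * sum(outer(q1, q2) / d)
  if (!is.null(eps1) && !is.null(eps2)) {
    eps_ij <- sqrt(outer(eps1, eps2))
    rmin_ij <- outer(rmin2_1, rmin2_2, "+")
    x6 <- (rmin_ij / d)^6
    e <- e + sum(eps_ij * (x6^2 - 2 * x6))
  }
  e
}

#' Score a charge set against water-probe reference energies
#'
#' Evaluates the solute-probe interaction energy for every probe pose
#' (Coulomb at 332.0636 kcal*Angstrom/(mol*e^2) plus Lennard-Jones,
#' E = eps[(rmin/r)^12 - 2 (rmin/r)^6], with Lorentz-Berthelot-style
#' combining: geometric-mean eps, summed rmin/2) and compares with the
#' reference. A set passes when every probe deviation is within the
#' problem's tolerance (default +/-0.2 kcal/mol).
#'
#' @param charges numeric vector of per-atom charges in e.
#' @param problem the [charge_fit_problem()]; probes must be non-empty.
#' @return list with `energies`, `deviations` (E - E_ref per probe), `rms`,
#'   `max_abs`, `pass`.
#' @export
score_interactions <- function(charges, problem) {
  stopifnot(inherits(problem, "charge_fit_problem"))
  if (!length(problem$probes)) stop("no probe poses in the problem")
  at <- problem$atoms
  pos <- as.matrix(at[, c("x", "y", "z")])
  has_lj <- all(c("eps", "rmin2") %in% names(at))
  res <- vapply(problem$probes, function(pr) {
    pa <- pr$atoms
    lj_probe <- has_lj && all(c("eps", "rmin2") %in% names(pa))
    interaction_energy(
      charges, pos, pa$charge, as.matrix(pa[, c("x", "y", "z")]),
      eps1 = if (lj_probe) at$eps else NULL,
      rmin2_1 = if (lj_probe) at$rmin2 else NULL,
      eps2 = if (lj_probe) pa$eps else NULL,
      rmin2_2 = if (lj_probe) pa$rmin2 else NULL
    )
  }, numeric(1))
  e_ref <- vapply(problem$probes, `[[`, numeric(1), "e_ref")
  dev <- res - e_ref
  list(energies = res, deviations = dev,
       rms = sqrt(mean(dev^2)), max_abs = max(abs(dev)),
       pass = all(abs(dev) <= problem$tolerance))
}

#' Rank passing charge sets by agreement with the probe references
#'
#' Orders candidates by RMS deviation over probes, breaking ties by the
#' maximum absolute deviation and then lexicographically by charges, so the
#' ordering is fully deterministic. This replaces a by-hand final
#' adjustment step with a reproducible criterion.
#'
#' @param sets a matrix of charge sets (rows).
#' @param problem the [charge_fit_problem()].
#' @param passing_only keep only sets within tolerance on every probe
#'   (default TRUE).
#' @return data.frame with one row per candidate: the charges, `rms`,
#'   `max_abs`, `pass`, sorted best first.
#' @export
rank_candidates <- function(sets, problem, passing_only = TRUE) {
  stopifnot(inherits(problem, "charge_fit_problem"))
  if (!nrow(sets)) {
    return(data.frame())
  }
  scores <- lapply(seq_len(nrow(sets)), function(i) {
    score_interactions(sets[i, ], problem)
  })
  df <- as.data.frame(unclass(sets)[, , drop = FALSE])
  df$rms <- vapply(scores, `[[`, numeric(1), "rms")
  df$max_abs <- vapply(scores, `[[`, numeric(1), "max_abs")
  df$pass <- vapply(scores, `[[`, logical(1), "pass")
  if (passing_only) df <- df[df$pass, , drop = FALSE]
  if (!nrow(df)) return(df)
  ord <- do.call(order, c(list(df$rms, df$max_abs),
                          unname(as.list(df[seq_len(ncol(sets))]))))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export charges as a force-field stream-style text block
#'
#' @param charges named numeric vector (atom name -> charge in e).
#' @param path output file.
#' @param resname residue name for the block header.
#' @return `path`, invisibly.
#' @export
write_charge_block <- function(charges, path, resname = "LIG") {
  lines <- c(sprintf("RESI %s  % .3f", resname, sum(charges)),
             sprintf("ATOM %-6s %8.4f", names(charges), charges),
             "END")
  writeLines(lines, path)
  invisible(path)
}
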