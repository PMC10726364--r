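## Synthetic two-ring trajectory ensembles with exact descriptor-level
## ground truth: lambda(t) follows a seeded Markov jump process and the
## molecular geometry is constructed each frame so that the rho and lambda
## descriptors computed from the coordinates equal the programmed values to
## machine precision. No force field, no solvent -- only the statistical
## structure the switching analysis assumes.

RING_ATOM_NAMES <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")

#' Ideal benzene ring template
#'
#' Six carbons with C-C bond length 1.39 Angstrom in the xy-plane, named by
#' standard phenylalanine side-chain nomenclature: CG is the ipso carbon,
#' CZ the para carbon (ring-graph distance 3 from ipso).
#'
#' @param cc C-C bond length in Angstrom (default 1.39).
#' @return a 6 x 3 matrix with rownames CG, CD1, CE1, CZ, CE2, CD2.
#' @export
benzene_ring_template <- function(cc = 1.39) {
  ang <- (seq(0, 300, by = 60) + 180) * pi / 180  # CG at angle 180
  m <- cbind(cc * cos(ang), cc * sin(ang), 0)
  rownames(m) <- RING_ATOM_NAMES
  m
}

#' Specification for a synthetic switching ensemble
#'
#' Defines the population layout (default 25 molecules x 2500 frames,
#' matching a 50 ns run sampled every 20 ps), the lambda switching process
#' and the programmed rho. Per frame step and molecule, lambda jumps with
#' probability `switch_probability` by a magnitude drawn from `jump_range`
#' (support at or above the switching threshold) and otherwise jitters by a
#' magnitude drawn from `jitter_range` (support strictly below the
#' threshold), so the ground-truth switch count equals the number of jump
#' events exactly under the circular delta-lambda convention.
#'
#' @param n_molecules molecules per ensemble (default 25).
#' @param n_frames frames (default 2500).
#' @param switch_probability per-step jump probability in [0, 1].
#' @param jump_range degrees, c(lo, hi) with lo >= threshold.
#' @param jitter_range degrees, c(lo, hi) with hi < threshold.
#' @param threshold switching threshold the supports are validated against
#'   (default 20 degrees).
#' @param rho_program target rho: a scalar or a length-`n_frames` vector.
#' @param lambda_program optional deterministic lambda program in degrees
#'   (length-`n_frames` vector recycled across molecules, or an
#'   `n_frames` x `n_molecules` matrix); overrides the Markov jump process.
#'   Ground-truth jumps are then the steps whose circular change meets the
#'   threshold.
#' @param d_ipso ipso-ipso distance in Angstrom (default 5).
#' @param cc C-C bond length of the ideal rings (default 1.39).
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_molecules = 25, n_frames = 2500,
                           switch_probability = 0.02,
                           jump_range = c(25, 120),
                           jitter_range = c(0, 5),
                           threshold = 20,
                           rho_program = 1.0, lambda_program = NULL,
                           d_ipso = 5.0, cc = 1.39, seed = 1) {
  stopifnot(n_molecules >= 1, n_frames >= 2,
            switch_probability >= 0, switch_probability <= 1,
            length(jump_range) == 2L, length(jitter_range) == 2L)
  if (jump_range[1] < threshold) {
    stop("jump_range support must lie at or above the threshold (",
         threshold, " deg) so ground-truth switch counts are exact")
  }
  if (jitter_range[2] >= threshold) {
    stop("jitter_range support must lie strictly below the threshold (",
         threshold, " deg)")
  }
  stopifnot(length(rho_program) %in% c(1L, n_frames), all(rho_program > 0))
  if (!is.null(lambda_program)) {
    lambda_program <- if (is.matrix(lambda_program)) lambda_program
    else matrix(lambda_program, n_frames, n_molecules)
    stopifnot(nrow(lambda_program) == n_frames,
              ncol(lambda_program) == n_molecules)
  }
  structure(list(n_molecules = n_molecules, n_frames = n_frames,
                 switch_probability = switch_probability,
                 jump_range = jump_range, jitter_range = jitter_range,
                 threshold = threshold, rho_program = rho_program,
                 lambda_program = lambda_program,
                 d_ipso = d_ipso, cc = cc, seed = seed),
            class = "synthetic_spec")
}

#' Solve the ring-2 polar angle realizing (rho, lambda) in closed form
#'
#' In the local frame ipso1 = origin, para1 = (0, 2cc, 0), ipso2 = (d, 0, 0),
#' the para2 direction (cos mu, sin mu cos psi, sin mu sin psi) gives a
#' para-para distance r with
#'   r^2 = d^2 + 2 a^2 + 2 a (d cos mu - a cos psi sin mu),   a = 2 cc,
#' and an inter-ring torsion exactly psi. Solving for mu at fixed psi yields
#' any feasible rho = d / r without disturbing lambda.
#' @noRd
solve_ring2_mu <- function(rho, psi, d, a) {
  r2 <- (d / rho)^2
  R <- sqrt(d^2 + (a * cos(psi))^2)
  delta <- atan2(a * cos(psi), d)
  cosval <- (r2 - d^2 - 2 * a^2) / (2 * a * R)
  if (any(abs(cosval) > 1)) {
    stop("infeasible geometry: programmed rho unreachable at programmed ",
         "lambda (d_ipso = ", d, " A)")
  }
  base <- acos(cosval)
  mu <- base - delta
  alt <- -base - delta
  swap <- mu <= 0 | mu >= pi
  mu[swap] <- (alt[swap]) %% (2 * pi)
  if (any(mu <= 0 | mu >= pi | sin(mu) < 1e-3)) {
    stop("infeasible geometry: para2 would fall on the ipso-ipso axis ",
         "(degenerate torsion)")
  }
  mu
}

#' Build per-frame coordinates for one molecule from its (rho, lambda) program
#' @noRd
build_molecule_coords <- function(lam_deg, rho, d, cc) {
  nf <- length(lam_deg)
  a <- 2 * cc
  psi <- lam_deg * pi / 180
  rho <- rep_len(rho, nf)
  mu <- solve_ring2_mu(rho, psi, d, a)

  ipso1 <- c(0, 0, 0); para1 <- c(0, a, 0); ipso2 <- c(d, 0, 0)
  dir <- cbind(cos(mu), sin(mu) * cos(psi), sin(mu) * sin(psi))
  para2 <- matrix(ipso2, nf, 3, byrow = TRUE) + a * dir

  coords <- array(0, dim = c(nf, 12L, 3L))
  # ring 1 is constant: ideal ring with CG at ipso1, CZ at para1
  c1 <- (ipso1 + para1) / 2
  e1 <- (ipso1 - c1) / cc; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(0, 0, 1)  # perpendicular to the y-axis diameter
  ang <- seq(0, 300, by = 60) * pi / 180
  ring1 <- matrix(c1, 6L, 3L, byrow = TRUE) +
    cc * (outer(cos(ang), e1) + outer(sin(ang), e2))
  for (k in 1:6) coords[, k, ] <- matrix(ring1[k, ], nf, 3L, byrow = TRUE)

  # ring 2 varies by frame: diameter from ipso2 to para2(t)
  c2 <- (matrix(ipso2, nf, 3, byrow = TRUE) + para2) / 2
  f1 <- -dir                      # unit vector from ring-2 centre to ipso2
  xhat <- matrix(c(1, 0, 0), nf, 3, byrow = TRUE)
  f2 <- cross3(f1, xhat)
  f2 <- f2 / rownorm3(f2)
  for (k in 1:6) {
    coords[, 6L + k, ] <- c2 + cc * (cos(ang[k]) * f1 + sin(ang[k]) * f2)
  }
  coords
}

#' Generate a synthetic trajectory ensemble with ground truth
#'
#' Realises the lambda switching process in actual 3D coordinates: two
#' ideal benzene rings per molecule whose descriptor-level rho and lambda
#' match the programmed values to machine precision, each molecule placed
#' by its own random rigid transform (descriptors are rigid-invariant).
#' Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param label optional [amide_state_label()] or short-form string.
#' @return list with `ensemble` (a [trajectory_ensemble()]) and `truth`
#'   (ground truth: `lambda` and `rho` programs, per-step `jumps` logical
#'   matrix, per-molecule `n_jumps`, `wrap_crossings` where the literal
#'   delta-lambda convention disagrees with the circular one, and `seed`).
#' @export
generate_ensemble <- function(spec, label = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nf <- spec$n_frames; nm <- spec$n_molecules
  out <- with_seed(spec$seed, {
    if (!is.null(spec$lambda_program)) {
      lam <- wrap_360(spec$lambda_program)
      d <- abs(diff(lam))  # column-wise, keeps matrix shape
      jumps <- pmin(d, 360 - d) >= spec$threshold
    } else {
      lam <- matrix(0, nf, nm)
      jumps <- matrix(FALSE, nf - 1L, nm)
      for (m in seq_len(nm)) {
        l0 <- stats::runif(1, 0, 360)
        jump <- stats::runif(nf - 1L) < spec$switch_probability
        size <- ifelse(jump,
                       stats::runif(nf - 1L, spec$jump_range[1], spec$jump_range[2]),
                       stats::runif(nf - 1L, spec$jitter_range[1], spec$jitter_range[2]))
        sign <- sample(c(-1, 1), nf - 1L, replace = TRUE)
        lam[, m] <- wrap_360(cumsum(c(l0, sign * size)))
        jumps[, m] <- jump
      }
    }
    placements <- lapply(seq_len(nm), function(m) {
      tr <- random_rigid_transform(max_shift = 5)
      tr$t <- tr$t + c(((m - 1) %% 5) * 25, ((m - 1) %/% 5) * 25, 0)
      tr
    })
    list(lam = lam, jumps = jumps, placements = placements)
  })
  coords <- array(0, dim = c(nf, 12L * nm, 3L))
  for (m in seq_len(nm)) {
    mc <- build_molecule_coords(out$lam[, m], spec$rho_program,
                                spec$d_ipso, spec$cc)
    tr <- out$placements[[m]]
    flat <- matrix(mc, ncol = 3L)           # (nf*12) x 3, frame-major per atom
    flat <- flat %*% t(tr$R) +
      matrix(tr$t, nrow(flat), 3L, byrow = TRUE)
    coords[, (12L * (m - 1L) + 1L):(12L * m), ] <- array(flat, dim = c(nf, 12L, 3L))
  }
  atoms <- data.frame(
    elety = rep(RING_ATOM_NAMES, times = 2L * nm),
    resid = "NF",
    resno = rep(rep(1:2, each = 6L), times = nm),
    mol = rep(seq_len(nm), each = 12L),
    stringsAsFactors = FALSE
  )
  ens <- trajectory_ensemble(coords, atoms, label = label,
                             selection = ring_template(), validate = FALSE)
  dlam_lit <- abs(diff(out$lam))
  truth <- list(lambda = out$lam,
                rho = rep_len(spec$rho_program, nf),
                jumps = out$jumps,
                n_jumps = colSums(out$jumps),
                wrap_crossings = colSums(dlam_lit > 180),
                seed = spec$seed)
  list(ensemble = ens, truth = truth)
}

#' Generate a family of amide-state ensembles
#'
#' One independent ensemble per amide-state label, each with its own
#' switching probability and a seed split deterministically from the base
#' spec's seed. The ground-truth homogeneity ratio max(p)/min(p) is
#' recorded.
#'
#' @param spec a base [synthetic_spec()]; its `switch_probability` is
#'   overridden per state.
#' @param p_by_state named numeric vector: amide-state short form -> jump
#'   probability (at least 2 states).
#' @return list with `ensembles` (named list of [generate_ensemble()]
#'   results) and `eta_truth` (max(p)/min(p); Inf with a warning if any p
#'   is 0 alongside nonzero ones).
#' @export
generate_state_family <- function(spec, p_by_state) {
  stopifnot(inherits(spec, "synthetic_spec"),
            length(p_by_state) >= 2L, !is.null(names(p_by_state)))
  if (any(p_by_state == 0) && any(p_by_state > 0)) {
    warning("a state has switch probability 0: ground-truth eta is infinite")
  }
  ensembles <- vector("list", length(p_by_state))
  names(ensembles) <- names(p_by_state)
  for (i in seq_along(p_by_state)) {
    s <- spec
    s$switch_probability <- unname(p_by_state[i])
    s$seed <- spec$seed + 7919L * i  # distinct, deterministic per-state streams
    ensembles[[i]] <- generate_ensemble(s, label = names(p_by_state)[i])
  }
  eta_truth <- if (min(p_by_state) == 0) Inf else
    max(p_by_state) / min(p_by_state)
  list(ensembles = ensembles, eta_truth = eta_truth)
}
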