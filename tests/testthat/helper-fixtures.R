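# Shared fixtures and independent oracles. All fixtures are built in code.

# Independent torsion oracle: explicit plane-normal construction with the
# sign taken from the triple product, deliberately different from the
# package's atan2 formulation.
oracle_torsion <- function(a, b, c, d) {
  v <- function(p, q) q - p
  crs <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                          x[3] * y[1] - x[1] * y[3],
                          x[1] * y[2] - x[2] * y[1])
  n1 <- crs(v(a, b), v(b, c))
  n2 <- crs(v(b, c), v(c, d))
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  s <- sum(crs(n1, n2) * v(b, c))
  if (s < 0) -ang else ang
}

# Two identical parallel benzene rings stacked exactly face to face:
# every ring-1 atom directly above its ring-2 counterpart.
stacked_rings <- function(offset = 3.5) {
  ring <- benzene_ring_template()
  list(ring1 = ring, ring2 = ring + matrix(c(0, 0, offset), 6, 3, byrow = TRUE))
}

# A tiny in-memory ensemble built directly from a lambda program via the
# generator's geometry (one molecule unless stated).
tiny_ensemble <- function(n_frames = 10, n_molecules = 1, p = 0.1, seed = 42,
                          label = "cc", ...) {
  generate_ensemble(
    synthetic_spec(n_molecules = n_molecules, n_frames = n_frames,
                   switch_probability = p, seed = seed, ...),
    label = label
  )
}

# Random non-degenerate torsion quadruple (points in a box, rejecting
# near-collinear triples).
random_quadruple <- function() {
  repeat {
    pts <- matrix(stats::runif(12, -5, 5), 4, 3)
    b1 <- pts[2, ] - pts[1, ]; b2 <- pts[3, ] - pts[2, ]; b3 <- pts[4, ] - pts[3, ]
    n1 <- sqrt(sum((c(b1[2] * b2[3] - b1[3] * b2[2],
                      b1[3] * b2[1] - b1[1] * b2[3],
                      b1[1] * b2[2] - b1[2] * b2[1]))^2))
    n2 <- sqrt(sum((c(b2[2] * b3[3] - b2[3] * b3[2],
                      b2[3] * b3[1] - b2[1] * b3[3],
                      b2[1] * b3[2] - b2[2] * b3[1]))^2))
    if (n1 > 0.5 && n2 > 0.5) return(pts)
  }
}

# Brute-force oracle for grid charge enumeration: expand the full lattice
# over free symmetry groups and keep combinations matching the total charge.
brute_force_charge_count <- function(problem) {
  atoms <- problem$atoms
  groups <- unique(atoms$group)
  vals <- lapply(groups, function(g) {
    sub <- atoms[atoms$group == g, ][1, ]
    seq(ceiling(round(sub$q_min / problem$grid, 9)),
        floor(round(sub$q_max / problem$grid, 9)))
  })
  mult <- vapply(groups, function(g) sum(atoms$group == g), numeric(1))
  lattice <- expand.grid(vals)
  target <- round(problem$total_charge / problem$grid)
  sum(as.matrix(lattice) %*% mult == target)
}
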