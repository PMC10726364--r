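# rho and lambda descriptor geometry

test_that("rho is 1 for exact face-to-face stacking and follows the ratio orientation", {
  s <- stacked_rings(3.5)
  expect_identical(
    compute_rho(s$ring1["CG", ], s$ring2["CG", ],
                s$ring1["CZ", ], s$ring2["CZ", ]),
    1
  )
  # direct ratio: r_ipso = 6, r_para = 4 -> 1.5 (para closer than ipso)
  expect_equal(compute_rho(c(0, 0, 0), c(6, 0, 0), c(0, 1, 0), c(4, 1, 0)), 1.5)
  # coincident para carbons are degenerate input, not chemistry
  expect_error(compute_rho(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0)),
               "degenerate")
})

test_that("lambda handles anti, syn and wrapped negative torsions", {
  # coplanar anti (zig-zag): para atoms on opposite sides of the axis
  expect_equal(compute_lambda(c(-1, 1, 0), c(0, 0, 0), c(3, 0, 0), c(4, -1, 0)),
               180)
  # coplanar syn (eclipsed): same side
  expect_equal(compute_lambda(c(-1, 1, 0), c(0, 0, 0), c(3, 0, 0), c(4, 1, 0)),
               0)
  # signed torsion -90 wraps to 270; frozen from the plane-normal oracle
  q <- list(a = c(0, 1, 0), b = c(0, 0, 0), c = c(3, 0, 0), d = c(3, 0, -1))
  expect_equal(oracle_torsion(q$a, q$b, q$c, q$d), -90)
  expect_equal(compute_lambda(q$a, q$b, q$c, q$d), 270)
  expect_error(compute_lambda(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "degenerate")
})

test_that("lambda agrees with independent torsion oracles on random quadruples", {
  set.seed(101)
  for (i in 1:250) {
    q <- random_quadruple()
    expected <- oracle_torsion(q[1, ], q[2, ], q[3, ], q[4, ])
    got <- compute_lambda(q[1, ], q[2, ], q[3, ], q[4, ])
    expect_equal(got, wrap_360(expected), tolerance = 1e-9)
    # second, established implementation
    expect_equal(got, wrap_360(bio3d::torsion.xyz(as.vector(t(q)))),
                 tolerance = 1e-6)
  }
})

test_that("descriptors are invariant under rigid transforms and ring-swap maps lambda to 360 - lambda", {
  set.seed(7)
  for (i in 1:50) {
    q <- random_quadruple()
    rho0 <- compute_rho(q[2, ], q[3, ], q[1, ], q[4, ])
    lam0 <- compute_lambda(q[1, ], q[2, ], q[3, ], q[4, ])
    tr <- ringalign:::random_rigid_transform()
    qt <- ringalign:::apply_rigid(q, tr)
    expect_equal(compute_rho(qt[2, ], qt[3, ], qt[1, ], qt[4, ]), rho0,
                 tolerance = 1e-9)
    expect_equal(compute_lambda(qt[1, ], qt[2, ], qt[3, ], qt[4, ]), lam0,
                 tolerance = 1e-9)
    # swapping ring roles reverses the traversal, which leaves a proper
    # dihedral unchanged (the ring-order rule exists for reproducibility,
    # not because the value depends on it)
    lam_swap <- compute_lambda(q[4, ], q[3, ], q[2, ], q[1, ])
    expect_equal(lam_swap, lam0, tolerance = 1e-9)
  }
})

test_that("compute_series recovers the programmed lambda and rho and is rigid-invariant", {
  g <- tiny_ensemble(n_frames = 200, n_molecules = 3, seed = 11,
                     rho_program = 0.9)
  s <- compute_series(g$ensemble)
  expect_s3_class(s, "descriptor_table")
  expect_equal(nrow(s), 200 * 3)
  expect_equal(s$rho, s$r_ipso / s$r_para)
  expect_true(all(s$lam >= 0 & s$lam < 360))
  lm <- lambda_matrix(s)
  expect_equal(unname(lm), unname(g$truth$lambda), tolerance = 1e-6)
  expect_equal(max(abs(s$rho - 0.9)), 0, tolerance = 1e-9)

  # rigid transform of all coordinates leaves the series unchanged
  set.seed(5)
  tr <- ringalign:::random_rigid_transform()
  e2 <- g$ensemble
  flat <- matrix(e2$coords, ncol = 3)
  flat <- flat %*% t(tr$R) + matrix(tr$t, nrow(flat), 3, byrow = TRUE)
  e2$coords <- array(flat, dim = dim(e2$coords))
  s2 <- compute_series(e2)
  expect_equal(s2$rho, s$rho, tolerance = 1e-9)
  expect_equal(s2$lam, s$lam, tolerance = 1e-9)
})

test_that("constant conformations give constant series and TSV export round-trips", {
  g <- tiny_ensemble(n_frames = 10, p = 0, jitter_range = c(0, 0), seed = 1)
  s <- compute_series(g$ensemble)
  expect_equal(diff(range(s$rho)), 0, tolerance = 1e-12)
  expect_equal(diff(range(s$lam)), 0, tolerance = 1e-9)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_descriptor_tsv(s, path)
  back <- read.delim(path)
  expect_equal(back$lam, s$lam, tolerance = 1e-9)
})
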