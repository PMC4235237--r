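test_that("linear and constant fields are reproduced exactly", {
  b <- generate_box(3, 2, 2)
  phi <- solve_harmonic(b, dirichlet_spec(x0 = 0, x1 = 1))
  expect_equal(phi, b$nodes[, 1], tolerance = 1e-10)

  # constant seeds give the constant solution
  phic <- solve_harmonic(b, dirichlet_spec(x0 = 0.5, x1 = 0.5))
  expect_equal(phic, rep(0.5, nrow(b$nodes)), tolerance = 1e-12)

  # linear exactness persists under refinement
  for (n in c(1L, 4L)) {
    bn <- generate_box(n, n, n)
    pn <- solve_harmonic(bn, dirichlet_spec(x0 = 0, x1 = 1))
    expect_equal(pn, bn$nodes[, 1], tolerance = 1e-10)
  }
})

test_that("discrete maximum principle holds on quality fixtures", {
  b <- generate_box(4, 3, 3)
  phi <- solve_harmonic(b, dirichlet_spec(x0 = 0, x1 = 1))
  seeds <- c(b$node_sets$x0, b$node_sets$x1)
  interior <- setdiff(seq_len(nrow(b$nodes)), seeds)
  expect_true(all(phi[interior] > 0 & phi[interior] < 1))

  # unjittered proxy, end-cap seeds {0, 1}
  pm <- generate_proxy(proxy_params(edge_length = 2.5, jitter = 0))
  phi2 <- suppressMessages(
    solve_harmonic(pm, dirichlet_spec(end_cap_A = 0, end_cap_B = 1),
                   include_regions = c(1L, 2L, 3L, 9L)))
  seeds2 <- c(pm$node_sets$end_cap_A, pm$node_sets$end_cap_B)
  inner <- setdiff(which(!is.na(phi2)), seeds2)
  expect_gt(min(phi2[inner]), 0)
  expect_lt(max(phi2[inner]), 1)
})

test_that("the solution minimises the discrete Dirichlet energy", {
  b <- generate_box(2, 2, 2)
  phi <- solve_harmonic(b, dirichlet_spec(x0 = 0, x1 = 1))
  e0 <- orthobone:::dirichlet_energy(b, phi)
  seeds <- c(b$node_sets$x0, b$node_sets$x1)
  free <- setdiff(seq_len(nrow(b$nodes)), seeds)
  set.seed(8)
  for (rep in 1:10) {
    pert <- phi
    pert[free] <- pert[free] + rnorm(length(free), sd = 0.05)
    expect_gt(orthobone:::dirichlet_energy(b, pert), e0)
  }
})

test_that("element gradients match the closed-form P1 derivative", {
  b <- generate_box(2, 2, 2)
  g <- element_gradients(b, b$nodes[, 1])
  expect_equal(g, matrix(rep(c(1, 0, 0), each = nrow(b$tets)),
                         ncol = 3), tolerance = 1e-12)
  gz <- element_gradients(b, rep(3.7, nrow(b$nodes)))
  expect_lt(max(abs(gz)), 1e-12)

  # random P1 field on a random tet vs barycentric differentiation
  set.seed(21)
  nodes <- rbind(c(0, 0, 0), c(1.3, 0.2, 0), c(0.1, 1.1, 0.3),
                 c(0.4, 0.2, 0.9))
  mt <- tet_mesh(nodes, matrix(1:4, 1L))
  vals <- rnorm(4)
  # phi(x) = sum_a vals_a lambda_a(x); grad = t(A^-1 rows 2:4) vals
  A <- rbind(1, t(mt$nodes))
  L <- solve(A)                       # lambda_a = L[a, ] . (1, x)
  expected <- as.numeric(crossprod(L[, 2:4], vals))
  got <- as.numeric(element_gradients(mt, vals))
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("longitudinal field flows through the virtual fill", {
  mesh <- default_proxy()
  f_with <- default_fields(TRUE)
  f_without <- default_fields(FALSE)

  # virtual nodes get values only in the filled solve
  virt_nodes <- setdiff(
    unique(as.vector(mesh$tets[mesh$region == 9L, ])),
    unique(as.vector(mesh$tets[mesh$region %in% c(1L, 2L), ])))
  expect_true(all(!is.na(f_with$phi_long[virt_nodes])))
  expect_true(all(is.na(f_without$phi_long[virt_nodes])))

  # bone-node changes are localised around the notch: the peak change sits
  # in the notch neighbourhood and the far field sees under a tenth of it
  bone_nodes <- which(!is.na(f_without$phi_long))
  dchange <- abs(f_with$phi_long[bone_nodes] - f_without$phi_long[bone_nodes])
  gp <- attr(mesh, "proxy_params")
  theta <- gp$arc_angle * pi / 180
  sfrac <- atan2(mesh$nodes[bone_nodes, 2], mesh$nodes[bone_nodes, 1]) /
    theta + 0.5
  half <- (gp$notch_extent * pi / 180) / 2 / theta
  dist <- abs(sfrac - gp$notch_center)
  expect_equal(max(dchange[dist <= 3 * half]), max(dchange))
  far <- dist > 4 * half
  expect_lt(max(dchange[far]), 0.1 * max(dchange))

  # radial field is identical in both runs (solved on bone either way)
  expect_equal(f_with$phi_rad, f_without$phi_rad, tolerance = 1e-12)
})

test_that("degenerate Dirichlet problems are rejected", {
  b <- generate_box(1, 1, 1)
  expect_error(solve_harmonic(b, dirichlet_spec(nope = 1)), "unknown")
  expect_error(dirichlet_spec(), "named")

  # disconnected domain: two tets sharing no nodes
  nodes <- rbind(diag(3), c(0, 0, 0),
                 diag(3) + 10, c(10, 10, 10))
  tets <- rbind(c(4L, 1L, 2L, 3L), c(8L, 5L, 6L, 7L))
  m2 <- tet_mesh(nodes, tets, region = 1L,
                 node_sets = list(a = 1L, b = 5L))
  expect_error(solve_harmonic(m2, dirichlet_spec(a = 0, b = 1)),
               "disconnected")
})
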