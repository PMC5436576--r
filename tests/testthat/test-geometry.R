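# Exact and simplified helical-parameter equations, omega wrapping,
# same-type distances and helix radii.

test_that("wrap_omega maps into [delta, delta + 360) and is idempotent", {
  expect_equal(wrap_omega(350, -90), -10)
  expect_equal(wrap_omega(-180, -90), 180)
  expect_equal(wrap_omega(180, -90), 180)
  x <- seq(-720, 720, by = 37.5)
  w <- wrap_omega(x)
  expect_true(all(w >= -90 & w < 270))
  expect_equal(wrap_omega(w), w)
  expect_equal(wrap_omega(x, delta = 10), ((x - 10) %% 360) + 10)
  expect_error(wrap_omega(NaN), "finite")
  expect_error(wrap_omega(10, Inf), "finite")
})

test_that("backbone geometry validates and defaults to equilibrium values", {
  g <- backbone_geometry()
  expect_equal(unlist(g[c("v_n_alpha", "v_alpha_c", "v_c_n")]),
               c(v_n_alpha = 1.459, v_alpha_c = 1.525, v_c_n = 1.336))
  expect_equal(unlist(g[c("sigma_n", "sigma_alpha", "sigma_c")]),
               c(sigma_n = 121.7, sigma_alpha = 111.0, sigma_c = 117.2))
  expect_error(backbone_geometry(v_n_alpha = -1), "positive")
  expect_error(backbone_geometry(sigma_n = 180), "inside")
  expect_error(backbone_geometry(sigma_c = NA), "finite")
})

test_that("dihedral_state wraps omega and phi/psi into the declared frame", {
  st <- dihedral_state(-57, -47, -180)
  expect_equal(st$omega, 180)
  st2 <- dihedral_state(190, -200, 180, frame = -180)
  expect_equal(st2$phi, -170)
  expect_equal(st2$psi, 160)
  st3 <- dihedral_state(-100, -100, 180, frame = 0)
  expect_equal(c(st3$phi, st3$psi), c(260, 260))
  expect_error(dihedral_state(0, 0, frame = 90), "frame")
})

test_that("exact equations reproduce reference helical parameters", {
  # ideal right-handed alpha helix: ~3.6 residues/turn, ~1.5 A rise
  hp <- helical_params_exact(-57, -47, 180)
  expect_equal(hp$theta, 99.3711852325, tolerance = 1e-9)
  expect_equal(hp$d, 1.5621836479, tolerance = 1e-9)
  expect_equal(360 / hp$theta, 3.62, tolerance = 0.01)
  # phi = psi = -100: compressed left-handed helix, negative rise
  hp2 <- helical_params_exact(-100, -100, 180)
  expect_equal(hp2$theta, 71.6163905961, tolerance = 1e-9)
  expect_equal(hp2$d, -2.0137278494, tolerance = 1e-9)
  # dihedral_state input form agrees with the raw-number form
  expect_equal(helical_params_exact(dihedral_state(-57, -47, 180)), hp)
})

test_that("mirror antisymmetry: (-phi,-psi,-omega) gives (-d, theta)", {
  g <- expand.grid(phi = seq(-180, 180, 15), psi = seq(-180, 180, 15))
  for (om in c(0, -60, 60, -120, 120, 180)) {
    a <- helical_params_exact(g$phi, g$psi, om)
    b <- helical_params_exact(-g$phi, -g$psi, -om)
    expect_lt(max(abs(a$d + b$d)), 1e-9)
    expect_lt(max(abs(a$theta - b$theta)), 1e-9)
  }
})

test_that("degenerate and out-of-range cos(theta/2) are signalled", {
  expect_error(peptwist:::dtheta_from_rhs(1, 0.5), "degenerate")
  expect_error(peptwist:::dtheta_from_rhs(-1, 0.5), "degenerate")
  expect_error(peptwist:::dtheta_from_rhs(1 + 1e-10, 0.5), "1e-12")
  # within clamp tolerance: clamps instead of erroring
  expect_error(peptwist:::dtheta_from_rhs(1 + 1e-13, 0), "degenerate")
})

test_that("simplified forms evaluate the published coefficients verbatim", {
  # trans, phi = psi = 90: both sine terms collapse to the first coefficient
  hp <- helical_params_simplified(90, 90, "trans")
  expect_equal(cos(hp$theta / 2 * pi / 180), -0.8235, tolerance = 1e-12)
  # trans, phi = psi = 0: flat extended zig-zag, d is the coefficient sum
  hp0 <- helical_params_simplified(0, 0, "trans")
  expect_equal(hp0$theta, 180)
  expect_equal(hp0$d, 2.3411, tolerance = 1e-12)
  # cis, phi = psi = 0
  hpc <- helical_params_simplified(0, 0, "cis")
  expect_equal(cos(hpc$theta / 2 * pi / 180), 0.4052 - 0.4932,
               tolerance = 1e-12)
})

test_that("simplified forms agree with exact equations at default geometry", {
  g <- expand.grid(phi = seq(-180, 180, 2), psi = seq(-180, 180, 2))
  geom <- backbone_geometry()
  for (m in c("trans", "cis")) {
    om <- if (m == "trans") 180 else 0
    ex_x <- peptwist:::cos_half_theta_rhs(g$phi, g$psi, om, geom)
    ex_y <- peptwist:::d_sin_half_theta_rhs(g$phi, g$psi, om, geom)
    k <- peptwist:::.simplified_published[[m]]
    s <- (g$phi + g$psi) * pi / 360
    t <- (g$phi - g$psi) * pi / 360
    if (m == "trans") {
      sx <- k$theta[1] * sin(s) + k$theta[2] * sin(t)
      sy <- k$d[1] * cos(s) + k$d[2] * cos(t)
    } else {
      sx <- k$theta[1] * cos(s) + k$theta[2] * cos(t)
      sy <- k$d[1] * sin(s) + k$d[2] * sin(t)
    }
    expect_lt(max(abs(sx - ex_x)), 2e-3)
    expect_lt(max(abs(sy - ex_y)), 2e-3)
  }
})

test_that("no trans conformation approaches theta = 0", {
  g <- expand.grid(phi = seq(-180, 180, 2), psi = seq(-180, 180, 2))
  x <- peptwist:::cos_half_theta_rhs(g$phi, g$psi, 180, backbone_geometry())
  expect_lt(max(x), 0.846)
})

test_that("coefficient derivation recovers all printed values to 4 decimals", {
  tr <- derive_simplified_coefficients(180)
  expect_equal(round(as.numeric(tr), 4), c(-0.8235, 0.0222, 2.9986, -0.6575))
  ci <- derive_simplified_coefficients(0)
  expect_equal(round(as.numeric(ci), 4), c(0.4052, -0.4932, 2.3093, 0.0028))
  expect_equal(unname(attr(tr, "basis")), c("sin", "cos"))
  expect_equal(unname(attr(ci, "basis")), c("cos", "sin"))
  # equal flanking bond angles kill the cross term of the trans cosine form
  sym <- derive_simplified_coefficients(
    180, backbone_geometry(sigma_n = 119, sigma_c = 119))
  expect_equal(unname(sym["b_cos"]), 0, tolerance = 1e-12)
  # a two-term reduction only exists for cis/trans omega
  expect_error(derive_simplified_coefficients(90), "omega")
  # derived coefficients reproduce the exact field, not just the table
  co <- derive_simplified_coefficients(180)
  g <- expand.grid(phi = seq(-170, 170, 35), psi = seq(-170, 170, 35))
  s <- (g$phi + g$psi) * pi / 360
  t <- (g$phi - g$psi) * pi / 360
  expect_equal(co[["a_cos"]] * sin(s) + co[["b_cos"]] * sin(t),
               peptwist:::cos_half_theta_rhs(g$phi, g$psi, 180,
                                             backbone_geometry()),
               tolerance = 1e-12)
  expect_equal(co[["a_d"]] * cos(s) + co[["b_d"]] * cos(t),
               peptwist:::d_sin_half_theta_rhs(g$phi, g$psi, 180,
                                               backbone_geometry()),
               tolerance = 1e-12)
})

test_that("same-type distances match reference values and wrap correctly", {
  tr <- same_type_distance(list(phi = 0, psi = 0, omega = 180))
  expect_equal(tr, 3.819233, tolerance = 1e-6)
  expect_equal(round(tr, 1), 3.8)
  ci <- same_type_distance(list(phi = 0, psi = 0, omega = 0))
  expect_equal(ci, 2.802099, tolerance = 1e-6)
  expect_equal(round(ci), 3)
  expect_equal(same_type_distance(list(phi = 0, psi = 0, omega = -180)), tr)
  # subscript cycling: each type's distance matches the built chain
  st <- dihedral_state(-70, 150, 170)
  ch <- build_regular(4, st)
  for (tp in c("n", "alpha", "c")) {
    atoms <- ch$xyz[peptwist:::atom_rows(ch, c(n = "N", alpha = "CA",
                                               c = "C")[[tp]]), ]
    expect_equal(same_type_distance(st, atom_type = tp),
                 sqrt(sum((atoms[2, ] - atoms[1, ])^2)), tolerance = 1e-9)
  }
})

test_that("helix radii satisfy the distance identity and handle edge cases", {
  st <- dihedral_state(-57, -47, 180)
  rho <- helix_radii(st)
  expect_equal(unname(rho["rho_alpha"]), 2.285313, tolerance = 1e-5)
  # identity: 2 rho^2 (1 - cos theta) + d^2 = d_alpha^2 across a grid
  g <- expand.grid(phi = seq(-180, 180, 10), psi = seq(-180, 180, 10))
  hp <- helical_params_exact(g$phi, g$psi, 180)
  da <- same_type_distance(list(phi = 0, psi = 0, omega = 180))
  rho2 <- (da^2 - hp$d^2) / (2 - 2 * cos(hp$theta * pi / 180))
  lhs <- 2 * rho2 * (1 - cos(hp$theta * pi / 180)) + hp$d^2
  expect_lt(max(abs(lhs - da^2) / da^2), 1e-9)
  expect_true(all(rho2 > -1e-9))
  # d = d_alpha at theta = 180 gives a zero alpha radius
  expect_equal(unname(helix_radii(st, d = da, theta = 180,
                                  types = "alpha")), 0)
  # an inconsistent (d, theta) pair is refused
  expect_error(helix_radii(st, d = 10, theta = 180), "inconsistent")
})

test_that("helical_params wrapper combines d, theta, radii and handedness", {
  hp <- helical_params(dihedral_state(-57, -47, 180))
  expect_s3_class(hp, "helical_params")
  expect_equal(hp$h, 0.9866541755, tolerance = 1e-8)
  expect_equal(hp$region, "right")
  hps <- helical_params(dihedral_state(-57, -47, 180), mode = "simplified")
  expect_equal(hps$d, hp$d, tolerance = 5e-3)
  expect_error(helical_params(dihedral_state(0, 0, 90), mode = "simplified"),
               "omega")
})
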