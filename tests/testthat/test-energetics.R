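make_param_table <- function(s, charge = 0, rmin_half = 1.7, epsilon = 0.1,
                             born = 1.5, screen = 0.8) {
  a <- s$atoms
  df <- data.frame(chain = a$chain, resno = a$resno, atom = a$name,
                   charge = rep_len(charge, nrow(a)),
                   rmin_half = rep_len(rmin_half, nrow(a)),
                   epsilon = rep_len(epsilon, nrow(a)),
                   born_radius = rep_len(born, nrow(a)),
                   screen = rep_len(screen, nrow(a)), stringsAsFactors = FALSE)
  class(df) <- c("ff_parameters", "data.frame")
  df
}

two_atom_complex <- function(d) {
  mk_complex(mk_structure("CB", "ALA", "D", 1, 0, 0, 0),
             mk_structure("CB", "ALA", "C", 1, d, 0, 0))
}

test_that("MM interaction matches Coulomb and Lennard-Jones closed forms", {
  ann <- mk_annotation()
  s <- two_atom_complex(3.320637)
  p <- make_param_table(s, charge = 1, epsilon = 0)
  e <- mm_interaction_energy(s, p, ann)
  expect_equal(e$E_elec, 100.0, tolerance = 1e-6)

  # at r = rmin the well depth is -sqrt(eps_i eps_j)
  s <- two_atom_complex(3.4)
  p <- make_param_table(s, charge = 0, rmin_half = 1.7)
  p$epsilon <- c(0.16, 0.09)
  e <- mm_interaction_energy(s, p, ann)
  expect_equal(e$E_vdw, -sqrt(0.16 * 0.09), tolerance = 1e-10)

  # clashing atoms are rejected
  expect_error(mm_interaction_energy(two_atom_complex(0.05),
                                     make_param_table(two_atom_complex(0.05)),
                                     ann), "overlap")
})

test_that("MM interaction equals a direct double-loop oracle", {
  set.seed(19)
  n <- 25
  sa <- mk_structure("CB", "ALA", "D", 1:n, runif(n, 0, 10), runif(n, 0, 10),
                     runif(n, 5, 12))
  sb <- mk_structure("CB", "ALA", "C", 1:n, runif(n, 0, 10), runif(n, 0, 10),
                     runif(n, -7, 0))
  s <- mk_complex(sa, sb)
  p <- make_param_table(s)
  p$charge <- runif(2 * n, -0.5, 0.5)
  p$rmin_half <- runif(2 * n, 1.5, 2)
  p$epsilon <- runif(2 * n, 0.05, 0.2)
  got <- mm_interaction_energy(s, p, mk_annotation())

  ee <- 0; ev <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      pi_ <- p[i, ]; pj <- p[j + n, ]      # rows 1..n are the TCR side
      ai <- s$atoms[i, ]; aj <- s$atoms[j + n, ]
      r <- sqrt((ai$x - aj$x)^2 + (ai$y - aj$y)^2 + (ai$z - aj$z)^2)
      ee <- ee + 332.0637 * pi_$charge * pj$charge / r
      rm <- pi_$rmin_half + pj$rmin_half
      ev <- ev + sqrt(pi_$epsilon * pj$epsilon) * ((rm / r)^12 - 2 * (rm / r)^6)
    }
  }
  expect_equal(got$E_elec, ee, tolerance = 1e-8)
  expect_equal(got$E_vdw, ev, tolerance = 1e-8)
})

test_that("generalized Born reproduces the Born ion and a two-charge oracle", {
  ion <- mk_structure("CB", "ALA", "C", 1, 0, 0, 0)
  ann <- mk_annotation()
  p <- make_param_table(ion, charge = 1, born = 2.09)  # intrinsic radius 2.0
  cfg0 <- energetics_config(salt_molar = 0)
  g <- gb_polar_energy(ion, p, cfg0)
  expect_equal(g$effective_radii, 2.0, tolerance = 1e-12)
  born_exact <- -(332.0637 / 2) * (1 - 1 / 78.5) / 2.0
  expect_equal(g$G_pol, born_exact, tolerance = 1e-6)

  # zero charge means zero polar energy
  p0 <- make_param_table(ion, charge = 0)
  expect_equal(gb_polar_energy(ion, p0, cfg0)$G_pol, 0)

  # two charges: independent scalar re-implementation of the same model
  s2 <- two_atom_complex(4.0)
  p2 <- make_param_table(s2, born = 1.7, screen = 0.8)
  p2$charge <- c(0.5, -0.5)
  cfg <- energetics_config(salt_molar = 0.15)
  got <- gb_polar_energy(s2, p2, cfg)

  rho <- 1.7 - 0.09; r <- 4.0; sr <- 0.8 * rho
  hct <- function() {
    U <- r + sr; L <- max(abs(r - sr), rho)
    0.5 * (1 / L - 1 / U + (r - sr^2 / r) * (1 / U^2 - 1 / L^2) / 4 +
             log(L / U) / (2 * r))
  }
  psi <- rho * hct()
  Reff <- 1 / (1 / rho - tanh(psi - 0.8 * psi^2 + 4.85 * psi^3) / 1.7)
  kappa <- sqrt(0.15) / 3.047
  fgb <- function(d, Ri, Rj) sqrt(d^2 + Ri * Rj * exp(-d^2 / (4 * Ri * Rj)))
  term <- function(d, qi, qj, Ri, Rj) {
    f <- fgb(d, Ri, Rj)
    -(332.0637 / 2) * (1 - exp(-kappa * f) / 78.5) * qi * qj / f
  }
  want <- term(0, 0.5, 0.5, Reff, Reff) + term(0, -0.5, -0.5, Reff, Reff) +
    2 * term(4, 0.5, -0.5, Reff, Reff)
  expect_equal(got$G_pol, want, tolerance = 1e-8)
})

test_that("salt screening strengthens G_pol monotonically and continuously", {
  ion <- mk_structure("CB", "ALA", "C", 1, 0, 0, 0)
  p <- make_param_table(ion, charge = 1, born = 2.09)
  g <- function(salt) gb_polar_energy(ion, p, energetics_config(salt_molar = salt))$G_pol
  expect_lt(g(0.15), g(0))
  expect_lt(g(0.5), g(0.15))
  expect_equal(g(1e-12), g(0), tolerance = 1e-8)
})

test_that("nonpolar term follows gamma * SASA and the burial identity", {
  ion <- mk_structure("CB", "ALA", "C", 1, 0, 0, 0)
  expect_equal(nonpolar_energy(ion, energetics_config(gamma_np = 0))$G_np, 0)
  got <- nonpolar_energy(ion, energetics_config(sasa_points = 960))
  expect_equal(got$G_np, 0.0072 * 4 * pi * 3.1^2, tolerance = 0.01)

  # complex minus parts equals -gamma * BSASA at matched quadrature
  s <- mk_docked_mini()
  cfg <- energetics_config(sasa_points = 240)
  tcr <- c("D", "E"); phla <- c("C", "A", "B")
  dnp <- nonpolar_energy(s, cfg)$G_np -
    nonpolar_energy(s, cfg, chains = phla)$G_np -
    nonpolar_energy(s, cfg, chains = tcr)$G_np
  bs <- compute_bsasa(s, mk_annotation(), n_points = 240)
  expect_equal(dnp, -0.0072 * bs, tolerance = 1e-9)
})

test_that("binding estimate is stable, translation invariant and averages snapshots", {
  s <- mk_docked_mini()
  ann <- mk_annotation()
  p <- make_param_table(s)
  p$charge <- rep_len(c(0.3, -0.3), nrow(p))
  be1 <- mmgbsa_binding(s, p, ann)
  be3 <- mmgbsa_binding(list(s, s, s), p, ann)
  expect_equal(be3$dG_bind, be1$dG_bind)
  expect_equal(be3$sd, 0)
  expect_equal(be3$n_snapshots, 3L)

  shifted <- shift_chains(s, unique(s$atoms$chain), dx = 11, dy = -4, dz = 7)
  be2 <- mmgbsa_binding(shifted, p, ann)
  expect_equal(be2$dG_bind, be1$dG_bind, tolerance = 1e-9)

  expect_error(mmgbsa_binding(list(), p, ann), "empty|must be")
})

test_that("per-residue decomposition conserves the total and localises charge", {
  ann <- mk_annotation()
  for (seed in 1:2) {
    s <- mk_docked_mini()
    set.seed(seed)
    p <- make_param_table(s)
    p$charge <- runif(nrow(p), -0.5, 0.5)
    p$born_radius <- runif(nrow(p), 1.3, 2.0)
    be <- mmgbsa_binding(s, p, ann)
    d <- decompose_per_residue(s, p, ann)
    expect_equal(sum(d$total), be$dG_bind, tolerance = 1e-6)
  }

  # only one cross-interface pair carries charge: the electrostatic part
  # lands half on each partner residue
  s <- mk_docked_mini()
  p <- make_param_table(s, charge = 0, epsilon = 0)
  p$charge[p$chain == "C" & p$resno == 5] <- 0.5
  p$charge[p$chain == "D" & p$resno == 8] <- -0.5
  d <- decompose_per_residue(s, p, ann)
  elec <- d$elec
  nonzero <- which(abs(elec) > 1e-12)
  expect_setequal(paste(d$chain[nonzero], d$resno[nonzero]), c("C 5", "D 8"))
  expect_equal(elec[d$chain == "C" & d$resno == 5],
               elec[d$chain == "D" & d$resno == 8], tolerance = 1e-12)

  # permuting atom order leaves the table content unchanged
  s2 <- s
  set.seed(3)
  perm <- sample(nrow(s2$atoms))
  s2$atoms <- s2$atoms[perm, ]
  d2 <- decompose_per_residue(s2, p, ann)
  k1 <- paste(d$chain, d$resno); k2 <- paste(d2$chain, d2$resno)
  expect_setequal(k2, k1)
  expect_equal(d2$total[match(k1, k2)], d$total, tolerance = 1e-9)
})

test_that("ddG classification applies the 0.5 kcal/mol threshold bands", {
  mk_table <- function(total, resname = "ALA") {
    df <- data.frame(chain = "D", resno = seq_along(total),
                     resname = rep_len(resname, length(total)),
                     vdw = 0, elec = 0, gb = 0, np = 0, total = total,
                     stringsAsFactors = FALSE)
    class(df) <- c("per_residue_energy", "data.frame")
    df
  }
  wt <- mk_table(c(0, 0, 0, 0))
  va <- mk_table(c(-1.0, 0.2, 0.7, 0.5))
  cl <- classify_ddg(wt, va)
  expect_equal(cl$label, c("favorable", "neutral", "unfavorable", "unfavorable"))

  cl0 <- classify_ddg(wt, wt)
  expect_true(all(cl0$label == "neutral") && all(cl0$ddG == 0))

  # threshold zero leaves no neutral class for nonzero differences
  clz <- classify_ddg(wt, mk_table(c(-0.1, 0.1, -2, 2)), threshold = 0)
  expect_false(any(clz$label == "neutral"))

  # mutated positions are flagged
  vam <- mk_table(c(0, 0, 0, 0), resname = c("ALA", "TRP", "ALA", "ALA"))
  expect_equal(classify_ddg(wt, vam)$mutation_site, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("affinity conversions reproduce the MEL5 fold change and ddG", {
  expect_equal(fold_change(18000, 0.61), 29508.2, tolerance = 1e-4)
  expect_equal(ddg_exp(18000, 0.61), 0.0019872 * 298.15 * log(0.61 / 18000),
               tolerance = 1e-10)
  expect_equal(ddg_exp(18000, 0.61), -6.10, tolerance = 0.01)
  expect_equal(fold_change(5, 5), 1)
  expect_equal(ddg_exp(5, 5), 0)
  expect_equal(kd_to_dg(1e9), 0)          # 1 M reference state
  expect_lt(kd_to_dg(13300), 0)
  expect_error(kd_to_dg(-1), "positive")
  expect_error(fold_change(0, 1), "positive")
})

test_that("rank agreement counts sign matches and matches a rank oracle", {
  x <- c(-3, -2, -1, -4)
  expect_equal(rank_correlation(x, x)$sign_agreement, 1)
  expect_equal(rank_correlation(x, x)$spearman_rho, 1)
  y <- x; y[2] <- 2
  expect_equal(rank_correlation(x, y)$n_agree, 3L)
  set.seed(14)
  a <- rnorm(10); b <- rnorm(10)
  got <- rank_correlation(a, b)
  expect_equal(got$spearman_rho, cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_error(rank_correlation(1:3, 1:4), "length")
})

test_that("parameter and affinity tables read back faithfully", {
  s <- mk_docked_mini()
  p <- make_param_table(s)
  tf <- tempfile(fileext = ".txt")
  writeLines(c("# toy parameter set",
               paste(c("chain", "resno", "atom", "charge", "rmin_half",
                       "epsilon", "born_radius", "screen"), collapse = " "),
               do.call(paste, c(unclass(p)[c("chain", "resno", "atom", "charge",
                                             "rmin_half", "epsilon",
                                             "born_radius", "screen")]))), tf)
  back <- read_parameters(tf)
  expect_equal(nrow(back), nrow(p))
  expect_equal(back$charge, p$charge)
  bad <- tempfile(); writeLines("chain resno atom", bad)
  expect_error(read_parameters(bad), "lacks column")

  aff <- read_affinities(system.file("extdata", "tcr_affinities.csv",
                                     package = "tcrlens"))
  expect_equal(nrow(aff), 17L)
  mel5 <- aff[aff$group == "MEL5-A2-ELA", ]
  expect_equal(fold_change(mel5$kd_nM[mel5$type == "wild-type"],
                           mel5$kd_nM[mel5$type == "variant"]),
               29508.2, tolerance = 1e-4)
  # where both rates exist the kinetic K_D roughly agrees with the reported one
  ok <- !is.na(aff$kd_kinetic_ratio)
  expect_true(all(aff$kd_kinetic_ratio[ok] > 0.25 & aff$kd_kinetic_ratio[ok] < 4))
})
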