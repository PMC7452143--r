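# a small non-degenerate chain for ensemble fixtures
mk_wiggly_chain <- function(n = 20, seed = 5) {
  base <- make_toy_chain(n)
  set.seed(seed)
  base$atoms$y <- rnorm(n, 0, 2)
  base$atoms$z <- rnorm(n, 0, 2)
  base
}

test_that("alignment removes rigid-body motion and is idempotent", {
  base <- mk_wiggly_chain()
  co0 <- as.vector(t(as.matrix(base$atoms[, c("x", "y", "z")])))
  set.seed(13)
  frames <- t(vapply(1:8, function(f) {
    R <- random_rotation(); tr <- rnorm(3, 0, 10)
    co <- as.matrix(base$atoms[, c("x", "y", "z")]) %*% t(R)
    as.vector(t(sweep(co, 2, tr, "+")))
  }, numeric(length(co0))))
  e <- trajectory_ensemble(base, list(frames[1:4, ], frames[5:8, ]),
                           burn_in_fraction = 0)
  al <- align_frames(e)
  all_fr <- do.call(rbind, al$replicas)
  spread <- apply(all_fr, 2, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-6)

  al2 <- align_frames(al)
  expect_lt(max(abs(do.call(rbind, al2$replicas) - all_fr)), 1e-6)

  expect_error(align_frames(e, resno = 999), "empty")
})

test_that("RMSF is zero for static ensembles and recovers sigma sqrt(3)", {
  base <- mk_wiggly_chain()
  e0 <- make_ensemble(base, replicas = 3, frames = 10, sigma = 0)
  expect_equal(max(compute_rmsf(e0)$rmsf), 0)

  e1 <- make_ensemble(base, replicas = 10, frames = 1000, sigma = 0.3, seed = 8)
  r1 <- compute_rmsf(e1)
  expect_equal(mean(r1$mean), 0.3 * sqrt(3), tolerance = 0.05)

  # doubling sigma doubles the fluctuation
  e2 <- make_ensemble(base, replicas = 10, frames = 1000, sigma = 0.6, seed = 8)
  r2 <- compute_rmsf(e2)
  expect_equal(mean(r2$mean) / mean(r1$mean), 2, tolerance = 0.05)

  # burn-in on a stationary ensemble does not shift the estimate
  e3 <- e1; e3$burn_in_fraction <- 0.10
  expect_equal(mean(compute_rmsf(e3)$mean), mean(r1$mean), tolerance = 0.02)

  # single-frame replicas cannot define a fluctuation
  es <- make_ensemble(base, replicas = 2, frames = 1, sigma = 0.1)
  expect_error(compute_rmsf(es), "fewer than 2")
})

test_that("flexibility comparison flags planted effects and nothing on itself", {
  base <- mk_wiggly_chain(30)
  resnos <- base$atoms$resno
  e <- make_ensemble(base, replicas = 4, frames = 50, sigma = 0.3, seed = 2)
  same <- compare_rmsf(e, e)
  expect_equal(max(abs(same$delta_rmsf)), 0)
  expect_equal(sum(same$significant), 0L)

  sig_var <- ifelse(resnos %in% 10:15, 0.6, 0.3)
  ew <- make_ensemble(base, replicas = 10, frames = 400, sigma = 0.3, seed = 3)
  ev <- make_ensemble(base, replicas = 10, frames = 400, sigma = sig_var, seed = 4)
  fc <- compare_rmsf(ew, ev)
  expect_true(all(fc$significant[fc$resno %in% 10:15]))
  expect_true(all(fc$delta_rmsf[fc$resno %in% 10:15] > 0.3))

  # Welch and pooled flavours agree on a planted effect this strong
  fp <- compare_rmsf(ew, ev, var_equal = TRUE)
  expect_equal(fp$significant[fp$resno %in% 10:15],
               fc$significant[fc$resno %in% 10:15])

  expect_error(compare_rmsf(make_ensemble(base, replicas = 1, frames = 5), e),
               "replicas")
})

test_that("frame-averaged contacts equal the static map and count fractions", {
  toy <- make_toy_complex(45, planted_contacts = list(
    list(type = "HB", target = "peptide", tcr_chain = "alpha", distance = 2.9),
    list(type = "vdW", target = "HLA", tcr_chain = "beta", distance = 3.6)))
  s <- toy$structure; a <- toy$annotation
  static_map <- per_residue_contact_map(find_contacts(s, a))

  xyz <- as.vector(t(as.matrix(s$atoms[, c("x", "y", "z")])))
  e_static <- trajectory_ensemble(s, list(rbind(xyz, xyz), rbind(xyz, xyz)),
                                  burn_in_fraction = 0)
  avg <- average_contacts(e_static, a)
  expect_equal(avg$mean_vdw, as.numeric(static_map$n_vdw))
  expect_equal(avg$mean_hb, as.numeric(static_map$n_hb))

  # a contact present in one of two frames averages to 0.5
  idx <- which(s$atoms$chain == "D" & s$atoms$name == "N")   # planted donor
  xyz_off <- xyz
  xyz_off[(3 * idx - 2):(3 * idx)] <- xyz_off[(3 * idx - 2):(3 * idx)] + c(0, 0, 30)
  e_half <- trajectory_ensemble(s, list(rbind(xyz, xyz_off)), burn_in_fraction = 0)
  avg2 <- average_contacts(e_half, a)
  pep_row <- avg2$target == "peptide"
  expect_equal(avg2$mean_vdw[pep_row], 0.5)

  # replica order never matters
  e_sw <- e_half; e_sw$replicas <- rev(e_sw$replicas)
  expect_equal(average_contacts(e_sw, a), avg2)

  # jittered frames match a frame-by-frame oracle
  ej <- make_ensemble(s, replicas = 2, frames = 4, sigma = 0.05, seed = 6)
  got <- average_contacts(ej, a)
  maps <- list()
  for (k in 1:2) for (f in 1:4) {
    sf <- s
    co <- matrix(ej$replicas[[k]][f, ], ncol = 3, byrow = TRUE)
    sf$atoms$x <- co[, 1]; sf$atoms$y <- co[, 2]; sf$atoms$z <- co[, 3]
    maps[[length(maps) + 1L]] <- per_residue_contact_map(find_contacts(sf, a))
  }
  all_res <- unique(do.call(rbind, maps)[, c("target", "tgt_chain", "tgt_resno")])
  key <- function(m) paste(m$target, m$tgt_chain, m$tgt_resno)
  want_v <- rowMeans(vapply(maps, function(m) {
    v <- m$n_vdw[match(key(all_res), key(m))]
    ifelse(is.na(v), 0, v)
  }, numeric(nrow(all_res))))
  got_v <- got$mean_vdw[match(key(all_res), key(got))]
  expect_equal(sort(got_v), sort(want_v))
})

test_that("hydrogen-bond occupancy counts frames below the cutoff", {
  don <- mk_structure("N", "GLY", "D", 1, 0, 0, 2.9)
  acc <- mk_structure("O", "ALA", "C", 1, 0, 0, 0)
  s <- mk_complex(don, acc)
  pairs <- data.frame(donor_chain = "D", donor_resno = 1, donor_atom = "N",
                      acceptor_chain = "C", acceptor_resno = 1,
                      acceptor_atom = "O", stringsAsFactors = FALSE)
  xyz <- as.vector(t(as.matrix(s$atoms[, c("x", "y", "z")])))
  xyz_far <- xyz; xyz_far[3] <- 4.0
  e1 <- trajectory_ensemble(s, list(rbind(xyz, xyz, xyz, xyz)), burn_in_fraction = 0)
  expect_equal(hb_occupancy(e1, pairs)$pooled, 1.0)
  e2 <- trajectory_ensemble(s, list(rbind(xyz, xyz_far, xyz, xyz_far)),
                            burn_in_fraction = 0)
  expect_equal(hb_occupancy(e2, pairs)$pooled, 0.5)

  # stochastic two-state switching recovers the bound probability
  hb <- data.frame(chain = "D", resno = 1, atom = "N",
                   partner_chain = "C", partner_resno = 1, partner_atom = "O",
                   p_bound = 0.7, stringsAsFactors = FALSE)
  e3 <- make_ensemble(s, replicas = 5, frames = 400, sigma = 0, hb_pairs = hb,
                      seed = 12)
  occ <- hb_occupancy(e3, pairs)
  expect_equal(occ$pooled, 0.7, tolerance = 0.05)

  bad <- pairs; bad$donor_atom <- "ZZ"
  expect_error(hb_occupancy(e1, bad), "not found")
})

test_that("frame-averaged burial reduces to the static value and mixes linearly", {
  s <- mk_docked_mini()
  ann <- mk_annotation()
  b_static <- compute_bsasa(s, ann, n_points = 240)
  xyz <- as.vector(t(as.matrix(s$atoms[, c("x", "y", "z")])))
  e <- trajectory_ensemble(s, list(rbind(xyz, xyz), rbind(xyz, xyz)),
                           burn_in_fraction = 0)
  ab <- average_bsasa(e, ann, n_points = 240)
  expect_equal(ab$mean, b_static)
  expect_equal(ab$sd, 0)

  # mixture of a docked and a separated conformation averages the burials
  s_far <- shift_chains(s, c("D", "E"), dz = 60)
  xyz_far <- as.vector(t(as.matrix(s_far$atoms[, c("x", "y", "z")])))
  em <- trajectory_ensemble(s, list(rbind(xyz, xyz_far)), burn_in_fraction = 0)
  abm <- average_bsasa(em, ann, n_points = 240)
  expect_equal(abm$mean, b_static / 2, tolerance = 1e-6)
})
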