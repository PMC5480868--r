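test_that("RMSF vanishes on rigid motion and matches isotropic noise", {
  toy <- get_toy()
  st <- toy$structure
  flat <- riborigid:::structure_xyz(st)

  # identical frames
  ens0 <- read_ensemble(st, matrix(rep(flat, 3), nrow = 3, byrow = TRUE))
  expect_lt(max(rmsf(ens0)$rmsf), 1e-10)

  # rigid rotations/translations are removed by fitting
  ens_r <- simulate_trajectory(st, n_frames = 6, seed = 31, sigma = 0,
                               global_motion = TRUE)
  expect_lt(max(rmsf(ens_r)$rmsf), 1e-8)

  # isotropic Gaussian jitter: per-atom RMSF -> sigma * sqrt(3)
  sig <- 0.4
  ens <- simulate_trajectory(st, n_frames = 80, seed = 32, sigma = sig)
  pr <- rmsf(ens)
  expect_lt(abs(mean(pr$rmsf) - sig * sqrt(3)) / (sig * sqrt(3)), 0.05)

  expect_error(rmsf(ens, fit_selection = integer()), "empty")
})

test_that("core selection takes the least-fluctuating fraction", {
  toy <- get_toy()
  ens <- simulate_trajectory(toy$structure, n_frames = 12, seed = 33,
                             sigma = 0.3)
  pr <- rmsf(ens)
  core <- select_core(pr)
  expect_length(core, 54)  # round(0.8 * 67)
  expect_true(all(core %in% pr$resid))
  expect_length(select_core(pr, fraction = 1), 67)
  expect_error(select_core(pr, fraction = 0), "fraction")
  expect_error(select_core(pr, fraction = 1.2), "fraction")

  # ties at the cut keep the lower nucleotide id
  pr_tie <- pr
  pr_tie$rmsf <- rep(1, nrow(pr_tie))
  core_tie <- select_core(pr_tie, fraction = 0.5)
  expect_equal(as.integer(core_tie), sort(pr$resid)[1:round(0.5 * 67)])
})

test_that("RMSD is zero under rigid transforms and matches hand arithmetic", {
  toy <- get_toy()
  st <- toy$structure
  flat <- riborigid:::structure_xyz(st)
  shifted <- flat + rep(c(3, 0, 0), nrow(st$atoms))
  ens <- read_ensemble(st, rbind(flat, flat, shifted))
  rs <- rmsd_series(ens)
  expect_equal(rs$rmsd[1], 0, tolerance = 1e-10)
  expect_lt(rs$rmsd[3], 1e-10)

  # hand-computed: fit on all atoms but two, displace those two
  sel_fit <- seq_len(nrow(st$atoms) - 2)
  sel_meas <- nrow(st$atoms) - c(1, 0)
  moved <- flat
  moved[3 * (sel_meas[1] - 1) + 1] <- moved[3 * (sel_meas[1] - 1) + 1] + 1
  moved[3 * (sel_meas[2] - 1) + 1] <- moved[3 * (sel_meas[2] - 1) + 1] + 2
  ens2 <- read_ensemble(st, rbind(flat, moved))
  rs2 <- rmsd_series(ens2, fit_selection = sel_fit,
                     measure_selection = sel_meas)
  # the fit moves the frame slightly; tolerance reflects that
  expect_equal(rs2$rmsd[2], sqrt((1 + 4) / 2), tolerance = 0.02)
})

test_that("radius of gyration matches its definition and invariances", {
  tab <- tibble::tibble(serial = 1:3, name = "C1'", resid = 1:3,
                        resname = "A", chain = "A",
                        x = c(0, 1, 2), y = 0, z = 0)
  st3 <- riborigid:::build_structure_from_table(tab)
  st3$atoms$mass <- 1
  expect_equal(radius_of_gyration(st3, exclude_region = NULL), sqrt(2 / 3))

  # coincident atoms
  st0 <- st3
  st0$atoms$x <- 1
  expect_equal(radius_of_gyration(st0, exclude_region = NULL), 0)

  # rotation invariance
  rot <- riborigid:::rot_xyz(c(0.3, 1.1, 0.5))
  str <- st3
  m <- as.matrix(st3$atoms[, c("x", "y", "z")]) %*% rot
  str$atoms$x <- m[, 1]; str$atoms$y <- m[, 2]; str$atoms$z <- m[, 3]
  expect_equal(radius_of_gyration(str, exclude_region = NULL),
               radius_of_gyration(st3, exclude_region = NULL))

  # excluding P1 changes the value on the toy aptamer and needs a map
  toy <- get_toy()
  rg_all <- radius_of_gyration(toy$structure, exclude_region = NULL)
  rg_nop1 <- radius_of_gyration(toy$structure, toy$regions)
  expect_true(rg_nop1 != rg_all)
  expect_error(radius_of_gyration(toy$structure, exclude_region = "P1"),
               "region_map")
})

test_that("RAC is definitionally consistent and averages down white noise", {
  toy <- get_toy()
  st <- toy$structure
  flat <- riborigid:::structure_xyz(st)

  # constant trajectory
  ens0 <- read_ensemble(st, matrix(rep(flat, 6), nrow = 6, byrow = TRUE))
  rc0 <- rac(ens0, windows = 1:3)
  expect_true(all(rc0$rac < 1e-12))

  # RAC(1) equals the mean RMSD to the reference
  ens <- simulate_trajectory(st, n_frames = 20, seed = 41, sigma = 0.3)
  rc1 <- rac(ens, windows = 1)
  rs <- rmsd_series(ens, reference = ens$xyz[1, ])
  expect_equal(rc1$rac, mean(rs$rmsd), tolerance = 1e-10)

  # white noise about an exact reference: RAC(w) ~ 1/sqrt(w)
  sig <- 0.3
  xyz <- ens$xyz
  xyz[1, ] <- flat  # make the reference frame noise-free
  set.seed(42)
  for (f in 2:20) xyz[f, ] <- flat + rnorm(length(flat), 0, sig)
  ens_w <- read_ensemble(st, xyz)
  rc <- rac(ens_w, windows = c(1, 4, 9))
  slope <- coef(lm(log(rc$rac) ~ log(rc$window)))[2]
  expect_lt(abs(slope - (-0.5)), 0.1)

  # oversized windows are dropped with a message
  expect_message(rac(ens_w, windows = c(2, 50)), "dropping")
})

test_that("phosphorus PCA recovers variance structure", {
  toy <- get_toy()
  st <- toy$structure
  flat <- riborigid:::structure_xyz(st)
  psel <- select_atoms(st, elements = "P")

  # variation along a single coordinate: PC1 explains everything
  xyz <- matrix(rep(flat, 10), nrow = 10, byrow = TRUE)
  col1 <- 3 * (psel[1] - 1) + 1
  xyz[, col1] <- xyz[, col1] + seq(0, 9)
  pc <- pca_project(read_ensemble(st, xyz), selection = psel)
  expect_gt(pc$var_explained[1], 0.999)
  expect_lt(abs(mean(pc$projections$PC1)), 1e-8)

  # anisotropic Gaussian on two coordinates of one atom:
  # eigenvalue ratio approaches sigma1^2 / sigma2^2
  set.seed(5)
  n <- 4000
  xyz2 <- matrix(rep(flat, n), nrow = n, byrow = TRUE)
  xyz2[, col1] <- xyz2[, col1] + rnorm(n, 0, 2)
  xyz2[, col1 + 1] <- xyz2[, col1 + 1] + rnorm(n, 0, 1)
  pc2 <- pca_project(read_ensemble(st, xyz2), selection = psel[1],
                     fit = FALSE)
  ratio <- pc2$eigenvalues[1] / pc2$eigenvalues[2]
  expect_lt(abs(ratio - 4) / 4, 0.2)
})

test_that("Mg hydration tracking applies the 3.5 A shell rule", {
  toy <- get_toy()
  spec <- tibble::tibble(x = 40, y = 0, z = 0)
  ens <- simulate_trajectory(toy$structure, n_frames = 3, seed = 51,
                             sigma = 0, ion_spec = spec)
  h <- mg_hydration(ens)
  expect_true(all(h$n_waters == 6))
  expect_true(all(h$hexahydrated))
  expect_false(any(h$chelated))

  # move one shell water to 3.6 A: count drops to 5
  wat_rows <- which(ens$topology$atoms$category == "WATER")
  xyz <- ens$xyz
  col <- 3 * (wat_rows[1] - 1) + 1
  xyz[, col] <- 40 + 3.6
  ens2 <- read_ensemble(ens$topology, xyz)
  h2 <- mg_hydration(ens2)
  expect_true(all(h2$n_waters == 5))
  expect_false(any(h2$hexahydrated))

  # an RNA atom within 3.5 A flags chelation
  mg_row <- which(ens$topology$atoms$category == "MG")
  rna_xyz <- ens$xyz[1, 1:3]
  xyz3 <- ens$xyz
  xyz3[, 3 * (mg_row - 1) + 1:3] <-
    matrix(rep(rna_xyz + c(2.2, 0, 0), 3), nrow = 3, byrow = TRUE)
  h3 <- mg_hydration(read_ensemble(ens$topology, xyz3))
  expect_true(all(h3$chelated))

  # no ions: empty series with a warning
  flat <- riborigid:::structure_xyz(toy$structure)
  ens_nomg <- read_ensemble(toy$structure,
                            matrix(flat, nrow = 1, byrow = TRUE))
  expect_warning(h4 <- mg_hydration(ens_nomg), "no Mg")
  expect_equal(nrow(h4), 0)
})

test_that("the occupancy grid counts ion presence per cell and site", {
  toy <- get_toy()
  spec <- tibble::tibble(x = 40, y = 0, z = 0)
  ens <- simulate_trajectory(toy$structure, n_frames = 4, seed = 52,
                             sigma = 0, ion_spec = spec)
  gm <- occupancy_grid(ens, sites = tibble::tibble(label = "s1", x = 40,
                                                   y = 0, z = 0))
  expect_equal(max(gm$grid$count), 4)
  expect_equal(gm$sites$occupancy, 100)

  # ion outside the site radius half the time -> 50%
  mg_row <- which(ens$topology$atoms$category == "MG")
  xyz <- ens$xyz
  xyz[c(2, 4), 3 * (mg_row - 1) + 1] <- 60
  ens2 <- read_ensemble(ens$topology, xyz)
  gm2 <- occupancy_grid(ens2, sites = tibble::tibble(label = "s1", x = 40,
                                                     y = 0, z = 0))
  expect_equal(gm2$sites$occupancy, 50)

  expect_error(occupancy_grid(ens, spacing = 0), "positive")

  # grid file output is plain text with the documented header
  f <- tempfile()
  write_grid(gm, f)
  lines <- readLines(f)
  expect_true(any(grepl("spacing", lines)))
  unlink(f)
})

test_that("chi histograms are normalized and place known dihedrals", {
  toy <- get_toy()
  st <- toy$structure
  flat <- riborigid:::structure_xyz(st)
  ens <- read_ensemble(st, matrix(rep(flat, 3), nrow = 3, byrow = TRUE))
  ch <- chi_histogram(ens)
  sums <- tapply(ch$prob, ch$resid, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # identical frames: each nucleotide occupies a single bin
  occupied <- tapply(ch$prob > 0, ch$resid, sum)
  expect_true(all(occupied == 1))
  pooled <- attr(ch, "pooled")
  expect_equal(sum(pooled$prob), 1)

  # planar four-point fixture with a 90-degree dihedral
  expect_equal(
    riborigid:::dihedral_deg(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                             c(0, 1, 1)) %% 360, 90)
})
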