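# noiseless monoenergetic pair of a phantom at two energies
mono_pair <- function(ph, e_lo = 70, e_hi = 120, n_out = nrow(ph$labels),
                      n_angles = 120) {
  geo <- default_geometry(ph, n_angles)
  paths <- project(ph, geo)
  lo <- reconstruct(acquire(ph, geo, mono_spectrum(e_lo), paths = paths),
                    n_out = n_out)
  hi <- reconstruct(acquire(ph, geo, mono_spectrum(e_hi, "kv140Sn"),
                            paths = paths), n_out = n_out)
  de_pair(lo, hi)
}

test_that("mixing is the stated convex blend", {
  a <- flat_image(100, 32)
  b <- flat_image(200, 32)
  b$energy_meta$effective_kev <- 90
  pair <- de_pair(a, b)
  expect_equal(mix_images(pair, 1)$hu, a$hu)
  expect_equal(mix_images(pair, 0)$hu, b$hu)
  expect_true(all(mix_images(pair, 0.5)$hu == 150))
  expect_equal(mix_images(pair)$arm_label, "NOMAR")
  expect_error(mix_images(pair, 1.5))
})

test_that("decomposition recovers material basis coefficients", {
  ph <- fixture("water_disk_128", function() disk_phantom("water", 0.3, 128))
  pair <- mono_pair(ph)
  maps <- decompose(pair)
  tab <- material_table()
  w <- tab[tab$name == "water", ]
  inside <- disk_mask(128, 0.25)
  expect_lt(abs(mean(maps$c_pe[inside]) / w$a_pe - 1), 0.02)
  expect_lt(abs(mean(maps$c_c[inside]) / w$a_c - 1), 0.02)
  # air region decomposes to roughly nothing
  outside <- !disk_mask(128, 0.45)
  expect_lt(max(abs(mean(maps$c_pe[outside])), abs(mean(maps$c_c[outside]))),
            0.01)
  # linearity: decomposition of an averaged pair = averaged decompositions
  pair2 <- pair
  pair2$low$hu <- pair$low$hu + 50
  pair2$high$hu <- pair$high$hu + 30
  avg <- pair
  avg$low$hu <- (pair$low$hu + pair2$low$hu) / 2
  avg$high$hu <- (pair$high$hu + pair2$high$hu) / 2
  m1 <- decompose(pair); m2 <- decompose(pair2); ma <- decompose(avg)
  expect_equal(ma$c_pe, (m1$c_pe + m2$c_pe) / 2, tolerance = 1e-12)
  # equal energies are rejected
  same <- pair
  same$high$energy_meta$effective_kev <- pair$low$energy_meta$effective_kev
  expect_error(decompose(same), "singular")
})

test_that("virtual monoenergetic images interpolate and extrapolate correctly", {
  ph <- fixture("water_disk_128", function() disk_phantom("water", 0.3, 128))
  pair <- mono_pair(ph)
  maps <- decompose(pair)
  # a VMI at the low knot reproduces the low image
  v70 <- vmi(maps, 70)
  expect_lt(max(abs(v70$hu - pair$low$hu)), 1)
  # water is the anchor at every energy
  inside <- disk_mask(128, 0.25)
  for (kev in c(50, 100, 150)) {
    expect_lt(max(abs(mean(vmi(maps, kev)$hu[inside]))), 5)
  }
  expect_error(vmi(maps, 20), "target_kev")
  expect_equal(v70$arm_label, "DEMAR")
})

test_that("iodine contrast collapses towards high energies", {
  mats <- material_table()
  code <- stats::setNames(seq_len(nrow(mats)), mats$name)
  lab <- matrix(code[["air"]], 128, 128)
  lab[disk_mask(128, 0.35)] <- code[["soft_tissue"]]
  lab[disk_mask(128, 0.08, c(0.5, 0.4))] <- code[["iodine_blood"]]
  ph <- ct_phantom(lab, mats, pixel_size = 0.3)
  pair <- mono_pair(ph)
  maps <- decompose(pair)
  vessel <- disk_mask(128, 0.06, c(0.5, 0.4))
  means <- vapply(c(70, 100, 130), function(k) mean(vmi(maps, k)$hu[vessel]),
                  numeric(1))
  expect_true(all(diff(means) < 0))
  # matches the closed-form HU of the attenuation model
  expect_equal(means[1], hu_of("iodine_blood", 70), tolerance = 0.05)
})

test_that("the frequency-split noise technique trades bands as designed", {
  ph <- fixture("water_disk_128", function() disk_phantom("water", 0.3, 128))
  pair <- mono_pair(ph)
  maps <- decompose(pair)
  target <- vmi(maps, 130)
  # reference = target -> identity
  out <- vmi_frequency_split(target, target, 2, 1)
  expect_equal(out$hu, target$hu, tolerance = 1e-10)
  # noiseless inputs: plateau means undisturbed beyond filter ripple
  ref <- vmi(maps, 70)
  out2 <- vmi_frequency_split(target, ref, 2, 1)
  inside <- disk_mask(128, 0.2)
  expect_lt(abs(mean(out2$hu[inside]) - mean(target$hu[inside])), 1)
  expect_error(vmi_frequency_split(target, ref, 0), "sigma")
})

test_that("the noise technique lowers high-keV noise on noisy data", {
  ph <- disk_phantom("water", 0.4, 128, fov = 30)
  geo <- default_geometry(ph, 90)
  paths <- project(ph, geo)
  worse <- 0
  for (seed in 1:5) {
    lo <- reconstruct(acquire(ph, geo, make_spectrum("kv100", 12), n0 = 2e5,
                              seed = seed, paths = paths), n_out = 128)
    hi <- reconstruct(acquire(ph, geo, make_spectrum("kv140Sn", 12), n0 = 4e5,
                              seed = seed + 50, paths = paths), n_out = 128)
    maps <- decompose(de_pair(lo, hi))
    raw130 <- vmi(maps, 130)
    demar <- vmi_frequency_split(raw130, vmi(maps, 70), 2, 1)
    ctr <- c(63.5, 63.5)
    if (noise_roi(demar, ctr, 12) >= noise_roi(raw130, ctr, 12)) {
      worse <- worse + 1
    }
  }
  expect_lte(worse, 1)
})

test_that("run_arm produces the four study arms coherently", {
  fx <- hip128()
  cfg <- fx$cfg
  expect_error(run_arm("SMAR", fx$pair, cfg), "unknown arm")
  # determinism of the uncorrected arm
  a1 <- run_arm("NOMAR", fx$pair, cfg, n_out = 128)
  a2 <- run_arm("NOMAR", fx$pair, cfg, n_out = 128)
  expect_identical(a1$hu, a2$hu)
  expect_equal(a1$arm_label, "NOMAR")
  # run_arms agrees with individual run_arm calls
  all4 <- suppressMessages(run_arms(fx$pair, cfg, n_out = 128))
  expect_named(all4, c("NOMAR", "IMAR", "DEMAR", "IMAR+DEMAR"))
  expect_equal(all4$NOMAR$hu, a1$hu)
  d1 <- run_arm("DEMAR", fx$pair, cfg, n_out = 128)
  expect_equal(all4$DEMAR$hu, d1$hu)
})

test_that("arms agree on an artefact-free phantom", {
  mats <- material_table()
  code <- stats::setNames(seq_len(nrow(mats)), mats$name)
  lab <- matrix(code[["air"]], 128, 128)
  lab[disk_mask(128, 0.4)] <- code[["soft_tissue"]]
  lab[disk_mask(128, 0.1, c(0.45, 0.5))] <- code[["bone"]]
  ph <- ct_phantom(lab, mats, pixel_size = 0.3)
  geo <- default_geometry(ph, 180)
  paths <- project(ph, geo)
  # single-bin channels: no beam hardening, so truly artefact-free
  pair <- list(
    low = acquire(ph, geo, mono_spectrum(70), paths = paths),
    high = acquire(ph, geo, mono_spectrum(105, "kv140Sn"), paths = paths)
  )
  arms <- suppressMessages(run_arms(pair, mar_config(), n_out = 128))
  soft <- disk_mask(128, 0.35) & !disk_mask(128, 0.14, c(0.45, 0.5))
  for (a in names(arms)) {
    for (b in names(arms)) {
      expect_lte(mean(abs(arms[[a]]$hu[soft] - arms[[b]]$hu[soft])), 10)
    }
  }
})

test_that("combining IMAR with DEMAR beats IMAR alone on a hip case", {
  fx <- hip128()
  arms <- suppressMessages(run_arms(fx$pair, fx$cfg, n_out = 128))
  roi <- fx$ph$roi
  sc <- function(img) streak_spectrum(trace_polygon(img, roi))$total_low
  expect_lte(sc(arms$`IMAR+DEMAR`), sc(arms$IMAR))
})
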