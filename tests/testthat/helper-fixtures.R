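# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# uniform disk phantom of one material centred in an air grid
disk_phantom <- function(material = "water", radius_frac = 0.35, n = 128,
                         fov = 40) {
  mats <- material_table()
  code <- stats::setNames(seq_len(nrow(mats)), mats$name)
  cn <- (n - 1) / 2
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), n), n, n)
  r <- sqrt((x - cn)^2 + (y - cn)^2) / n
  lab <- matrix(code[["air"]], n, n)
  lab[r <= radius_frac] <- code[[material]]
  ct_phantom(lab, mats, pixel_size = fov / n)
}

disk_mask <- function(n, radius_frac, center_frac = c(0.5, 0.5)) {
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), n), n, n)
  sqrt((x / n - center_frac[1])^2 + (y / n - center_frac[2])^2) <= radius_frac
}

# single-bin (monoenergetic) spectrum for exact Beer-Lambert tests
mono_spectrum <- function(kev, kvp_label = "kv100") {
  s <- make_spectrum(kvp_label, 24)
  s$energies <- kev
  s$weights <- 1
  s$mean_energy <- kev
  s
}

# constant-HU image helper
flat_image <- function(value, n = 64, pixel_size = 0.1, arm = "raw") {
  marstreak:::new_ct_image(matrix(value, n, n), pixel_size, arm,
                           list(effective_kev = 70))
}

hu_of <- function(material, kev) {
  1000 * (attenuation(material, kev) - mu_water(kev)) / mu_water(kev)
}

# small noisy hip case reused across MAR tests (128 grid keeps it fast)
hip128 <- function() {
  fixture("hip128", function() {
    ph <- make_phantom("hip_unilateral", 128, seed = 7)
    geo <- default_geometry(ph, 180)
    cfg <- mar_config()
    pair <- acquire_pair(ph, cfg, seed = 11)
    list(ph = ph, geo = geo, cfg = cfg, pair = pair)
  })
}
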