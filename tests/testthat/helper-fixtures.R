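# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# A 96^3 fibrosis phantom exercising every tissue class.
small_phantom <- function() fixture("small_phantom", function() {
  generate_phantom(phantom_config(
    shape = c(96, 96, 96), seed = 3,
    tree_params = list(root_radius = 12, depth = 2, root_length = 60,
                       n_central = 1, n_portal = 1),
    sinusoid_params = list(node_density = 1e5, tube_radius = 3),
    steatosis_params = list(band_edges = c(0, 20, 40),
                            band_probabilities = c(0.6, 0.35),
                            droplet_radius = c(4, 8))))
})

# Low-noise variant for segmentation-recovery checks (noise 2.5% of the
# 0.4 lumen-parenchyma contrast).
quiet_phantom <- function() fixture("quiet_phantom", function() {
  generate_phantom(phantom_config(
    shape = c(96, 96, 96), seed = 13,
    tree_params = list(root_radius = 12, depth = 2, root_length = 60,
                       n_central = 1, n_portal = 1),
    sinusoid_params = list(node_density = 1e5, tube_radius = 3),
    steatosis_params = list(band_edges = c(0, 30, 60),
                            band_probabilities = c(0.6, 0.35),
                            droplet_radius = c(3, 6)),
    intensity_model = list(noise_sd = 0.01, bias_amplitude = 0,
                           stripe_amplitude = 0)))
})

# Separable two-class phantom pair for classifier checks: parenchyma 0.35 /
# steatosis 0.60 at noise sd 0.035 (~7 sigma separation), large droplets.
separable_config <- function(seed, shape = c(96, 96, 96)) {
  phantom_config(
    shape = shape, seed = seed,
    tree_params = list(root_radius = 14, depth = 2, root_length = 70,
                       n_central = 1, n_portal = 1),
    sinusoid_params = list(node_density = 5e4, tube_radius = 3),
    steatosis_params = list(band_edges = c(0, 25, 50),
                            band_probabilities = c(0.6, 0.35),
                            droplet_radius = c(6, 12)),
    intensity_model = list(steatosis_mean = 0.60, noise_sd = 0.035,
                           bias_amplitude = 0.05))
}

# Preprocessed grayscale of the quiet phantom (normalized, no median; the
# quiet phantom renders no bias field, so no flat-fielding is applied).
quiet_normalized <- function() fixture("quiet_normalized", function() {
  denoise_and_normalize(quiet_phantom()$gray, 0, 0.5, 99.5)
})

# Independent brute-force EDT oracle (distance to nearest TRUE voxel).
edt_oracle <- function(mask, spacing) {
  d <- dim(mask)
  idx <- which(mask)
  out <- array(Inf, d)
  if (length(idx) == 0) return(out)
  fg <- arrayInd(idx, d)
  all_idx <- arrayInd(seq_len(prod(d)), d)
  for (v in seq_len(nrow(all_idx))) {
    dd <- sweep(fg, 2, all_idx[v, ], "-")
    dd <- sweep(dd, 2, spacing, "*")
    out[v] <- sqrt(min(rowSums(dd^2)))
  }
  out
}

# Independent flood-fill oracle for seeded region growing: repeated masked
# dilation via array shifts (no shared code with the BFS implementation).
flood_oracle <- function(gray, seeds_idx, low, high, connectivity) {
  d <- dim(gray)
  ok <- gray >= low & gray <= high
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  shift_or <- function(m, off) {
    out <- array(FALSE, d)
    src <- list(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
    dst <- src
    for (a in 1:3) {
      o <- off[a]
      if (o == 1) { src[[a]] <- seq_len(d[a] - 1); dst[[a]] <- 2:d[a] }
      if (o == -1) { src[[a]] <- 2:d[a]; dst[[a]] <- seq_len(d[a] - 1) }
    }
    out[dst$x, dst$y, dst$z] <- m[src$x, src$y, src$z]
    out
  }
  lab <- array(0L, d)
  for (s in seq_len(nrow(seeds_idx))) {
    cur <- array(FALSE, d)
    cur[seeds_idx[s, 1], seeds_idx[s, 2], seeds_idx[s, 3]] <- TRUE
    if (lab[which(cur)] != 0) next
    cur <- cur & ok
    repeat {
      grown <- cur
      for (t in seq_len(nrow(offs))) grown <- grown | shift_or(cur, offs[t, ])
      grown <- grown & ok & lab == 0L
      if (identical(grown, cur)) break
      cur <- grown
    }
    lab[cur] <- s
  }
  lab
}
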