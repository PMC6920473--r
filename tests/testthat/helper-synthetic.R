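# Shared fixture builders: everything synthetic, generated at test time.

# A BoutonField with hand-placed centers (bypasses random sampling).
manual_field <- function(centers, radii, region, intensities = NULL) {
  centers <- matrix(centers, ncol = 3, byrow = FALSE)
  if (is.null(intensities)) intensities <- rep(1, nrow(centers))
  structure(list(centers = centers, radii = rep(radii, length.out = nrow(centers)),
                 intensities = intensities,
                 region = rbind(lo = c(0, 0, 0), hi = region),
                 rho = nrow(centers) / prod(region), min_sep = 0, seed = NULL),
            class = "BoutonField")
}

# Two boutons `sep` um apart along x, centered in `region`.
two_bouton_field <- function(sep, radius, region) {
  ctr <- rbind(region / 2 - c(0, 0, sep / 2), region / 2 + c(0, 0, sep / 2))
  manual_field(ctr, radius, region)
}

# Count significant regional maxima of a stack: local maxima above
# `frac` of the global maximum, after 1-voxel Gaussian smoothing to kill
# shot-noise wiggles, merged within `merge` um.
count_intensity_peaks <- function(grid, frac = 0.3, merge = 0.5) {
  sm <- bouton3d:::convolve_psf(grid$data, psf_model(sigma = grid$voxel_size),
                                grid$voxel_size)
  pk <- bouton3d:::local_maxima_3d(sm, frac * max(sm))
  if (nrow(pk) < 2) return(nrow(pk))
  pts <- sweep(pk[, 1:3, drop = FALSE] - 0.5, 2, grid$voxel_size, `*`)
  max(bouton3d:::.link_components(pts, merge))
}

# The PSF used for paper-like anisotropic rendering: axial/lateral sigma
# ratio 3.3/0.86 = 3.837.
anisotropic_psf <- function(sigma_lateral = 0.3) {
  psf_model(sigma = sigma_lateral * c(3.3 / 0.86, 1, 1))
}

# Brute-force O(n^2) single-linkage clustering oracle (igraph components
# when available, otherwise a plain union-find over all pairs).
bruteforce_single_linkage <- function(pts, link) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  adj <- as.matrix(stats::dist(pts)) < link
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    return(igraph::components(g)$membership)
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (adj[i, j]) parent[find(j)] <- find(i)
  vapply(seq_len(n), find, integer(1))
}

# Full-coverage binary mask VoxelGrid of a given extent (um).
full_mask <- function(extent, voxel = 1) {
  dims <- as.integer(round(extent / voxel))
  voxel_grid(array(1, dims), rep(voxel, 3))
}
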