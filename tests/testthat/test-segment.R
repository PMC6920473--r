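# A dumbbell phantom: two spheres joined by a dim bridge, so the object
# fuses at low thresholds and splits at high ones.
dumbbell_grid <- function() {
  vs <- c(0.1, 0.1, 0.1)
  img <- array(0, c(30, 30, 50))
  fill_sphere <- function(img, ctr, r, value) {
    d <- dim(img)
    zc <- (seq_len(d[1]) - 0.5) * vs[1]
    yc <- (seq_len(d[2]) - 0.5) * vs[2]
    xc <- (seq_len(d[3]) - 0.5) * vs[3]
    q <- outer(outer((zc - ctr[1])^2, (yc - ctr[2])^2, `+`), (xc - ctr[3])^2, `+`)
    img[q <= r^2] <- pmax(img[q <= r^2], value)
    img
  }
  img <- fill_sphere(img, c(1.5, 1.5, 1.5), 0.7, 1.0)
  img <- fill_sphere(img, c(1.5, 1.5, 3.5), 0.7, 1.0)
  # bridge at 40% intensity along x between the lobes
  img[13:17, 13:17, 15:35] <- pmax(img[13:17, 13:17, 15:35], 0.4)
  voxel_grid(img, vs)
}

# reference flood fill (6-connectivity agrees with 26 for these solid phantoms)
bruteforce_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  for (i in which(mask)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      z <- (v - 1) %% d[1] + 1
      y <- ((v - 1) %/% d[1]) %% d[2] + 1
      x <- (v - 1) %/% (d[1] * d[2]) + 1
      for (nb in list(c(z - 1, y, x), c(z + 1, y, x), c(z, y - 1, x),
                      c(z, y + 1, x), c(z, y, x - 1), c(z, y, x + 1))) {
        if (any(nb < 1) || any(nb > d)) next
        j <- nb[1] + d[1] * (nb[2] - 1 + d[2] * (nb[3] - 1))
        if (mask[j] && lab[j] == 0L) { lab[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  lab
}

test_that("well-separated spheres segment as distinct objects at every threshold", {
  f <- manual_field(rbind(c(2, 2, 2), c(2, 2, 6)), radii = 0.8,
                    region = c(4, 4, 8))
  st <- render_stack(f, render_spec(), voxel_size = c(0.1, 0.1, 0.1))
  obj <- multithreshold_segment(st)
  expect_equal(unname(table(obj$threshold)), rep(2L, 8),
               ignore_attr = TRUE)
  expect_equal(obj$volume, obj$voxel_count * voxel_volume(st))
})

test_that("a uniform image is one object at any threshold", {
  g <- voxel_grid(array(3, c(6, 6, 6)), c(0.2, 0.2, 0.2))
  obj <- multithreshold_segment(g, thresholds = c(20, 50, 100))
  expect_equal(nrow(obj), 3L)
  expect_true(all(obj$voxel_count == 216L))
  expect_error(multithreshold_segment(voxel_grid(array(0, c(4, 4, 4)),
                                                 c(1, 1, 1))), "all-zero")
})

test_that("a dumbbell fuses at low threshold and splits at high, matching brute-force flood fill", {
  g <- dumbbell_grid()
  obj <- multithreshold_segment(g, thresholds = c(20, 70))
  expect_equal(sum(obj$threshold == 20), 1L)
  expect_equal(sum(obj$threshold == 70), 2L)
  for (t in c(20, 70)) {
    mask <- g$data >= t / 100 * max(g$data)
    expect_equal(sum(obj$threshold == t), max(bruteforce_components(mask)))
  }
})

test_that("size filters apply the maximum everywhere and the minimum at the lowest threshold only", {
  obj <- data.frame(threshold = c(50, 20, 40, 20, 30),
                    label = 1:5, z = 1, y = 1, x = 1,
                    voxel_count = 1L,
                    volume = c(12, 0.03, 0.03, 5, 10.0001))
  out <- filter_objects(obj)
  # 12 um3 removed at any threshold; 0.03 removed at 20% but kept at 40%
  expect_equal(out$volume, c(0.03, 5))
  expect_equal(out$threshold, c(40, 20))
  expect_equal(nrow(filter_objects(obj[0, ])), 0L)
})

test_that("center merging follows the strict 0.8 um single-linkage rule", {
  mk <- function(pts) data.frame(threshold = 20, label = seq_len(nrow(pts)),
                                 z = pts[, 1], y = pts[, 2], x = pts[, 3],
                                 voxel_count = 1L, volume = 0.1)
  close_pair <- mk(rbind(c(1, 1, 1), c(1, 1, 1.5)))      # 0.5 um
  expect_equal(nrow(merge_centers(close_pair)$centers), 1L)
  far_pair <- mk(rbind(c(1, 1, 1), c(1, 1, 1.9)))        # 0.9 um
  expect_equal(nrow(merge_centers(far_pair)$centers), 2L)
  tie_pair <- mk(rbind(c(1, 1, 1), c(1, 1, 1.8)))        # exactly 0.8: not linked
  expect_equal(nrow(merge_centers(tie_pair)$centers), 2L)

  # transitive chain: A-B 0.7, B-C 0.7, A-C 1.4 -> one bouton
  chain <- mk(rbind(c(1, 1, 1), c(1, 1, 1.7), c(1, 1, 2.4)))
  bs <- merge_centers(chain)
  expect_equal(nrow(bs$centers), 1L)
  expect_equal(bs$centers[1, ], c(z = 1, y = 1, x = 1.7))
})

test_that("merging agrees with a brute-force O(n^2) single-linkage oracle", {
  set.seed(77)
  for (n in c(50, 1000)) {
    pts <- cbind(runif(n, 0, 15), runif(n, 0, 15), runif(n, 0, 15))
    obj <- data.frame(threshold = 20, label = seq_len(n), z = pts[, 1],
                      y = pts[, 2], x = pts[, 3], voxel_count = 1L,
                      volume = 0.1)
    bs <- merge_centers(obj, link_distance = 0.8)
    oracle <- bruteforce_single_linkage(pts, 0.8)
    expect_equal(nrow(bs$centers), length(unique(oracle)))
    # identical partitions, not just identical counts
    ours <- bouton3d:::.link_components(pts, 0.8)
    expect_equal(length(unique(paste(ours, oracle))),
                 length(unique(oracle)))
  }
})

test_that("merging is idempotent and invariant to object order", {
  set.seed(5)
  pts <- cbind(runif(200, 0, 8), runif(200, 0, 8), runif(200, 0, 8))
  obj <- data.frame(threshold = sample(seq(20, 90, 10), 200, TRUE),
                    label = 1:200, z = pts[, 1], y = pts[, 2], x = pts[, 3],
                    voxel_count = 1L, volume = 0.1)
  bs <- merge_centers(obj)
  # re-merging the merged centers changes nothing
  again <- merge_centers(data.frame(threshold = 20,
                                    label = seq_len(nrow(bs$centers)),
                                    z = bs$centers[, 1], y = bs$centers[, 2],
                                    x = bs$centers[, 3], voxel_count = 1L,
                                    volume = 0.1))
  expect_equal(nrow(again$centers), nrow(bs$centers))
  expect_equal(again$centers[order(again$centers[, 1]), ],
               bs$centers[order(bs$centers[, 1]), ], tolerance = 1e-12)
  # permuting rows permutes nothing observable
  perm <- obj[sample(nrow(obj)), ]
  expect_equal(nrow(merge_centers(perm)$centers), nrow(bs$centers))
})

test_that("ROI counting uses half-open boxes", {
  bs <- structure(list(centers = rbind(c(0, 5, 5), c(10, 5, 5), c(5, 5, 5)),
                       members = list(NULL, NULL, NULL), link_distance = 0.8),
                  class = "BoutonSet")
  roi <- roi_spec(c(0, 0, 0), 10)
  # center on the lower face counts, on the upper face does not
  expect_equal(count_in_roi(bs, roi), 2)
  empty <- structure(list(centers = matrix(numeric(0), 0, 3),
                          members = list(), link_distance = 0.8),
                     class = "BoutonSet")
  expect_equal(count_in_roi(empty, roi), 0L)
})

test_that("tightening size filters never increases the bouton count", {
  f <- generate_field(c(10, 10, 10), rho = 0.02, min_sep = 2.2, seed = 55)
  st <- render_stack(f, render_spec(psf = anisotropic_psf(0.25),
                                    photon_scale = 500),
                     voxel_size = c(0.4, 0.34, 0.34), seed = 55)
  iso <- resample_isotropic(richardson_lucy(st, anisotropic_psf(0.25),
                                            iterations = 40), 0.15)
  obj <- multithreshold_segment(iso)
  count_with <- function(vmax, vmin)
    nrow(merge_centers(filter_objects(obj, vmax = vmax, vmin = vmin,
                                      lowest_threshold = 20))$centers)
  base <- count_with(10, 0.05)
  expect_lte(count_with(5, 0.05), base)
  expect_lte(count_with(10, 0.2), base)
  expect_lte(count_with(5, 0.2), base)
})

test_that("the end-to-end pipeline recovers well-separated boutons and is deterministic", {
  f <- generate_field(c(14, 14, 14), rho = 15 / 14^3, min_sep = 2.5, seed = 42)
  psf <- anisotropic_psf(0.3)
  st <- render_stack(f, render_spec(psf = psf, photon_scale = 200,
                                    read_noise_sd = 0.002),
                     voxel_size = c(0.4, 0.34, 0.34), seed = 42)
  iso <- resample_isotropic(richardson_lucy(st, psf, iterations = 100), 0.1)
  res1 <- count_pipeline(iso)
  res2 <- count_pipeline(iso)
  m <- match_centers(attr(st, "truth"), res1$bouton_set$centers)
  expect_lte(abs(res1$n_raw - nrow(f$centers)), 1)
  expect_gte(m$precision, 0.9)
  expect_gte(m$recall, 0.9)
  expect_identical(res1$n_raw, res2$n_raw)
  expect_equal(res1$bouton_set$centers, res2$bouton_set$centers)
  expect_equal(res1$n_corr, res1$n_raw / (1 + 2 * 1.16 / 14))

  # featureless stack: the single giant component exceeds the maximum
  # object size at every threshold, so nothing survives the filters
  flat <- voxel_grid(array(0.01, c(30, 30, 30)), c(0.1, 0.1, 0.1))
  expect_equal(count_pipeline(flat)$n_raw, 0L)
  # an all-dark stack has no maximum to threshold against
  dark <- voxel_grid(array(0, c(20, 20, 20)), c(0.1, 0.1, 0.1))
  expect_error(count_pipeline(dark), "all-zero")
})

test_that("the pipeline refuses saturated stacks", {
  g <- voxel_grid(array(c(rep(255, 10), runif(1000 - 10, 0, 200)),
                        c(10, 10, 10)), c(0.5, 0.5, 0.5), full_scale = 255)
  expect_error(count_pipeline(g), "saturated")
})
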