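# Shared fixtures: small phantoms, geometries and cached reconstructions.
# Everything is generated in code at test time; heavier artifacts are built
# once per session through lazy accessors.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

smallPhantom <- function() {
  fixture("smallPhantom", function() generatePhantom(phantomParams(grid = 32), seed = 1))
}

smallGeom <- function() geometryForPhantom(smallPhantom())

# noise-free projections of the small phantom
smallProjections <- function() {
  fixture("smallProjections", function() projectPhantom(smallPhantom()))
}

# uniform-attenuation cylinder on an odd grid (exact rotation centre)
cylinderSetup <- function(n = 33L, muVal = 0.08, radiusVox = 10.49,
                          voxel = 0.5) {
  ctr <- (n + 1) / 2
  idx <- seq_len(n)
  r2 <- outer(idx - ctr, rep(1, n))^2 + outer(rep(1, n), idx - ctr)^2
  mask <- r2 <= radiusVox^2
  mu <- array(0, rep(n, 3))
  for (z in idx) mu[, , z] <- muVal * mask
  list(n = n, ctr = ctr, mask = mask, mu = mu, radiusVox = radiusVox,
       muVal = muVal, voxel = voxel)
}

expect_partition <- function(labels, K) {
  expect_true(all(labels >= 0L & labels < K))
  expect_equal(length(labels), sum(tabulate(labels + 1L, K)))
}
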