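# Shared fixtures, built once per test run.

toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_atlas(seed = 1L)
    cache
  }
})

cube_corners <- function(side_um = 1000, origin = c(0, 0, 0)) {
  as.matrix(expand.grid(origin[1] + c(0, side_um),
                        origin[2] + c(0, side_um),
                        origin[3] + c(0, side_um)))
}

# regular tetrahedron with unit-ish edge, scaled to micrometers
tetrahedron <- function(scale = 1000) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * scale
  triangulate_boundary(v)
}

random_affine <- function() {
  theta <- runif(1, -pi, pi)
  A <- rbind(runif(2, -0.5, 0.5),
             2.0 * c(cos(theta), -sin(theta)),
             2.0 * c(sin(theta), cos(theta)))
  list(A = A, b = runif(3, -1000, 1000))
}
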