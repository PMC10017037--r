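# shared test utilities: independent geometric oracles and helpers

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_move <- function(f, rot, shift) {
  f$beads <- f$beads %*% t(rot) + matrix(shift, nrow(f$beads), 3,
                                         byrow = TRUE)
  f$directors <- f$directors %*% t(rot)
  f$frames <- cdvsim:::filament_frames(f$beads, f$directors)
  f
}

# particles sampled on a radius-modulated tube surface r(z), plus a fake
# trajectory wrapper for the constriction-trace analyser
modulated_tube_traj <- function(rfun, R0 = 8, L = 40, n = 4000, seed = 1) {
  set.seed(seed)
  z <- runif(n, 0, L)
  th <- runif(n, 0, 2 * pi)
  r <- rfun(z)
  mem <- cbind(r * cos(th), r * sin(th), z)
  list(snapshots = list(list(time = 0, membrane = mem,
                             beads = list())),
       config = list(tube_length = L, tube_radius = R0))
}
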