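# Hand-built and random trajectories used across the suite.

make_traj <- function(x, y, pressure = NULL, pen = NULL, t_ms = NULL) {
  n <- length(x)
  if (is.null(pressure)) pressure <- rep(500, n)
  if (is.null(pen)) pen <- rep(1L, n)
  if (is.null(t_ms)) t_ms <- seq(0, by = 20, length.out = n)
  pen_trajectory(x, y, pressure, pen, t_ms)
}

# Random multi-stroke trajectory with duplicate-timestamp and pen-lift
# structure; integer coordinates so exact-value entropies see ties.
random_traj <- function(seed, n = 120L) {
  set.seed(seed)
  x <- cumsum(sample(-3:4, n, replace = TRUE))
  y <- cumsum(sample(-4:3, n, replace = TRUE))
  pressure <- pmax(round(500 + cumsum(rnorm(n, 0, 8))), 0)
  pen <- rep(1L, n)
  n_lifts <- sample(0:3, 1)
  if (n_lifts > 0) {
    for (s in sample(5:(n - 5), n_lifts)) {
      pen[s:min(s + sample(2:5, 1), n)] <- 0L
    }
  }
  t_ms <- cumsum(c(0, sample(c(0, 10, 20, 20, 30), n - 1, replace = TRUE)))
  pressure[pen == 0L] <- 0
  pen_trajectory(x, y, pressure, pen, t_ms)
}
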