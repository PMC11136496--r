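## Independent oracles used across tests. These deliberately avoid the code
## paths they check.

## Jaccard overlap of two polygons by dense point sampling
jaccard_polygons <- function(p1, p2, step = 0.2) {
  b <- rbind(p1, p2)
  xs <- seq(min(b[, 1]), max(b[, 1]), by = step)
  ys <- seq(min(b[, 2]), max(b[, 2]), by = step)
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
  i1 <- points_in_polygon(pts, p1)
  i2 <- points_in_polygon(pts, p2)
  sum(i1 & i2) / sum(i1 | i2)
}

## exact two-sided rank-sum p-value by full enumeration of assignments
ranksum_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  stats_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

## lower empirical quantile by plain sorting (oracle for attraction distance)
sorted_quantile <- function(d, q) sort(d)[ceiling(q * length(d))]

## Pearson R from the covariance formula, no cor()
pearson_formula <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) * sqrt(sum((y - mean(y))^2) / (n - 1)))
}

## closed-form OLS slope
ols_slope <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

## shared boundary length by dense sampling of one boundary against the other
shared_length_sampled <- function(p1, p2, step = 0.01, tol = 1e-7) {
  b <- ehtkit:::densify_polygon(p1, step)
  d <- ehtkit:::dist_to_boundary(b, p2)
  sum(d <= tol) * step
}

## small standard fixtures
rect_poly <- function(w = 40, h = 10) cbind(c(0, w, w, 0), c(0, 0, h, h))
disk_poly <- function(r = 10, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}
rotate_poly <- function(p, deg) {
  a <- deg * pi / 180
  p %*% t(matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2))
}

small_scene_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_roof = 3, n_hemogenic = 3, n_sub_aortic = 2, n_spots = 40,
         clustering_scale_um = 2, fraction_extra_aortic = 0.2,
         cell_radius_um = 2.5, aorta_radius_um = 7,
         box_um = c(x = 24, y = 20, z = 24), spacing_um = 1.0, seed = seed),
    list(...))
  do.call(spot_scene_config, args)
}

scaled_tube_config <- function(...) {
  args <- utils::modifyList(
    list(radius_um = 25, segment_length_um = 330 / 4, pixel_xy_um = 0.27 * 4,
         step_z_um = 0.3 * 4, noise_sd = 0),
    list(...))
  do.call(tube_phantom_config, args)
}
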