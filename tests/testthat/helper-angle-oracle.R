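# Independent flexion-angle oracle used to validate the renderer: fits a
# two-capsule silhouette model directly to the binary mask (multi-start
# Nelder-Mead with ramp annealing on a soft-edge rasterization surrogate)
# and reads the knee angle off the fitted parameters. It sees only the
# mask, never the pose.
#
# Parameter vector: (knee_x, knee_y, theta_thigh, delta, len1, len2,
# halfwidth) with the second segment at theta_thigh + delta; the flexion
# angle is |180 - delta|, so both bend chiralities are representable.

oracle_soft_capsules <- function(par, px, py, ramp = 1) {
  u <- function(d) c(cos(d * pi / 180), sin(d * pi / 180))
  K <- par[1:2]
  P1 <- K + par[5] * u(par[3])
  P2 <- K + par[6] * u(par[3] + par[4])
  d1 <- kromnet:::.dist_to_segment(px, py, K, P1)
  d2 <- kromnet:::.dist_to_segment(px, py, K, P2)
  pmin(1, pmax(0, (par[7] + ramp / 2 - pmin(d1, d2)) / ramp))
}

oracle_fit_flexion <- function(mask) {
  n <- nrow(mask)
  grid_at <- function(step) {
    sub <- seq(1, n, by = step)
    list(m = mask[sub, sub],
         px = matrix(rep(sub, each = length(sub)), length(sub)),
         py = matrix(rep(sub, times = length(sub)), length(sub)))
  }
  g4 <- grid_at(4); g2 <- grid_at(2); g1 <- grid_at(1)
  obj_on <- function(g, ramp) {
    force(g); force(ramp)
    function(par) {
      if (par[4] < 25 || par[4] > 335 || par[7] < 2 || par[7] > 16 ||
          par[5] < 12 || par[6] < 12) return(1e9)
      sum((oracle_soft_capsules(par, g$px, g$py, ramp) - g$m)^2)
    }
  }
  nm <- function(par, fn, maxit) {
    stats::optim(par, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12))
  }

  pts <- which(mask == 1, arr.ind = TRUE)
  xy <- cbind(pts[, 2], pts[, 1])            # (x, y)
  ctr <- colMeans(xy)
  T1 <- as.numeric(xy[which.max(rowSums(sweep(xy, 2, ctr)^2)), ])
  T2 <- as.numeric(xy[which.max(rowSums(sweep(xy, 2, T1)^2)), ])
  dt <- EBImage::distmap(mask)
  Kdt <- which(dt == max(dt), arr.ind = TRUE)[1, ]
  hw0 <- min(max(dt), 12)

  grid_starts <- list()
  for (Kc in list(c(Kdt[2], Kdt[1]), T1, T2, ctr, (T1 + T2) / 2)) {
    l1 <- max(15, sqrt(sum((T1 - Kc)^2)))
    l2 <- max(15, sqrt(sum((T2 - Kc)^2)))
    for (th1 in seq(0, 345, by = 15))
      for (delta in seq(30, 330, by = 15))
        grid_starts[[length(grid_starts) + 1L]] <- c(Kc, th1, delta, l1, l2, hw0)
  }
  # dedicated starts for strongly folded limbs, where the silhouette is a
  # near-merged blob: knee at a far tip, arms straddling the other tip
  fold_starts <- list()
  for (Kc in list(T1, T2)) {
    To <- if (identical(Kc, T1)) T2 else T1
    v <- To - Kc
    L <- sqrt(sum(v^2))
    th_to <- atan2(v[2], v[1]) * 180 / pi
    for (delta in c(28, 35, 325, 332))
      for (dth in c(-15, 0, 15))
        for (lf in c(1.1, 1.4))
          fold_starts[[length(fold_starts) + 1L]] <-
            c(Kc, th_to - delta / 2 + dth, delta, lf * L, lf * L, hw0)
  }

  anneal <- function(par) {
    o <- nm(par, obj_on(g4, 4), 200)
    o <- nm(o$par, obj_on(g4, 2), 250)
    nm(o$par, obj_on(g2, 1), 350)
  }
  polish <- function(par) {
    o <- nm(par, obj_on(g2, 0.5), 300)
    o <- nm(o$par, obj_on(g2, 0.25), 300)
    nm(o$par, obj_on(g1, 0.25), 500)
  }
  run_round <- function(starts_sub) {
    cand <- lapply(starts_sub, anneal)
    cand <- cand[order(vapply(cand, `[[`, numeric(1), "value"))]
    best <- NULL
    for (o in cand[seq_len(min(2, length(cand)))]) {
      o2 <- polish(o$par)
      if (is.null(best) || o2$value < best$value) best <- o2
    }
    best
  }

  screen <- obj_on(g4, 2)
  ord_g <- order(vapply(grid_starts, screen, numeric(1)))
  ord_f <- order(vapply(fold_starts, screen, numeric(1)))
  best <- run_round(c(grid_starts[ord_g[1:6]], fold_starts[ord_f[1:3]]))
  if (best$value > 0.012 * sum(mask) + 8) {
    alt <- run_round(c(grid_starts[ord_g[7:16]], fold_starts[ord_f[4:9]]))
    if (alt$value < best$value) best <- alt
  }
  delta <- best$par[4] %% 360
  max(0, min(150, abs(180 - delta)))
}
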