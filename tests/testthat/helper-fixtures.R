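# shared fixtures, built once per test run
.fx <- new.env()

fx_joint <- function() {
  if (is.null(.fx$joint))
    .fx$joint <- make_joint_phantom(
      phantom_spec(noise_sd = 0, grid_shape = c(48, 48, 56)), "left")
  .fx$joint
}

fx_head <- function() {
  if (is.null(.fx$head))
    .fx$head <- make_head_phantom(phantom_spec(noise_sd = 0,
                                               grid_shape = c(48, 48, 56)))
  .fx$head
}

fx_ball_mask <- function(r = 20, n = 2 * r + 11) {
  key <- paste0("ball", r, "_", n)
  if (is.null(.fx[[key]])) {
    c0 <- (n + 1) / 2
    x <- seq_len(n) - c0
    d2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
    .fx[[key]] <- nv_mask(d2 <= r^2, c(1, 1, 1))
  }
  .fx[[key]]
}

# brute-force directed+symmetric Hausdorff oracle: plain double loop over
# squared point distances, computed term by term as (a-b)^2 sums
hausdorff_oracle <- function(A, B) {
  directed <- function(P, Q) {
    max(vapply(seq_len(nrow(P)), function(i) {
      dx <- Q[, 1] - P[i, 1]; dy <- Q[, 2] - P[i, 2]; dz <- Q[, 3] - P[i, 3]
      min(dx * dx + dy * dy + dz * dz)
    }, numeric(1)))
  }
  sqrt(max(directed(A, B), directed(B, A)))
}

# cached symmetric-pair negative volumes + report
fx_sym <- function() {
  if (is.null(.fx$sym)) {
    hp <- fx_head()
    p <- inflation_params(step = 0.2, max_iters = 16, laplacian_weight = 0.2,
                          sdf_resolution = 96)
    nvl <- negative_volume(hp$left$mc_mesh, hp$left$tb_mesh,
                           hp$left$clip_plane, p, resolution = 96)
    nvr <- negative_volume(hp$right$mc_mesh, hp$right$tb_mesh,
                           hp$right$clip_plane, p, resolution = 96)
    rep <- symmetry_report(nvl$mesh, nvr$mesh, mid_plane = hp$mid_plane,
                           refine = "centroid", seed = 3)
    .fx$sym <- list(nvl = nvl, nvr = nvr, report = rep)
  }
  .fx$sym
}
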