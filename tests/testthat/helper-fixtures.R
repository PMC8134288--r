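# Shared fixtures, built in code. The small dataset is cached per test run.

tiny_geometry <- function(n = 32L) fan_geometry(n_axial = n, n_lines = n)

tiny_phantom_cfg <- function(n = 32L, ...) {
  phantom_config(n_axial = n, n_lines = n, ...)
}

bone_only_cfg <- function(n = 64L) {
  phantom_config(n_axial = n, n_lines = n,
                 n_liver = c(0L, 0L), n_cyst = c(0L, 0L),
                 n_muscle = c(0L, 0L), n_bone = c(1L, 1L))
}

.fixture_env <- new.env(parent = emptyenv())

# 10-record 32x32 dataset shared across test files.
small_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- make_dataset(10, 42, tiny_phantom_cfg(),
                                    tiny_geometry(), sim_config())
  }
  .fixture_env$ds
}

# Finite-difference gradient checker: fwd(params) must return
# list(loss, grads); a handful of entries per parameter are probed.
fd_grad_check <- function(fwd, params, n_probe = 3, eps = 1e-6) {
  res <- fwd(params)
  worst <- 0
  for (nm in names(res$grads)) {
    g <- res$grads[[nm]]
    ks <- sample(seq_along(g), min(n_probe, length(g)))
    for (k in ks) {
      p2 <- params; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- params; p3[[nm]][k] <- p3[[nm]][k] - eps
      num <- (fwd(p2)$loss - fwd(p3)$loss) / (2 * eps)
      worst <- max(worst, abs(num - g[k]) / max(1e-8, abs(num) + abs(g[k])))
    }
  }
  worst
}
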