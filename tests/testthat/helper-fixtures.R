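# Shared fixtures: the group and a few lattices are expensive enough to
# build once per test run.
icosa <- build_icosahedral_group()
icosa_ax <- symmetry_axes(icosa)
lat41 <- build_capsid_lattice(4, 1, group = icosa)

axis_of_fold <- function(fold, i = 1) {
  as.numeric(icosa_ax[icosa_ax$fold == fold, c("x", "y", "z")][i, ])
}

# a hexamer site direction at a general position (no axis within tolerance)
generic_site_41 <- function() {
  hx <- lat41$sites[lat41$sites$kind == "hexamer" & !lat41$sites$on_threefold, ]
  A <- as.matrix(icosa_ax[, c("x", "y", "z")])
  for (i in seq_len(nrow(hx))) {
    v <- as.numeric(hx[i, c("x", "y", "z")])
    if (max(abs(A %*% v)) < 1 - 1e-4) return(v)
  }
  stop("no generic hexamer found")
}
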