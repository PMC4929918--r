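# Small systems shared across test files.  Everything is generated in code;
# sizes are chosen so each builder runs in well under a second.

# membrane-only system on a small patch
tiny_membrane_system <- function(L = 120, a0 = 10, kappa = 20, sigma = 0,
                                 spacing = a0, n_receptors = 0, seed = 1) {
  p <- load_config(overrides = list(
    membrane = list(L = L, a0 = a0, kappa = kappa, sigma = sigma)))
  build_system(flat_patch(L, a0, spacing = spacing), p, nc = FALSE,
               n_receptors = n_receptors, seed = seed)
}

# one receptor under one downward ligand, rigid flat membrane; the
# receptor base sits at the vertex directly below the carrier centre
one_bond_system <- function(H0_kBT = -2, tip_height = 19.5, L = 120,
                            seed = 3) {
  p <- load_config(overrides = list(bond = list(H0_J = kBT_to_joule(H0_kBT))))
  mesh <- flat_patch(L, 10)
  center <- c(L / 2, L / 2, tip_height + p$carrier$r_nc + p$carrier$L_ab)
  sys <- build_system(mesh, p, nc = TRUE, n_receptors = 1, seed = seed,
                      ligand_dirs = matrix(c(0, 0, -1), 1),
                      nc_center = center)
  d2 <- colSums((t(mesh$vertices[, 1:2]) - c(L / 2, L / 2))^2)
  sys$receptors$vertex <- which.min(d2)
  sys
}

# move weights restricted to the named kinds
only_moves <- function(...) {
  w <- setNames(numeric(7), names(move_mix()))
  sel <- unlist(list(...))
  w[sel] <- 1 / length(sel)
  w
}

expect_within <- function(value, target, rel_tol, label = NULL) {
  expect_lt(abs(value - target), rel_tol * abs(target),
            label = label %||% paste0(value, " vs ", target))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
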