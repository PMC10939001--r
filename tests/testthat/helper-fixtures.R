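# Shared small fixtures, built once per test run.

small_slab <- function(nx = 4, ny = 4, layers = 2, vacuum = 20, frozen = 1) {
  build_slab(slab_spec(3.632, nx, ny, layers, vacuum, frozen))
}

probe_atom <- function(el = "O") {
  structure_new(el, matrix(0, 1, 3))
}

# rigid transform of a structure's positions
transform_structure <- function(s, axis = c(1, 2, 3), angle = 35,
                                shift = c(1, -2, 0.5)) {
  R <- rotation_about_axis(axis, angle)
  s$positions <- sweep(s$positions %*% t(R), 2, shift, "+")
  s
}

# current reduced-coordinate values of a conformer space on its template
space_current_x <- function(sugar, space) {
  vapply(seq_len(space_dim(space)), function(d) {
    structure_dihedral(sugar$structure, space$specs[[d]]$atoms)
  }, numeric(1))
}

expect_structures_equal <- function(a, b, tol = 1e-8) {
  expect_equal(a$symbols, b$symbols)
  expect_lt(max(abs(a$positions - b$positions)), tol)
}

vnorm_test <- function(v) sqrt(sum(v * v))
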