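# Shared fixtures, built in code at test time.

straight_tube <- function(y0 = 24, y1 = 176, radius = 120, id = "t1",
                          direction = 1L) {
  tube_model(rbind(c(100, y0, 60), c(100, y1, 60)), radius = radius, id,
             direction_flag = direction)
}

small_lattice_phantom <- function(n_units = 12, rise = 28, twist = 24,
                                  shape = c(200, 200, 120), seed = 1,
                                  membrane = TRUE) {
  tb <- straight_tube()
  lp <- lattice_params(rise = rise, twist = twist, tube_radius = 120,
                       n_units = n_units)
  truth <- build_lattice(lp, tb, voxel_size = 4, seed = seed)
  ph <- render_phantom(truth, tb, shape, 4, membrane = membrane)
  list(tube = tb, lattice = lp, truth = truth, phantom = ph)
}

random_map <- function(n = 16, seed = 1, voxel_size = 4) {
  set.seed(seed)
  density_map(array(stats::rnorm(n^3), c(n, n, n)), voxel_size = voxel_size)
}
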