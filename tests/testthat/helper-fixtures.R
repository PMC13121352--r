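# Fixtures built in code: noise-free design grids for both model families.

# Busscher data generated exactly from a parameter set on a BD x w grid.
make_busscher_grid <- function(params, bd = seq(1.0, 1.45, length.out = 6),
                               w = seq(0.20, 0.45, length.out = 5)) {
  g <- expand.grid(bulk_density = bd, water_content = w)
  g$measured_qp <- predict_qp(params, g$bulk_density, g$water_content)
  g
}

# Surface observations generated exactly from a parameter set on an S x Qp grid.
make_surface_grid <- function(params, s = seq(50, 95, length.out = 9),
                              qp = seq(0.3, 5, length.out = 8)) {
  g <- expand.grid(s = s, qp = qp)
  g$re <- relative_elongation(params, g$qp, g$s)
  g
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
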