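# Shared fixtures and independent oracles (dense quadrature, closed forms).

# dense-quadrature projection of the analytic cone model: independent of
# project_field (no grid rasterisation, no interpolation)
oracle_cone_projection <- function(x, diameter, peak = 1, sigma = 0.8,
                                   dz = 0.005, zmax = 30) {
  zz <- seq(dz / 2, zmax, by = dz)
  vapply(x, function(xx)
    2 * sum(cone_radial_dose(sqrt(xx^2 + zz^2), diameter, peak, sigma)) * dz,
    numeric(1))
}

# ground-truth FWHM of the analytic cone radial dose, by root finding
oracle_cone_fwhm <- function(diameter, sigma = 0.8) {
  dmax <- cone_radial_dose(0, diameter, 1, sigma)
  2 * stats::uniroot(function(r) cone_radial_dose(r, diameter, 1, sigma) -
                       dmax / 2, c(0, diameter), tol = 1e-10)$root
}

default_half_grid <- function() (0:122) * 0.2

make_profile <- function(x, p) scifidose:::new_projected_profile(
  x, p, unique(round(diff(x), 9))[1])

suite_diams <- c(4, 5, 6, 7.5, 10, 12.5, 15)
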