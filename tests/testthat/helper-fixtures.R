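# Shared fixture builders. Everything is generated in code at test time;
# no binary or stored fixtures.

# Standard geometries used across tests.
geom_cyl <- function(R = 1e-6) indenter_geometry("cylinder", radius = R)
geom_cone <- function(deg = 25) indenter_geometry("cone", half_angle = deg * pi / 180)
geom_par <- function(R = 1e-6) indenter_geometry("paraboloid", radius = R)
geom_sph <- function(R = 1e-6) indenter_geometry("sphere", radius = R)

# Noiseless Hertzian curve from a constant or depth-dependent average
# modulus (Pa or function of h in m), on n samples up to h_max.
hertz_curve <- function(E, geometry = geom_par(), v = 0.5,
                        h_max = 800e-9, n = 64) {
  h <- seq(0, h_max, length.out = n + 1)
  g <- shape_function(geometry, v, h)
  Ebar <- if (is.function(E)) c(0, E(h[-1])) else E
  F <- g * Ebar
  if (is.function(E)) F[1] <- 0
  force_curve(h, F)
}

# Write a small curve file in the documented dialect and return its path.
write_dialect_file <- function(rows, header = c("# units: nm nN"),
                               path = tempfile(fileext = ".txt")) {
  writeLines(c(header, rows), path)
  path
}

expect_rel_equal <- function(object, expected, tol = 1e-9) {
  expect_true(all(abs(object - expected) <= tol * pmax(abs(expected), 1e-300)),
              label = sprintf("relative difference %.3g exceeds %.3g",
                              max(abs(object - expected) /
                                    pmax(abs(expected), 1e-300)), tol))
}
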