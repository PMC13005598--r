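# shared fixtures built in code

# small theory family at the default study parameters
theory_family <- function(direction, r_inner, mus = c(22, 26, 30, 34),
                          g = 0.9, mu_a = 0.1, ...) {
  theory_fsp_family(direction, cylinder_geometry(r_inner), mus,
                    g = g, mu_a = mu_a, ...)
}

# trapezoid integral used as the independent check against the package's
# internal one
trapz_oracle <- function(x, y) pracma::trapz(x, y)

# brute-force marching oracle for segment/cylinder intersection:
# samples the segment densely and reports the first parameter at which the
# point lies inside the lumen
march_intersect <- function(p0, dir, step, r_inner, ds = 1e-4) {
  t_grid <- seq(0, step, by = ds)
  xx <- p0[1] + t_grid * dir[1]
  zz <- p0[3] + t_grid * dir[3]
  inside <- (xx^2 + zz^2) < r_inner^2
  if (!any(inside)) return(NULL)
  t_grid[which(inside)[1]]
}
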