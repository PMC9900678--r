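# Shared fixtures, built lazily and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Complex-argument modified Bessel function K0 via the integral
# representation K0(z) = \int_0^inf exp(-z cosh t) dt (Re z > 0) --
# the independent oracle for the homogeneous-disk diffusion kernel.
besselK0_complex <- function(z) {
  vapply(z, function(zz) {
    re <- stats::integrate(function(t) Re(exp(-zz * cosh(t))), 0, 30,
                           rel.tol = 1e-10)$value
    im <- stats::integrate(function(t) Im(exp(-zz * cosh(t))), 0, 30,
                           rel.tol = 1e-10)$value
    complex(real = re, imaginary = im)
  }, complex(1))
}

# Homogeneous 80 mm phantom with the reference background properties.
homog_phantom <- function() {
  phantom_spec(80, optical_properties(0.0080, 0.5634), frequency_mhz = 20)
}

# Small single-inclusion phantom for inverse-problem tests.
small_inverse_setup <- function() {
  fixture("inverse_setup", function() {
    spec <- phantom_spec(40, optical_properties(0.01, 1),
                         frequency_mhz = 50)
    acq <- acquisition_config(8, 50)
    mesh <- build_mesh(spec, 8)
    state <- inverse_state(mesh, acq, 0.01, 1.0)
    jac <- compute_jacobian(state)
    list(spec = spec, acq = acq, mesh = mesh, state = jac$state,
         J = jac$J, modeled = jac$modeled)
  })
}

# A tiny trained-from-scratch dataset shared by network smoke tests.
tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    generate_dataset(dataset_manifest(12, seed = 5),
                     acquisition_config(16))
  })
}
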