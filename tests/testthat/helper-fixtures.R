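# Shared fixtures: the study parameter set and small meshes.

study_params <- function(...) set_params(vr_params(), ...)

small_mesh <- function(params = vr_params(), n = 60, n_z = 0, model = "I1") {
  make_mesh(params = params, n = n, n_z = n_z, model = model)
}

# deterministic tiny records table with every missingness pattern
toy_records <- function() {
  data.frame(
    id = c(1L, 1L, 2L, 3L, 4L),
    year = c(1L, 2L, 1L, 1L, 1L),
    m = c(2.5, 2.8, 3.1, 2.0, 2.9),
    a_next = c(1L, 1L, 1L, 0L, 1L),
    r_next = c(1L, 0L, NA, NA, 1L),
    m_next = c(2.8, 2.9, 3.0, NA, 3.05),
    c_next = c(2.2, NA, NA, NA, NA),
    newborn = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}
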