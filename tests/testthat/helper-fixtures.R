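# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

bg_props <- function() optical_properties(0.004, 1)

# small homogeneous slab with a 2x2 mirrored probe, coarse mesh:
# cheap enough for forward/Jacobian unit tests
small_setup <- function(h = 6) fixture(paste0("small_", h), function() {
  op <- bg_props()
  mesh <- slab_mesh(c(44, 52, 42), h = h, op)
  probe <- build_probe(2, 2, 13, 14, 44, center = c(26, 21))
  pairs <- enumerate_pairs(probe)
  list(op = op, mesh = mesh, probe = probe, pairs = pairs)
})

# analytic task data on the 3x4 simulation probe (translation invariant,
# class-constant): the homogeneous noiseless measurement fixture
analytic_sim_task <- function() fixture("an34", function() {
  probe <- build_probe(3, 4, 13, 14, 44, center = c(65, 39.5))
  pairs <- enumerate_pairs(probe)
  an <- analytic_slab_flux(bg_props(), probe, pairs)
  task <- measurement_set(pairs, an$amplitude, role = "task")
  list(probe = probe, pairs = pairs, predicted = an, task = task,
       classes = group_by_distance(pairs))
})

# compact two-target phantom for coarse reconstruction tests:
# scaled-down twin of the baseline geometry
small_phantom <- function(h = 4) fixture(paste0("ph_", h), function() {
  spec <- phantom_spec(c(44, 80, 60), bg_props(), list(
    list(center = c(17, 25, 30), radius = 7.5, height = 10, axis = "x",
         props = optical_properties(0.012, 1)),
    list(center = c(17, 55, 30), radius = 7.5, height = 10, axis = "x",
         props = optical_properties(0.012, 1))
  ))
  probe <- build_probe(3, 4, 13, 14, 44, center = c(40, 30))
  list(spec = spec, phantom = build_phantom(spec, h = h), probe = probe,
       pairs = enumerate_pairs(probe))
})

expect_sd_pairs_partition <- function(classes, pairs) {
  members <- sort(unlist(lapply(classes, `[[`, "members")))
  expect_identical(members, which(!pairs$excluded))
  expect_false(any(duplicated(unlist(lapply(classes, `[[`, "members")))))
}
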