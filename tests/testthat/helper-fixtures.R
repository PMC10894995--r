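# Shared fixtures, computed lazily and cached for the whole test run.
# The phantom scales mirror the study conditions at desk scale: a 50 mm
# five-shell sphere meshed at 2 mm with clinical-style shaft implantations.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

RADII_50 <- c(scalp = 50, skull = 46, csf = 42, gray = 38, white = 30)
RADII_4SHELL <- c(scalp = 50, skull = 46, csf = 42, gray = 38)
RADII_TINY <- c(scalp = 9, skull = 8, csf = 7, gray = 6, white = 5)

fix_vol50 <- function() fixture("vol50", function() sphere_phantom(RADII_50, 2))

fix_mesh50 <- function() fixture("mesh50", function()
  voxels_to_hex_mesh(fix_vol50(), 0.3))

fix_vol4 <- function() fixture("vol4", function()
  sphere_phantom(RADII_4SHELL, 2))

fix_mesh4 <- function() fixture("mesh4", function()
  voxels_to_hex_mesh(fix_vol4(), 0.3))

fix_sys4 <- function() fixture("sys4", function()
  assemble_stiffness(fix_mesh4(), conductivity_profile("4C")))

# small phantom for solver-level tests (cheap solves)
fix_small <- function() fixture("small", function() {
  radii <- c(scalp = 25, skull = 23, csf = 21, gray = 19)
  vol <- sphere_phantom(radii, 2)
  mesh <- voxels_to_hex_mesh(vol, 0.3)
  el <- place_shafts(vol, 3, 6, seed = 5, depth_range_mm = c(18, 21),
                     inside_radius_mm = 25)
  plan <- make_stimulation_plan(el, 4, seed = 6,
                                max_midpoint_radius_mm = 18)
  list(radii = radii, vol = vol, mesh = mesh, electrodes = el, plan = plan,
       profile = conductivity_profile("4C"))
})

# end-to-end synthetic dataset on the 50 mm phantom (shared by processing,
# validation, and acceptance tests)
make_e2e <- function(seed, noise_sd_uv) {
  vol <- fix_vol50()
  el <- place_shafts(vol, 8, 10, seed = seed, inside_radius_mm = 50)
  plan <- make_stimulation_plan(el, 10, 2, seed = seed + 1L,
                                max_midpoint_radius_mm = 29)
  truth <- shell_model_for_profile(RADII_50, "5C")
  rec <- simulate_recording(el, plan, truth, pulse_model(),
                            noise_sd_uv = noise_sd_uv, seed = seed + 2L)
  list(vol = vol, electrodes = el, plan = plan, truth = truth, rec = rec)
}

fix_e2e_clean <- function() fixture("e2e_clean", function() make_e2e(100L, 0))

# analytic bipolar table matching a montage (ground truth, unit source)
analytic_table <- function(truth, electrodes, plan, montage) {
  pos <- contact_positions(electrodes)
  tab <- matrix(0, nrow(plan$pairs), nrow(montage),
                dimnames = list(plan$pairs$pair_id, montage$channel))
  for (k in seq_len(nrow(plan$pairs))) {
    pa <- pos[plan$pairs$anode[k], ]
    pc <- pos[plan$pairs$cathode[k], ]
    v <- analytic_dipole_potential(truth, (pa + pc) / 2, (pa - pc) * 1e-3,
                                   pos)
    names(v) <- rownames(pos)
    tab[k, ] <- v[montage$contact_a] - v[montage$contact_b]
  }
  tab
}

# FEM tables for several profiles on the shared 50 mm mesh
fem_tables <- function(profiles, electrodes, plan, montage,
                       rel_tol = 1e-8) {
  mesh <- fix_mesh50()
  lapply(profiles, function(p) {
    sys <- assemble_stiffness(mesh, p)
    simulate_potential_table(mesh, p, electrodes, plan, montage = montage,
                             rel_tol = rel_tol, system = sys)
  })
}
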