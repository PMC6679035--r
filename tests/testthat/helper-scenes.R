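# Shared synthetic scenes, built once per test session.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(name, builder) {
  if (is.null(.scene_cache[[name]])) .scene_cache[[name]] <- builder()
  .scene_cache[[name]]
}

# 30 disjoint 20 nm disks at 0.98 nm/px -- small and fast
scene_disks_small <- function() cached_scene("disks_small", function() {
  simulate_scene(scene_spec("sphere", list(family = "constant", value = 20),
                            particle_count = 30, fov_nm = 500, n_pixels = 512,
                            seed = 3))
})

# touching/slightly overlapping 20 x 30 nm ellipsoids in clusters
scene_ellipsoids <- function() cached_scene("ellipsoids", function() {
  simulate_scene(scene_spec("ellipsoid", list(family = "constant", value = 20),
                            aspect = 1.5, particle_count = 30, cluster_mean = 3,
                            overlap_fraction = 0.05, fov_nm = 700,
                            n_pixels = 700, seed = 11))
})

# irregular rods (15 x 45 nm stadiums) in clusters, finely sampled
scene_rods <- function() cached_scene("rods", function() {
  simulate_scene(scene_spec("rod", list(family = "constant", value = 15),
                            aspect = 3, particle_count = 18, cluster_mean = 3,
                            overlap_fraction = 0.08, fov_nm = 450,
                            n_pixels = 768, seed = 7))
})

baseline_params <- function(mode = "default", min_otb = 200, ...)
  detection_params(mode = mode, min_otb = min_otb, ...)
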