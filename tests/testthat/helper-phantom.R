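# Shared fixture builders. Everything is generated in code, seeded.

# one bright sphere in a darker background, the minimal segmentation world
sphere_world <- function(n = 32, radius = 8, bg = 50, fg = 150,
                         noise = 0, seed = 1) {
  make_phantom(phantom_spec(
    grid_shape = rep(n, 3),
    structures = list(list(label = 1L, shape = "sphere",
                           center = rep((n + 1) / 2, 3), radii = radius,
                           mean = fg)),
    background_mean = bg, noise_sigma = noise, seed = seed))
}

# nested-sphere brain-like phantom: CSF shell / GM shell / WM core inside an
# intracranial mask, class proportions of the same order of magnitude
three_class_phantom <- function(n = 64, means = c(40, 120, 200), sigma = 5,
                                seed = 1) {
  ctr <- rep((n + 1) / 2, 3)
  r_icc <- round(0.42 * n); r_gm <- round(0.34 * n); r_wm <- round(0.22 * n)
  ph <- make_phantom(phantom_spec(
    grid_shape = rep(n, 3),
    structures = list(
      list(label = 1L, shape = "sphere", center = ctr, radii = r_icc,
           mean = means[1]),                               # CSF shell
      list(label = 2L, shape = "sphere", center = ctr, radii = r_gm,
           mean = means[2]),                               # GM shell
      list(label = 3L, shape = "sphere", center = ctr, radii = r_wm,
           mean = means[3])),                              # WM core
    background_mean = 0, noise_sigma = sigma, seed = seed))
  ph$icc <- as.array(ph$labels) != 0
  ph
}

# two mirrored lateral spheres, labels 11 (left) / 12 (right)
lateral_world <- function(n = 32, radius = 6, seed = 1, noise = 0) {
  q <- round(n / 4)
  make_phantom(phantom_spec(
    grid_shape = rep(n, 3),
    structures = list(
      list(label = 11L, shape = "sphere", center = c(q + 1, (n + 1) / 2, (n + 1) / 2),
           radii = radius, mean = 150),
      list(label = 12L, shape = "sphere", center = c(n - q, (n + 1) / 2, (n + 1) / 2),
           radii = radius, mean = 150)),
    background_mean = 50, noise_sigma = noise, seed = seed))
}

deformed_sphere_library <- function(base, n_templates, amplitude = 2,
                                    smoothness = 8, noise = 5, seed = 1) {
  make_library(base$intensity, base$labels,
               deform_spec(n_templates, amplitude, smoothness, noise,
                           seed = seed))
}
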