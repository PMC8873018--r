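# Shared fixtures, all generated in code.

# tetrahedron in the package's 0-based triangle_text dialect
write_tetra_text <- function(path = tempfile(fileext = ".txt")) {
  writeLines(c(
    "v 1 1 1", "v 1 -1 -1", "v -1 1 -1", "v -1 -1 1",
    "f 0 1 2", "f 0 3 1", "f 0 2 3", "f 1 3 2"), path)
  path
}

single_triangle_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               rbind(c(1L, 2L, 3L)))
}

# small longitudinal dataset with known generating parameters
tiny_sim <- function(seed = 1, n = 15L, subdiv = 0L, ...) {
  simulate_dataset(simulation_config(
    mesh_subdivisions = subdiv,
    groups = c(control = n, case = n), seed = seed, ...))
}

# noiseless config: effectively zero random effects and residual noise
noiseless_config <- function(seed = 1, n = 8L, ...) {
  simulation_config(
    mesh_subdivisions = 0L, groups = c(control = n, case = n),
    random_sd = c(intercept = 0, slope = 0, cor = 0),
    residual_sd = 1e-12, sex_effect = 0,
    scanner_offsets = c(0, 0, 0), seed = seed, ...)
}

# convert a raw-age polynomial (c0, c1, c2) to centered-age coefficients
center_poly <- function(cf, center) {
  c(cf[1] + cf[2] * center + cf[3] * center^2,
    cf[2] + 2 * cf[3] * center,
    cf[3])
}

# independent flood-fill connected components (recursive, no shared code
# with the package implementation)
oracle_components <- function(vertices, adjacency) {
  remaining <- vertices
  comps <- list()
  while (length(remaining)) {
    comp <- remaining[1L]
    repeat {
      grow <- unique(unlist(adjacency[comp]))
      grow <- intersect(grow, remaining)
      new <- setdiff(grow, comp)
      if (!length(new)) break
      comp <- c(comp, new)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}
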