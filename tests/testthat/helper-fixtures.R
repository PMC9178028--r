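# shared fixtures, built in code and cached for the test run

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

unit_tetrahedron <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

# axis-aligned box (8 x 6 x 7 mm), closed, outward-oriented
box_mesh <- function(a = 8, b = 6, h = 7) {
  v <- as.matrix(expand.grid(x = c(0, a), y = c(0, b), z = c(0, h)))
  dimnames(v) <- NULL
  f <- rbind(c(1, 3, 2), c(2, 3, 4),  # bottom (z = 0)
             c(5, 6, 7), c(6, 8, 7),  # top
             c(1, 2, 5), c(2, 6, 5),  # y = 0
             c(3, 7, 4), c(4, 7, 8),  # y = b
             c(1, 5, 3), c(3, 5, 7),  # x = 0
             c(2, 4, 6), c(4, 8, 6))  # x = a
  tri_mesh(v, f)
}

small_arch <- function(seed = 4, crowding = "none")
  fixture(paste0("arch_", seed, "_", crowding),
          function() generate_arch(arch_config(crowding = crowding),
                                   seed = seed))

arch_curvature <- function(seed = 4)
  fixture(paste0("H_", seed), function() mean_curvature(small_arch(seed)$mesh))

# open cylindrical "tooth column" for margin-push success fixtures:
# reference crown = vertices with z >= z_ref; CCH = top - z_ref = 8 mm
# exactly; z grid step 0.4 so pushes of 1.6 / 2.0 / 2.4 mm land on rows
tooth_column <- function() {
  fixture("tooth_column", function() {
    mesh <- cylinder_surface(r = 3.5, h = 12, n_theta = 40, n_z = 31)
    frame <- structure(list(
      plane_point = c(0, 0, 12), normal = c(0, 0, 1),
      axes = tibble::tibble(position = 1L, md_axis = list(c(1, 0, 0)),
                            bl_axis = list(c(0, 1, 0)))),
      class = "occlusal_frame")
    list(mesh = mesh, frame = frame, z_ref = 4, cch = 8)
  })
}

column_region <- function(z_min) {
  which(tooth_column()$mesh$vertices[, 3] >= z_min - 1e-9)
}

# two disjoint labelled icospheres in one mesh
two_spheres <- function() {
  fixture("two_spheres", function() {
    s1 <- icosphere(1.5, 2)
    s2 <- icosphere(1.0, 2)
    s2$vertices <- sweep(s2$vertices, 2, c(6, 0, 0), "+")
    mesh <- tri_mesh(rbind(s1$vertices, s2$vertices),
                     rbind(s1$faces, s2$faces + n_vertices(s1)))
    labels <- label_map(c(rep(3L, n_vertices(s1)), rep(5L, n_vertices(s2))),
                        mesh)
    list(mesh = mesh, labels = labels, n1 = n_faces(s1), n2 = n_faces(s2))
  })
}

rotation_matrix <- function(yaw = 0.53, pitch = 0.31) {
  Rz <- rbind(c(cos(yaw), -sin(yaw), 0), c(sin(yaw), cos(yaw), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(pitch), -sin(pitch)),
              c(0, sin(pitch), cos(pitch)))
  Rz %*% Rx
}
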