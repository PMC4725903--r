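# ---- mesh / field / configuration writers -----------------------------------

#' Write a mesh (and optionally a solved field) as legacy ASCII VTK
#'
#' Unstructured-grid VTK with triangle cells; node boundary tags are stored
#' as an integer point scalar (0 interior, k > 0 protein k, -1 outer, -2
#' symmetry edge), and a solved field adds point scalars u and |grad u|.
#'
#' @param mesh \code{tri_mesh}.
#' @param path output file.
#' @param field optional \code{nodal_field} solved on this mesh.
#' @return path, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, field = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "msclattice membrane patch", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.12g %.12g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  tag <- integer(n)
  if (length(mesh$tags$outer)) tag[mesh$tags$outer] <- -1L
  if (length(mesh$tags$sym_x)) tag[mesh$tags$sym_x] <- -2L
  if (length(mesh$tags$sym_y)) tag[mesh$tags$sym_y] <- -2L
  for (k in seq_along(mesh$tags$protein)) tag[mesh$tags$protein[[k]]] <- k
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS boundary_tag int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", tag), con)
  if (!is.null(field)) {
    writeLines(c("SCALARS u double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.12g", field$u), con)
    writeLines(c("SCALARS grad_mag double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.12g", sqrt(field$ux^2 + field$uy^2)), con)
  }
  invisible(path)
}

#' Read a mesh written by \code{\link{write_mesh_vtk}}
#'
#' @param path VTK file.
#' @return list with \code{nodes}, \code{triangles}, \code{tag} (per-node
#'   integer boundary code) and, when present, \code{u}.
#' @export
read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  nodes <- do.call(rbind, lapply(ln[(ip + 1):(ip + n)], function(s)
    as.numeric(strsplit(trimws(s), " +")[[1]][1:2])))
  ic <- grep("^CELLS", ln)[1]
  m <- as.integer(strsplit(ln[ic], " ")[[1]][2])
  tris <- do.call(rbind, lapply(ln[(ic + 1):(ic + m)], function(s)
    as.integer(strsplit(trimws(s), " +")[[1]][2:4]) + 1L))
  it <- grep("SCALARS boundary_tag", ln)[1]
  tag <- as.integer(ln[(it + 2):(it + 1 + n)])
  iu <- grep("SCALARS u double", ln)
  u <- if (length(iu)) as.numeric(ln[(iu[1] + 2):(iu[1] + 1 + n)]) else NULL
  list(nodes = nodes, triangles = tris, tag = tag, u = u)
}

#' Write / read configurations as extended-XYZ-style text
#'
#' One frame: count line, comment line (box, pbc, seed), then one row per
#' protein: label x y omega state.
#'
#' @param config \code{particle_config}.
#' @param path output file.
#' @param append append as an additional trajectory frame.
#' @return path (write) or \code{particle_config} (read; last frame).
#' @export
write_xyz <- function(config, path, append = FALSE) {
  N <- n_proteins(config)
  box <- if (is.null(config$box)) c(NA, NA) else config$box
  hdr <- sprintf("box=%.9g,%.9g pbc=%d seed=%s", box[1], box[2],
                 as.integer(config$pbc),
                 ifelse(is.na(config$rng_seed), "NA", config$rng_seed))
  rows <- vapply(seq_len(N), function(i) {
    s <- config$shapes[[i]]
    sprintf("%s %.12g %.12g %.12g %s", s$label, config$pos[i, 1],
            config$pos[i, 2], s$omega, s$state)
  }, "")
  cat(c(sprintf("%d", N), hdr, rows), file = path, sep = "\n", append = append)
  invisible(path)
}

#' @rdname write_xyz
#' @param shape_registry named list mapping labels to \code{protein_shape}s
#'   (orientation is overridden per row on read).
#' @export
read_xyz <- function(path, shape_registry) {
  ln <- readLines(path)
  # last frame
  starts <- which(grepl("^[0-9]+$", ln))
  st <- starts[length(starts)]
  N <- as.integer(ln[st])
  hdr <- ln[st + 1]
  box <- as.numeric(strsplit(sub(".*box=([^ ]+).*", "\\1", hdr), ",")[[1]])
  pbc <- sub(".*pbc=([01]).*", "\\1", hdr) == "1"
  rows <- strsplit(ln[(st + 2):(st + 1 + N)], " +")
  labs <- vapply(rows, `[`, "", 1)
  pos <- t(vapply(rows, function(r) as.numeric(r[2:3]), numeric(2)))
  om <- vapply(rows, function(r) as.numeric(r[4]), 0)
  shapes <- lapply(seq_len(N), function(i) {
    sh <- shape_registry[[labs[i]]]
    if (is.null(sh)) stop("unknown species label ", labs[i])
    if (sh$s > 0) sh$omega <- wrap_angle(om[i], sector(sh$s))
    sh
  })
  particle_config(shapes, pos, box = if (any(is.na(box))) NULL else box,
                  pbc = pbc)
}

#' Append an energy record to a results CSV
#'
#' Columns: config_hash, tau, E. The hash is the md5 of the serialized
#' inputs, so identical runs land on identical rows.
#'
#' @param path CSV path (created with a header if absent).
#' @param config_hash identifying hash (see \code{\link{hash_of}}).
#' @param tau membrane tension, kBT/nm^2.
#' @param E energy, kBT.
#' @return path, invisibly.
#' @export
append_energy_csv <- function(path, config_hash, tau, E) {
  row <- data.frame(config_hash = config_hash, tau = tau, E = E)
  write.table(row, path, sep = ",", row.names = FALSE,
              col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}

#' Deterministic hash of an R object
#'
#' md5 of the canonical serialization; used for run manifests and result
#' keying.
#'
#' @param x any serializable object.
#' @return hex string.
#' @export
hash_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Write a run manifest
#'
#' JSON record sufficient to regenerate an output: configuration, seed,
#' package version, and input hashes.
#'
#' @param path output JSON path.
#' @param config serializable run configuration (named list).
#' @param seed RNG seed used.
#' @param inputs named list of objects whose hashes are recorded.
#' @return path, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = list()) {
  man <- list(package = "msclattice",
              version = as.character(utils::packageVersion("msclattice")),
              r_version = as.character(getRversion()),
              seed = seed, config = config,
              input_hashes = lapply(inputs, hash_of))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Deterministic test fixtures
#'
#' Writes small fixtures used by the test battery: a coarse annulus mesh
#' ("toy-mesh"), a random non-overlapping protein gas ("random-gas"), or a
#' pre-built lattice configuration ("lattice-seeded"). Byte-identical for a
#' given seed.
#'
#' @param kind fixture family.
#' @param dir output directory.
#' @param seed integer seed.
#' @param N protein count (gas / lattice kinds).
#' @return named character vector of written paths (with the generating
#'   objects as attribute "objects").
#' @export
fixture_generator <- function(kind = c("toy-mesh", "random-gas", "lattice-seeded"),
                              dir = tempdir(), seed = 1L, N = 16L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "toy-mesh") {
    cyl <- mscl_shape("cylinder", "closed")
    cfg <- particle_config(list(cyl), rbind(c(0, 0)))
    per <- contour_perimeter(cyl)
    m <- mesh_patch(cfg, "disc", h_near = per / 40, h_far = per / 10,
                    maxit = 20L)
    f <- file.path(dir, sprintf("toy_mesh_seed%d.vtk", seed))
    write_mesh_vtk(m, f)
    structure(c(mesh = f), objects = list(mesh = m))
  } else if (kind == "random-gas") {
    pent <- mscl_shape("pentamer", "closed")
    box <- rep(sqrt(N * shape_area(pent) / 0.2), 2)
    cfg <- random_gas(pent, N, box, seed = seed)
    f <- file.path(dir, sprintf("random_gas_seed%d.xyz", seed))
    write_xyz(cfg, f)
    structure(c(config = f), objects = list(config = cfg))
  } else {
    tet <- mscl_shape("tetramer", "closed")
    spec <- lattice_spec("square", d = 6, orientation = "face-on",
                         L = ceiling(sqrt(N)), N = N)
    cfg <- build_lattice(spec, tet)
    f <- file.path(dir, sprintf("lattice_seed%d.xyz", seed))
    write_xyz(cfg, f)
    structure(c(config = f), objects = list(config = cfg))
  }
}
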