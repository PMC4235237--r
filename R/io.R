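# Mesh I/O: VTK legacy ASCII unstructured grids (read + write) and Gmsh
# MSH 4.1 ASCII (read).  Legacy ASCII VTK is used as the on-disk exchange
# format because its byte output is stable and viewer support is universal.
#
# Conventions:
#  * tets are VTK cell type 10; face-set triangles are appended as cell
#    type 5 with their set id in CELL_DATA "faceset_id" (0 = not a face);
#  * region tags live in CELL_DATA "region" (-1 on face cells);
#  * node sets are 0/1 POINT_DATA arrays named "nodeset_<name>";
#  * VTK indices are 0-based on disk, converted to 1-based in memory;
#    Gmsh node tags are arbitrary and remapped to 1..n.

#' Read a tetrahedral mesh
#'
#' @param path file path.
#' @param format `"vtk"` (legacy ASCII unstructured grid) or `"gmsh"`
#'   (MSH 4.1 ASCII). Default guesses from the file extension.
#' @return A [tet_mesh()]. Any point-data / cell-data arrays present in a
#'   VTK file (other than the structural arrays above) are attached as
#'   `node_fields` / `elem_fields` list components.
#' @export
read_mesh <- function(path, format = c("auto", "vtk", "gmsh")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("msh", "gmsh")) "gmsh" else "vtk"
  }
  switch(format, vtk = read_mesh_vtk(path), gmsh = read_mesh_gmsh(path))
}

#' Write a mesh (with optional fields) as legacy ASCII VTK
#'
#' @param mesh a [tet_mesh()].
#' @param path output file path.
#' @param node_fields named list of per-node data: numeric vectors
#'   (SCALARS) or n x 3 matrices (VECTORS).
#' @param elem_fields named list of per-element data, same shapes.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, node_fields = list(), elem_fields = list()) {
  nn <- n_nodes(mesh); ne <- n_elems(mesh)
  for (nm in names(node_fields)) {
    len <- NROW(node_fields[[nm]])
    if (len != nn) stop(sprintf("node field '%s' has length %d, expected %d",
                                nm, len, nn))
  }
  for (nm in names(elem_fields)) {
    len <- NROW(elem_fields[[nm]])
    if (len != ne) stop(sprintf("element field '%s' has length %d, expected %d",
                                nm, len, ne))
  }
  fs_names <- names(mesh$face_sets)
  faces <- if (length(fs_names))
    do.call(rbind, mesh$face_sets[fs_names]) else matrix(0L, 0L, 3L)
  face_id <- rep(seq_along(fs_names),
                 vapply(mesh$face_sets[fs_names], nrow, integer(1)))
  nf <- nrow(faces)

  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  num <- function(x) formatC(x, format = "g", digits = 17)
  wl("# vtk DataFile Version 3.0")
  wl(paste0("orthobone mesh facesets:", paste(fs_names, collapse = ",")))
  wl("ASCII", "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", nn))
  wl(paste(num(mesh$nodes[, 1]), num(mesh$nodes[, 2]), num(mesh$nodes[, 3])))
  wl(sprintf("CELLS %d %d", ne + nf, 5L * ne + 4L * nf))
  wl(paste(4L, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
           mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L))
  if (nf)
    wl(paste(3L, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L))
  wl(sprintf("CELL_TYPES %d", ne + nf))
  wl(c(rep("10", ne), rep("5", nf)))
  wl(sprintf("CELL_DATA %d", ne + nf))
  wl("SCALARS region int 1", "LOOKUP_TABLE default")
  wl(c(as.character(mesh$region), rep("-1", nf)))
  if (nf) {
    wl("SCALARS faceset_id int 1", "LOOKUP_TABLE default")
    wl(c(rep("0", ne), as.character(face_id)))
  }
  for (nm in names(elem_fields)) {
    x <- elem_fields[[nm]]
    if (is.matrix(x)) {
      wl(sprintf("VECTORS %s double", nm))
      wl(c(paste(num(x[, 1]), num(x[, 2]), num(x[, 3])),
           if (nf) rep("0 0 0", nf)))
    } else {
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      wl(c(num(as.numeric(x)), if (nf) rep("0", nf)))
    }
  }
  wl(sprintf("POINT_DATA %d", nn))
  for (nm in names(mesh$node_sets)) {
    memb <- integer(nn)
    memb[mesh$node_sets[[nm]]] <- 1L
    wl(sprintf("SCALARS nodeset_%s int 1", nm), "LOOKUP_TABLE default")
    wl(as.character(memb))
  }
  for (nm in names(node_fields)) {
    x <- node_fields[[nm]]
    if (is.matrix(x)) {
      wl(sprintf("VECTORS %s double", nm))
      wl(paste(num(x[, 1]), num(x[, 2]), num(x[, 3])))
    } else {
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      wl(num(as.numeric(x)))
    }
  }
  invisible(path)
}

read_mesh_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L || !grepl("^# vtk DataFile", lines[1]))
    stop("not a legacy VTK file: ", path)
  title <- lines[2]
  if (toupper(trimws(lines[3])) != "ASCII")
    stop("only ASCII VTK files are supported")
  if (!grepl("UNSTRUCTURED_GRID", lines[4]))
    stop("only DATASET UNSTRUCTURED_GRID is supported")
  toks <- scan(text = paste(lines[-(1:2)], collapse = "\n"),
               what = character(), quiet = TRUE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function(k = 1L) {
    out <- toks[pos:(pos + k - 1L)]
    pos <<- pos + k
    out
  }
  expect <- function(word) {
    t <- take()
    if (toupper(t) != word) stop("expected ", word, ", found ", t)
  }
  # skip ASCII / DATASET UNSTRUCTURED_GRID tokens
  while (!is.na(peek()) && toupper(peek()) != "POINTS") pos <- pos + 1L
  expect("POINTS")
  nn <- as.integer(take()); take()   # dtype ignored
  pts <- matrix(as.numeric(take(3L * nn)), ncol = 3L, byrow = TRUE)
  expect("CELLS")
  nc <- as.integer(take()); ntok <- as.integer(take())
  cell_tok <- as.integer(take(ntok))
  expect("CELL_TYPES")
  nct <- as.integer(take())
  ctypes <- as.integer(take(nct))
  # unpack cells
  conn <- vector("list", nc)
  p <- 1L
  for (i in seq_len(nc)) {
    k <- cell_tok[p]
    conn[[i]] <- cell_tok[(p + 1L):(p + k)] + 1L
    p <- p + k + 1L
  }
  bad <- which(!(ctypes %in% c(10L, 5L)))
  if (length(bad))
    stop(sprintf("unsupported VTK cell type %d at cell %d (only tetrahedra and triangles are read)",
                 ctypes[bad[1]], bad[1]))
  is_tet <- ctypes == 10L
  tets <- do.call(rbind, conn[is_tet])
  tris <- if (any(!is_tet)) do.call(rbind, conn[!is_tet]) else NULL

  region <- NULL; faceset_id <- NULL
  node_fields <- list(); elem_fields <- list(); node_sets <- list()
  read_array <- function(n) {
    kind <- toupper(take())
    nm <- take()
    if (kind == "SCALARS") {
      take()                                    # dtype
      if (!is.na(peek()) && grepl("^[0-9]+$", peek())) take()  # numComp
      if (!is.na(peek()) && toupper(peek()) == "LOOKUP_TABLE") take(2L)
      list(name = nm, data = as.numeric(take(n)))
    } else if (kind == "VECTORS") {
      take()
      list(name = nm,
           data = matrix(as.numeric(take(3L * n)), ncol = 3L, byrow = TRUE))
    } else stop("unsupported data array kind: ", kind)
  }
  while (!is.na(peek())) {
    sect <- toupper(take())
    if (sect == "CELL_DATA") {
      n <- as.integer(take())
      while (!is.na(peek()) && toupper(peek()) %in% c("SCALARS", "VECTORS")) {
        a <- read_array(n)
        if (a$name == "region") region <- as.integer(a$data)
        else if (a$name == "faceset_id") faceset_id <- as.integer(a$data)
        else elem_fields[[a$name]] <-
            if (is.matrix(a$data)) a$data[is_tet, , drop = FALSE]
            else a$data[is_tet]
      }
    } else if (sect == "POINT_DATA") {
      n <- as.integer(take())
      while (!is.na(peek()) && toupper(peek()) %in% c("SCALARS", "VECTORS")) {
        a <- read_array(n)
        if (grepl("^nodeset_", a$name))
          node_sets[[sub("^nodeset_", "", a$name)]] <- which(a$data != 0)
        else node_fields[[a$name]] <- a$data
      }
    } else stop("unexpected VTK section: ", sect)
  }
  if (is.null(region))
    stop("VTK file carries no CELL_DATA array 'region'; tag element regions before reading")
  face_sets <- list()
  if (!is.null(tris)) {
    ids <- faceset_id[!is_tet]
    fs_names <- strsplit(sub("^.*facesets:", "", title), ",")[[1]]
    fs_names <- fs_names[nzchar(fs_names)]
    for (k in seq_along(fs_names))
      face_sets[[fs_names[k]]] <- tris[ids == k, , drop = FALSE]
  }
  m <- tet_mesh(pts, tets, region = region[is_tet], node_sets = node_sets,
                face_sets = face_sets, fix_orientation = FALSE)
  if (length(node_fields)) m$node_fields <- node_fields
  if (length(elem_fields)) m$elem_fields <- elem_fields
  m
}

read_mesh_gmsh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sect <- function(name) {
    i0 <- which(lines == paste0("$", name))
    i1 <- which(lines == paste0("$End", name))
    if (!length(i0)) return(NULL)
    lines[(i0[1] + 1L):(i1[1] - 1L)]
  }
  fmt <- sect("MeshFormat")
  if (is.null(fmt)) stop("not a Gmsh MSH file: ", path)
  ver <- as.numeric(strsplit(trimws(fmt[1]), "\\s+")[[1]][1])
  if (ver < 4.0) stop("only MSH 4.x ASCII is supported (found ", ver, ")")

  nodes_sec <- sect("Nodes")
  toks <- as.numeric(scan(text = paste(nodes_sec, collapse = "\n"),
                          what = character(), quiet = TRUE))
  p <- 1L
  nblk <- toks[p]; nn <- toks[p + 1L]; p <- p + 4L
  tag <- numeric(nn); xyz <- matrix(0, nn, 3L); got <- 0L
  for (b in seq_len(nblk)) {
    nb <- toks[p + 3L]; p <- p + 4L
    if (nb > 0) {
      idx <- got + seq_len(nb)
      tag[idx] <- toks[p:(p + nb - 1L)]; p <- p + nb
      xyz[idx, ] <- matrix(toks[p:(p + 3L * nb - 1L)], ncol = 3L,
                           byrow = TRUE)
      p <- p + 3L * nb
      got <- got + nb
    }
  }
  remap <- integer(max(tag))
  remap[tag] <- seq_len(nn)

  elems_sec <- sect("Elements")
  toks <- as.numeric(scan(text = paste(elems_sec, collapse = "\n"),
                          what = character(), quiet = TRUE))
  p <- 1L
  nblk <- toks[p]; p <- p + 4L
  tets <- list(); regions <- list(); tris <- list(); tri_ent <- list()
  n_per <- c(`1` = 2L, `2` = 3L, `3` = 4L, `4` = 4L, `15` = 1L)
  for (b in seq_len(nblk)) {
    ent <- toks[p + 1L]; etype <- toks[p + 2L]; nb <- toks[p + 3L]
    p <- p + 4L
    npe <- n_per[as.character(etype)]
    if (is.na(npe))
      stop("unsupported Gmsh element type ", etype,
           " (only points, lines, triangles, tetrahedra)")
    blk <- matrix(toks[p:(p + nb * (npe + 1L) - 1L)], ncol = npe + 1L,
                  byrow = TRUE)
    p <- p + nb * (npe + 1L)
    if (etype == 4) {
      tets[[length(tets) + 1L]] <- blk[, -1L, drop = FALSE]
      regions[[length(regions) + 1L]] <- rep(as.integer(ent), nb)
    } else if (etype == 2) {
      tris[[length(tris) + 1L]] <- blk[, -1L, drop = FALSE]
      tri_ent[[length(tri_ent) + 1L]] <- rep(as.integer(ent), nb)
    }
  }
  if (!length(tets)) stop("Gmsh file contains no tetrahedra")
  T1 <- do.call(rbind, tets)
  T1 <- matrix(remap[T1], ncol = 4L)
  region <- unlist(regions)
  face_sets <- list()
  if (length(tris)) {
    F1 <- matrix(remap[do.call(rbind, tris)], ncol = 3L)
    fe <- unlist(tri_ent)
    for (e in sort(unique(fe)))
      face_sets[[paste0("surface_", e)]] <- F1[fe == e, , drop = FALSE]
  }
  tet_mesh(xyz, T1, region = region, face_sets = face_sets)
}
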