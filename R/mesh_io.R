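#' Write a mesh to OFF or ASCII PLY
#'
#' PLY output can carry named per-vertex attributes (e.g. motion
#' components) as float properties.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output file ending in `.off` or `.ply`.
#' @param attributes Optional named list/data frame of per-vertex numeric
#'   attributes (PLY only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, attributes = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  if (grepl("\\.off$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
    writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  } else if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    attrs <- if (is.null(attributes)) list() else as.list(attributes)
    hdr <- c("ply", "format ascii 1.0",
             sprintf("comment structure %s", mesh$tag),
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             sprintf("property float %s", names(attrs)),
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con)
    vm <- cbind(v, do.call(cbind, attrs))
    writeLines(apply(format(vm, digits = 7, trim = TRUE), 1, paste,
                     collapse = " "), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  } else stop("unsupported mesh format (use .off or .ply)")
  invisible(path)
}

#' Read an OFF mesh
#'
#' @param path `.off` file path.
#' @param tag Structure tag for the resulting mesh.
#' @return A [surface_mesh()].
#' @export
read_mesh_off <- function(path, tag = "surface") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  stopifnot(trimws(lines[1]) == "OFF")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- do.call(rbind, lapply(lines[3:(2 + nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]][2:4]) + 1L))
  surface_mesh(vtx, fc, tag)
}
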