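#' Hippocampal subfield names and label codes
#'
#' The package's own 6-code label table for hippocampal subfields, ordered
#' along the transverse axis: subiculum, CA1-CA4 and dentate gyrus.
#'
#' @return named integer vector of label codes.
#' @export
subfield_codes <- function() {
  c(Subiculum = 1L, CA1 = 2L, CA2 = 3L, CA3 = 4L, CA4 = 5L, DG = 6L)
}

#' Paired inner/midthickness/outer subfield surfaces
#'
#' The geometric scaffold of all depth sampling: three triangulated surfaces
#' with one-to-one vertex correspondence (same vertex count and ordering) and
#' one subfield label per vertex. "Outer" is the stratum-oriens side of the
#' sheet, "inner" the stratum-radiatum side; the midthickness surface sits at
#' the equivolume depth between them.
#'
#' @param vertices_inner,vertices_mid,vertices_outer n x 3 matrices of
#'   world-mm vertex coordinates with index correspondence.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param labels length-n character vector of subfield names (see
#'   [subfield_codes()]).
#' @return an object of class `subfield_surface_set`.
#' @export
subfield_surface_set <- function(vertices_inner, vertices_mid, vertices_outer,
                                 triangles, labels) {
  vi <- as.matrix(vertices_inner); vm <- as.matrix(vertices_mid)
  vo <- as.matrix(vertices_outer)
  n <- nrow(vo)
  if (nrow(vi) != n || nrow(vm) != n)
    stop("vertex-count mismatch across surfaces: inner=", nrow(vi),
         " mid=", nrow(vm), " outer=", n)
  if (ncol(vi) != 3L || ncol(vm) != 3L || ncol(vo) != 3L)
    stop("vertex arrays must be n x 3")
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  if (any(triangles < 1L) || any(triangles > n))
    stop("triangle indices out of range [1, ", n, "]")
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("need one label per vertex: ", length(labels), " labels for ", n,
         " vertices")
  unknown <- setdiff(unique(labels), names(subfield_codes()))
  if (length(unknown) > 0L)
    stop("unknown subfield label(s): ", paste(unknown, collapse = ", "))
  thick <- sqrt(rowSums((vi - vo)^2))
  if (any(thick < 1e-12))
    warning(sum(thick < 1e-12), " vertex/vertices have zero thickness")
  structure(list(vertices_inner = vi, vertices_mid = vm, vertices_outer = vo,
                 triangles = triangles, labels = labels),
            class = "subfield_surface_set")
}

#' @export
print.subfield_surface_set <- function(x, ...) {
  cat("<subfield_surface_set> ", nrow(x$vertices_outer), " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Read a surface set from GIFTI files
#'
#' @param inner_path,mid_path,outer_path GIFTI geometry files (`.surf.gii`)
#'   with equal vertex counts.
#' @param label_path GIFTI label file (`.label.gii`).
#' @return a [subfield_surface_set].
#' @export
read_surface_set <- function(inner_path, mid_path, outer_path, label_path) {
  read_geom <- function(p) {
    arrs <- read_gifti_arrays(p)
    ints <- vapply(arrs, `[[`, character(1), "intent")
    pts <- arrs[[match("NIFTI_INTENT_POINTSET", ints)]]$data
    tri <- arrs[[match("NIFTI_INTENT_TRIANGLE", ints)]]$data + 1L
    list(vertices = pts, triangles = tri)
  }
  gi <- read_geom(inner_path); gm <- read_geom(mid_path)
  go <- read_geom(outer_path)
  counts <- c(inner = nrow(gi$vertices), mid = nrow(gm$vertices),
              outer = nrow(go$vertices))
  if (length(unique(counts)) != 1L)
    stop("vertex-count mismatch across surfaces: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  la <- read_gifti_arrays(label_path)
  codes <- as.integer(la[[1L]]$data)
  lt <- attr(la, "label_table")
  if (is.null(lt)) lt <- stats::setNames(names(subfield_codes()),
                                         subfield_codes())
  labels <- unname(lt[as.character(codes)])
  if (anyNA(labels))
    stop("label file contains unknown code(s): ",
         paste(unique(codes[is.na(labels)]), collapse = ", "))
  subfield_surface_set(gi$vertices, gm$vertices, go$vertices, go$triangles,
                       labels)
}

#' Write a surface set as GIFTI files
#'
#' @param surface a [subfield_surface_set].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return named character vector of the four written paths.
#' @export
write_surface_set <- function(surface, dir, prefix = "hippo") {
  stopifnot(inherits(surface, "subfield_surface_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(inner = file.path(dir, paste0(prefix, "_inner.surf.gii")),
             mid = file.path(dir, paste0(prefix, "_midthickness.surf.gii")),
             outer = file.path(dir, paste0(prefix, "_outer.surf.gii")),
             labels = file.path(dir, paste0(prefix, "_subfields.label.gii")))
  write_gifti_surface(surface$vertices_inner, surface$triangles, paths["inner"])
  write_gifti_surface(surface$vertices_mid, surface$triangles, paths["mid"])
  write_gifti_surface(surface$vertices_outer, surface$triangles, paths["outer"])
  sc <- subfield_codes()
  write_gifti_labels(sc[surface$labels],
                     stats::setNames(names(sc), sc), paths["labels"])
  paths
}
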