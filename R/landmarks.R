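#' Landmark configuration for one specimen
#'
#' A landmark configuration holds the ordered 2-D Cartesian coordinates of
#' `k` homologous landmarks digitized on one specimen (here, vein
#' intersections of an insect forewing), together with the specimen
#' identifier, an optional physical scale factor, and a flag recording
#' whether the coordinates have been mirrored (left/right reflected).
#'
#' Landmark order is positional and is never re-sorted: landmark homology
#' across specimens is the core assumption of the whole analysis.
#'
#' @param coords numeric k x 2 matrix of (x, y) coordinates, k >= 3, all
#'   finite, no two landmarks coincident.
#' @param specimen_id character scalar identifying the specimen.
#' @param scale optional positive scalar: physical units per coordinate unit
#'   (as recorded by a `SCALE=` line in a TPS file). Not applied to the
#'   coordinates; see [read_tps()].
#' @param mirrored logical: have the coordinates been reflected?
#' @return An object of class `landmark_config`.
#' @seealso [mirror_config()], [shape_dataset()], [read_tps()]
#' @export
#' @examples
#' cfg <- landmark_config(cbind(c(0, 2, 0), c(0, 0, 2)), "tri1")
#' cfg
landmark_config <- function(coords, specimen_id = "unknown", scale = NULL,
                            mirrored = FALSE) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L)
    stop("'coords' must be a numeric k x 2 matrix")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (nrow(coords) < 3L)
    stop("a landmark configuration needs at least 3 landmarks, got ",
         nrow(coords))
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in configuration '", specimen_id, "'")
  if (anyDuplicated(coords))
    stop("coincident landmarks in configuration '", specimen_id,
         "': all landmarks must be distinct points")
  if (!is.null(scale)) {
    scale <- as.numeric(scale)
    if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
      stop("'scale' must be a single positive number")
  }
  structure(
    list(specimen_id = as.character(specimen_id)[1L],
         coords = coords,
         scale = scale,
         mirrored = isTRUE(mirrored)),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration '", x$specimen_id, "': ",
      nrow(x$coords), " landmarks",
      if (x$mirrored) " (mirrored)", "\n", sep = "")
  cat("  centroid size:", format(centroid_size(x)), "\n")
  invisible(x)
}

#' Centroid size of a configuration
#'
#' The square root of the summed squared distances of the landmarks to their
#' centroid -- the standard size measure removed by Procrustes
#' superimposition.
#'
#' @param x a `landmark_config` or a k x 2 coordinate matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(x) {
  m <- config_coords(x)
  ctr <- colMeans(m)
  sqrt(sum(sweep(m, 2L, ctr)^2))
}

## Accept either a landmark_config or a bare k x 2 matrix.
config_coords <- function(x) {
  if (inherits(x, "landmark_config")) return(x$coords)
  m <- as.matrix(x)
  if (!is.numeric(m) || ncol(m) != 2L)
    stop("expected a landmark_config or a numeric k x 2 matrix")
  m
}

#' Mirror (reflect) a landmark configuration
#'
#' Negates the x-coordinates and toggles the `mirrored` flag. Applying it
#' twice returns the original configuration. Reference collections are
#' usually digitized on left wings; a fossil preserving the right wing must
#' be mirrored before superimposition, because the rotation-only Procrustes
#' fit deliberately does not absorb reflections.
#'
#' @param config a `landmark_config`.
#' @return the mirrored `landmark_config`.
#' @export
mirror_config <- function(config) {
  if (!inherits(config, "landmark_config"))
    stop("'config' must be a landmark_config")
  config$coords[, 1L] <- -config$coords[, 1L]
  config$mirrored <- !config$mirrored
  config
}

#' Collection of landmark configurations with taxon labels
#'
#' A shape dataset bundles configurations that share one landmark scheme
#' (identical `k`, same positional homology) with a table of hierarchical
#' taxon labels. The label table has one row per specimen and one column per
#' taxonomic level (e.g. `tribe`, `subgenus`); missing values mark levels at
#' which a specimen (such as a fossil "unknown") is unlabeled.
#'
#' @param configs list of `landmark_config` objects with unique specimen ids
#'   and identical landmark count.
#' @param labels optional data.frame with a `specimen_id` column plus one
#'   column per taxonomic level; rows are matched to configurations by id.
#' @param scheme_name character name of the landmark scheme (documents which
#'   digitization convention the coordinates follow).
#' @return An object of class `shape_dataset`.
#' @seealso [read_tps()], [read_labels()], [generate_dataset()]
#' @export
shape_dataset <- function(configs, labels = NULL,
                          scheme_name = "bee-forewing-18") {
  if (!is.list(configs) ||
      !all(vapply(configs, inherits, logical(1L), "landmark_config")))
    stop("'configs' must be a list of landmark_config objects")
  ids <- vapply(configs, function(c) c$specimen_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate specimen ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(configs)) {
    ks <- vapply(configs, function(c) nrow(c$coords), integer(1L))
    if (length(unique(ks)) > 1L)
      stop("inconsistent landmark counts across configurations: ",
           paste(sort(unique(ks)), collapse = ", "),
           " (all specimens analyzed together must share one scheme)")
  }
  if (!is.null(labels)) {
    labels <- as.data.frame(labels, stringsAsFactors = FALSE)
    if (!"specimen_id" %in% names(labels))
      stop("'labels' must contain a specimen_id column")
    labels$specimen_id <- as.character(labels$specimen_id)
    if (anyDuplicated(labels$specimen_id))
      stop("duplicate specimen_id rows in labels")
  }
  names(configs) <- ids
  structure(list(configs = configs, labels = labels,
                 scheme_name = scheme_name),
            class = "shape_dataset")
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat("Shape dataset (scheme '", x$scheme_name, "'): ",
      length(x$configs), " specimens",
      if (length(x$configs)) paste0(", k = ", landmark_count(x)),
      "\n", sep = "")
  if (!is.null(x$labels)) {
    lv <- setdiff(names(x$labels), "specimen_id")
    cat("  label levels:", paste(lv, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.shape_dataset <- function(x) length(x$configs)

#' Number of landmarks in a dataset's scheme
#' @param x a `shape_dataset`.
#' @return integer k.
#' @export
landmark_count <- function(x) {
  stopifnot(inherits(x, "shape_dataset"))
  if (!length(x$configs)) return(0L)
  nrow(x$configs[[1L]]$coords)
}

#' Specimen identifiers of a dataset
#' @param x a `shape_dataset`.
#' @return character vector.
#' @export
specimen_ids <- function(x) {
  stopifnot(inherits(x, "shape_dataset"))
  vapply(x$configs, function(c) c$specimen_id, character(1L))
}

#' Extract the grouping labels at one taxonomic level
#'
#' @param x a `shape_dataset` with a label table.
#' @param level character: name of a label column (e.g. `"tribe"`).
#' @param require_complete error if any specimen is unlabeled at this level.
#' @return character vector in specimen order (NA where unlabeled).
#' @export
taxon_labels <- function(x, level, require_complete = FALSE) {
  stopifnot(inherits(x, "shape_dataset"))
  labels_lookup(x$labels, specimen_ids(x), level, require_complete)
}

labels_lookup <- function(labels, ids, level, require_complete = FALSE) {
  if (is.null(labels)) stop("dataset has no label table")
  if (!level %in% names(labels))
    stop("no label level '", level, "'; available: ",
         paste(setdiff(names(labels), "specimen_id"), collapse = ", "))
  idx <- match(ids, labels$specimen_id)
  if (anyNA(idx))
    stop("specimens missing from label table: ",
         paste(ids[is.na(idx)], collapse = ", "))
  out <- as.character(labels[[level]])[idx]
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  if (require_complete && anyNA(out))
    stop("specimens unlabeled at level '", level, "': ",
         paste(ids[is.na(out)], collapse = ", "))
  out
}

#' Stack a dataset's coordinates into a k x 2 x n array
#' @param x a `shape_dataset`.
#' @return numeric array with specimen ids on the third dimension.
#' @export
coords_array <- function(x) {
  stopifnot(inherits(x, "shape_dataset"))
  k <- landmark_count(x)
  n <- length(x$configs)
  a <- array(NA_real_, c(k, 2L, n),
             dimnames = list(NULL, c("x", "y"), specimen_ids(x)))
  for (i in seq_len(n)) a[, , i] <- x$configs[[i]]$coords
  a
}

#' Subset a shape dataset by specimen
#' @param x a `shape_dataset`.
#' @param i index vector (logical, integer, or specimen ids).
#' @param ... ignored.
#' @return a `shape_dataset`.
#' @export
`[.shape_dataset` <- function(x, i, ...) {
  ids <- specimen_ids(x)
  if (is.character(i)) i <- match(i, ids)
  keep <- ids[i]
  labels <- x$labels
  if (!is.null(labels))
    labels <- labels[labels$specimen_id %in% keep, , drop = FALSE]
  shape_dataset(x$configs[i], labels, x$scheme_name)
}

#' The 18-landmark bee forewing scheme
#'
#' Documents the positional convention used for bee forewings with three
#' submarginal cells: 18 landmarks at vein intersections and cell corners,
#' digitized in a fixed order on left forewings. The scheme is a convention
#' of this package's data model; any dataset whose configurations follow one
#' consistent 18-point digitization order can use it.
#'
#' @return character vector of 18 short landmark descriptions, in landmark
#'   order.
#' @export
bee_forewing_scheme <- function() {
  c("base of marginal cell at pterostigma",
    "apex of marginal cell",
    "anterior junction 1rs-m / Rs",
    "posterior junction 1rs-m / M",
    "anterior junction 2rs-m / Rs",
    "posterior junction 2rs-m / M",
    "junction Rs+M split (1Rs base)",
    "junction 1M / 1Rs (basal vein apex)",
    "junction 1m-cu / M",
    "junction 1m-cu / Cu",
    "junction 2m-cu / M",
    "junction 2m-cu / Cu",
    "junction 1cu-a / Cu",
    "junction 1cu-a / A",
    "base of pterostigma at costal margin",
    "apex of pterostigma",
    "origin of Rs+M on M",
    "wing base at junction of M and Cu")
}
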