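#' @keywords internal
read_data_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read an interaction network from an edge list file
#'
#' Supports two dialects: `"tsv"` (two tab-separated identifier columns) and
#' `"sif"` (node, relation, node; the relation is ignored). Lines starting
#' with `#` and blank lines are skipped. The parsed network is normalized by
#' [protein_network()]: self-loops dropped, duplicate/reversed pairs merged,
#' with a message recording how many lines were affected.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"sif"`.
#' @param name Label for the network; defaults to the file name.
#' @param quiet Passed to [protein_network()].
#' @return A `protein_network`.
#' @export
read_edge_list <- function(path, format = c("tsv", "sif"), name = basename(path),
                           quiet = FALSE) {
  format <- match.arg(format)
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0L) stop(sprintf("no interactions in %s", path))
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  want <- if (format == "tsv") 2L else 3L
  bad <- which(lengths(fields) != want)
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: expected %d tab-separated fields, got %d",
                 dat$lineno[bad[1L]], path, want, lengths(fields)[bad[1L]]))
  }
  m <- do.call(rbind, fields)
  edges <- if (format == "tsv") m else m[, c(1L, 3L), drop = FALSE]
  protein_network(edges, name = name, quiet = quiet)
}

#' Write a network as a two-column TSV edge list
#'
#' Isolated nodes cannot be represented in an edge list and are omitted with
#' a warning.
#'
#' @param net A `protein_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  iso <- sum(lengths(net$adj) == 0L)
  if (iso > 0L) warning(sprintf("%d isolated protein(s) omitted from edge list", iso))
  lines <- sprintf("%s\t%s", net$nodes[net$edges[, 1L]], net$nodes[net$edges[, 2L]])
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene set (one identifier per line)
#'
#' Duplicates are collapsed. An empty file yields an empty set with a
#' warning rather than an error, so downstream analyses report zero overlaps.
#'
#' @param path Path to the file.
#' @param label Free-text label attached as an attribute.
#' @return Character vector of unique identifiers (class `gene_set`).
#' @export
read_gene_set <- function(path, label = basename(path)) {
  dat <- read_data_lines(path)
  ids <- unique(trimws(dat$lines))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) warning(sprintf("gene set %s is empty", path))
  structure(ids, label = label, class = c("gene_set", "character"))
}

#' @rdname read_gene_set
#' @param genes Character vector of identifiers.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(unique(as.character(genes)), path)
  invisible(path)
}

#' Read a protein complex catalog
#'
#' Two dialects: `"long"` (one `complex_id<TAB>member` row per membership)
#' and `"wide"` (`complex_id<TAB>memberA;memberB;...`). Overlapping
#' membership is preserved; a protein may belong to several complexes.
#'
#' @param path Path to the file.
#' @param format `"long"` or `"wide"`.
#' @return A `complex_catalog`: a named list mapping complex identifiers to
#'   character vectors of members. `length()` of the catalog is the total
#'   number of complexes N.
#' @export
read_complex_catalog <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  dat <- read_data_lines(path)
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: expected 2 tab-separated fields",
                 dat$lineno[bad[1L]], path))
  }
  m <- do.call(rbind, fields)
  if (format == "long") {
    cx <- lapply(split(m[, 2L], m[, 1L]), function(x) unique(x))
  } else {
    members <- strsplit(m[, 2L], ";", fixed = TRUE)
    cx <- lapply(members, function(x) unique(x[nzchar(x)]))
    names(cx) <- m[, 1L]
  }
  empty <- lengths(cx) == 0L
  if (any(empty)) {
    stop(sprintf("complex '%s' has no members after parsing", names(cx)[empty][1L]))
  }
  complex_catalog(cx)
}

#' Construct a complex catalog from a named list
#' @param complexes Named list of nonempty character vectors of members.
#' @return A `complex_catalog`.
#' @export
complex_catalog <- function(complexes) {
  stopifnot(is.list(complexes), length(names(complexes)) == length(complexes))
  if (any(lengths(complexes) == 0L)) stop("every complex must be nonempty")
  structure(lapply(complexes, function(x) unique(as.character(x))),
            class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat(sprintf("Complex catalog: %d complexes, %d distinct proteins, sizes %d-%d\n",
              length(x), length(unique(unlist(x))),
              min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' @rdname read_complex_catalog
#' @param catalog A `complex_catalog`.
#' @export
write_complex_catalog <- function(catalog, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    lines <- unlist(mapply(function(id, mem) sprintf("%s\t%s", id, mem),
                           names(catalog), catalog, SIMPLIFY = FALSE))
  } else {
    lines <- sprintf("%s\t%s", names(catalog),
                     vapply(catalog, paste, "", collapse = ";"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read COG-style functional class annotations
#'
#' Expects `protein<TAB>codes` rows where `codes` is a string of
#' single-character class letters (e.g. `"KLT"` for a protein annotated to
#' transcription, replication and signal transduction). A protein may carry
#' several codes.
#'
#' @param path Path to the file.
#' @return A `class_annotation`: a named list mapping protein identifiers to
#'   character vectors of single-letter codes.
#' @export
read_class_annotation <- function(path) {
  dat <- read_data_lines(path)
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: expected 2 tab-separated fields",
                 dat$lineno[bad[1L]], path))
  }
  m <- do.call(rbind, fields)
  codes <- lapply(strsplit(m[, 2L], ""), unique)
  names(codes) <- m[, 1L]
  if (any(lengths(codes) == 0L)) stop("annotation with empty class string")
  structure(codes, class = "class_annotation")
}

#' @rdname read_class_annotation
#' @param annotation A `class_annotation`.
#' @export
write_class_annotation <- function(annotation, path) {
  lines <- sprintf("%s\t%s", names(annotation),
                   vapply(annotation, paste, "", collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.class_annotation <- function(x, ...) {
  cat(sprintf("Class annotation: %d proteins, alphabet {%s}\n",
              length(x), paste(sort(unique(unlist(x))), collapse = "")))
  invisible(x)
}
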