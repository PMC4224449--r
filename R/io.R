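#' Read a genes-by-columns TSV matrix
#'
#' Reads a tab-separated matrix with a header row and row identifiers in the
#' first column (header `probe_id`, `gene_id` or similar).  Windows line
#' endings are tolerated.  Parsing is strict: ragged rows, duplicated row
#' identifiers and non-numeric cells raise errors naming the offending line.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with row and column names.
#' @seealso [write_matrix_tsv()]
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  if (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 2L) {
    stop("matrix file ", path, " has no data rows")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != nfield[1L])) {
    bad <- which(nfield != nfield[1L])[1L]
    stop("ragged row in ", path, " at line ", bad,
         " (expected ", nfield[1L], " fields, found ", nfield[bad], ")")
  }
  header <- fields[[1L]]
  ids <- vapply(fields[-1L], `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    bad <- which(duplicated(ids))[1L] + 1L
    stop("duplicate row id '", ids[bad - 1L], "' in ", path,
         " at line ", bad)
  }
  raw <- unlist(lapply(fields[-1L], `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals) && !anyNA(raw)) {
    bad_cell <- which(is.na(vals))[1L]
    bad_line <- (bad_cell - 1L) %/% (nfield[1L] - 1L) + 2L
    stop("non-numeric cell in ", path, " at line ", bad_line)
  }
  m <- matrix(vals, nrow = length(ids), byrow = TRUE,
              dimnames = list(ids, header[-1L]))
  m
}

#' Write a matrix as TSV
#'
#' Values are written with 17 significant digits so that a
#' write/read round trip is lossless to well below 1e-12.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name of the first (row identifier) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(x)
    paste(formatC(x, digits = 17, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description and members, tab-separated.
#' Duplicated members within a set are collapsed with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; each element carries the set
#'   description in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("GMT parse error in ", path, " at line ", i,
           ": fewer than 3 tab-separated fields")
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop("GMT parse error in ", path, " at line ", i, ": empty member list")
    }
    if (anyDuplicated(members)) {
      warning("duplicated members in set '", f[1L], "' collapsed")
      members <- unique(members)
    }
    sets[[f[1L]]] <- structure(members, description = f[2L])
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors (optionally with a
#'   `"description"` attribute per set).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction network from an edge list
#'
#' Accepts a two-column TSV (extra columns ignored) or the SIF dialect
#' (`node TAB relation TAB node`).  The result is a simple undirected
#' graph: self-loops and duplicate (including reversed) edges are dropped,
#' with the counts reported in graph attributes `n_self_loops` and
#' `n_duplicates`.
#'
#' @param path Path to the edge-list file.
#' @param sif Logical; `TRUE` to parse the SIF dialect (columns 1 and 3 are
#'   the endpoints).  Defaults to `TRUE` for files ending in `.sif`.
#' @return An [igraph::igraph] object with vertex names.
#' @export
read_edge_list <- function(path, sif = grepl("\\.sif$", path)) {
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  min_fields <- if (sif) 3L else 2L
  if (any(nfield < min_fields)) {
    bad <- which(nfield < min_fields)[1L]
    stop("edge list parse error in ", path, " at line ", bad,
         ": fewer than ", min_fields, " columns")
  }
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), if (sif) 3L else 2L)
  loops <- a == b
  a2 <- a[!loops]
  b2 <- b[!loops]
  key <- ifelse(a2 < b2, paste(a2, b2, sep = "\r"), paste(b2, a2, sep = "\r"))
  dup <- duplicated(key)
  g <- igraph::graph_from_edgelist(cbind(a2[!dup], b2[!dup]), directed = FALSE)
  g <- igraph::set_graph_attr(g, "n_self_loops", sum(loops))
  g <- igraph::set_graph_attr(g, "n_duplicates", sum(dup))
  g
}

#' Write an undirected network as a two-column edge-list TSV
#'
#' @param graph An igraph object with vertex names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Write a JSON provenance record next to an output file
#'
#' Records the producing stage, its parameters and seed so a stage can be
#' re-run from its sidecar alone.
#'
#' @param path Path of the output file the record describes; the sidecar is
#'   written to `paste0(path, ".prov.json")`.
#' @param stage Stage name.
#' @param params Named list of stage parameters.
#' @param seed Integer seed used by the stage (or `NULL`).
#' @return Sidecar path, invisibly.
#' @export
write_provenance <- function(path, stage, params = list(), seed = NULL) {
  rec <- list(stage = stage, output = basename(path), params = params,
              seed = seed,
              package_version = as.character(utils::packageVersion("fibronet")),
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  out <- paste0(path, ".prov.json")
  jsonlite::write_json(rec, out, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(out)
}
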