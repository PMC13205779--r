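# GMT gene-set collections.

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (set name -> member gene ids).
#'   Duplicate members within a set are removed; empty sets are an error.
#' @param provenance free-text origin note.
#' @return an object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, provenance = "") {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stopf("`sets` must be a nonempty named list")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stopf("empty gene set(s): %s", paste(empty, collapse = ", "))
  structure(list(sets = sets, provenance = provenance),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, %d unique genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a set are deduplicated; a memberless
#' set or an empty file is an error.
#'
#' @param path GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("no gene sets in '%s'", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, "", 1L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  empty <- nm[lengths(sets) == 0L]
  if (length(empty))
    stopf("gene set with zero members in '%s': %s", path,
          paste(empty, collapse = ", "))
  gene_set_collection(sets, provenance = path)
}

#' Write a gene-set collection as GMT
#' @param gsc a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "GeneSetCollection"))
  lines <- vapply(names(gsc$sets), function(nm)
    paste(c(nm, gsc$provenance, gsc$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

# Effective set sizes after intersecting with a measured-gene universe.
effective_set_sizes <- function(gsc, universe) {
  vapply(gsc$sets, function(s) length(intersect(s, universe)), 0L)
}
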