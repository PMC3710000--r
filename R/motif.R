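MOTIF_CLASSES <- c("oscillation", "adaptation", "bistable_switch", "custom")

#' Construct a query regulatory motif
#'
#' A motif is a small signed digraph (at most 6 nodes; built-ins use 1-3)
#' annotated with an identifier, a regulatory class, and an optional minimum
#' realized size. The minimum-size annotation marks compressed forms whose
#' dynamic behaviour requires the realized circuit in the original network to
#' span at least that many molecules (e.g. a compressed negative feedback
#' loop only oscillates when the underlying loop has three or more
#' components); it is enforced when instances are built, not during search.
#'
#' @param id motif identifier (non-empty string)
#' @param graph a [signed_digraph()], or anything `signed_digraph()` accepts
#'   as its `edges` argument
#' @param class regulatory class: `"oscillation"`, `"adaptation"`,
#'   `"bistable_switch"` or `"custom"`
#' @param min_size minimum number of distinct original-network nodes a
#'   realized instance must span, or `NA` for no constraint
#' @param note free-text provenance note
#' @return an object of class `regmotif_motif`
#' @examples
#' motif("neg_loop", data.frame(from = c("A", "B"), to = c("B", "A"),
#'                              sign = c(1, -1)), class = "oscillation")
#' @export
motif <- function(id, graph, class = "custom", min_size = NA, note = "") {
  class <- match.arg(class, MOTIF_CLASSES)
  if (!is_signed_digraph(graph)) graph <- signed_digraph(graph)
  k <- n_nodes(graph)
  if (k < 1L) rlang::abort("motif graph must have at least one node")
  if (k > MAX_MOTIF_SIZE) {
    rlang::abort(sprintf("motif '%s' has %d nodes; limit is %d", id, k, MAX_MOTIF_SIZE))
  }
  structure(list(id = as.character(id), regulatory_class = class, graph = graph,
                 min_size = if (is.na(min_size)) NA_integer_ else as.integer(min_size),
                 note = note),
            class = "regmotif_motif")
}

#' @export
print.regmotif_motif <- function(x, ...) {
  cat(sprintf("<motif %s> class=%s, %d nodes, %d edges%s\n", x$id,
              x$regulatory_class, n_nodes(x$graph), n_edges(x$graph),
              if (!is.na(x$min_size)) sprintf(", min realized size %d", x$min_size) else ""))
  invisible(x)
}

motif_size <- function(m) n_nodes(m$graph)

# Library = tibble(id, class, size, min_size, motif<list>); kept pairwise
# non-isomorphic by construction.
library_tibble <- function(motifs) {
  tibble::tibble(
    id = vapply(motifs, `[[`, character(1), "id"),
    class = vapply(motifs, `[[`, character(1), "regulatory_class"),
    size = vapply(motifs, motif_size, integer(1)),
    min_size = vapply(motifs, `[[`, integer(1), "min_size"),
    motif = motifs
  )
}

the <- new.env(parent = emptyenv())

load_builtin_library <- function() {
  if (!is.null(the$builtins)) return(the$builtins)
  dir <- system.file("extdata", "motifs", package = "regmotif")
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  motifs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    g <- read_network(file.path(dir, manifest$file[i]), on_conflict = "error")
    motifs[[i]] <- motif(manifest$id[i], g, class = manifest$class[i],
                         min_size = manifest$min_size[i],
                         note = "built-in compressed regulatory motif")
  }
  lib <- library_tibble(motifs)
  # the shipped set must be pairwise non-isomorphic; guard against data edits
  for (k in unique(lib$size)) {
    same <- lib$motif[lib$size == k]
    keys <- vapply(same, function(m) label_key(canonical_form(m$graph)), character(1))
    if (anyDuplicated(keys)) {
      rlang::abort("built-in motif data contains isomorphic duplicates")
    }
  }
  the$builtins <- lib
  lib
}

#' Built-in compressed regulatory motifs
#'
#' Returns the shipped library of compressed regulatory motif topologies in
#' pairwise non-isomorphic form, spanning the three classes established by
#' dynamical-modeling studies: oscillation (negative feedback loops and
#' their self-regulated variants), adaptation (negative feedback with a
#' buffer node; incoherent feedforward with a proportioner node) and
#' bistable switch (positive feedback via autocatalysis, mutual activation
#' or mutual inhibition, singly and coupled). Motifs are stored as plain
#' edge-list files under `system.file("extdata", "motifs", package =
#' "regmotif")` so the set can be extended without code changes.
#'
#' @param class optional filter: `"oscillation"`, `"adaptation"` or
#'   `"bistable_switch"` (alias `"bistable"`)
#' @return a motif-library tibble with columns `id`, `class`, `size`,
#'   `min_size` and a list-column `motif` of [motif()] objects
#' @examples
#' builtin_motifs("bistable_switch")
#' @export
builtin_motifs <- function(class = NULL) {
  lib <- load_builtin_library()
  if (is.null(class)) return(lib)
  if (identical(class, "bistable")) class <- "bistable_switch"
  if (!class %in% setdiff(MOTIF_CLASSES, "custom")) {
    rlang::abort(sprintf("unknown motif class '%s'", class))
  }
  lib[lib$class == class, , drop = FALSE]
}

#' Add a motif to a library, rejecting isomorphic duplicates
#'
#' Appends `m` unless an existing member of the same size is isomorphic to
#' it (signed, directed), in which case the library is returned unchanged
#' and the duplicate's id is reported via a message and the
#' `"duplicate_of"` attribute.
#'
#' @param lib a motif-library tibble ([builtin_motifs()] or an empty one)
#' @param m a [motif()]
#' @return the updated library tibble
#' @export
add_motif <- function(lib, m) {
  stopifnot(inherits(m, "regmotif_motif"))
  k <- motif_size(m)
  same <- lib[lib$size == k, , drop = FALSE]
  if (nrow(same) > 0) {
    key <- label_key(canonical_form(m$graph))
    for (i in seq_len(nrow(same))) {
      if (identical(key, label_key(canonical_form(same$motif[[i]]$graph)))) {
        message(sprintf("motif '%s' is isomorphic to existing motif '%s'; not added",
                        m$id, same$id[i]))
        attr(lib, "duplicate_of") <- same$id[i]
        return(lib)
      }
    }
  }
  attr(lib, "duplicate_of") <- NULL
  dplyr::bind_rows(lib, library_tibble(list(m)))
}

#' An empty motif library
#' @return a zero-row motif-library tibble
#' @export
empty_motif_library <- function() library_tibble(list())[0, ]

# Normalize "list of motifs or library tibble" arguments.
as_motif_list <- function(motifs) {
  if (inherits(motifs, "regmotif_motif")) return(list(motifs))
  if (is.data.frame(motifs)) return(motifs$motif)
  motifs
}
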