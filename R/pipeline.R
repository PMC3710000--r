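#' Identify regulatory motifs in a signaling network
#'
#' End-to-end analysis: (1) compress the network by node-based reduction;
#' (2) search the compressed network for induced occurrences of the
#' compressed query motifs, one path-tree/ESU pass per motif size; (3)
#' recover original-network paths for every matched edge; (4) instantiate
#' concrete regulatory motifs by selecting one path per edge, annotated
#' with per-edge sign and length and total size. With `compress = FALSE`
#' steps 1 and 3 are skipped and every instance path is a direct edge.
#'
#' @param network a validated [signed_digraph()]
#' @param motifs query motifs: a motif-library tibble (default
#'   [builtin_motifs()]) or list of [motif()]s
#' @param compress run the compression step (default `TRUE`)
#' @param protected node ids never eliminated by compression
#' @param max_path_len per-edge path length cap for expansion
#' @param allow_shared_internals see [instantiate_matches()]
#' @return an object of class `regmotif_report`: list with `instances`
#'   (tibble, one row per motif instance), `matches` (compressed-level
#'   matches), `counts` (per-motif match and instance counts),
#'   `compression` (a `compressed_network`, or `NULL`), and `config`
#' @examples
#' g <- read_network(c("A + B", "B + X", "X - A"))
#' analyze_network(g)
#' @export
analyze_network <- function(network, motifs = builtin_motifs(),
                            compress = TRUE, protected = character(),
                            max_path_len = 8L,
                            allow_shared_internals = FALSE) {
  stopifnot(is_signed_digraph(network))
  ml <- as_motif_list(motifs)
  if (length(ml) == 0) rlang::abort("`motifs` must be non-empty")
  ids <- vapply(ml, `[[`, character(1), "id")
  classes <- vapply(ml, `[[`, character(1), "regulatory_class")
  sizes <- vapply(ml, motif_size, integer(1))

  comp <- NULL
  searched <- network
  eliminated <- character(0)
  if (compress) {
    comp <- compress_network(network, protected = protected)
    searched <- comp$reduced
    eliminated <- comp$eliminated
  }

  match_list <- lapply(sort(unique(sizes)), function(k) {
    find_matches(searched, build_path_tree(ml[sizes == k], k))
  })
  matches <- dplyr::bind_rows(lapply(match_list, function(m) {
    tibble::as_tibble(m)
  }))
  if (nrow(matches) == 0) {
    matches <- tibble::tibble(motif_id = character(), nodes = list(),
                              matrix = list())
  }

  instances <- instantiate_matches(matches, network, eliminated = eliminated,
                                   motifs = ml, max_len = max_path_len,
                                   allow_shared_internals = allow_shared_internals)

  counts <- tibble::tibble(motif_id = ids, class = classes, size = sizes) %>%
    dplyr::left_join(dplyr::count(matches, .data$motif_id, name = "n_matches"),
                     by = "motif_id") %>%
    dplyr::left_join(dplyr::count(instances, .data$motif_id, name = "n_instances"),
                     by = "motif_id") %>%
    dplyr::mutate(n_matches = dplyr::coalesce(.data$n_matches, 0L),
                  n_instances = dplyr::coalesce(.data$n_instances, 0L))

  structure(list(
    instances = instances,
    matches = matches,
    counts = counts,
    compression = comp,
    config = list(compress = compress, protected = protected,
                  max_path_len = as.integer(max_path_len),
                  allow_shared_internals = allow_shared_internals,
                  motif_ids = ids)
  ), class = "regmotif_report")
}

#' @export
print.regmotif_report <- function(x, ...) {
  cat(sprintf("<regmotif_report> %d match(es), %d instance(s) of %d quer%s\n",
              nrow(x$matches), nrow(x$instances), length(x$config$motif_ids),
              if (length(x$config$motif_ids) == 1) "y" else "ies"))
  if (!is.null(x$compression)) print(x$compression)
  hit <- x$counts[x$counts$n_instances > 0, , drop = FALSE]
  if (nrow(hit) > 0) print(hit) else cat("no motif instances found\n")
  invisible(x)
}

#' @describeIn analyze_network tidy method: per-edge structural properties
#'   of all instances (see [structural_properties()])
#' @param x a `regmotif_report`
#' @param ... unused
#' @export
tidy.regmotif_report <- function(x, ...) structural_properties(x$instances)

#' @describeIn analyze_network glance method: one-row analysis summary
#' @export
glance.regmotif_report <- function(x, ...) {
  comp <- x$compression
  tibble::tibble(
    n_nodes = if (is.null(comp)) NA_integer_ else n_nodes(comp$original),
    n_nodes_reduced = if (is.null(comp)) NA_integer_ else n_nodes(comp$reduced),
    n_eliminated = length(if (is.null(comp)) character(0) else comp$eliminated),
    n_matches = nrow(x$matches),
    n_instances = nrow(x$instances),
    n_motifs_hit = sum(x$counts$n_instances > 0)
  )
}

#' All shortest directed paths between two nodes
#'
#' Returns every minimum-edge-count directed path from `source` to
#' `target`. By convention the path from a node to itself is the single
#' zero-length path `[source]`. An unreachable pair yields an empty list.
#'
#' @param network a [signed_digraph()]
#' @param source,target node ids present in the network
#' @return a list of character node sequences
#' @examples
#' g <- read_network(c("A + B", "B + D", "A + C", "C - D"))
#' shortest_paths_between(g, "A", "D")
#' @export
shortest_paths_between <- function(network, source, target) {
  missing <- setdiff(c(source, target), network$nodes)
  if (length(missing) > 0) {
    rlang::abort(paste0("unknown node(s): ", paste(missing, collapse = ", ")))
  }
  if (identical(source, target)) return(list(source))
  ig <- as_igraph(network)
  res <- suppressWarnings(
    igraph::all_shortest_paths(ig, from = source, to = target, mode = "out")
  )
  paths <- lapply(res$vpaths %||% res$res, function(p) igraph::as_ids(p))
  paths <- paths[vapply(paths, length, integer(1)) > 0]
  paths[order(vapply(paths, paste, character(1), collapse = "\r"))]
}

#' Path-constrained regulatory motif analysis
#'
#' Runs [analyze_network()] and keeps only the motifs that lie along the
#' shortest routes from `source` to `target`: the compressed-level match
#' nodes of a retained instance must all be on shortest paths. With
#' `path_scope = "union"` (default) membership is tested against the union
#' of nodes over all shortest paths; with `"single"` the match nodes must
#' fit within one individual shortest path. Compression protects `source`
#' and `target` so the endpoints survive into the compressed network.
#'
#' @inheritParams analyze_network
#' @param source,target endpoint node ids
#' @param path_scope `"union"` or `"single"` (see Details)
#' @return a `regmotif_report`; when `target` is unreachable from
#'   `source`, an empty report whose `notice` field says so
#' @export
analyze_path <- function(network, motifs = builtin_motifs(), source, target,
                         path_scope = c("union", "single"), compress = TRUE,
                         max_path_len = 8L, allow_shared_internals = FALSE) {
  path_scope <- match.arg(path_scope)
  paths <- shortest_paths_between(network, source, target)
  rep <- analyze_network(network, motifs, compress = compress,
                         protected = c(source, target),
                         max_path_len = max_path_len,
                         allow_shared_internals = allow_shared_internals)
  if (length(paths) == 0) {
    rep$instances <- rep$instances[0, , drop = FALSE]
    rep$matches <- rep$matches[0, , drop = FALSE]
    rep$counts$n_matches <- 0L
    rep$counts$n_instances <- 0L
    rep$notice <- sprintf("'%s' cannot reach '%s'; no path-constrained motifs", source, target)
    message(rep$notice)
    return(rep)
  }
  on_path <- if (path_scope == "union") {
    pool <- unique(unlist(paths))
    function(nodes) all(nodes %in% pool)
  } else {
    function(nodes) any(vapply(paths, function(p) all(nodes %in% p), logical(1)))
  }
  keep_inst <- vapply(rep$instances$match_nodes, on_path, logical(1))
  keep_match <- vapply(rep$matches$nodes, on_path, logical(1))
  rep$instances <- rep$instances[keep_inst, , drop = FALSE]
  rep$matches <- rep$matches[keep_match, , drop = FALSE]
  rep$counts <- rep$counts %>%
    dplyr::select(-"n_matches", -"n_instances") %>%
    dplyr::left_join(dplyr::count(rep$matches, .data$motif_id, name = "n_matches"),
                     by = "motif_id") %>%
    dplyr::left_join(dplyr::count(rep$instances, .data$motif_id, name = "n_instances"),
                     by = "motif_id") %>%
    dplyr::mutate(n_matches = dplyr::coalesce(.data$n_matches, 0L),
                  n_instances = dplyr::coalesce(.data$n_instances, 0L))
  rep$config$path <- list(source = source, target = target, scope = path_scope)
  rep
}

#' Write an analysis report to files
#'
#' Emits `<prefix>.instances.tsv` (flattened per-edge instance table),
#' `<prefix>.summary.json` (counts plus configuration echo) and, when
#' compression ran, `<prefix>.compressed.tsv` (reduced edge list with the
#' eliminated nodes as comments).
#'
#' @param report a `regmotif_report`
#' @param prefix output path prefix
#' @return invisibly, the paths written
#' @export
write_report <- function(report, prefix) {
  inst_path <- paste0(prefix, ".instances.tsv")
  utils::write.table(tidy(report), inst_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sum_path <- paste0(prefix, ".summary.json")
  jsonlite::write_json(list(counts = report$counts[, c("motif_id", "class", "n_matches", "n_instances")],
                            config = report$config,
                            notice = report$notice %||% ""),
                       sum_path, auto_unbox = TRUE, digits = NA)
  written <- c(inst_path, sum_path)
  if (!is.null(report$compression)) {
    comp_path <- paste0(prefix, ".compressed.tsv")
    con <- file(comp_path, "w")
    writeLines(paste0("# eliminated: ",
                      paste(report$compression$eliminated, collapse = " ")), con)
    write_network(report$compression$reduced, con)
    close(con)
    written <- c(written, comp_path)
  }
  invisible(written)
}
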