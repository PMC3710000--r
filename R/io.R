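#' Read a signed network from 3-column edge-list text
#'
#' Parses the standard signaling-network exchange format: one interaction per
#' line, whitespace- or tab-separated, with columns regulator, relation,
#' target. The relation is `"+"` (activation) or `"-"` (inhibition; the
#' Unicode minus `"−"` is also accepted). Lines starting with `#` and
#' blank lines are ignored. Duplicate identical edges collapse to one;
#' ordered pairs reported with both signs are handled by `on_conflict`.
#'
#' @param source a file path, a connection, or a character vector of lines
#' @param on_conflict `"drop"` (default) removes all edges of a pair seen
#'   with both signs; `"error"` aborts
#' @return a validated [signed_digraph()]
#' @examples
#' read_network(c("A + B", "B - C"))
#' @export
read_network <- function(source, on_conflict = c("drop", "error")) {
  on_conflict <- match.arg(on_conflict)
  lines <- if (is.character(source) && length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) rlang::abort("empty network input: no edge lines found")
  from <- character(length(idx)); rel <- character(length(idx)); to <- character(length(idx))
  for (j in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[j]]), "\\s+")[[1]]
    if (length(fields) < 3) {
      rlang::abort(sprintf("line %d: expected 3 columns (regulator relation target), got %d",
                           idx[j], length(fields)))
    }
    if (!fields[2] %in% c("+", "-", "−")) {
      rlang::abort(sprintf("line %d: unknown relation symbol '%s' (use + or -)",
                           idx[j], fields[2]))
    }
    from[j] <- fields[1]; rel[j] <- fields[2]; to[j] <- fields[3]
  }
  signed_digraph(data.frame(from = from, to = to,
                            sign = ifelse(rel == "+", 1L, -1L)),
                 on_conflict = on_conflict)
}

#' Write a signed network as 3-column edge-list text
#'
#' Inverse of [read_network()]: emits one `regulator<TAB>relation<TAB>target`
#' line per edge with ASCII `+`/`-` relation symbols. The format cannot
#' express isolated nodes; they are omitted with a warning.
#'
#' @param g a [signed_digraph()]
#' @param path file path or connection to write to
#' @return `g`, invisibly
#' @export
write_network <- function(g, path) {
  stopifnot(is_signed_digraph(g))
  isolated <- setdiff(g$nodes, unique(c(g$edges$from, g$edges$to)))
  if (length(isolated) > 0) {
    rlang::warn(paste0("edge-list format cannot express isolated node(s), omitting: ",
                       paste(isolated, collapse = ", ")))
  }
  lines <- sprintf("%s\t%s\t%s", g$edges$from,
                   ifelse(g$edges$sign == 1L, "+", "-"), g$edges$to)
  writeLines(lines, path)
  invisible(g)
}
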