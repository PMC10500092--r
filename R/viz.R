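# Tree rendering: indented text and DOT (Graphviz) export. Pure functions;
# summary formatting is fixed (3 significant digits) so snapshots stay
# stable.

.mt_fmt_summary <- function(model, nd) {
  parts <- vapply(seq_along(model$targets), function(j) {
    t <- model$targets[[j]]
    s <- nd$summary[[j]]
    switch(t$type,
      continuous = sprintf("%s=%s", t$name, signif(s$mean, 3)),
      categorical = sprintf("%s=%s (%s)", t$name, s$modal,
                            signif(max(s$prop), 3)),
      count = sprintf("%s: rate=%s", t$name, signif(s$rate, 3)),
      survival = sprintf("%s: rate=%s", t$name, signif(s$rate, 3)))
  }, "")
  paste(parts, collapse = ", ")
}

.mt_rule <- function(model, id) {
  nd <- model$nodes[[id]]
  parent <- NULL
  for (cand in model$nodes)
    if (!cand$is_leaf && id %in% cand$children) { parent <- cand; break }
  if (is.null(parent)) return("root")
  sp <- parent$split
  left <- parent$children[1] == id
  if (sp$kind == "numeric_threshold") {
    sprintf("%s %s %s", sp$feature, if (left) "<=" else ">",
            signif(sp$threshold, 3))
  } else {
    sprintf("%s %s %s", sp$feature, if (left) "=" else "!=", sp$level)
  }
}

#' Render a tree as indented text
#'
#' One line per node in pre-order, indented two spaces per depth level,
#' showing the incoming split rule, the node size, and the per-target
#' summaries rounded to 3 significant digits.
#'
#' @param model An `mttree`.
#' @param max_width Lines longer than this are truncated with `...`.
#' @return Character vector of lines.
#' @export
mt_render_text <- function(model, max_width = 120L) {
  stopifnot(inherits(model, "mttree"))
  lines <- character(0)
  walk <- function(id) {
    nd <- model$nodes[[id]]
    ln <- sprintf("%s[%d] %s | n=%d | %s",
                  strrep("  ", nd$depth), nd$id, .mt_rule(model, id),
                  nd$n, .mt_fmt_summary(model, nd))
    if (nchar(ln) > max_width)
      ln <- paste0(substr(ln, 1L, max_width - 3L), "...")
    lines[[length(lines) + 1L]] <<- ln
    if (!nd$is_leaf) for (ch in nd$children) walk(ch)
  }
  walk(1L)
  unlist(lines)
}

.mt_dot_escape <- function(s) gsub('"', '\\\\"', s)

#' Render a tree as DOT (Graphviz) text
#'
#' Emits a `digraph` with one box per node, labelled with its size, split
#' rule (internal nodes), and per-target summaries; edges are labelled with
#' the branch condition. The output parses under a standard DOT grammar and
#' can be piped to any Graphviz renderer.
#'
#' @param model An `mttree`.
#' @return A single string of DOT source.
#' @export
mt_render_dot <- function(model) {
  stopifnot(inherits(model, "mttree"))
  out <- c("digraph mttree {", "  node [shape=box];")
  for (nd in model$nodes) {
    head <- if (nd$is_leaf) sprintf("leaf %d", nd$id)
            else sprintf("%s %s", nd$split$feature,
                         if (nd$split$kind == "numeric_threshold")
                           sprintf("<= %s", signif(nd$split$threshold, 3))
                         else sprintf("= %s", nd$split$level))
    label <- sprintf("%s\\nn=%d\\n%s", head, nd$n,
                     .mt_dot_escape(.mt_fmt_summary(model, nd)))
    out <- c(out, sprintf('  n%d [label="%s"];', nd$id, label))
  }
  for (nd in model$nodes) {
    if (nd$is_leaf) next
    sp <- nd$split
    labs <- if (sp$kind == "numeric_threshold")
      c(sprintf("<= %s", signif(sp$threshold, 3)),
        sprintf("> %s", signif(sp$threshold, 3)))
    else c(sprintf("= %s", sp$level), "other")
    out <- c(out,
             sprintf('  n%d -> n%d [label="%s"];', nd$id, nd$children[1],
                     .mt_dot_escape(labs[1])),
             sprintf('  n%d -> n%d [label="%s"];', nd$id, nd$children[2],
                     .mt_dot_escape(labs[2])))
  }
  paste(c(out, "}"), collapse = "\n")
}
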