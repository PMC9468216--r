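#' Export a network structure in DOT format
#'
#' Writes the graph (structure only) in Graphviz DOT syntax. Works for DAGs,
#' CPDAGs (undirected edges rendered with `dir=none`) and fitted networks.
#'
#' @param x A [bn_dag()], [cpdag()] result, or `bn_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(x, path) {
  if (inherits(x, "bn_fit")) x <- x$dag
  lines <- c("digraph bn {")
  lines <- c(lines, paste0("  \"", x$nodes, "\";"))
  if (nrow(x$edges)) {
    directed <- if (inherits(x, "bn_cpdag")) x$edges$directed else rep(TRUE, nrow(x$edges))
    lines <- c(lines, paste0(
      "  \"", x$edges$from, "\" -> \"", x$edges$to, "\"",
      ifelse(directed, "", " [dir=none]"), ";"
    ))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export a fitted network in BIF-compatible text format
#'
#' Writes structure and conditional probability tables in the Bayesian
#' Interchange Format dialect understood by common BN toolkits: one
#' `variable` block per node (categories are the integer codes) and one
#' `probability` block per CPT, with parent configurations listed first
#' parent fastest.
#'
#' @param bn A `bn_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bif <- function(bn, path) {
  stopifnot(inherits(bn, "bn_fit"))
  fmt <- function(p) format(p, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c("network mmdbn {", "}")
  for (v in bn$dag$nodes) {
    codes <- bn$levels[[v]]
    lines <- c(lines,
      sprintf("variable %s {", v),
      sprintf("  type discrete [ %d ] { %s };", length(codes),
              paste(codes, collapse = ", ")),
      "}")
  }
  for (v in bn$dag$nodes) {
    f <- bn$cpts[[v]]
    pa <- f$vars[-1]
    k <- f$card[1]
    tab <- matrix(f$val, nrow = k)
    if (!length(pa)) {
      lines <- c(lines,
        sprintf("probability ( %s ) {", v),
        sprintf("  table %s;", paste(fmt(tab[, 1]), collapse = ", ")),
        "}")
    } else {
      head_line <- sprintf("probability ( %s | %s ) {", v, paste(pa, collapse = ", "))
      rows <- vapply(seq_len(ncol(tab)), function(j) {
        cfg <- vapply(seq_along(pa), function(i) {
          code <- bn$levels[[pa[i]]][grid_coord(f$card, i + 1)[1 + (j - 1) * k] + 1L]
          as.character(code)
        }, character(1))
        sprintf("  (%s) %s;", paste(cfg, collapse = ", "),
                paste(fmt(tab[, j]), collapse = ", "))
      }, character(1))
      lines <- c(lines, head_line, rows, "}")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export learned structure and CPTs as CSV files
#'
#' @param bn A `bn_fit`.
#' @param edges_path,cpts_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, a list with the written tibbles.
#' @export
write_network_csv <- function(bn, edges_path = NULL, cpts_path = NULL) {
  edges <- bn$dag$edges
  cpts <- tidy(bn)
  if (!is.null(edges_path)) readr::write_csv(edges, edges_path)
  if (!is.null(cpts_path)) readr::write_csv(cpts, cpts_path)
  invisible(list(edges = edges, cpts = cpts))
}
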